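#' A fluctuation experiment (plate-count table)
#'
#' @param cultures Data frame with columns `Nt` (final cell number),
#'   `plated` (cells plated) and `mutants` (resistant colony count); one
#'   row per independent culture.
#' @param condition Condition label.
#' @return An object of class `fluctuation_experiment`.
#' @export
fluctuation_experiment <- function(cultures, condition = "") {
  need <- c("Nt", "plated", "mutants")
  miss <- setdiff(need, names(cultures))
  if (length(miss)) stop("cultures lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(cultures$mutants < 0) || any(cultures$mutants != round(cultures$mutants)))
    stop("mutant counts must be non-negative integers")
  if (any(cultures$plated > cultures$Nt))
    stop("cannot plate more cells than grown")
  structure(list(cultures = cultures, condition = condition),
            class = "fluctuation_experiment")
}

#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Exact generative process (independent of the estimators): cultures
#' grow by doublings from `n0` to `nt`; at each generation the number of
#' newly arising mutants is binomial over the cells dividing, with
#' per-division mutation probability `rate`.  Each mutation is assigned
#' the time of its founding division within the doubling interval
#' (arrival density proportional to the growing population), and its
#' clone expands exponentially until sampling: a mutation in generation
#' `g` of `G` contributes `floor(2^(G-g+1) / (1 + U))` mutant cells,
#' `U ~ Uniform(0,1)`.  This forward process reproduces the classic
#' Luria-Delbruck clone-size law `P(k) = 1/(k(k+1))` exactly without
#' ever sampling the asymptotic count distribution.  Partial plating is
#' binomial thinning.
#'
#' @param rate Per-division mutation probability (< 1).
#' @param n0 Initial cells per culture.
#' @param nt Final cells per culture.
#' @param n_cultures Number of parallel cultures.
#' @param plated Cells plated per culture (default all of `nt`).
#' @param condition Label.
#' @param seed Optional integer seed.
#' @return A [fluctuation_experiment()].
#' @export
simulate_luria_delbruck <- function(rate, n0, nt, n_cultures,
                                    plated = nt, condition = "",
                                    seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (!(nt > n0 && n0 >= 1)) stop("need nt > n0 >= 1")
  .seed_if(seed)
  n_gen <- ceiling(log2(nt / n0))
  nt_eff <- n0 * 2^n_gen         # realized final size (whole doublings)
  plated <- min(plated, nt_eff)
  counts <- integer(n_cultures)
  for (cu in seq_len(n_cultures)) {
    mut <- 0
    pop <- n0
    for (g in seq_len(n_gen)) {
      new_mut <- stats::rbinom(1, round(pop), rate)
      if (new_mut > 0) {
        u <- stats::runif(new_mut)
        mut <- mut + sum(floor(2^(n_gen - g + 1) / (1 + u)))
      }
      pop <- pop * 2
    }
    counts[cu] <- if (plated < nt_eff)
      stats::rbinom(1, mut, plated / nt_eff) else mut
  }
  fluctuation_experiment(
    data.frame(culture_id = seq_len(n_cultures), Nt = nt_eff,
               plated = plated, mutants = counts),
    condition = condition)
}

#' Rate estimate container
#' @keywords internal
.rate_estimate <- function(rate, lo, hi, method, m = NA_real_) {
  structure(list(rate = rate, ci_low = lo, ci_high = hi, method = method,
                 m = m),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate %.3g [95%% CI %.3g - %.3g] (%s)\n",
              x$rate, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' p0-method mutation-rate estimate
#'
#' `rate = -ln(p0) / Nt` with `p0` the fraction of cultures without
#' mutants; the 95% CI is a Wilson interval on `p0` propagated through
#' the transform.  Partial plating is corrected by using the effective
#' number of cell divisions assayed, `Nt * plated / Nt = plated`.
#'
#' @param exp A [fluctuation_experiment()].
#' @return A `rate_estimate`.
#' @export
#' @examples
#' e <- fluctuation_experiment(data.frame(
#'   Nt = 1e8, plated = 1e8, mutants = c(rep(0, 14), rep(2, 6))))
#' estimate_rate_p0(e)   # -log(0.7) / 1e8
estimate_rate_p0 <- function(exp) {
  stopifnot(inherits(exp, "fluctuation_experiment"))
  cu <- exp$cultures
  n <- nrow(cu)
  z <- sum(cu$mutants == 0L)
  if (z == 0L)
    stop("no zero-mutant culture: the p0 method is inapplicable, ",
         "use estimate_rate_mle()")
  p0 <- z / n
  n_eff <- mean(cu$plated)       # divisions effectively assayed
  # Wilson interval on p0
  zq <- stats::qnorm(0.975)
  den <- 1 + zq^2 / n
  ctr <- (p0 + zq^2 / (2 * n)) / den
  hw <- zq * sqrt(p0 * (1 - p0) / n + zq^2 / (4 * n^2)) / den
  p_lo <- max(ctr - hw, 1e-12)
  p_hi <- min(ctr + hw, 1)
  rate <- -log(p0) / n_eff
  .rate_estimate(rate,
                 lo = -log(p_hi) / n_eff,
                 hi = -log(p_lo) / n_eff,
                 method = "p0", m = -log(p0))
}

#' Ma-Sandri-Sarkar probabilities of the Luria-Delbruck distribution
#'
#' `p0 = exp(-m)`; `p_k = (m / k) * sum_{i=0}^{k-1} p_i / (k - i + 1)`.
#'
#' @param m Expected number of mutations per culture.
#' @param kmax Highest count needed.
#' @return Numeric vector `p[0..kmax]` (length `kmax + 1`).
#' @export
mss_probs <- function(m, kmax) {
  p <- numeric(kmax + 1L)
  p[1] <- exp(-m)
  if (kmax >= 1L) {
    for (k in seq_len(kmax)) {
      i <- 0:(k - 1L)
      p[k + 1L] <- (m / k) * sum(p[i + 1L] / (k - i + 1L))
    }
  }
  p
}

# log-likelihood of observed counts given m, with plating efficiency eff.
# The MSS recursion is O(kmax^2); jackpot cultures (clone sizes in the
# 10^4-10^7 range) are therefore right-censored at `cap`: a count > cap
# contributes P(X > cap) = 1 - sum_{k<=cap} p_k.
.mss_loglik <- function(m, counts, eff = 1, cap = 128L) {
  kmax <- min(max(counts), cap)
  if (eff >= 1 - 1e-12) {
    p <- pmax(mss_probs(m, kmax), 1e-300)
    ll <- sum(log(p[counts[counts <= cap] + 1L]))
    n_cens <- sum(counts > cap)
    if (n_cens > 0L)
      ll <- ll + n_cens * log(max(1 - sum(p), 1e-300))
    return(ll)
  }
  # thinned likelihood: P_obs(k) = sum_j p_j * dbinom(k; j, eff)
  jmax <- max(50L, ceiling(kmax / eff + 10 * sqrt(kmax + 1) / eff))
  jmax <- min(jmax, 8192L)
  p <- pmax(mss_probs(m, jmax), 1e-300)
  j <- 0:jmax
  p_obs <- vapply(0:kmax, function(k)
    max(sum(p * stats::dbinom(k, j, eff)), 1e-300), numeric(1))
  ll <- sum(log(p_obs[counts[counts <= cap] + 1L]))
  n_cens <- sum(counts > cap)
  if (n_cens > 0L)
    ll <- ll + n_cens * log(max(1 - sum(p_obs), 1e-300))
  ll
}

#' Maximum-likelihood mutation-rate estimate (Ma-Sandri-Sarkar)
#'
#' MLE of the expected mutations per culture `m` under the
#' Luria-Delbruck distribution computed by the Ma-Sandri-Sarkar
#' recursion, with binomial-thinning correction for partial plating;
#' the 95% CI comes from the profile likelihood (chi-square 1 df).
#' The rate per cell division is `m / Nt`.
#'
#' @param exp A [fluctuation_experiment()] (>= 2 cultures).
#' @return A `rate_estimate`.
#' @export
estimate_rate_mle <- function(exp) {
  stopifnot(inherits(exp, "fluctuation_experiment"))
  cu <- exp$cultures
  if (nrow(cu) < 2L) stop("need at least 2 cultures")
  if (any(cu$mutants != round(cu$mutants))) stop("non-integer counts")
  counts <- as.integer(cu$mutants)
  nt <- mean(cu$Nt)
  eff <- mean(cu$plated / cu$Nt)

  if (all(counts == 0L)) {
    # degenerate: agrees with the p0 method's all-zero case
    n <- length(counts)
    m_hi <- -log(0.05) / n       # exact one-sided 95% bound on m
    return(.rate_estimate(0, 0, m_hi / (nt * eff), "mle", m = 0))
  }

  nll <- function(logm) -.mss_loglik(exp(logm), counts, eff)
  opt <- stats::optimize(nll, c(-12, 8))
  logm_hat <- opt$minimum
  m_hat <- exp(logm_hat)
  target <- opt$objective + stats::qchisq(0.95, 1) / 2

  bound <- function(side) {
    f <- function(lm) nll(lm) - target
    lo <- logm_hat
    hi <- logm_hat + side * 1
    for (i in 1:40) {
      if (f(hi) > 0) break
      hi <- hi + side * 1
    }
    if (f(hi) <= 0) return(exp(hi))
    exp(stats::uniroot(f, sort(c(lo, hi)))$root)
  }
  m_lo <- bound(-1)
  m_hi <- bound(+1)
  # the thinned likelihood estimates the whole-culture m directly, so
  # the per-division rate is m / Nt regardless of plating efficiency
  .rate_estimate(m_hat / nt, m_lo / nt, m_hi / nt, "mle", m = m_hat)
}

#' Fold change between two rate estimates
#'
#' Ratio `a / b` with a 95% CI by independent log-scale propagation of
#' each estimate's CI half-widths.
#'
#' @param a,b `rate_estimate` objects; `b$rate` must be positive.
#' @return List with `ratio`, `ci_low`, `ci_high`.
#' @export
fold_change <- function(a, b) {
  stopifnot(inherits(a, "rate_estimate"), inherits(b, "rate_estimate"))
  if (b$rate <= 0) stop("zero denominator rate")
  se_log <- function(x) {
    if (x$ci_low <= 0 || x$ci_high <= 0) return(NA_real_)
    (log(x$ci_high) - log(x$ci_low)) / (2 * stats::qnorm(0.975))
  }
  ratio <- a$rate / b$rate
  se <- sqrt(se_log(a)^2 + se_log(b)^2)
  if (is.na(se)) return(list(ratio = ratio, ci_low = NA_real_,
                             ci_high = NA_real_))
  hw <- stats::qnorm(0.975) * se
  list(ratio = ratio, ci_low = ratio * exp(-hw), ci_high = ratio * exp(hw))
}

#' Classify mutation events from dual-marker phenotypes
#'
#' Canavanine-resistant colonies are partitioned by their linked-marker
#' phenotype: simultaneous 5-FOA resistance and uracil auxotrophy marks
#' loss of the whole reporter cassette (gross chromosomal
#' rearrangement); 5-FOA sensitivity with uracil prototrophy marks a
#' point mutation; any other combination violates the marker logic and
#' is flagged inconsistent.
#'
#' @param phenotypes Data frame with columns `canavanine`
#'   (`"resistant"`/`"sensitive"`), `foa` (same levels) and `uracil`
#'   (`"prototroph"`/`"auxotroph"`).
#' @return The input with an added `event` column
#'   (`"GCR"`/`"point"`/`"inconsistent"`), plus a `table` attribute.
#' @export
classify_mutation_events <- function(phenotypes) {
  need <- c("canavanine", "foa", "uracil")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) stop("phenotypes lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(phenotypes$canavanine != "resistant"))
    stop("classification applies to canavanine-resistant colonies only")
  ev <- ifelse(phenotypes$foa == "resistant" &
                 phenotypes$uracil == "auxotroph", "GCR",
        ifelse(phenotypes$foa == "sensitive" &
                 phenotypes$uracil == "prototroph", "point",
               "inconsistent"))
  phenotypes$event <- ev
  attr(phenotypes, "table") <- table(factor(ev, c("GCR", "point",
                                                  "inconsistent")))
  phenotypes
}
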