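#' Calibrate the per-division cut probability
#'
#' Inverts the cumulative cut fraction `1 - (1 - q)^k` at the expected
#' number of divisions `k` reached `target_time_h` hours after galactose
#' addition, so that the simulated fraction of cut lineages matches the
#' experimentally measured cutting efficiency (80-90% of the uncut signal
#' converted within 6-9 h; default target 85% at the 7.5 h midpoint).
#'
#' @param target_fraction Cut fraction to reach, in (0, 1) (or exactly 1).
#' @param target_time_h Hours after galactose addition.
#' @param cdm A [cycle_duration_model()] (normal-cycle means set the
#'   division clock).
#' @param protocol A [protocol_timeline()].
#' @return The per-division cut probability `q_cut`.
#' @export
#' @examples
#' calibrate_cut_probability(0.85, 7.5)
calibrate_cut_probability <- function(target_fraction, target_time_h,
                                      cdm = default_cycle_model(),
                                      protocol = protocol_timeline()) {
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must be in (0, 1]")
  k <- expected_divisions(target_time_h, cdm, protocol)
  if (k < 1) stop("fit error: less than one division is expected within ",
                  target_time_h, " h; the target fraction is unreachable")
  if (target_fraction == 1) return(1)
  1 - (1 - target_fraction)^(1 / k)
}

#' Expected number of divisions within a window after galactose addition
#'
#' Piecewise over the medium schedule, using each medium's normal-cycle
#' mean as the division clock.
#'
#' @inheritParams calibrate_cut_probability
#' @param window_h Hours after galactose addition.
#' @return Expected division count (not rounded).
#' @export
expected_divisions <- function(window_h, cdm = default_cycle_model(),
                               protocol = protocol_timeline()) {
  t0 <- protocol$t_gal
  t1 <- t0 + window_h
  gal_h <- max(0, min(t1, protocol$t_raf) - t0)
  raf_h <- max(0, t1 - max(t0, protocol$t_raf))
  gal_h * 60 / cdm$media$galactose$normal_mean +
    raf_h * 60 / cdm$media$raffinose$normal_mean
}

#' Interpolated median of an integer sample
#'
#' Mid-distribution (continuity-corrected) median: integer values are
#' treated as bins `[x - 0.5, x + 0.5)` and the empirical CDF is
#' interpolated linearly.  For discrete generation counts the plain
#' median is quantized to steps of 0.5, which makes a squared-error fit
#' surface flat over wide parameter plateaus; the interpolated median is
#' a smooth location statistic for the same quantity.
#'
#' @param x Numeric (integer-valued) sample.
#' @return The interpolated median.
#' @export
interpolated_median <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tb <- table(x)
  v <- as.numeric(names(tb))
  cdf <- cumsum(tb) / length(x)
  i <- which(cdf >= 0.5)[1]
  lo <- if (i == 1L) 0 else cdf[i - 1L]
  unname(v[i] - 0.5 + (0.5 - lo) / (cdf[i] - lo))
}

#' Scan candidate threshold lengths against observed onset medians
#'
#' For each candidate value of the Type A threshold length, cohorts are
#' simulated for each observed condition and scored by the summed squared
#' error of the simulated median onset generation (interpolated median,
#' see [interpolated_median()]) against the observed medians.
#' Ties are broken toward the smallest candidate.
#'
#' @param observed_medians Named numeric vector or list, names are
#'   condition labels (e.g. `c(FC40 = 2.5, FC50 = 4, FC70 = 9)`).
#' @param candidates Candidate threshold lengths in bp (default
#'   `seq(20, 60, by = 1)`).
#' @param n_sims_per_candidate Lineages per condition per candidate.
#' @param seed Integer seed; every (candidate, condition) cohort derives
#'   its own stream from it.
#' @param params Baseline [senescence_params()] whose `ell_min_A` is
#'   replaced by each candidate.
#' @param ... Passed to [condition_bundle()] (e.g. `cdm`, `protocol`).
#' @return A `fit_result`: list with `best_threshold`,
#'   `loss_by_candidate` (named numeric), `medians` (matrix candidate x
#'   condition), `observed`, `n_sims`, `seed`.
#' @export
threshold_scan <- function(observed_medians, candidates = seq(20, 60, 1),
                           n_sims_per_candidate = 200, seed = NULL,
                           params = senescence_params(), ...) {
  observed <- unlist(observed_medians)
  if (length(candidates) < 1L) stop("empty candidate list")
  if (length(observed) < 1L) stop("no observed medians")
  conds <- names(observed)
  loss <- numeric(length(candidates))
  med <- matrix(NA_real_, length(candidates), length(conds),
                dimnames = list(as.character(candidates), conds))
  for (i in seq_along(candidates)) {
    p <- params
    p$ell_min_A <- candidates[i]
    for (cond in conds) {
      b <- condition_bundle(cond, params = p, ...)
      co <- simulate_cohort(n_sims_per_candidate, cond,
                            seed = derive_seed(seed,
                                               paste0(cond, "@", candidates[i])),
                            bundle = b)
      med[i, cond] <- co$summary$median_onset_interp
    }
    loss[i] <- sum((med[i, ] - observed)^2)
  }
  names(loss) <- as.character(candidates)
  ord <- order(loss, candidates)   # stable: smallest candidate on ties
  structure(list(best_threshold = candidates[ord[1]],
                 loss_by_candidate = loss, medians = med,
                 observed = observed,
                 n_sims = n_sims_per_candidate, seed = seed),
            class = "fit_result")
}

#' Tabulate a threshold-scan result
#'
#' @param fit A `fit_result` from [threshold_scan()].
#' @return A data.frame (one row per candidate, sorted by loss, ties by
#'   candidate value) with the loss and per-condition simulated medians.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  cand <- as.numeric(names(fit$loss_by_candidate))
  out <- data.frame(candidate_bp = cand, loss = unname(fit$loss_by_candidate))
  out <- cbind(out, as.data.frame(fit$medians))
  out[order(out$loss, out$candidate_bp), , drop = FALSE]
}

#' Ordered-lifespan envelope comparison
#'
#' Simulates `n_sims` cohorts of the same size as the observed lifespan
#' set, orders each simulated cohort's senescing-lineage lifespans, and
#' summarizes rank-wise the mean and the central 95% band, together with
#' the fraction of observed order statistics falling inside the band.
#'
#' @param observed_lifespans Numeric vector of observed lifespans
#'   (generations), senescing lineages only.
#' @param condition Condition label for the simulations.
#' @param n_sims Number of simulated cohorts (default 100).
#' @param seed Integer seed.
#' @param ... Passed to [condition_bundle()].
#' @return An `envelope_summary`: list with `rank_mean`, `lower`, `upper`
#'   (numeric vectors over the observed ranks), and `coverage`.
#' @export
envelope_compare <- function(observed_lifespans, condition = "noFC",
                             n_sims = 100, seed = NULL, ...) {
  obs <- sort(observed_lifespans)
  m <- length(obs)
  if (m < 1L) stop("observed lifespans must be non-empty")
  bundle <- condition_bundle(condition, ...)
  probs <- (seq_len(m) - 0.5) / m
  curves <- matrix(NA_real_, n_sims, m)
  for (s in seq_len(n_sims)) {
    co <- simulate_cohort(m, condition,
                          seed = derive_seed(seed, paste0("env", s)),
                          bundle = bundle)
    life <- co$per_lineage$lifespan_generations
    life <- sort(life[!is.na(life)])
    if (length(life) == 0L) life <- NA_real_
    curves[s, ] <- stats::quantile(life, probs = probs, type = 1,
                                   na.rm = TRUE, names = FALSE)
  }
  lower <- apply(curves, 2, stats::quantile, probs = 0.025, na.rm = TRUE)
  upper <- apply(curves, 2, stats::quantile, probs = 0.975, na.rm = TRUE)
  structure(list(rank_mean = colMeans(curves, na.rm = TRUE),
                 lower = lower, upper = upper,
                 coverage = mean(obs >= lower & obs <= upper),
                 n_sims = n_sims),
            class = "envelope_summary")
}
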