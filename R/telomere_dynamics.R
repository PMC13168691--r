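#' Telomere set of a single cell
#'
#' A cell carries a fixed number of telomeres (32 in budding yeast: 16
#' chromosomes, two ends each), each represented by the length in bp of its
#' TG(1-3) repeat tract.  One telomere may carry the inducible-endonuclease
#' construct ("finalcut" telomere): when the cut fires it is truncated to a
#' defined residual length and `cut_done` is set.
#'
#' @param lengths Non-negative integer vector of telomere lengths (bp).
#' @param finalcut_index Optional index (1-based) of the engineered
#'   telomere, or `NA` for strains without the construct.
#' @param cut_done Logical; has the cut already fired in this lineage?
#' @return An object of class `telomere_set`.
#' @export
telomere_set <- function(lengths, finalcut_index = NA_integer_,
                         cut_done = FALSE) {
  lengths <- as.integer(lengths)
  if (length(lengths) < 1L || anyNA(lengths) || any(lengths < 0L))
    stop("telomere lengths must be non-negative integers")
  if (!is.na(finalcut_index) &&
      (finalcut_index < 1L || finalcut_index > length(lengths)))
    stop("finalcut_index out of range")
  structure(
    list(lengths = lengths,
         finalcut_index = as.integer(finalcut_index),
         cut_done = isTRUE(cut_done)),
    class = "telomere_set")
}

#' @export
format.telomere_set <- function(x, ...) {
  sprintf("<telomere_set: %d telomeres, min %d bp, finalcut %s%s>",
          length(x$lengths), min(x$lengths),
          ifelse(is.na(x$finalcut_index), "none", x$finalcut_index),
          if (x$cut_done) " (cut)" else "")
}

#' @export
print.telomere_set <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Serialize a telomere set as a one-row tab-separated record
#'
#' Debugging dump: one column per telomere plus the construct index and cut
#' flag.
#'
#' @param ts A [telomere_set()].
#' @param path Optional path; if `NULL` the line is returned invisibly.
#' @return The TSV line, invisibly.
#' @export
write_telomere_set <- function(ts, path = NULL) {
  stopifnot(inherits(ts, "telomere_set"))
  hdr <- c(paste0("tel", seq_along(ts$lengths)), "finalcut_index", "cut_done")
  val <- c(ts$lengths, ts$finalcut_index, as.integer(ts$cut_done))
  txt <- paste(paste(hdr, collapse = "\t"),
               paste(val, collapse = "\t"), sep = "\n")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Overhang (per-division shortening) model
#'
#' The DNA end-replication problem: at each replication passage one
#' telomere out of two shortens, by the length of the 3' G-overhang, as
#' measured on the 3'-containing strand.  Per telomere and division this is
#' a coin with probability `shorten_prob` and, when it falls, a step drawn
#' from `step_support` with weights `step_probs`.  Single-molecule data
#' place the overhang at ~6-11 nt; the distribution over that range is not
#' observed, so the default is uniform on 6..11 (mean 8.5 nt, i.e. a
#' population rate of 4.25 bp per population doubling).
#'
#' @param step_support Positive integer step sizes (nt).
#' @param step_probs Probabilities, same length, summing to 1.
#' @param shorten_prob Per-division probability that a given telomere
#'   shortens (default 1/2: one sister out of two).
#' @return An object of class `overhang_model`.
#' @export
overhang_model <- function(step_support = 6:11,
                           step_probs = rep(1 / 6, 6),
                           shorten_prob = 0.5) {
  step_support <- as.integer(step_support)
  if (any(step_support < 0L)) stop("step sizes must be non-negative")
  if (length(step_probs) != length(step_support) || any(step_probs < 0) ||
      abs(sum(step_probs) - 1) > 1e-8)
    stop("step_probs must be non-negative and sum to 1")
  if (shorten_prob < 0 || shorten_prob > 1)
    stop("shorten_prob must be in [0, 1]")
  structure(list(step_support = step_support,
                 step_probs = as.numeric(step_probs),
                 shorten_prob = shorten_prob),
            class = "overhang_model")
}

#' Expected per-telomere shortening per division
#'
#' `shorten_prob * E[step]`; with defaults 0.5 * 8.5 = 4.25 bp/division,
#' inside the 3-5 bp band measured on telomere populations.
#'
#' @param om An [overhang_model()].
#' @return Expected bp lost per telomere per division.
#' @export
expected_shortening <- function(om) {
  stopifnot(inherits(om, "overhang_model"))
  om$shorten_prob * sum(om$step_support * om$step_probs)
}

#' Inducible cut model
#'
#' Cas9 under a galactose-driven promoter truncates the construct-bearing
#' telomere to `ell_cut` bp.  Modelled as acting at divisions: while the
#' division time lies in the window `[t_gal, t_noCut]`, an uncut lineage is
#' cut with probability `q_cut` per division (`t_noCut = t_raf + delay`
#' accounts for enzyme persistence after the carbon-source switch back to
#' raffinose).  `p_pre_replication` is the probability that the cleavage
#' precedes the passage of the replication fork over the telomere within
#' the cut division's cycle; telomeres replicate in late S phase, so the
#' default is 0.75.  Only when the cut precedes the fork can the freshly
#' cut end take part in that division's overhang-sized shortening.
#'
#' @param ell_cut Residual telomere length after the cut (bp).
#' @param q_cut Per-division cut probability; see
#'   [calibrate_cut_probability()].
#' @param t_gal Galactose addition time (h, from telomerase inactivation).
#' @param t_raf Return to raffinose (h); default `t_gal + 6`.
#' @param delay Enzyme persistence after `t_raf` (h); default 9.
#' @param p_pre_replication See description.
#' @return An object of class `cut_model`.
#' @export
cut_model <- function(ell_cut, q_cut = 0.45, t_gal = 6, t_raf = t_gal + 6,
                      delay = 9, p_pre_replication = 0.75) {
  if (ell_cut < 0) stop("ell_cut must be non-negative")
  if (q_cut < 0 || q_cut > 1) stop("q_cut must be in [0, 1]")
  if (!(t_gal < t_raf)) stop("need t_gal < t_raf")
  if (delay <= 0) stop("delay must be positive")
  structure(list(ell_cut = as.integer(ell_cut), q_cut = q_cut,
                 t_gal = t_gal, t_raf = t_raf, delay = delay,
                 t_noCut = t_raf + delay,
                 p_pre_replication = p_pre_replication),
            class = "cut_model")
}

#' Initialize a telomere set
#'
#' Native telomere lengths are drawn i.i.d. from a Gaussian (budding
#' yeast: ~300 +/- 75 bp) truncated below `min_bp` and rounded to
#' integer bp.  The default truncation is 1 bp (no negative lengths);
#' lineage simulations initialize cells leaving telomerase-positive
#' growth with `min_bp = 100`, because telomerase preferentially
#' elongates short telomeres and the steady state carries essentially no
#' telomere in the critically short range (see the methods vignette).
#'
#' @param n Number of telomeres (default 32).
#' @param mean_bp,sd_bp Gaussian location and spread (bp).
#' @param min_bp Lower truncation (bp), by redrawing.
#' @param finalcut_index Optional construct-bearing telomere index.
#' @param seed Optional integer seed.
#' @return A [telomere_set()].
#' @export
#' @examples
#' init_telomere_set(32, 300, 75, seed = 1)
init_telomere_set <- function(n = 32L, mean_bp = 300, sd_bp = 75,
                              min_bp = 1L, finalcut_index = NA_integer_,
                              seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (mean_bp <= 0) stop("mean_bp must be positive")
  if (sd_bp < 0) stop("sd_bp must be non-negative")
  .seed_if(seed)
  x <- round(stats::rnorm(n, mean_bp, sd_bp))
  while (any(x < min_bp)) {      # truncation by redrawing
    k <- which(x < min_bp)
    x[k] <- round(stats::rnorm(length(k), mean_bp, sd_bp))
  }
  telomere_set(x, finalcut_index = finalcut_index)
}

# vector of sampled steps, one per telomere (internal)
.sample_steps <- function(om, n) {
  if (length(om$step_support) == 1L) rep(om$step_support, n)
  else sample(om$step_support, n, replace = TRUE, prob = om$step_probs)
}

#' Apply one division of end-replication shortening
#'
#' Each telomere independently shortens by a sampled overhang step with
#' probability `om$shorten_prob`, else is transmitted unchanged; lengths
#' are floored at 0.  `shorten_prob_override` replaces the coin probability
#' for selected telomeres (used for the division at which the cut fires,
#' where the coin is scaled by `p_pre_replication`).
#'
#' @param ts A [telomere_set()].
#' @param om An [overhang_model()].
#' @param shorten_prob_override Optional named override: a numeric vector
#'   of per-telomere coin probabilities (length 1 or `length(ts$lengths)`).
#' @return The updated [telomere_set()].
#' @export
apply_division_shortening <- function(ts, om, shorten_prob_override = NULL) {
  stopifnot(inherits(ts, "telomere_set"), inherits(om, "overhang_model"))
  n <- length(ts$lengths)
  p <- if (is.null(shorten_prob_override)) rep(om$shorten_prob, n)
       else rep_len(shorten_prob_override, n)
  hit <- stats::runif(n) < p
  if (any(hit)) {
    steps <- .sample_steps(om, sum(hit))
    ts$lengths[hit] <- pmax(0L, ts$lengths[hit] - steps)
  }
  ts
}

#' Maybe fire the telomere cut at a division
#'
#' If the division occurs inside the cut window and the lineage is still
#' uncut, the construct telomere is truncated to `cm$ell_cut` with
#' probability `cm$q_cut`.  The cut fires at most once per lineage.
#'
#' @param ts A [telomere_set()] with a `finalcut_index`.
#' @param cm A [cut_model()].
#' @param t_now Division time in hours (from telomerase inactivation).
#' @return The (possibly cut) [telomere_set()], with attribute
#'   `"cut_now"` set to `TRUE` when the cut fired at this division.
#' @export
maybe_cut <- function(ts, cm, t_now) {
  stopifnot(inherits(ts, "telomere_set"), inherits(cm, "cut_model"))
  attr(ts, "cut_now") <- FALSE
  if (ts$cut_done) return(ts)
  if (t_now < cm$t_gal || t_now > cm$t_noCut) return(ts)
  if (is.na(ts$finalcut_index))
    stop("cut requested on a telomere set with no finalcut_index")
  if (stats::runif(1) < cm$q_cut) {
    ts$lengths[ts$finalcut_index] <- cm$ell_cut
    ts$cut_done <- TRUE
    attr(ts, "cut_now") <- TRUE
  }
  ts
}

#' Length of the shortest telomere
#'
#' The senescence-triggering covariate: the checkpoint responds to the
#' shortest telomere in the cell.
#'
#' @param ts A [telomere_set()].
#' @return Minimum length (bp).
#' @export
shortest <- function(ts) {
  stopifnot(inherits(ts, "telomere_set"))
  if (length(ts$lengths) == 0L) stop("empty telomere set")
  min(ts$lengths)
}
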