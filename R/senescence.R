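#' Senescence-model parameters
#'
#' Transition laws of the Type A / Type B senescence state machine, all
#' functions of the length `l` of the shortest telomere:
#'
#' * `p_sen_A(l)`: probability per division that a Type A (default-route)
#'   cell enters terminal arrest.  Default: logistic step
#'   `1 / (1 + exp((l - ell_min_A) / width_A))` with a small width, so the
#'   onset is driven by a near-deterministic threshold at `ell_min_A`
#'   (36 bp after recalibration on the cut-telomere cohorts).
#' * `p_nta(l)`: probability per division that a cycling cell undergoes a
#'   first non-terminal prolonged-cycle episode and converts to the Type B
#'   route.  Default: `min(1, nta_scale * exp(-l / nta_decay))`.
#' * `p_sen_B`: constant per-division probability of terminal arrest for
#'   Type B cells ("uniformly random" onset); in addition Type B cells
#'   remain subject to the deterministic threshold law, since the
#'   threshold scan applies to both routes.
#'
#' Terminal arrest comprises `terminal_arrest_range[1]`..`[2]` consecutive
#' extremely prolonged cycles followed by death.  `baseline_death_prob` is
#' the telomere-independent per-division death rate (0.5%).
#'
#' Defaults for `nta_scale`, `nta_decay` and `p_sen_B_const` are
#' calibrated (see the methods vignette) so that telomerase-negative
#' no-construct cohorts reproduce the two printed population anchors: a
#' Type B fraction in the 40-60% band and a median lifespan of ~30
#' generations.
#'
#' @param ell_min_A Threshold length centring the Type A law (bp).
#' @param width_A Logistic width (bp); small = near-deterministic.
#' @param nta_scale,nta_decay Parameters of `p_nta`.
#' @param p_sen_B_const Constant Type B onset probability per division.
#' @param terminal_arrest_range Integer pair: min and max consecutive
#'   terminal long cycles.
#' @param baseline_death_prob Per-division accidental death probability.
#' @return An object of class `senescence_params`.
#' @export
senescence_params <- function(ell_min_A = 36, width_A = 1,
                              nta_scale = 0.33, nta_decay = 40,
                              p_sen_B_const = 0.03,
                              terminal_arrest_range = c(2L, 4L),
                              baseline_death_prob = 0.005) {
  if (ell_min_A <= 0) stop("ell_min_A must be positive")
  if (width_A <= 0) stop("width_A must be positive")
  probs <- c(p_sen_B_const, baseline_death_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  terminal_arrest_range <- as.integer(terminal_arrest_range)
  if (length(terminal_arrest_range) != 2L ||
      terminal_arrest_range[1] < 1L ||
      terminal_arrest_range[1] > terminal_arrest_range[2])
    stop("terminal_arrest_range must be an increasing integer pair")
  structure(list(ell_min_A = ell_min_A, width_A = width_A,
                 nta_scale = nta_scale, nta_decay = nta_decay,
                 p_sen_B_const = p_sen_B_const,
                 terminal_arrest_range = terminal_arrest_range,
                 baseline_death_prob = baseline_death_prob),
            class = "senescence_params")
}

#' Type A senescence-onset law
#' @param ell Shortest-telomere length (bp), vectorized.
#' @param params A [senescence_params()].
#' @return Probability in `[0, 1]`, non-increasing in `ell`.
#' @export
p_sen_A <- function(ell, params) {
  stopifnot(inherits(params, "senescence_params"))
  if (any(ell < 0)) stop("ell must be non-negative")
  1 / (1 + exp((ell - params$ell_min_A) / params$width_A))
}

#' Type A to Type B conversion law (first non-terminal arrest)
#' @inheritParams p_sen_A
#' @return Probability in `[0, 1]`, non-increasing in `ell`.
#' @export
p_nta <- function(ell, params) {
  stopifnot(inherits(params, "senescence_params"))
  if (any(ell < 0)) stop("ell must be non-negative")
  pmin(1, params$nta_scale * exp(-ell / params$nta_decay))
}

#' Type B senescence-onset law (length-independent)
#' @inheritParams p_sen_A
#' @return Constant probability `p_sen_B_const`.
#' @export
p_sen_B <- function(ell, params) {
  stopifnot(inherits(params, "senescence_params"))
  rep(params$p_sen_B_const, length(ell))
}

#' Per-medium cell-cycle duration model
#'
#' For each growth medium: normal cycles are Gaussian, truncated to
#' `[min_duration, long_threshold)`; prolonged (checkpoint-arrest or
#' baseline-long) cycles are `long_threshold + Exponential(long_excess)`.
#' `long_threshold` is the classification cutoff (the empirical
#' mean + 2 SD of control datasets); `p_long_baseline` is the rate of
#' spontaneous long cycles in unlimited-proliferation controls.
#'
#' Use [calibrate_cycle_model()] to build a model whose generated control
#' datasets reproduce a target mean, SD and long fraction.
#'
#' @param media Named list; each element a list with `normal_mean`,
#'   `normal_sd`, `long_threshold`, `long_excess`, `p_long_baseline`.
#' @param min_duration Lower truncation of normal cycles (minutes).
#' @return An object of class `cycle_duration_model`.
#' @export
cycle_duration_model <- function(media, min_duration = 20) {
  need <- c("normal_mean", "normal_sd", "long_threshold", "long_excess",
            "p_long_baseline")
  for (m in names(media)) {
    miss <- setdiff(need, names(media[[m]]))
    if (length(miss)) stop("medium '", m, "' lacks: ",
                           paste(miss, collapse = ", "))
    if (media[[m]]$long_threshold <= media[[m]]$normal_mean)
      stop("long_threshold must exceed the normal-cycle location")
  }
  structure(list(media = media, min_duration = min_duration),
            class = "cycle_duration_model")
}

#' Calibrate a per-medium cycle model from dataset-level targets
#'
#' Control microfluidics datasets are summarized by their overall mean,
#' SD (hence the long-cycle threshold mean + 2 SD) and the fraction of
#' long cycles.  A single Gaussian cannot carry ~4% of its mass above its
#' own mean + 2 SD, so the dataset is modelled as a two-component mixture
#' (normal cycles + rare long cycles); this function solves the normal
#' component's location and spread by moment matching so that the mixture
#' reproduces the targets.
#'
#' @param target_mean,target_sd Dataset mean and SD (minutes).
#' @param long_frac Fraction of cycles above `target_mean + 2*target_sd`.
#' @param long_excess Mean excess above the threshold of long cycles
#'   (minutes; exponential).
#' @return A list suitable as one `media` entry of
#'   [cycle_duration_model()].
#' @export
#' @examples
#' calibrate_cycle_medium(145, 72.5, 0.043, 90)   # raffinose: threshold 290
#' calibrate_cycle_medium(140, 42, 0.042, 40)     # galactose: threshold 224
calibrate_cycle_medium <- function(target_mean, target_sd, long_frac,
                                   long_excess) {
  thr <- target_mean + 2 * target_sd
  long_mean <- thr + long_excess
  long_e2 <- long_excess^2 + long_mean^2        # E[X^2] of shifted exp
  mu_n <- (target_mean - long_frac * long_mean) / (1 - long_frac)
  e2 <- target_sd^2 + target_mean^2
  e2_n <- (e2 - long_frac * long_e2) / (1 - long_frac)
  var_n <- e2_n - mu_n^2
  if (var_n <= 1) stop("targets not reachable: normal-component variance ",
                       "collapses; reduce long_excess or long_frac")
  list(normal_mean = mu_n, normal_sd = sqrt(var_n), long_threshold = thr,
       long_excess = long_excess, p_long_baseline = long_frac)
}

#' Default cycle-duration model (raffinose / galactose / glucose)
#'
#' Raffinose: dataset mean 145 min, threshold 290 min, 4.3% long.
#' Galactose: mean 140 min, threshold 224 min, 4.2% long.  Glucose (used
#' only before telomerase inactivation and in bulk-culture contexts) is
#' given a conventional 90-min cycle.
#'
#' @return A [cycle_duration_model()].
#' @export
default_cycle_model <- function() {
  cycle_duration_model(list(
    raffinose = calibrate_cycle_medium(145, 72.5, 0.043, 90),
    galactose = calibrate_cycle_medium(140, 42, 0.042, 40),
    glucose = calibrate_cycle_medium(90, 25, 0.02, 40)))
}

#' Cell state of the lineage state machine
#'
#' @param telomeres A [telomere_set()].
#' @param lineage_type `"A"` (default route) or `"B"` (after a first
#'   non-terminal arrest).
#' @param nta_remaining Long cycles left in the current non-terminal
#'   episode (0 = cycling normally).
#' @param terminal_remaining Long cycles left in the terminal block
#'   (`NA` = senescence onset not reached).
#' @param alive Logical.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(telomeres, lineage_type = "A", nta_remaining = 0L,
                       terminal_remaining = NA_integer_, alive = TRUE) {
  stopifnot(inherits(telomeres, "telomere_set"),
            lineage_type %in% c("A", "B"))
  structure(list(telomeres = telomeres, lineage_type = lineage_type,
                 nta_remaining = as.integer(nta_remaining),
                 terminal_remaining = as.integer(terminal_remaining),
                 alive = isTRUE(alive)),
            class = "cell_state")
}

#' Sample one cell-cycle duration
#'
#' Normal cycles come from the truncated-Gaussian normal component;
#' arrested cycles (non-terminal episodes or terminal block) from the
#' long-cycle law, which always exceeds the medium's long threshold.
#'
#' @param arrested Logical: is this cycle a checkpoint arrest?
#' @param medium Medium name, must exist in `cdm`.
#' @param cdm A [cycle_duration_model()].
#' @return Duration in minutes.
#' @export
sample_cycle_duration <- function(arrested, medium, cdm) {
  stopifnot(inherits(cdm, "cycle_duration_model"))
  p <- cdm$media[[medium]]
  if (is.null(p)) stop("unknown medium: ", medium)
  if (arrested) return(p$long_threshold + stats::rexp(1, 1 / p$long_excess))
  repeat {
    d <- stats::rnorm(1, p$normal_mean, p$normal_sd)
    if (d >= cdm$min_duration && d < p$long_threshold) return(d)
  }
}

# Episode length of a non-terminal arrest: >= 1, geometric, mean 2.
.sample_nta_episode <- function() 1L + stats::rgeom(1, 0.5)

.sample_terminal_block <- function(range) {
  if (range[1] == range[2]) range[1]
  else sample(seq(range[1], range[2]), 1L)
}

#' Advance a cell by one cell cycle
#'
#' One step of the lineage state machine, at a birth (division) occurring
#' at time `t_now` hours:
#' 1. the cut may fire ([maybe_cut()]) if the division is in the window;
#' 2. end-replication shortening is applied ([apply_division_shortening()];
#'    at the division where the cut fires, the freshly cut telomere's coin
#'    is scaled by `cm$p_pre_replication`);
#' 3. transition laws are evaluated on the new shortest length to decide
#'    the nature of the cycle now beginning (normal, episode long, or
#'    terminal long), and its duration is sampled;
#' 4. baseline death and end-of-terminal-block death apply at the end of
#'    the cycle.
#'
#' @param state A [cell_state()]; must be alive.
#' @param params A [senescence_params()].
#' @param cdm A [cycle_duration_model()].
#' @param om An [overhang_model()]; `NULL` disables shortening
#'   (telomerase-positive control mode).
#' @param cm A [cut_model()]; `NULL` disables the cut.
#' @param t_now Birth time (hours from telomerase inactivation).
#' @param medium Medium name at `t_now`.
#' @param laws_enabled Set `FALSE` for the telomerase-positive control
#'   mode (only baseline death applies).
#' @return A list: `state` (updated [cell_state()]) and `cycle` (list with
#'   `duration_min`, `arrest_kind` in `"none"/"nta"/"terminal"`, `died`,
#'   `cut_now`).
#' @export
advance_cell <- function(state, params, cdm, om, cm = NULL, t_now,
                         medium, laws_enabled = TRUE) {
  stopifnot(inherits(state, "cell_state"))
  if (!state$alive) stop("cannot advance a dead cell")
  ts <- state$telomeres
  cut_now <- FALSE

  if (!is.null(cm) && !is.na(ts$finalcut_index)) {
    ts <- maybe_cut(ts, cm, t_now)
    cut_now <- isTRUE(attr(ts, "cut_now"))
  }
  if (!is.null(om)) {
    override <- NULL
    if (cut_now) {
      # the cut division leaves the construct telomere at exactly ell_cut
      # (the cut defines the length); end-replication shortening of the
      # cut end starts at the next division
      override <- rep(om$shorten_prob, length(ts$lengths))
      override[ts$finalcut_index] <- 0
    }
    ts <- apply_division_shortening(ts, om, shorten_prob_override = override)
  }
  state$telomeres <- ts
  ell <- shortest(ts)

  arrest_kind <- "none"
  if (!is.na(state$terminal_remaining)) {
    arrest_kind <- "terminal"
  } else if (state$nta_remaining > 0L) {
    arrest_kind <- "nta"
  } else if (laws_enabled) {
    if (state$lineage_type == "A") {
      if (stats::runif(1) < p_sen_A(ell, params)) {
        state$terminal_remaining <-
          .sample_terminal_block(params$terminal_arrest_range)
        arrest_kind <- "terminal"
      } else if (stats::runif(1) < p_nta(ell, params)) {
        state$lineage_type <- "B"
        state$nta_remaining <- .sample_nta_episode()
        arrest_kind <- "nta"
      }
    } else {                     # Type B: constant law + threshold law
      p_term <- 1 - (1 - p_sen_B(ell, params)) * (1 - p_sen_A(ell, params))
      if (stats::runif(1) < p_term) {
        state$terminal_remaining <-
          .sample_terminal_block(params$terminal_arrest_range)
        arrest_kind <- "terminal"
      } else if (stats::runif(1) < p_nta(ell, params)) {
        state$nta_remaining <- .sample_nta_episode()
        arrest_kind <- "nta"
      }
    }
  }

  duration <- sample_cycle_duration(arrest_kind != "none", medium, cdm)

  died <- FALSE
  if (arrest_kind == "terminal") {
    state$terminal_remaining <- state$terminal_remaining - 1L
    if (state$terminal_remaining <= 0L) died <- TRUE
  } else if (arrest_kind == "nta") {
    state$nta_remaining <- state$nta_remaining - 1L
  }
  # accidental death applies to cycling/episode cells; a terminal block
  # always runs its 2-4 long cycles to completion
  if (!died && arrest_kind != "terminal" &&
      stats::runif(1) < params$baseline_death_prob) died <- TRUE
  if (died) state$alive <- FALSE

  list(state = state,
       cycle = list(duration_min = duration, arrest_kind = arrest_kind,
                    died = died, cut_now = cut_now))
}
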