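#' Microfluidics protocol timeline
#'
#' Time 0 is telomerase inactivation (doxycycline).  Cells grow in
#' raffinose; galactose is added at `t_gal` for `t_raf - t_gal` hours to
#' induce the endonuclease, then the medium returns to raffinose.  The cut
#' can fire at divisions up to `t_noCut = t_raf + delay` (enzyme
#' persistence).  Recording stops at `horizon_h` (5 days).  The lineage
#' generation counter resets at galactose addition: the first cell born
#' under galactose has generation 0.
#'
#' @param t_gal Galactose addition (h); default 6.
#' @param t_raf Return to raffinose (h); default `t_gal + 6`.
#' @param delay Cut-window extension beyond `t_raf` (h); default 9.
#' @param horizon_h Experiment end (h); default 120.
#' @return An object of class `protocol_timeline`.
#' @export
protocol_timeline <- function(t_gal = 6, t_raf = t_gal + 6, delay = 9,
                              horizon_h = 120) {
  if (!(0 <= t_gal && t_gal < t_raf && t_raf < t_raf + delay))
    stop("inconsistent timeline: need 0 <= t_gal < t_raf < t_raf + delay")
  if (horizon_h <= t_raf) stop("horizon must exceed t_raf")
  structure(list(t_gal = t_gal, t_raf = t_raf, delay = delay,
                 t_noCut = t_raf + delay, horizon_h = horizon_h),
            class = "protocol_timeline")
}

#' Medium in effect at a given time
#' @param protocol A [protocol_timeline()].
#' @param t Hours from telomerase inactivation.
#' @return `"raffinose"` or `"galactose"`.
#' @export
medium_at <- function(protocol, t) {
  ifelse(t >= protocol$t_gal & t < protocol$t_raf, "galactose", "raffinose")
}

#' Long-cycle classification threshold
#'
#' Mean + 2 x SD (population SD) of a control set of cycle durations, the
#' procedure used to call prolonged cell cycles.
#'
#' @param control_durations Numeric vector of durations (minutes), n >= 2.
#' @return Threshold in minutes.
#' @export
#' @examples
#' compute_long_cycle_threshold(c(100, 120, 140))
compute_long_cycle_threshold <- function(control_durations) {
  n <- length(control_durations)
  if (n < 2L) stop("need at least 2 control durations")
  m <- mean(control_durations)
  sd_pop <- sqrt(sum((control_durations - m)^2) / n)
  m + 2 * sd_pop
}

#' Simulate one tracked lineage
#'
#' One mother line from telomerase inactivation to death or to the end of
#' the recording horizon.  Exactly one daughter is followed at each
#' division, so each telomere's inheritance is an independent coin under
#' the overhang model.
#'
#' @param params A [senescence_params()].
#' @param cdm A [cycle_duration_model()].
#' @param om An [overhang_model()] (`NULL` = no shortening).
#' @param cm A [cut_model()] (`NULL` = no cut construct).
#' @param protocol A [protocol_timeline()].
#' @param init Initial [telomere_set()]; default drawn by
#'   [init_telomere_set()] with the construct on telomere 1 when `cm` is
#'   given.
#' @param laws_enabled `FALSE` for the telomerase-positive control mode.
#' @param lineage_id Identifier stored in the record.
#' @return A `lineage_record`: list with `cycles` (data.frame: generation,
#'   t_start_h, duration_min, medium, arrest_kind, cut_now), `fate`
#'   (`"died"` or `"alive_at_end"`), plus `onset_generation`,
#'   `lifespan_generations` and `cut_done`.
#' @export
simulate_lineage <- function(params, cdm, om, cm = NULL,
                             protocol = protocol_timeline(),
                             init = NULL, laws_enabled = TRUE,
                             lineage_id = "L1") {
  if (is.null(init)) {
    # cells enter from telomerase-positive growth: homeostatic floor
    init <- init_telomere_set(
      min_bp = 100L,
      finalcut_index = if (is.null(cm)) NA_integer_ else 1L)
  }
  state <- cell_state(init)
  t <- 0
  gen0_t <- NA_real_             # birth time of generation 0
  t_start <- duration <- numeric(0)
  medium <- arrest <- character(0)
  cut_flag <- logical(0)
  fate <- "alive_at_end"
  fc_min_at_onset <- NA          # was the cut telomere the shortest at onset?
  post_cut_div <- post_cut_fc_min <- 0L

  while (t < protocol$horizon_h) {
    med <- medium_at(protocol, t)
    step <- advance_cell(state, params, cdm, om, cm, t_now = t,
                         medium = med, laws_enabled = laws_enabled)
    state <- step$state
    if (is.na(fc_min_at_onset) && step$cycle$arrest_kind == "terminal" &&
        !is.na(state$telomeres$finalcut_index)) {
      fc_min_at_onset <-
        state$telomeres$lengths[state$telomeres$finalcut_index] ==
          shortest(state$telomeres)
    }
    if (state$telomeres$cut_done) {
      post_cut_div <- post_cut_div + 1L
      if (state$telomeres$lengths[state$telomeres$finalcut_index] ==
            shortest(state$telomeres))
        post_cut_fc_min <- post_cut_fc_min + 1L
    }
    if (is.na(gen0_t) && t >= protocol$t_gal) gen0_t <- t
    t_start <- c(t_start, t)
    duration <- c(duration, step$cycle$duration_min)
    medium <- c(medium, med)
    arrest <- c(arrest, step$cycle$arrest_kind)
    cut_flag <- c(cut_flag, step$cycle$cut_now)
    t <- t + step$cycle$duration_min / 60
    if (!state$alive) { fate <- "died"; break }
  }

  n <- length(t_start)
  generation <- if (is.na(gen0_t)) {
    # never reached galactose (died first): all pre-window
    seq_len(n) - n - 1L
  } else {
    i0 <- which(t_start >= protocol$t_gal)[1]
    seq_len(n) - i0
  }
  cycles <- data.frame(
    lineage_id = lineage_id, generation = as.integer(generation),
    t_start_h = t_start, duration_min = duration, medium = medium,
    arrest_kind = arrest, cut_now = cut_flag,
    stringsAsFactors = FALSE)
  rec <- structure(
    list(cycles = cycles, fate = fate,
         cut_done = state$telomeres$cut_done,
         final_shortest = shortest(state$telomeres),
         final_finalcut_len = if (is.na(state$telomeres$finalcut_index))
           NA_integer_
         else state$telomeres$lengths[state$telomeres$finalcut_index],
         finalcut_min_at_onset = fc_min_at_onset,
         post_cut_divisions = post_cut_div,
         post_cut_fc_min_divisions = post_cut_fc_min,
         final_type = state$lineage_type),
    class = "lineage_record")
  rec$onset_generation <- senescence_onset_generation(rec)
  rec$lifespan_generations <- if (fate == "died") n else NA_integer_
  rec
}

# long flags for a record's cycles, via per-medium thresholds (internal)
.long_flags <- function(cycles, threshold_by_medium) {
  thr <- unlist(threshold_by_medium)[cycles$medium]
  cycles$duration_min > unname(thr)
}

#' Classify a lineage as Type A, Type B or none
#'
#' Type B: at least one prolonged-cycle episode is followed by a normal
#' cycle (reversible arrest).  Type A: the only prolonged cycles form the
#' terminal block before death.  None: no prolonged cycles at all.
#'
#' @param rec A `lineage_record` from [simulate_lineage()], or a
#'   data.frame of its `cycles`.
#' @param threshold_by_medium Named list/vector of long thresholds in
#'   minutes (e.g. `list(raffinose = 290, galactose = 224)`); `NULL` uses
#'   the recorded `arrest_kind` flags instead of durations.
#' @return `"A"`, `"B"` or `"none"`.
#' @export
classify_type <- function(rec, threshold_by_medium = NULL) {
  cycles <- if (inherits(rec, "lineage_record")) rec$cycles else rec
  if (nrow(cycles) < 1L) stop("record has no cycles")
  long <- if (is.null(threshold_by_medium)) cycles$arrest_kind != "none"
          else .long_flags(cycles, threshold_by_medium)
  if (!any(long)) return("none")
  # any long cycle later followed by a normal one?
  last_normal <- max(which(!long), 0L)
  if (any(which(long) < last_normal)) "B" else "A"
}

#' Generation of senescence onset
#'
#' The generation index (0 at galactose addition) of the first cycle of
#' the terminal prolonged-cycle block, i.e. the trailing run of long
#' cycles that ends in cell death.  `NA` for censored or non-senescent
#' (accidental-death) lineages.
#'
#' @inheritParams classify_type
#' @return Integer generation, or `NA`.
#' @export
senescence_onset_generation <- function(rec, threshold_by_medium = NULL) {
  cycles <- if (inherits(rec, "lineage_record")) rec$cycles else rec
  died <- if (inherits(rec, "lineage_record")) rec$fate == "died"
          else TRUE
  if (!died || nrow(cycles) == 0L) return(NA_integer_)
  long <- if (is.null(threshold_by_medium)) cycles$arrest_kind != "none"
          else .long_flags(cycles, threshold_by_medium)
  n <- length(long)
  if (!long[n]) return(NA_integer_)  # death not during a prolonged cycle
  first <- n
  while (first > 1L && long[first - 1L]) first <- first - 1L
  as.integer(cycles$generation[first])
}

#' Build the parameter bundle for a named experimental condition
#'
#' Conditions: `"control"` (telomerase-positive, no construct, transition
#' laws disabled), `"noFC"` (telomerase-negative, native telomeres only),
#' or `"FC<x>"` (telomerase-negative with the construct cut to x bp, e.g.
#' `"FC50"`).
#'
#' @param condition Condition label.
#' @param params,cdm,protocol Model components (defaults used if `NULL`).
#' @param q_cut Per-division cut probability; default calibrated by
#'   [calibrate_cut_probability()] against the 85% cut efficiency at
#'   7.5 h after galactose.
#' @param om An [overhang_model()].
#' @return List with elements `params`, `cdm`, `om`, `cm`, `protocol`,
#'   `laws_enabled`.
#' @export
condition_bundle <- function(condition, params = senescence_params(),
                             cdm = default_cycle_model(),
                             protocol = protocol_timeline(),
                             om = overhang_model(), q_cut = NULL) {
  cm <- NULL
  laws <- TRUE
  if (condition == "control") {
    om <- NULL
    laws <- FALSE
  } else if (condition == "noFC") {
    # nothing to add
  } else if (grepl("^FC[0-9]+$", condition)) {
    ell <- as.integer(sub("^FC", "", condition))
    if (is.null(q_cut))
      q_cut <- calibrate_cut_probability(0.85, 7.5, cdm, protocol)
    cm <- cut_model(ell, q_cut = q_cut, t_gal = protocol$t_gal,
                    t_raf = protocol$t_raf, delay = protocol$delay)
  } else stop("unknown condition: ", condition)
  list(params = params, cdm = cdm, om = om, cm = cm, protocol = protocol,
       laws_enabled = laws)
}

#' Simulate a cohort of lineages and summarize it
#'
#' Reproduces the microfluidics cohort analysis: simulate `n_lineages`
#' independent mother lines under a named condition, drop lineages that
#' arrested before galactose addition (as in the experimental analysis),
#' and summarize onset medians (among lineages actually senescing within
#' the horizon), type fractions and the death rate.
#'
#' @param n_lineages Number of lineages (>= 1).
#' @param condition See [condition_bundle()].
#' @param seed Optional integer seed.
#' @param bundle Optional pre-built [condition_bundle()] (overrides
#'   `condition` defaults).
#' @param ... Passed to [condition_bundle()].
#' @return List with `lineages` (data.frame of all cycles), `per_lineage`
#'   (one row per lineage: fate, type, onset, lifespan, cut_done) and
#'   `summary` (list of cohort statistics).
#' @export
simulate_cohort <- function(n_lineages, condition = "noFC", seed = NULL,
                            bundle = NULL, ...) {
  if (n_lineages < 1L) stop("n_lineages must be >= 1")
  .seed_if(seed)
  if (is.null(bundle)) bundle <- condition_bundle(condition, ...)
  thr <- lapply(bundle$cdm$media, `[[`, "long_threshold")

  cyc_list <- vector("list", n_lineages)
  per <- vector("list", n_lineages)
  kept <- 0L
  tried <- 0L
  while (kept < n_lineages && tried < 20L * n_lineages) {
    tried <- tried + 1L
    rec <- simulate_lineage(bundle$params, bundle$cdm, bundle$om,
                            bundle$cm, bundle$protocol,
                            laws_enabled = bundle$laws_enabled,
                            lineage_id = sprintf("L%04d", kept + 1L))
    pre_gal <- rec$cycles$generation < 0L
    if (any(pre_gal & rec$cycles$arrest_kind != "none")) next
    if (all(pre_gal)) next       # died before galactose: excluded
    kept <- kept + 1L
    cyc_list[[kept]] <- rec$cycles
    per[[kept]] <- data.frame(
      lineage_id = rec$cycles$lineage_id[1],
      fate = rec$fate,
      type = classify_type(rec, thr),
      onset_generation = rec$onset_generation,
      lifespan_generations = rec$lifespan_generations,
      cut_done = rec$cut_done,
      final_shortest = rec$final_shortest,
      final_finalcut_len = rec$final_finalcut_len,
      finalcut_min_at_onset = rec$finalcut_min_at_onset,
      post_cut_divisions = rec$post_cut_divisions,
      post_cut_fc_min_divisions = rec$post_cut_fc_min_divisions,
      stringsAsFactors = FALSE)
  }
  per_lineage <- do.call(rbind, per[seq_len(kept)])
  lineages <- do.call(rbind, cyc_list[seq_len(kept)])

  onset <- per_lineage$onset_generation
  summary <- list(
    condition = condition,
    n = kept,
    n_senescing = sum(!is.na(onset)),
    median_onset = stats::median(onset[!is.na(onset) & onset >= 0L]),
    median_onset_interp =
      interpolated_median(onset[!is.na(onset) & onset >= 0L]),
    median_lifespan = stats::median(per_lineage$lifespan_generations,
                                    na.rm = TRUE),
    frac_type_A = mean(per_lineage$type == "A"),
    frac_type_B = mean(per_lineage$type == "B"),
    frac_died = mean(per_lineage$fate == "died"),
    frac_cut = mean(per_lineage$cut_done))
  list(lineages = lineages, per_lineage = per_lineage, summary = summary)
}
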