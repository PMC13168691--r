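#' Convert a simulated cohort to the canonical lineage table
#'
#' Columns: `lineage_id`, `generation`, `duration_min`, `medium`,
#' `long_flag`, `arrest_kind`, `fate` -- the format written by the
#' simulator and read back by the analysis operations, so real
#' microfluidics exports can be converted in.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param threshold_by_medium Named list of long thresholds (minutes);
#'   `NULL` takes each medium's `long_threshold` from nothing and flags
#'   by recorded arrest kind.
#' @return A data.frame.
#' @export
as_lineage_table <- function(cohort, threshold_by_medium = NULL) {
  cyc <- cohort$lineages
  long <- if (is.null(threshold_by_medium)) cyc$arrest_kind != "none"
          else .long_flags(cyc, threshold_by_medium)
  fate <- cohort$per_lineage$fate[match(cyc$lineage_id,
                                        cohort$per_lineage$lineage_id)]
  data.frame(lineage_id = cyc$lineage_id, generation = cyc$generation,
             duration_min = cyc$duration_min, medium = cyc$medium,
             long_flag = long, arrest_kind = cyc$arrest_kind,
             fate = fate, stringsAsFactors = FALSE)
}

#' Generate control (unlimited-proliferation) lineages
#'
#' Telomerase-positive-like lineages: no telomere bookkeeping, cycle
#' durations from the calibrated per-medium mixture (normal cycles plus
#' spontaneous long cycles at the baseline rate), and accidental death
#' at 0.5% per division.
#'
#' @param n Number of lineages.
#' @param medium Medium name.
#' @param cdm A [cycle_duration_model()].
#' @param death_prob Per-division death probability.
#' @param horizon_h Recording horizon (hours).
#' @param seed Optional integer seed.
#' @return A lineage table (see [as_lineage_table()]).
#' @export
generate_control_lineages <- function(n, medium = "raffinose",
                                      cdm = default_cycle_model(),
                                      death_prob = 0.005, horizon_h = 120,
                                      seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  .seed_if(seed)
  p <- cdm$media[[medium]]
  if (is.null(p)) stop("unknown medium: ", medium)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t <- 0; dur <- numeric(0); long <- logical(0)
    died <- FALSE
    while (t < horizon_h) {
      is_long <- stats::runif(1) < p$p_long_baseline
      d <- sample_cycle_duration(is_long, medium, cdm)
      dur <- c(dur, d); long <- c(long, is_long)
      t <- t + d / 60
      if (stats::runif(1) < death_prob) { died <- TRUE; break }
    }
    rows[[i]] <- data.frame(
      lineage_id = sprintf("C%04d", i),
      generation = seq_along(dur) - 1L,
      duration_min = dur, medium = medium, long_flag = long,
      arrest_kind = ifelse(long, "baseline", "none"),
      fate = if (died) "died" else "alive_at_end",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a cut-telomere cohort with known ground truth
#'
#' Full lineage simulation at a known threshold, for parameter-recovery
#' tests and threshold-scan validation.
#'
#' @param ell_cut Residual cut length (bp), e.g. 0, 20, ..., 70.
#' @param true_threshold Type A threshold used for generation (bp).
#' @param n Number of lineages.
#' @param seed Optional integer seed.
#' @param ... Further arguments to [condition_bundle()].
#' @return List: `table` (lineage table), `per_lineage`, `summary`, and
#'   `ground_truth` (list of generating parameters and seed).
#' @export
generate_finalcut_cohort <- function(ell_cut, true_threshold = 36, n = 200,
                                     seed = NULL, ...) {
  params <- senescence_params(ell_min_A = true_threshold)
  condition <- sprintf("FC%d", as.integer(ell_cut))
  bundle <- condition_bundle(condition, params = params, ...)
  co <- simulate_cohort(n, condition, seed = seed, bundle = bundle)
  list(table = as_lineage_table(co),
       per_lineage = co$per_lineage,
       summary = co$summary,
       ground_truth = list(
         condition = condition, ell_cut = as.integer(ell_cut),
         true_threshold = true_threshold,
         q_cut = if (is.null(bundle$cm)) NA_real_ else bundle$cm$q_cut,
         overhang_steps = bundle$om$step_support,
         shorten_prob = bundle$om$shorten_prob,
         n = n, seed = seed))
}

#' Fixed synthetic subtelomere anchor used by the read generator
#'
#' A synthetic stand-in for the common subtelomeric prefix shared by all
#' reads of one locus (the real subtelomere sequence is not modelled).
#' @export
SYNTH_ANCHOR <- "ACGGATCCATTACGCAATGCTCAACTCAAG"

#' Fixed synthetic 29-nt endonuclease target sequence (stand-in)
#'
#' Its first eight nucleotides are telomere-like so that cut and
#' shortened ends falling inside the target region remain telomerase
#' substrates (the blunt 57-end reads ...TCCTGGG, the reported most
#' common substrate sequence).
#' @export
SYNTH_TTDNA <- "TCCTGGGTAGCATCGTAACGATCTAGCGG"

#' Build a synthetic construct sequence for the cut-telomere locus
#'
#' Proximal degenerate repeats, a fixed synthetic target sequence and
#' distal degenerate repeats, in construct coordinates (position 1 =
#' first repeat nucleotide).  The target sequence is a synthetic
#' stand-in (the real construct's sequence is not modelled).
#'
#' @param cmap A [construct_map()].
#' @param distal_len Distal repeat length (bp).
#' @param seed Optional integer seed.
#' @return List with `sequence` (character) and `cmap`.
#' @export
build_construct <- function(cmap = construct_map(), distal_len = 120L,
                            seed = NULL) {
  .seed_if(seed)
  ttdna <- substr(strrep(SYNTH_TTDNA, 3), 1, cmap$ttdna_len)
  seqs <- paste0(generate_telomeric_repeats(cmap$proximal_len),
                 ttdna,
                 generate_telomeric_repeats(distal_len))
  list(sequence = seqs, cmap = cmap)
}

#' Generate a synthetic single-molecule read library
#'
#' End positions are drawn from the coupled cut-kinetics /
#' end-replication population simulation; each read is the construct
#' prefix up to its end position, behind the common anchor.  In
#' telomerase-positive mode an independently simulated extension tail is
#' appended to each read (the end position is then the ground-truth
#' divergence point).  I.i.d. substitution noise is applied last.
#'
#' @param cmap A [construct_map()].
#' @param timepoints_h Sampling times in hours from galactose addition.
#' @param n_reads Reads per time point.
#' @param noise_rate Per-base substitution probability.
#' @param telomerase Append telomerase extension tails?
#' @param q_cut Per-division cut probability (default calibrated).
#' @param doubling_min Bulk doubling time (minutes).
#' @param seed Optional integer seed.
#' @param out_fasta Optional path: write a FASTA plus a JSON ground-truth
#'   sidecar (`<path>.truth.json`).
#' @return List: `reads` (list of [telomere_read()], cut molecules only),
#'   `ground_truth` (data.frame with read id, time, end position),
#'   `fasta` (path or `NA`).
#' @export
generate_read_library <- function(cmap = construct_map(),
                                  timepoints_h = c(4), n_reads = 200,
                                  noise_rate = 0.01, telomerase = FALSE,
                                  q_cut = NULL, doubling_min = 160,
                                  seed = NULL, out_fasta = NULL) {
  if (n_reads < 1) stop("n_reads must be >= 1")
  .seed_if(seed)
  if (is.null(q_cut)) q_cut <- calibrate_cut_probability(0.85, 7.5)
  cons <- build_construct(cmap)
  pop <- simulate_bulk_cut_population(
    n_molecules = n_reads * length(timepoints_h) * 3L, cmap = cmap,
    om = overhang_model(), q_cut = q_cut, doubling_min = doubling_min,
    cut_window_h = c(0, min(4, max(timepoints_h))),
    sample_times_h = timepoints_h)
  tmod <- telomerase_model()
  reads <- list()
  truth <- list()
  k <- 0L
  for (tp in timepoints_h) {
    cand <- pop[pop$time_h == tp & pop$cut, ]
    if (nrow(cand) == 0L) next
    take <- cand[sample.int(nrow(cand), min(n_reads, nrow(cand))), ]
    for (i in seq_len(nrow(take))) {
      k <- k + 1L
      pos <- max(1L, take$end_position[i])
      core <- substr(cons$sequence, 1, pos)
      if (telomerase) {
        core <- simulate_telomerase_extension(core, tmod)
      }
      if (noise_rate > 0) {
        b <- strsplit(core, "")[[1]]
        hit <- stats::runif(length(b)) < noise_rate
        if (any(hit))
          b[hit] <- vapply(b[hit], function(x)
            sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
        core <- paste(b, collapse = "")
      }
      id <- sprintf("read%05d_t%g", k, tp)
      reads[[k]] <- telomere_read(id, repeats = core,
                                  anchor = SYNTH_ANCHOR,
                                  end_position = pos)
      truth[[k]] <- data.frame(id = id, time_h = tp, end_position = pos,
                               stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  fasta <- NA_character_
  if (!is.null(out_fasta)) {
    seqs <- Biostrings::DNAStringSet(vapply(reads, function(r)
      paste0(r$anchor, r$repeats), ""))
    names(seqs) <- vapply(reads, `[[`, "", "id")
    Biostrings::writeXStringSet(seqs, out_fasta)
    jsonlite::write_json(
      list(seed = seed, q_cut = q_cut, doubling_min = doubling_min,
           noise_rate = noise_rate, telomerase = telomerase,
           construct = cons$sequence, anchor = SYNTH_ANCHOR,
           truth = truth),
      paste0(out_fasta, ".truth.json"), auto_unbox = TRUE, digits = NA)
    fasta <- out_fasta
  }
  list(reads = reads, ground_truth = truth, fasta = fasta,
       construct = cons$sequence)
}

#' Generate a synthetic fluctuation-assay dataset
#'
#' Luria-Delbruck simulated plate counts for several conditions with
#' recorded true rates, for estimator and fold-change validation.
#'
#' @param true_rates_by_condition Named numeric vector of per-division
#'   mutation rates.
#' @param design List with `n_cultures`, `n0`, `nt`, `plated`.
#' @param seed Optional integer seed.
#' @return List: `tables` (one plate-count data.frame per condition)
#'   and `ground_truth`.
#' @export
generate_fluctuation_dataset <- function(true_rates_by_condition,
                                         design = list(n_cultures = 20L,
                                                       n0 = 1000,
                                                       nt = 1e8,
                                                       plated = 1e8),
                                         seed = NULL) {
  if (any(true_rates_by_condition < 0)) stop("rates must be >= 0")
  tables <- list()
  for (cond in names(true_rates_by_condition)) {
    e <- simulate_luria_delbruck(
      true_rates_by_condition[[cond]], design$n0, design$nt,
      design$n_cultures, plated = design$plated, condition = cond,
      seed = derive_seed(seed, paste0("fluct-", cond)))
    tab <- e$cultures
    tab$condition <- cond
    tables[[cond]] <- tab
  }
  list(tables = tables,
       ground_truth = list(true_rates = as.list(true_rates_by_condition),
                           design = design, seed = seed))
}
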