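#' Construct coordinate map for the cut-telomere locus
#'
#' Coordinates are 1-based and count from the first nucleotide of the
#' construct's proximal TG(1-3) tract.  The construct is, centromere to
#' chromosome end: `proximal_len` bp of degenerate repeats, the `ttdna_len`
#' bp endonuclease target sequence, then distal repeats.  Blunt
#' double-stranded cleavage retains `proximal_len + cut_offset`
#' nucleotides (57 with the 50-bp defaults); staggered cleavage leaves a
#' 1-nt 5' overhang whose fill-in retains one more (58).
#'
#' @param proximal_len Length of the proximal repeat tract (bp); 50 by
#'   default (the 50-bp construct).
#' @param ttdna_len Length of the target sequence (bp).
#' @param cut_offset Retained target nucleotides after blunt cleavage.
#' @param staggered_prob Probability that a cut yields the +1 fill-in
#'   product (58) rather than the blunt product (57).
#' @return An object of class `construct_map`.
#' @export
construct_map <- function(proximal_len = 50L, ttdna_len = 29L,
                          cut_offset = 7L, staggered_prob = 0.5) {
  stopifnot(proximal_len >= 0, ttdna_len >= cut_offset, cut_offset >= 1)
  structure(list(proximal_len = as.integer(proximal_len),
                 ttdna_len = as.integer(ttdna_len),
                 cut_offset = as.integer(cut_offset),
                 blunt_end = as.integer(proximal_len + cut_offset),
                 staggered_prob = staggered_prob),
            class = "construct_map")
}

#' Generate a degenerate TG(1-3) repeat sequence (G-strand)
#'
#' Alternating runs of T (1-2 nt, uniform) and G (1-3 nt, uniform),
#' starting with either run type, trimmed to the requested length.  This
#' is the generative counterpart of [validate_tg_grammar()].
#'
#' @param length Target length in nt (>= 0).
#' @param seed Optional integer seed.
#' @return A character scalar over `{T, G}`.
#' @export
generate_telomeric_repeats <- function(length, seed = NULL) {
  if (length < 0) stop("length must be non-negative")
  if (length == 0) return("")
  .seed_if(seed)
  out <- character(0)
  g_turn <- stats::runif(1) < 0.5
  n <- 0L
  while (n < length) {
    run <- if (g_turn) sample(1:3, 1) else sample(1:2, 1)
    out <- c(out, strrep(if (g_turn) "G" else "T", run))
    n <- n + run
    g_turn <- !g_turn
  }
  substr(paste(out, collapse = ""), 1, length)
}

#' Validate a sequence against the TG(1-3) grammar
#'
#' Accepts G-strand sequences made of G-runs of length 1-3 separated by
#' T-runs of length 1-2, allowing truncated runs at both edges (sequences
#' are routinely cut mid-run).
#'
#' @param seq Character scalar.
#' @return Logical.
#' @export
validate_tg_grammar <- function(seq) {
  if (nchar(seq) == 0) return(TRUE)
  grepl("^G{0,3}(T{1,2}G{1,3})*T{0,2}$", seq)
}

#' Telomerase extension model
#'
#' The template RNA, written 3' to 5', is `ACACACACCCACACCAC`.  A
#' substrate's 3' suffix anneals to a complementary register on the
#' template and synthesis appends the complements of the template bases
#' 5'-ward of the register.  Iterated rounds of annealing/extension
#' produce divergent degenerate tails.
#'
#' @param template Template RNA written 3' to 5' (DNA alphabet).
#' @param min_anneal,max_anneal Annealing register lengths tried (longest
#'   first).
#' @param mean_rounds Mean number of extension rounds (geometric, >= 1).
#' @return An object of class `telomerase_model`.
#' @export
telomerase_model <- function(template = "ACACACACCCACACCAC",
                             min_anneal = 2L, max_anneal = 4L,
                             mean_rounds = 3) {
  stopifnot(nchar(template) > 0, min_anneal >= 1,
            max_anneal >= min_anneal, mean_rounds >= 1)
  structure(list(template = template, min_anneal = as.integer(min_anneal),
                 max_anneal = as.integer(max_anneal),
                 mean_rounds = mean_rounds),
            class = "telomerase_model")
}

.complement <- function(x) chartr("ACGT", "TGCA", x)

# all template registers matching the substrate's 3' suffix of length k:
# the suffix (5'->3') pairs antiparallel with the template (written
# 3'->5'), so complement(suffix) is searched directly in the template
# string; returns end indices of matches (last paired template position).
.anneal_registers <- function(substrate, template, k) {
  if (nchar(substrate) < k) return(integer(0))
  suffix <- substr(substrate, nchar(substrate) - k + 1L, nchar(substrate))
  pat <- .complement(suffix)
  hits <- gregexpr(pat, template, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) + k - 1L
}

#' Simulate telomerase extension of a substrate
#'
#' One or more rounds of annealing and templated synthesis.  Each round
#' anneals the current 3' end at a register chosen uniformly among the
#' longest-suffix matches and appends the complement of a random number
#' of downstream template bases (at least one, at most to the template's
#' 5' end).  The substrate is always a prefix of the result.
#'
#' @param substrate Character scalar, the 3'-ending sequence to extend.
#' @param model A [telomerase_model()].
#' @param rounds Number of rounds; default geometric with mean
#'   `model$mean_rounds`.
#' @param seed Optional integer seed.
#' @return The extended sequence.
#' @export
#' @examples
#' simulate_telomerase_extension("TCCTGGG", telomerase_model(), rounds = 1)
simulate_telomerase_extension <- function(substrate, model = telomerase_model(),
                                          rounds = NULL, seed = NULL) {
  if (nchar(substrate) == 0) stop("substrate must be non-empty")
  .seed_if(seed)
  if (is.null(rounds))
    rounds <- 1L + stats::rgeom(1, 1 / model$mean_rounds)
  seq <- substrate
  tlen <- nchar(model$template)
  for (r in seq_len(rounds)) {
    regs <- integer(0)
    # a 3' end with no complementary register may be trimmed by up to
    # 3 nt (nucleolytic processing of non-pairing ends) before annealing
    for (trim in 0:3) {
      if (nchar(seq) - trim < model$min_anneal) break
      cand <- substr(seq, 1, nchar(seq) - trim)
      for (k in seq(model$max_anneal, model$min_anneal)) {
        regs <- .anneal_registers(cand, model$template, k)
        regs <- regs[regs < tlen]        # need room to extend
        if (length(regs)) break
      }
      if (length(regs)) { seq <- cand; break }
    }
    if (!length(regs))
      stop("extension error: no complementary annealing register for 3' end ",
           substr(seq, max(1, nchar(seq) - 5), nchar(seq)))
    e <- if (length(regs) == 1L) regs else sample(regs, 1)
    room <- tlen - e
    n_add <- sample.int(room, 1)
    added <- .complement(substr(model$template, e + 1L, e + n_add))
    seq <- paste0(seq, added)
  }
  seq
}

#' A single-molecule telomere read
#'
#' @param id Read identifier.
#' @param repeats Telomeric portion of the read (construct coordinates
#'   start at its first nucleotide).
#' @param anchor Subtelomere/construct prefix preceding the repeats.
#' @param end_position Optional known last retained construct position
#'   (ground truth or mapping result); defaults to `nchar(repeats)` users
#'   relying on prefix reads.
#' @return An object of class `telomere_read`.
#' @export
telomere_read <- function(id, repeats, anchor = "",
                          end_position = NA_integer_) {
  if (nchar(repeats) == 0) stop("read sequence must be non-empty")
  structure(list(id = id, anchor = anchor, repeats = repeats,
                 end_position = as.integer(end_position)),
            class = "telomere_read")
}

#' A group of reads attributed to one telomere locus
#'
#' All reads must share the same anchor (tolerant matching is the
#' caller's responsibility when parsing real data).
#'
#' @param label Locus label.
#' @param reads List of [telomere_read()].
#' @return An object of class `read_group`.
#' @export
read_group <- function(label, reads) {
  stopifnot(length(reads) >= 1,
            all(vapply(reads, inherits, TRUE, "telomere_read")))
  anchors <- unique(vapply(reads, `[[`, "", "anchor"))
  if (length(anchors) > 1L) stop("reads in a group must share one anchor")
  structure(list(label = label, reads = reads), class = "read_group")
}

#' Find the divergence point of a read group
#'
#' After anchor alignment, scans repeat columns left to right and calls
#' divergence at the first position where the column disagrees with its
#' consensus, provided the disagreement is sustained for `min_run`
#' consecutive columns (isolated low-consensus columns are treated as
#' sequencing noise).  A column disagrees when its minority count is at
#' least `mismatch_tolerance` of its support and at least 2 reads (1
#' when fewer than 4 reads cover it), so that a single sequencing error
#' in a deep column does not breach the tolerance.  The reported
#' `divergence_position` is the last common (consensus-consistent)
#' position, i.e. the length of the shared prefix -- the substrate
#' length at the divergence-creating elongation.
#'
#' @param group A [read_group()] (>= 2 reads).
#' @param mismatch_tolerance Per-column minority fraction tolerated
#'   (default 0.05).
#' @param min_support Minimum reads covering a column (default 2).
#' @param min_run Consecutive failing columns required (default 3).
#' @return A `divergence_result`: list with `diverged` (logical),
#'   `divergence_position` (NA when no divergence), `support` (number of
#'   reads), `scanned` (last column examined).
#' @export
find_divergence_point <- function(group, mismatch_tolerance = 0.05,
                                  min_support = 2L, min_run = 3L) {
  stopifnot(inherits(group, "read_group"))
  seqs <- vapply(group$reads, `[[`, "", "repeats")
  if (length(seqs) < 2L) stop("need at least 2 reads")
  # zero tolerance = strict mode: any single mismatch is divergence
  # (exact longest-common-prefix semantics for noise-free data)
  if (mismatch_tolerance == 0) min_run <- 1L
  mat <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  maxlen <- max(lengths(mat))
  fail <- logical(maxlen)
  scanned <- 0L
  for (p in seq_len(maxlen)) {
    col <- vapply(mat, function(x) if (length(x) >= p) x[p] else NA_character_,
                  "")
    col <- col[!is.na(col)]
    if (length(col) < min_support) break
    scanned <- p
    minority <- length(col) - max(table(col))
    need <- if (mismatch_tolerance == 0) 1L
            else max(if (length(col) >= 4L) 2L else 1L,
                     ceiling(mismatch_tolerance * length(col)))
    fail[p] <- minority >= need
  }
  div_at <- NA_integer_
  if (scanned >= 1L) {
    run <- 0L
    for (p in seq_len(scanned)) {
      run <- if (fail[p]) run + 1L else 0L
      if (run >= min_run || (fail[p] && p == scanned && run == p)) {
        div_at <- p - run + 1L
        break
      }
    }
    # a shorter sustained run truncated by the end of coverage still counts
    if (is.na(div_at) && run >= 1L && run >= min(min_run, scanned))
      div_at <- scanned - run + 1L
  }
  structure(list(diverged = !is.na(div_at),
                 divergence_position = if (is.na(div_at)) NA_integer_
                                       else div_at - 1L,
                 support = length(seqs), scanned = scanned),
            class = "divergence_result")
}

#' End-position distribution of telomere reads
#'
#' Normalized histogram of last retained construct positions.
#'
#' @param reads List of [telomere_read()] or an integer vector of
#'   positions.
#' @param cmap Optional [construct_map()]; positions beyond the mapped
#'   construct (`proximal_len + ttdna_len`) are excluded with a warning
#'   count (attribute `n_excluded`).
#' @return Named numeric vector of class `endpos_hist` (probabilities by
#'   position, sums to 1).
#' @export
end_position_distribution <- function(reads, cmap = NULL) {
  pos <- if (is.numeric(reads)) as.integer(reads)
         else vapply(reads, function(r) {
           if (!is.na(r$end_position)) r$end_position
           else nchar(r$repeats)
         }, integer(1))
  n_excluded <- 0L
  if (!is.null(cmap)) {
    lim <- cmap$proximal_len + cmap$ttdna_len
    n_excluded <- sum(pos > lim | pos < 1L)
    if (n_excluded > 0L)
      warning(n_excluded, " read(s) outside the construct map excluded")
    pos <- pos[pos <= lim & pos >= 1L]
  }
  if (!length(pos)) stop("no mappable end positions")
  tab <- table(pos)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  structure(out, class = "endpos_hist", n_excluded = n_excluded)
}

# peak positions of a histogram: local maxima with mass >= min_mass
.hist_peaks <- function(h, min_mass = 0.1) {
  pos <- as.integer(names(h))
  v <- as.numeric(h)
  ord <- order(pos)
  pos <- pos[ord]; v <- v[ord]
  keep <- v >= min_mass
  is_peak <- keep & v >= c(-Inf, v[-length(v)]) & v >= c(v[-1], -Inf)
  pos[is_peak]
}

#' Infer shortening steps and the per-PD shortening rate
#'
#' From end-position histograms at successive population doublings:
#' the step estimate is the modal distance between histogram peaks
#' (within histograms and between the modal positions of consecutive
#' time points), and the rate is the negative slope of a linear
#' regression of mean end position on population doublings.
#'
#' @param histograms_by_time Named list of [end_position_distribution()]
#'   outputs; names are population-doubling values (numeric-coercible).
#' @return List with `step` (modal step in bp, `NA` when only one peak
#'   exists), `rate_bp_per_pd`, and `mean_positions`.
#' @export
infer_shortening_steps <- function(histograms_by_time) {
  if (length(histograms_by_time) < 2L) stop("need >= 2 time points")
  pd <- as.numeric(names(histograms_by_time))
  if (anyNA(pd)) stop("list names must be population-doubling values")
  means <- vapply(histograms_by_time, function(h)
    sum(as.integer(names(h)) * as.numeric(h)), numeric(1))
  fit <- stats::lm(means ~ pd)
  rate <- -unname(stats::coef(fit)[2])

  gaps <- integer(0)
  modes <- numeric(length(pd))
  for (i in seq_along(histograms_by_time)) {
    pk <- .hist_peaks(histograms_by_time[[i]])
    if (length(pk) >= 2L) gaps <- c(gaps, diff(sort(pk)))
    h <- histograms_by_time[[i]]
    modes[i] <- as.integer(names(h)[which.max(as.numeric(h))])
  }
  ord <- order(pd)
  cross <- -diff(modes[ord])
  gaps <- c(gaps, cross[cross > 0])
  step <- if (!length(gaps)) NA_integer_ else {
    tg <- table(gaps)
    as.integer(names(tg)[which.max(tg)])
  }
  list(step = step, rate_bp_per_pd = rate, mean_positions = means)
}

#' Fraction of divergence positions below a length cutoff
#'
#' The population statistic for short-telomere enrichment: the fraction
#' of telomeres whose divergence point (length at elongation) lies
#' strictly below `cutoff` bp.
#'
#' @param divergence_positions Numeric vector.
#' @param cutoff Length cutoff (bp).
#' @return Fraction in `[0, 1]`.
#' @export
divergence_length_fraction <- function(divergence_positions, cutoff) {
  if (!length(divergence_positions)) stop("empty position list")
  mean(divergence_positions < cutoff)
}

#' Coupled cut-kinetics / end-replication bulk population simulation
#'
#' Simulates a bulk culture of construct-bearing telomere molecules
#' through galactose induction: cells divide on a fixed doubling clock
#' with uniformly random phases; at each division an uncut molecule is
#' cut with probability `q_cut` (while within the cut window), producing
#' the blunt (57) or staggered (58) product; the freshly cut end joins
#' that division's overhang coin with probability `p_pre_replication`;
#' every later division shortens the molecule with probability
#' `om$shorten_prob` by a sampled overhang step.
#'
#' @param n_molecules Number of molecule lineages.
#' @param cmap A [construct_map()].
#' @param om An [overhang_model()].
#' @param q_cut Per-division cut probability.
#' @param doubling_min Bulk doubling time in minutes (default 160, so
#'   4 h is ~1.5 population doublings).
#' @param cut_window_h Cut-permissive interval `(start, end)` in hours
#'   from galactose addition; default `c(0, 4)` (enzyme degraded at 4 h).
#' @param sample_times_h Sampling times (hours from galactose addition).
#' @param p_pre_replication See [cut_model()].
#' @param seed Optional integer seed.
#' @return A data.frame: `time_h`, `molecule`, `cut`, `end_position`
#'   (NA while uncut), `divisions`.
#' @export
simulate_bulk_cut_population <- function(n_molecules, cmap = construct_map(),
                                         om = overhang_model(), q_cut,
                                         doubling_min = 160,
                                         cut_window_h = c(0, 4),
                                         sample_times_h = c(4),
                                         p_pre_replication = 0.75,
                                         seed = NULL) {
  .seed_if(seed)
  t_max <- max(sample_times_h) * 60
  phase <- stats::runif(n_molecules, 0, doubling_min)
  out <- vector("list", length(sample_times_h))
  cut <- rep(FALSE, n_molecules)
  pos <- rep(NA_integer_, n_molecules)
  ndiv <- rep(0L, n_molecules)
  j_max <- ceiling(t_max / doubling_min) + 1L
  div_times <- outer(phase, (seq_len(j_max) - 1L) * doubling_min, `+`)
  done_div <- rep(0L, n_molecules)
  sample_idx <- order(sample_times_h)
  # process chronologically: for each sample time, apply all divisions
  # occurring before it, then record.
  for (s in sample_idx) {
    t_s <- sample_times_h[s] * 60
    repeat {
      j <- pmin(done_div + 1L, j_max)
      due <- done_div < j_max &
        div_times[cbind(seq_len(n_molecules), j)] <= t_s
      if (!any(due)) break
      idx <- which(due)
      td <- div_times[cbind(idx, j[idx])]
      in_window <- td >= cut_window_h[1] * 60 & td <= cut_window_h[2] * 60
      fired <- integer(0)
      attempt <- idx[!cut[idx] & in_window]
      if (length(attempt)) {
        fired <- attempt[stats::runif(length(attempt)) < q_cut]
        if (length(fired)) {
          cut[fired] <- TRUE
          stag <- stats::runif(length(fired)) < cmap$staggered_prob
          pos[fired] <- cmap$blunt_end + as.integer(stag)
          # freshly cut ends join this division's coin, scaled by
          # the pre-replication probability
          coin <- stats::runif(length(fired)) <
            om$shorten_prob * p_pre_replication
          if (any(coin)) {
            st <- .sample_steps(om, sum(coin))
            pos[fired[coin]] <- pmax(0L, pos[fired[coin]] - st)
          }
        }
      }
      # molecules cut at an earlier division shorten with the plain coin
      old_cut <- setdiff(idx[cut[idx]], fired)
      if (length(old_cut)) {
        coin <- stats::runif(length(old_cut)) < om$shorten_prob
        if (any(coin)) {
          st <- .sample_steps(om, sum(coin))
          pos[old_cut[coin]] <- pmax(0L, pos[old_cut[coin]] - st)
        }
      }
      done_div[idx] <- done_div[idx] + 1L
      ndiv[idx] <- ndiv[idx] + 1L
    }
    out[[s]] <- data.frame(time_h = sample_times_h[s],
                           molecule = seq_len(n_molecules),
                           cut = cut, end_position = pos,
                           divisions = ndiv)
  }
  do.call(rbind, out[sample_idx])
}

#' Molecule-population shortening over population doublings
#'
#' Starts every molecule at a given end position (e.g. the cut products
#' 57/58) and applies the overhang coin once per population doubling.
#'
#' @param n_molecules Number of molecules.
#' @param start_positions Integer vector (recycled) of initial end
#'   positions.
#' @param om An [overhang_model()].
#' @param n_pd Number of population doublings.
#' @param seed Optional integer seed.
#' @return Integer matrix `n_molecules x (n_pd + 1)`; column `k` is the
#'   position after `k - 1` doublings.
#' @export
simulate_molecule_shortening <- function(n_molecules, start_positions,
                                         om = overhang_model(), n_pd = 4,
                                         seed = NULL) {
  .seed_if(seed)
  pos <- matrix(NA_integer_, n_molecules, n_pd + 1L)
  pos[, 1] <- rep_len(as.integer(start_positions), n_molecules)
  for (k in seq_len(n_pd)) {
    coin <- stats::runif(n_molecules) < om$shorten_prob
    st <- integer(n_molecules)
    if (any(coin)) st[coin] <- .sample_steps(om, sum(coin))
    pos[, k + 1L] <- pmax(0L, pos[, k] - st)
  }
  pos
}
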