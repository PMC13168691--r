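# Shared fixtures: small parameter bundles kept cheap for unit tests.

fast_protocol <- function(horizon_h = 120) protocol_timeline(horizon_h = horizon_h)

# constant-duration cycle model: deterministic clocks simplify oracles
constant_cdm <- function(normal = 144, threshold = 290) {
  cycle_duration_model(list(
    raffinose = list(normal_mean = normal, normal_sd = 1e-6,
                     long_threshold = threshold, long_excess = 60,
                     p_long_baseline = 0),
    galactose = list(normal_mean = normal, normal_sd = 1e-6,
                     long_threshold = threshold, long_excess = 60,
                     p_long_baseline = 0)))
}

# a lineage-cycles data.frame from a compact string spec, e.g. "NNLLX"
# (N normal 150 min, L long 400 min, X = died at end)
cycles_from_string <- function(s, gen0 = 0L) {
  died <- grepl("X$", s)
  s <- sub("X$", "", s)
  kinds <- strsplit(s, "")[[1]]
  data.frame(
    lineage_id = "L1",
    generation = seq_along(kinds) - 1L + gen0,
    t_start_h = seq_along(kinds),
    duration_min = ifelse(kinds == "L", 400, 150),
    medium = "raffinose",
    arrest_kind = ifelse(kinds == "L", "terminal", "none"),
    cut_now = FALSE, stringsAsFactors = FALSE) -> df
  structure(list(cycles = df, fate = if (died) "died" else "alive_at_end"),
            class = "lineage_record")
}

thr_fix <- list(raffinose = 290, galactose = 224)

# longest common prefix length of a character vector of sequences
lcp_length <- function(seqs) {
  n <- min(nchar(seqs))
  p <- 0L
  for (i in seq_len(n)) {
    if (length(unique(substr(seqs, i, i))) > 1L) break
    p <- i
  }
  p
}
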