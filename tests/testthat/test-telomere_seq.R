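test_that("repeat generator and grammar validator are dual", {
  expect_identical(generate_telomeric_repeats(0), "")
  expect_error(generate_telomeric_repeats(-1), "non-negative")
  set.seed(41)
  for (len in c(1, 7, 30, 200)) {
    s <- generate_telomeric_repeats(len)
    expect_identical(nchar(s), as.integer(len))
    expect_true(validate_tg_grammar(s))
  }
  expect_false(validate_tg_grammar("GGGG"))
  expect_false(validate_tg_grammar("TTT"))
  expect_false(validate_tg_grammar("TGAG"))
})

test_that("G fraction of long repeats matches the grammar expectation", {
  # enumeration oracle: runs alternate; E[G run] = mean(1:3) = 2,
  # E[T run] = mean(1:2) = 1.5 -> long-run G fraction 2/3.5
  oracle <- 2 / 3.5
  set.seed(42)
  s <- generate_telomeric_repeats(20000)
  expect_lt(abs(mean(strsplit(s, "")[[1]] == "G") - oracle), 0.02)
})

test_that("telomerase extension is templated on the RNA", {
  tm <- telomerase_model()
  # substrate ending GGG anneals at the template CCC; the downstream
  # template complement is TGTGGTG, so whatever length is appended must
  # be one of its prefixes (the first four bases being TGTG)
  set.seed(43)
  for (r in 1:10) {
    ext <- simulate_telomerase_extension("TCCTGGG", tm, rounds = 1)
    added <- substr(ext, 8, nchar(ext))
    expect_gt(nchar(added), 0)
    expect_identical(added, substr("TGTGGTG", 1, nchar(added)))
    expect_identical(substr(ext, 1, 7), "TCCTGGG")
  }
  # ...GTG substrates anneal (GTG-complement registers exist)
  expect_no_error(simulate_telomerase_extension("TTGTG", tm, rounds = 1))
  # no register: polyA substrate cannot anneal
  expect_error(simulate_telomerase_extension("AAAA", tm, rounds = 1),
               "extension error")
  expect_error(simulate_telomerase_extension("", tm), "non-empty")
  # independent extensions diverge but keep the substrate as prefix
  set.seed(44)
  exts <- replicate(6, simulate_telomerase_extension("TCCTGGG", tm,
                                                     rounds = 8))
  expect_true(all(substr(exts, 1, 7) == "TCCTGGG"))
  expect_gt(length(unique(exts)), 1)
})

test_that("divergence calls equal the constructed shared prefix", {
  set.seed(45)
  for (r in 1:8) {
    pre <- generate_telomeric_repeats(57)
    reads <- lapply(1:12, function(i)
      telomere_read(paste0("r", i),
                    paste0(pre, generate_telomeric_repeats(40))))
    truth <- lcp_length(vapply(reads, `[[`, "", "repeats"))
    dv <- find_divergence_point(read_group("g", reads),
                                mismatch_tolerance = 0)
    expect_true(dv$diverged)
    expect_identical(dv$divergence_position, truth)

    # 1% substitution noise, 5% tolerance: the call persists near the
    # truth (exact up to the realignment ambiguity of degenerate tails)
    noisy <- lapply(reads, function(rd) {
      b <- strsplit(rd$repeats, "")[[1]]
      hit <- runif(length(b)) < 0.01
      if (any(hit)) b[hit] <- vapply(b[hit], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
      telomere_read(rd$id, paste(b, collapse = ""))
    })
    dvn <- find_divergence_point(read_group("g", noisy),
                                 mismatch_tolerance = 0.05)
    expect_true(dvn$diverged)
    expect_gte(dvn$divergence_position, truth - 1L)
    expect_lte(dvn$divergence_position, truth + 6L)
  }
})

test_that("identical or undersized groups do not diverge", {
  reads <- lapply(1:5, function(i) telomere_read(paste0("i", i), "TTGGGTTGG"))
  dv <- find_divergence_point(read_group("g", reads))
  expect_false(dv$diverged)
  expect_true(is.na(dv$divergence_position))
  expect_error(find_divergence_point(read_group("g", reads[1])),
               "at least 2")
  expect_error(read_group("g", list(
    telomere_read("a", "TTG", anchor = "AAA"),
    telomere_read("b", "TTG", anchor = "CCC"))), "share one anchor")
})

test_that("end-position histograms normalize and ignore read order", {
  h <- end_position_distribution(rep(57L, 10))
  expect_identical(as.numeric(h), 1)
  expect_identical(names(h), "57")

  mix <- c(rep(57L, 50), rep(51L, 50))
  h2 <- end_position_distribution(mix)
  expect_equal(as.numeric(h2[c("51", "57")]), c(0.5, 0.5))
  h3 <- end_position_distribution(rev(mix))
  expect_identical(h2, h3)
  expect_equal(sum(h2), 1)

  # reads beyond the construct are excluded with a warning count
  cmap <- construct_map()
  expect_warning(h4 <- end_position_distribution(c(57L, 51L, 500L), cmap),
                 "excluded")
  expect_identical(attr(h4, "n_excluded"), 1L)
  expect_error(end_position_distribution(integer(0)), "no mappable")
})

test_that("step and rate inference recover constructed truths", {
  h1 <- end_position_distribution(c(rep(57L, 70), rep(51L, 30)))
  h2 <- end_position_distribution(c(rep(57L, 30), rep(51L, 55),
                                    rep(45L, 15)))
  est <- infer_shortening_steps(list(`1.5` = h1, `2.7` = h2))
  expect_identical(est$step, 6L)
  expect_gt(est$rate_bp_per_pd, 0)

  # stationary histograms: rate 0
  est0 <- infer_shortening_steps(list(`0` = h1, `1` = h1))
  expect_equal(est0$rate_bp_per_pd, 0, tolerance = 1e-10)

  # degenerate single peak: rate only, step absent
  hp <- end_position_distribution(rep(57L, 20))
  estna <- infer_shortening_steps(list(`0` = hp, `1` = hp))
  expect_true(is.na(estna$step))
  expect_error(infer_shortening_steps(list(`0` = h1)), ">= 2 time points")
})

test_that("divergence-length fractions mirror the printed statistic", {
  pos <- c(rep(50, 27), rep(90, 73))
  expect_equal(divergence_length_fraction(pos, 70), 0.27)
  expect_equal(divergence_length_fraction(c(80, 90), 70), 0)
  expect_error(divergence_length_fraction(numeric(0), 70), "empty")
})

test_that("bulk molecules decay from the cut positions at (1/2)^k", {
  om <- overhang_model()
  set.seed(46)
  n <- 4000
  pos <- simulate_molecule_shortening(n, c(57L, 58L), om, n_pd = 3)
  for (k in 1:3) {
    stay <- sum(pos[, k + 1L] >= 57L)
    bounds <- qbinom(c(0.0025, 0.9975), n, 0.5^k)
    expect_gte(stay, bounds[1])
    expect_lte(stay, bounds[2])
  }

  # coupled simulation: cut fraction grows with time and shortened
  # molecules only appear after cutting
  pop <- simulate_bulk_cut_population(3000, q_cut = 0.45,
                                      sample_times_h = c(1, 4), seed = 47)
  f1 <- mean(pop$cut[pop$time_h == 1])
  f4 <- mean(pop$cut[pop$time_h == 4])
  expect_gt(f4, f1)
  expect_true(all(is.na(pop$end_position[!pop$cut])))
  expect_true(all(pop$end_position[pop$cut] <= 58L))
})
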