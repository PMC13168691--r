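NT <- 1000 * 2^17            # whole-doubling culture size (from n0 = 1000)

test_that("the LD simulator produces the classic fluctuation signatures", {
  z <- simulate_luria_delbruck(0, 1000, 1e8, 10, seed = 51)
  expect_true(all(z$cultures$mutants == 0L))
  expect_error(simulate_luria_delbruck(1, 1000, 1e8, 5), "rate must be")
  expect_error(simulate_luria_delbruck(1e-9, 10, 5, 5), "nt > n0")

  # p0 closed form: fraction of zero cultures ~ exp(-m)
  rate <- 1 / NT
  ex <- simulate_luria_delbruck(rate, 1000, NT, 400, seed = 52)
  m <- rate * (NT - 1000)
  n0_obs <- sum(ex$cultures$mutants == 0L)
  bounds <- qbinom(c(0.0025, 0.9975), 400, exp(-m))
  expect_gte(n0_obs, bounds[1])
  expect_lte(n0_obs, bounds[2])

  # jackpots: variance far exceeds the mean
  ex2 <- simulate_luria_delbruck(2 / NT, 1000, NT, 200, seed = 53)
  expect_gt(var(ex2$cultures$mutants), 5 * mean(ex2$cultures$mutants))

  # determinism under seed
  a <- simulate_luria_delbruck(rate, 1000, NT, 30, seed = 54)
  b <- simulate_luria_delbruck(rate, 1000, NT, 30, seed = 54)
  expect_identical(a$cultures, b$cultures)
})

test_that("MSS probabilities match closed forms and the generative process", {
  m <- 1.3
  p <- mss_probs(m, 6)
  expect_equal(p[1], exp(-m))
  expect_equal(p[2], m * exp(-m) / 2)    # p1 = (m/1) * p0/2
  expect_true(all(p > 0) && sum(p) < 1)

  # independent oracle: empirical pmf of the forward simulator
  set.seed(55)
  ks <- replicate(4000,
    simulate_luria_delbruck(m / (NT - 1000), 1000, NT, 1)$cultures$mutants)
  for (k in 0:3) {
    hits <- sum(ks == k)
    bounds <- qbinom(c(0.0025, 0.9975), 4000, p[k + 1])
    expect_gte(hits, bounds[1])
    expect_lte(hits, bounds[2])
  }
})

test_that("p0 estimation reproduces the closed-form example", {
  e <- fluctuation_experiment(data.frame(
    Nt = 1e8, plated = 1e8, mutants = c(rep(0L, 14), rep(2L, 6))))
  est <- estimate_rate_p0(e)
  expect_equal(est$rate, -log(0.7) / 1e8, tolerance = 1e-12)
  expect_equal(signif(est$rate, 3), 3.57e-9)
  expect_lt(est$ci_low, est$rate)
  expect_gt(est$ci_high, est$rate)

  # all-zero: rate 0 with an upper bound only
  z <- fluctuation_experiment(data.frame(Nt = 1e8, plated = 1e8,
                                         mutants = rep(0L, 12)))
  est0 <- estimate_rate_p0(z)
  expect_identical(est0$rate, 0)
  expect_gt(est0$ci_high, 0)

  # no zero culture: directed to the MLE
  nz <- fluctuation_experiment(data.frame(Nt = 1e8, plated = 1e8,
                                          mutants = c(1L, 2L)))
  expect_error(estimate_rate_p0(nz), "estimate_rate_mle")
})

test_that("the MSS MLE is consistent, scale-equivariant and CI-calibrated", {
  rate <- 2 / NT
  ex <- simulate_luria_delbruck(rate, 1000, NT, 40, seed = 56)
  est <- estimate_rate_mle(ex)
  expect_gt(est$rate, rate / 2)
  expect_lt(est$rate, rate * 2)
  expect_lte(est$ci_low, est$rate)
  expect_gte(est$ci_high, est$rate)

  # doubling Nt at fixed counts halves the rate (likelihood scaling)
  cu <- data.frame(Nt = 1e8, plated = 1e8,
                   mutants = c(0L, 1L, 0L, 3L, 0L, 0L, 2L, 0L, 1L, 0L))
  r1 <- estimate_rate_mle(fluctuation_experiment(cu))
  cu2 <- transform(cu, Nt = 2e8, plated = 2e8)
  r2 <- estimate_rate_mle(fluctuation_experiment(cu2))
  expect_equal(r1$rate / r2$rate, 2, tolerance = 1e-6)

  # all-zero agrees with the p0 degenerate case
  z <- fluctuation_experiment(data.frame(Nt = 1e8, plated = 1e8,
                                         mutants = rep(0L, 10)))
  estz <- estimate_rate_mle(z)
  expect_identical(estz$rate, 0)
  expect_gt(estz$ci_high, 0)
  expect_error(estimate_rate_mle(fluctuation_experiment(
    data.frame(Nt = 1e8, plated = 1e8, mutants = c(0, 1))[0, ])),
    "at least 2")

  # partial plating: thinned counts still recover the full-culture rate
  exp_thin <- simulate_luria_delbruck(8 / NT, 1000, NT, 40,
                                      plated = round(NT * 0.3), seed = 57)
  est_thin <- estimate_rate_mle(exp_thin)
  expect_gt(est_thin$rate, (8 / NT) / 2)
  expect_lt(est_thin$rate, (8 / NT) * 2)
})

test_that("p0 and MLE agree within 2-fold at low mutation load", {
  set.seed(58)
  for (r in 1:5) {
    ex <- simulate_luria_delbruck(0.25 / NT, 1000, NT, 40)
    a <- estimate_rate_p0(ex)
    b <- estimate_rate_mle(ex)
    if (a$rate == 0 || b$rate == 0) next
    expect_lt(max(a$rate / b$rate, b$rate / a$rate), 2)
  }
})

test_that("fold changes propagate CIs on the log scale", {
  mk <- function(rate, lo, hi)
    structure(list(rate = rate, ci_low = lo, ci_high = hi, method = "mle"),
              class = "rate_estimate")
  same <- fold_change(mk(1e-9, 5e-10, 2e-9), mk(1e-9, 5e-10, 2e-9))
  expect_equal(same$ratio, 1)
  expect_lt(same$ci_low, 1)
  expect_gt(same$ci_high, 1)
  expect_equal(fold_change(mk(1.8e-9, 1e-9, 3e-9),
                           mk(1e-10, 5e-11, 2e-10))$ratio, 18)
  expect_error(fold_change(mk(1e-9, 1e-9, 1e-9), mk(0, 0, 0)), "denominator")

  # synthetic pair at a 29-fold true ratio: CI covers the truth
  ex_hi <- simulate_luria_delbruck(29 * 0.1 / NT, 1000, NT, 40, seed = 59)
  ex_lo <- simulate_luria_delbruck(0.1 / NT, 1000, NT, 40, seed = 60)
  fc <- fold_change(estimate_rate_mle(ex_hi), estimate_rate_mle(ex_lo))
  expect_gt(fc$ratio, 1)
  expect_lte(fc$ci_low, 29)
  expect_gte(fc$ci_high, 29)
})

test_that("dual-marker classification is exhaustive and deterministic", {
  ph <- data.frame(
    canavanine = rep("resistant", 4),
    foa = c("resistant", "sensitive", "resistant", "sensitive"),
    uracil = c("auxotroph", "prototroph", "prototroph", "auxotroph"))
  out <- classify_mutation_events(ph)
  expect_identical(out$event,
                   c("GCR", "point", "inconsistent", "inconsistent"))
  expect_identical(sum(attr(out, "table")), 4L)
  expect_identical(classify_mutation_events(ph)$event, out$event)
  bad <- ph
  bad$canavanine[1] <- "sensitive"
  expect_error(classify_mutation_events(bad), "resistant colonies only")
})
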