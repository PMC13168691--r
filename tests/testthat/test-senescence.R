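sp <- senescence_params()

test_that("transition laws are bounded, monotone and centred as specified", {
  ells <- seq(0, 400, by = 5)
  for (law in list(p_sen_A, p_nta, p_sen_B)) {
    v <- law(ells, sp)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) <= 1e-12))       # non-increasing
  }
  expect_equal(p_sen_A(0, sp), 1, tolerance = 1e-10)
  expect_lt(p_sen_A(300, sp), 1e-3)
  expect_gte(p_sen_A(sp$ell_min_A, sp), 0.5)
  expect_gte(p_nta(50, sp), p_nta(200, sp))
  expect_lt(p_nta(1000, sp), 1e-6)
  expect_identical(p_sen_B(10, sp), p_sen_B(300, sp))
  expect_error(p_sen_A(-1, sp), "non-negative")
  expect_error(p_nta(-1, sp), "non-negative")
})

test_that("Type B onset is geometric with mean 1/p_sen_B", {
  # closed-form oracle: generations from B entry to terminal onset under a
  # constant law are Geometric(p); simulate B cells at a long fixed length
  p <- 0.2
  pars <- senescence_params(p_sen_B_const = p, nta_scale = 0,
                            baseline_death_prob = 0)
  cdm <- constant_cdm()
  set.seed(11)
  waits <- replicate(800, {
    st <- cell_state(telomere_set(rep(500L, 4)), lineage_type = "B")
    g <- 0L
    repeat {
      g <- g + 1L
      st <- advance_cell(st, pars, cdm, om = NULL, t_now = 1,
                         medium = "raffinose")$state
      if (!is.na(st$terminal_remaining)) break
    }
    g
  })
  expect_lt(abs(mean(waits) - 1 / p), 3 * sqrt((1 - p) / p^2 / 800) + 0.2)
  # p_sen_B = 0 never enters terminal arrest
  pars0 <- senescence_params(p_sen_B_const = 0, nta_scale = 0,
                             baseline_death_prob = 0)
  st <- cell_state(telomere_set(rep(500L, 4)), lineage_type = "B")
  for (i in 1:50)
    st <- advance_cell(st, pars0, cdm, om = NULL, t_now = 1,
                       medium = "raffinose")$state
  expect_true(is.na(st$terminal_remaining))
})

test_that("cycle durations respect state and medium contracts", {
  cdm <- default_cycle_model()
  set.seed(12)
  long <- replicate(200, sample_cycle_duration(TRUE, "raffinose", cdm))
  expect_true(all(long > cdm$media$raffinose$long_threshold))
  normal <- replicate(500, sample_cycle_duration(FALSE, "galactose", cdm))
  expect_true(all(normal < cdm$media$galactose$long_threshold))
  expect_true(all(normal > 0))
  expect_error(sample_cycle_duration(FALSE, "lactose", cdm),
               "unknown medium")
})

test_that("calibrated media reproduce dataset mean, SD and long fraction", {
  m <- calibrate_cycle_medium(145, 72.5, 0.043, 90)
  expect_equal(m$long_threshold, 290)
  g <- calibrate_cycle_medium(140, 42, 0.042, 40)
  expect_equal(g$long_threshold, 224)
  # simulate the mixture and check the moments actually come back
  cdm <- cycle_duration_model(list(raffinose = m))
  set.seed(13)
  is_long <- runif(20000) < m$p_long_baseline
  d <- vapply(is_long, sample_cycle_duration, numeric(1),
              medium = "raffinose", cdm = cdm)
  expect_lt(abs(mean(d) - 145), 3)
  expect_lt(abs(sd(d) - 72.5), 5)
  expect_lt(abs(compute_long_cycle_threshold(d) - 290), 12)
  # unreachable targets error out
  expect_error(calibrate_cycle_medium(100, 5, 0.3, 300), "not reachable")
})

test_that("advance_cell enforces the state machine", {
  cdm <- constant_cdm()
  dead <- cell_state(telomere_set(300L), alive = FALSE)
  expect_error(advance_cell(dead, sp, cdm, NULL, t_now = 1,
                            medium = "raffinose"),
               "dead cell")

  # fully eroded shortest: terminal arrest within 1-2 divisions, then death
  set.seed(14)
  lifespans <- replicate(100, {
    st <- cell_state(telomere_set(c(0L, rep(300L, 31)), finalcut_index = 1L))
    n <- 0L
    while (st$alive && n < 20L) {
      n <- n + 1L
      st <- advance_cell(st, sp, cdm, overhang_model(), t_now = 1,
                         medium = "raffinose")$state
    }
    n
  })
  expect_true(all(lifespans <= 6L))   # at most 2 + max terminal block

  # telomerase-positive control mode: only baseline death, ~0.5%/division
  set.seed(15)
  n <- 20000
  died <- sum(replicate(n, {
    st <- cell_state(telomere_set(rep(300L, 4)))
    advance_cell(st, sp, cdm, om = NULL, t_now = 1, medium = "raffinose",
                 laws_enabled = FALSE)$cycle$died
  }))
  bounds <- qbinom(c(0.0025, 0.9975), n, 0.005)
  expect_gte(died, bounds[1])
  expect_lte(died, bounds[2])

  # zero-probability laws and death: never arrests
  free <- senescence_params(ell_min_A = 1e-6, width_A = 1e-9, nta_scale = 0,
                            p_sen_B_const = 0, baseline_death_prob = 0)
  st <- cell_state(telomere_set(rep(500L, 4)))
  for (i in 1:100) {
    out <- advance_cell(st, free, cdm, om = NULL, t_now = 1,
                        medium = "raffinose")
    st <- out$state
    expect_identical(out$cycle$arrest_kind, "none")
  }
  expect_true(st$alive)
})

test_that("terminal arrest is 2-4 consecutive long cycles ending in death", {
  set.seed(16)
  for (r in 1:30) {
    rec <- simulate_lineage(sp, constant_cdm(), overhang_model(),
                            cm = cut_model(0, q_cut = 1),
                            protocol = fast_protocol())
    if (rec$fate != "died") next
    kinds <- rec$cycles$arrest_kind
    n <- length(kinds)
    run <- 0L
    while (n - run >= 1L && kinds[n - run] == "terminal") run <- run + 1L
    if (run > 0L) {
      expect_gte(run, 2L)
      expect_lte(run, 4L)
    }
  }
})
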