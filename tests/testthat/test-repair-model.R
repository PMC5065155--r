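test_that("dose/DSB conversion uses the PFGE calibration", {
  expect_identical(dose_to_dsb(0), 0L)
  expect_identical(dose_to_dsb(0.0286), 1L)
  expect_identical(dose_to_dsb(20), 699L)
  expect_equal(dsb_to_dose(699), 19.9914)
  expect_equal(dsb_to_dose(dose_to_dsb(80)), 80, tolerance = 0.001)
  expect_error(dose_to_dsb(-1), "non-negative")
})

test_that("half-time is ln 2 over the rate constant", {
  expect_equal(half_time(log(2)), 1)
  expect_equal(half_time(3.06), log(2) / 3.06)
  expect_equal(half_time(0.04), 17.32868, tolerance = 1e-5)
  expect_error(half_time(0), "> 0")
  expect_error(half_time(-2), "> 0")
})

test_that("rate_params validates channel modes", {
  p <- rate_params(K = c(fast = 1, slow = 0.1), Kprime = c(fast = 2, slow = 0.1))
  expect_equal(unname(p$mode), c("full", "full", "absent"))
  expect_equal(unname(p$K[["aej"]]), 0)
  b <- rate_params(K = c(fast = 0.05), mode = c(fast = "binding_only"))
  expect_equal(unname(b$Kprime[["fast"]]), 0)
  expect_error(rate_params(K = c(fast = 1)), "Kprime > 0")
  expect_error(rate_params(K = c(nope = 1)), "unknown channel")
  expect_error(rate_params(K = c(fast = 0), mode = c(fast = "binding_only")),
               "K > 0")
})

test_that("propensities follow mass action with the free-pool fraction", {
  p <- rate_params(K = c(fast = 0.1, slow = 0.2), Kprime = c(fast = 1, slow = 0.4))
  # empty pool fraction: x = 10 free breaks, untouched pools
  pr <- repair_propensities(list(x = 10, y = c(0, 0, 0), C = c(5, 5, 5)), p)
  expect_equal(unname(pr$recruit), c(0.1 * 10, 0.2 * 10, 0))
  expect_equal(unname(pr$ligate), c(0, 0, 0))
  # partially occupied pool scales recruitment by the free fraction
  pr2 <- repair_propensities(list(x = 10, y = c(2, 3, 0), C = c(5, 5, 5)), p)
  expect_equal(unname(pr2$recruit[1]), 0.1 * 10 * 3 / 5)
  expect_equal(unname(pr2$ligate[2]), 0.4 * 3)
  # no substrate
  pr3 <- repair_propensities(list(x = 0, y = c(1, 0, 0), C = c(5, 5, 5)), p)
  expect_equal(unname(pr3$recruit), c(0, 0, 0))
  # binding-only channels never ligate
  b <- rate_params(K = c(fast = 0.5, slow = 0.1), Kprime = c(slow = 0.1),
                   mode = c(fast = "binding_only", slow = "full"))
  prb <- repair_propensities(list(x = 4, y = c(3, 0, 0), C = c(10, 10, 10)), b)
  expect_equal(unname(prb$ligate[1]), 0)
  expect_error(repair_propensities(list(x = -1, y = c(0, 0, 0), C = c(1, 1, 1)), p),
               "invalid state")
})

test_that("simulation respects conservation and degenerate inputs", {
  p <- default_true_rates()$D1
  tg <- c(0, 0.1, 0.5, 1, 2, 6, 12, 24)
  # no breaks: flat zero trajectory
  tr0 <- simulate_repair(p, 0, tg, seed = 1)
  expect_true(all(tr0$x == 0) && all(tr0$cum_recruit == 0))
  # break bookkeeping closes at every snapshot, across seeds
  for (s in 1:5) {
    tr <- simulate_repair(p, 400, tg, seed = s)
    expect_true(all(tr$x + rowSums(tr$y) + rowSums(tr$cum_ligate) == 400))
    expect_true(all(tr$y >= 0) && all(tr$x >= 0))
    # enzyme pools never overdrawn
    expect_true(all(sweep(tr$y, 2, tr$C, "<=")))
    # tallies non-decreasing, recruit >= ligate per channel
    expect_true(all(diff(tr$cum_recruit) >= 0) && all(diff(tr$cum_ligate) >= 0))
    expect_true(all(tr$cum_recruit >= tr$cum_ligate))
  }
  expect_error(simulate_repair(p, 10, numeric(0)), "non-empty")
  expect_error(simulate_repair(p, 10, c(1, 0.5)), "increasing")
})

test_that("identical seeds give bit-identical trajectories", {
  p <- default_true_rates()$D5
  a <- simulate_repair(p, 1000, default_timepoints(), seed = 42)
  b <- simulate_repair(p, 1000, default_timepoints(), seed = 42)
  expect_identical(a, b)
  c2 <- simulate_repair(p, 1000, default_timepoints(), seed = 43)
  expect_false(identical(a$x, c2$x))
})

test_that("single-channel completion times match the hypoexponential law", {
  # abundant enzyme: per-break time is Exp(K) then Exp(K'); the cumulative
  # ligation curve is the empirical CDF of 10^4 iid completion times
  K <- 1.2; Kp <- 0.8; n <- 10000
  p <- rate_params(K = c(fast = K), Kprime = c(fast = Kp))
  grid <- seq(0, 40, by = 0.05)
  tr <- simulate_repair(p, n, grid, C = c(100 * n, 0, 0), seed = 7)
  emp <- tr$cum_ligate[, 1] / n
  ks <- max(abs(emp - hypoexp_cdf(grid, K, Kp)))
  expect_lt(ks, 0.02)
})

test_that("mean remaining fraction matches the two-compartment solution", {
  # single channel, enzyme effectively constant: the deterministic limit of
  # the remaining fraction is the hypoexponential survival function
  K <- 0.9; Kp <- 0.5; x0 <- 300; reps <- 200
  p <- rate_params(K = c(slow = K), Kprime = c(slow = Kp))
  tg <- c(0, 0.5, 1, 2, 4, 8)
  set.seed(11)
  rem <- replicate(reps, {
    tr <- simulate_repair(p, x0, tg, C = c(0, 100 * x0, 0))
    (tr$x + rowSums(tr$y)) / x0
  })
  for (i in seq_along(tg)) {
    expected <- 1 - hypoexp_cdf(tg[i], K, Kp)
    se <- sd(rem[i, ]) / sqrt(reps)
    expect_lt(abs(mean(rem[i, ]) - expected), 3 * se + 1e-9)
  }
})

test_that("measured curve is the dose equivalent of unligated breaks", {
  # no active channels: constant at the initial dose equivalent
  p <- rate_params(K = c(slow = 1e-12), Kprime = c(slow = 1e-12))
  tr <- simulate_repair(p, 699, c(0, 6, 24), seed = 1)
  expect_equal(measured_curve(tr), rep(19.9914, 3), tolerance = 1e-6)
  # monotone non-increasing for full channels
  tr2 <- simulate_repair(default_true_rates()$D1, 699, default_timepoints(),
                         seed = 2)
  expect_true(all(diff(measured_curve(tr2)) <= 0))
  # binding-only channels sequester but never release: still non-increasing
  tr3 <- simulate_repair(default_true_rates()$D2, 699, default_timepoints(),
                         seed = 3)
  expect_true(all(diff(measured_curve(tr3)) <= 0))
})

test_that("trajectory CSV export round-trips the observable", {
  tr <- simulate_repair(default_true_rates()$D8, 500, c(0, 1, 4, 12), seed = 9)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  df <- read.csv(f)
  expect_named(df, c("time_hr", "x", "y_fast", "y_slow", "y_aej",
                     "cum_ligated_fast", "cum_ligated_slow",
                     "cum_ligated_aej", "dose_equiv_gy"))
  expect_equal(df$dose_equiv_gy, measured_curve(tr))
  expect_equal(df$x + df$y_fast + df$y_slow + df$y_aej +
                 df$cum_ligated_fast + df$cum_ligated_slow +
                 df$cum_ligated_aej, rep(500, 4))
})
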