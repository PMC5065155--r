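test_that("mechanism tallies close the break bookkeeping", {
  p <- default_true_rates()$D1
  tr <- simulate_repair(p, 699, seq(0, 48, by = 0.5), seed = 2)
  tl <- tally_mechanisms(tr)
  # every break is free, in some channel, or ligated
  expect_equal(sum(tl$entered) + tl$residual_free +
                 (tr$x[1] - 699), sum(tl$completed) +
                 sum(tr$y[nrow(tr$y), ]) + tl$residual_free)
  expect_true(all(tl$entered >= tl$completed))
  expect_true(all(tl$proportions >= 0 & tl$proportions <= 1))
  expect_equal(sum(tl$proportions) + tl$residual_free / 699, 1)
  # fully repaired single channel: everything enters it
  p1 <- rate_params(K = c(fast = 2), Kprime = c(fast = 2))
  tr1 <- simulate_repair(p1, 300, c(0, 2, 10, 30), seed = 3)
  expect_equal(unname(tally_mechanisms(tr1)$entered[["fast"]]), 300)
})

test_that("equal channels split the breaks symmetrically", {
  p <- rate_params(K = c(fast = 0.6, slow = 0.6), Kprime = c(fast = 1, slow = 1))
  set.seed(4)
  ratio <- replicate(60, {
    tl <- tally_mechanisms(simulate_repair(p, 500, c(0, 4, 12, 30)))
    tl$entered[["fast"]] / max(tl$entered[["slow"]], 1)
  })
  expect_lt(abs(mean(ratio) - 1), 3 * sd(ratio) / sqrt(length(ratio)))
})

test_that("event counts agree with the pathway-entry integral", {
  p <- default_true_rates()$D5
  for (s in 1:4) {
    tr <- simulate_repair(p, 2797, seq(0, 36, by = 0.25), seed = s)
    tl <- tally_mechanisms(tr)
    for (ch in c("slow", "aej")) {
      # the event count is a Poisson-type realisation of the integral, so
      # its relative fluctuation scales like 1/sqrt(count)
      tol <- max(0.05, 3 / sqrt(tl$entry_integral[[ch]]))
      expect_lt(abs(tl$entered[[ch]] - tl$entry_integral[[ch]]) /
                  tl$entry_integral[[ch]], tol)
      # grid quadrature tracks the exact along-path integral on a dense grid
      expect_lt(abs(tl$entry_quadrature[[ch]] - tl$entry_integral[[ch]]) /
                  tl$entry_integral[[ch]], 0.05)
    }
  }
})

test_that("predictive bands are nested and respond to prior spread", {
  ds <- make_single_channel_dataset("D1", K = 0.4, Kprime = 0.4)
  ens <- make_ensemble(list(c(NA, NA, log(0.4), NA),
                            c(NA, NA, log(0.5), NA)),
                       sigma2 = 0.02, datasets = ds)
  b <- predictive_bands(ens, ds$D1, n_draws = 60, seed = 5)
  expect_true(all(b$q025 <= b$q25 & b$q25 <= b$q50 &
                    b$q50 <= b$q75 & b$q75 <= b$q975))
  expect_error(predictive_bands(ens, ds$D1, n_draws = 5), "at least 10")
  # doubling the lognormal spread widens the envelopes on average
  ens_wide <- make_ensemble(list(c(NA, NA, log(0.4), NA),
                                 c(NA, NA, log(0.5), NA)),
                            sigma2 = 0.6, datasets = ds)
  bw <- predictive_bands(ens_wide, ds$D1, n_draws = 60, seed = 5)
  expect_gt(mean(bw$q975 - bw$q025), mean(b$q975 - b$q025))
})

test_that("half-maximum repair time behaves like a half-life", {
  # near-instant recruitment, ligation at ln 2 per hour: half of all
  # ligations are done by ~1 h
  p <- rate_params(K = c(aej = 500), Kprime = c(aej = log(2)))
  set.seed(6)
  hm <- replicate(30, time_to_half_max(
    simulate_repair(p, 2000, seq(0, 24, by = 0.05)), "aej"))
  expect_equal(median(hm), 1, tolerance = 0.1)
  # halving both rates roughly doubles the half-max time
  ph <- rate_params(K = c(aej = 0.4), Kprime = c(aej = 0.3))
  p2 <- rate_params(K = c(aej = 0.2), Kprime = c(aej = 0.15))
  set.seed(7)
  h1 <- median(replicate(30, time_to_half_max(
    simulate_repair(ph, 1500, seq(0, 96, by = 0.25)), "aej")))
  h2 <- median(replicate(30, time_to_half_max(
    simulate_repair(p2, 1500, seq(0, 96, by = 0.25)), "aej")))
  expect_equal(h2 / h1, 2, tolerance = 0.2)
  # undefined for binding-only and absent channels
  trb <- simulate_repair(default_true_rates()$D2, 300, c(0, 4), seed = 8)
  expect_error(time_to_half_max(trb, "fast"), "binding_only")
  tr8 <- simulate_repair(default_true_rates()$D8, 300, c(0, 4), seed = 8)
  expect_error(time_to_half_max(tr8, "aej"), "absent")
})

test_that("occupancy shares are normalised and single-channel trivial", {
  p1 <- rate_params(K = c(slow = 0.5), Kprime = c(slow = 0.2))
  tr <- simulate_repair(p1, 400, seq(0, 30, by = 0.5), seed = 9)
  occ <- occupancy_series(tr)
  bound <- rowSums(tr$y) > 0
  expect_true(all(occ$share_slow[bound] == 1))
  expect_true(all(occ$share_slow[!bound] == 0))
  tr3 <- simulate_repair(default_true_rates()$D1, 699,
                         seq(0, 24, by = 0.5), seed = 10)
  occ3 <- occupancy_series(tr3)
  tot <- occ3$share_fast + occ3$share_slow + occ3$share_aej
  bound3 <- rowSums(tr3$y) > 0
  expect_equal(tot[bound3], rep(1, sum(bound3)))
  # the fast channel dominates early and fades late
  s <- occ3[occ3$time %in% c(0.5, 8), ]
  expect_gt(s$share_fast[1], s$share_fast[2])
})

test_that("activity timelines flag mechanisms holding the in-process pool", {
  ds <- make_single_channel_dataset("D1", K = 0.4, Kprime = 0.4)
  ens <- make_ensemble(list(c(NA, NA, log(0.4), NA)), sigma2 = 1e-6,
                       datasets = ds)
  at <- activity_timeline(ens, ds$D1, n_draws = 12, seed = 11,
                          grid = seq(0, 24, by = 0.5))
  # single active channel: active whenever any break is bound
  expect_true(all(at$duration$aej > 0))
  expect_true(all(!at$active[, , "fast"]))
  expect_error(activity_timeline(ens, ds$D1, threshold = 1.2), "threshold")
  # faster rates spend less total time above the threshold
  ens_spread <- make_ensemble(lapply(log(c(0.1, 0.2, 0.5, 1, 2)), function(m)
    c(NA, NA, m, NA)), sigma2 = 1e-6, datasets = ds)
  at2 <- activity_timeline(ens_spread, ds$D1, n_draws = 40, seed = 12,
                           grid = seq(0, 48, by = 0.5))
  expect_lt(cor(at2$rates$aej, at2$duration$aej, method = "spearman"), 0)
})

test_that("KS comparison handles identical, disjoint and weighted samples", {
  x <- rnorm(50)
  expect_equal(ks_two_sample(x, x)$D, 0)
  out <- ks_two_sample(1:20, 101:120)
  expect_equal(out$D, 1)
  expect_lt(out$p_value, 1e-6)
  expect_error(ks_two_sample(1:3, 1:20), "at least 8")
  # weighted resampling: weights concentrated on one half shift the sample
  set.seed(13)
  a <- c(rnorm(500, 0), rnorm(500, 5))
  w <- c(rep(1, 500), rep(1e-9, 500))
  r <- ks_two_sample(a, rnorm(1000, 0), w_a = w, seed = 14)
  expect_lt(r$D, 0.1)
})

test_that("in-silico knockouts zero out the targeted channels", {
  ds <- make_single_channel_dataset("D1", K = 0.4, Kprime = 0.4)
  ens <- make_ensemble(list(c(log(2), log(0.04), log(0.4), NA)),
                       sigma2 = 1e-6, datasets = ds)
  spec3 <- dataset_spec("D1", 20, default_timepoints(),
                        analytic_curve(20, default_timepoints(), 0.4, 0.4),
                        default_pathway_config()$D1)
  # zeroing every channel: curve stays at the initial dose
  flat <- channel_knockout_resim(ens, spec3, c("fast", "slow", "aej"),
                                 n_draws = 15, seed = 15)
  expect_true(all(abs(flat$q50 - dsb_to_dose(699)) < 1e-9))
  expect_true(all(flat$q025 == flat$q975))
  # zeroing nothing reproduces predictive_bands draw for draw
  a <- channel_knockout_resim(ens, spec3, character(0), n_draws = 15, seed = 16)
  b <- predictive_bands(ens, spec3, n_draws = 15, seed = 16)
  expect_identical(a, b)
  # fast+slow knockout: the alternative channel still clears the breaks
  aej_only <- channel_knockout_resim(ens, spec3, c("fast", "slow"),
                                     grid = c(0, 12, 24, 48, 96),
                                     n_draws = 15, seed = 17)
  expect_lt(aej_only$q50[5], 0.05 * 20)
})
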