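test_that("stationary Poisson generator has the right rate and CV", {
  x <- simulate_spike_data(2e5, "poisson", rate_hz = 60, seed = 1)
  rate <- nrow(x) / 200
  expect_equal(rate, 60, tolerance = 0.03)
  expect_equal(cv_isi(x)$cv, 1, tolerance = 0.03)
  expect_equal(nrow(simulate_spike_data(1000, "poisson", rate_hz = 0)), 0L)
})

test_that("PPD generator enforces the dead-time and hits the target rate", {
  x <- simulate_spike_data(2e5, "ppd", rate_hz = 60, dead_time_ms = 1.6,
                           seed = 2)
  expect_gte(min(diff(x$time_ms)), 1.6)
  expect_equal(nrow(x) / 200, 60, tolerance = 0.03)
  # d = 0 degenerates to Poisson (KS on ISIs against the exponential)
  y <- simulate_spike_data(5e4, "ppd", rate_hz = 60, dead_time_ms = 0, seed = 3)
  ks <- suppressWarnings(
    stats::ks.test(diff(y$time_ms), stats::pexp, rate = 0.06)
  )
  expect_gt(ks$p.value, 0.01)
  expect_error(simulate_spike_data(1000, "ppd", rate_hz = 600,
                                   dead_time_ms = 2), "Infeasible")
})

test_that("Gamma generator matches CV = 1/sqrt(shape) within Monte-Carlo error", {
  for (g in c(1, 1.23, 2, 6.25)) {
    x <- simulate_spike_data(1e5, "gamma", rate_hz = 60, shape = g,
                             seed = 100 + round(10 * g))
    cv <- cv_isi(x)$cv
    n <- cv_isi(x)$n_isis
    se <- 3 * cv / sqrt(2 * n) * 2 # generous 3-SE band
    expect_lt(abs(cv - 1 / sqrt(g)), max(se, 0.02))
  }
  expect_error(simulate_spike_data(1000, "gamma", shape = -1), "positive")
})

test_that("CV / shape mapping is the stated involution", {
  expect_equal(cv_to_shape(1), 1)
  expect_equal(cv_to_shape(0.4), 6.25)
  expect_equal(shape_to_cv(cv_to_shape(0.7321)), 0.7321)
  expect_error(cv_to_shape(0), "positive")
})

test_that("dead-time estimation caps at d_max", {
  x <- spike_data(tibble::tibble(
    trial_id = 1L, unit_id = "a", time_ms = c(0, 2.1, 7.1, 14.1)
  ), t_stop = 200)
  expect_equal(estimate_deadtime(x)$dead_time_ms, 2.1)

  y <- spike_data(tibble::tibble(
    trial_id = 1L, unit_id = "a", time_ms = c(0, 120)
  ), t_stop = 200)
  expect_equal(estimate_deadtime(y)$dead_time_ms, 4)

  z <- spike_data(tibble::tibble(
    trial_id = 1L, unit_id = "a", time_ms = c(0, 4)
  ), t_stop = 200)
  expect_equal(estimate_deadtime(z)$dead_time_ms, 4) # boundary

  lone <- spike_data(tibble::tibble(
    trial_id = 1L, unit_id = c("a", "b"), time_ms = c(1, 2)
  ), t_stop = 10)
  expect_warning(dt <- estimate_deadtime(lone), "d_max")
  expect_equal(dt$dead_time_ms, c(4, 4))
})

test_that("rate profiles: construction, cumulative integral, step and band-limited kinds", {
  p <- make_rate_profile("constant", 1000, rate_hz = 60)
  lam <- cumulative_rate(p)
  expect_equal(lam[length(lam)], 0.06 * 1000, tolerance = 1e-9)
  expect_true(all(diff(lam) >= 0))

  s <- make_rate_profile("step", 150, rate_from = 10, rate_to = 80,
                         step_at_ms = 75)
  expect_equal(s$rate_hz[s$time_ms < 75], rep(10, sum(s$time_ms < 75)))
  expect_equal(s$rate_hz[s$time_ms >= 75], rep(80, sum(s$time_ms >= 75)))

  e1 <- make_rate_profile("experimental", 500, rate_range = c(5, 80), seed = 4)
  e2 <- make_rate_profile("experimental", 500, rate_range = c(5, 80), seed = 4)
  expect_identical(e1, e2)
  expect_gte(min(e1$rate_hz), 5)
  expect_lte(max(e1$rate_hz), 80)

  expect_error(rate_profile(c(0, 1, 3), c(1, 1, 1)), "uniform")
  expect_error(rate_profile(c(0, 1), c(1, -1)), "nonnegative")
})

test_that("nonstationary generators track the profile (thinning and operational time)", {
  prof <- make_rate_profile("step", 150, rate_from = 10, rate_to = 80,
                            step_at_ms = 75)
  x <- simulate_spike_data(150, "poisson", profile = prof, n_trials = 3000,
                           seed = 5)
  r <- psth(x, 25)
  expect_equal(r$rate_hz[2], 10, tolerance = 0.12)
  expect_equal(r$rate_hz[5], 80, tolerance = 0.06)

  # PPD thinning keeps the dead-time and the profile
  xp <- simulate_spike_data(150, "ppd", profile = prof, dead_time_ms = 2,
                            n_trials = 3000, seed = 6)
  expect_gte(min(isi_values(xp)$isi_ms), 2)
  rp <- psth(xp, 25)
  expect_equal(rp$rate_hz[2], 10, tolerance = 0.15)

  # operational time: window counts of a nonstationary Gamma process match
  # the integrated rate (away from the ordinary-renewal start transient)
  prof2 <- make_rate_profile("step", 2000, rate_from = 20, rate_to = 60,
                             step_at_ms = 1000)
  xg <- simulate_spike_data(2000, "gamma", profile = prof2, shape = 4,
                            n_trials = 400, seed = 7)
  n_lo <- sum(xg$time_ms < 1000) / 400
  n_hi <- sum(xg$time_ms >= 1000) / 400
  expect_equal(n_lo, 20, tolerance = 0.05)
  expect_equal(n_hi, 60, tolerance = 0.05)
})

test_that("kernel rate estimation is consistent and mass-conserving", {
  x <- simulate_spike_data(2000, "poisson", rate_hz = 60, n_trials = 50,
                           seed = 8)
  est <- estimate_rate_profile(x, bandwidth_ms = 50)
  mid <- est$rate_hz[est$time_ms > 200 & est$time_ms < 1800]
  expect_equal(mean(mid), 60, tolerance = 0.05)
  # integral over the trial ~ mean spike count per trial
  integral <- sum(est$rate_hz) * 1 / 1000
  expect_equal(integral, nrow(x) / 50, tolerance = 0.02)

  z <- simulate_spike_data(1000, "poisson", rate_hz = 0)
  expect_equal(unique(estimate_rate_profile(z)$rate_hz), 0)
  expect_error(estimate_rate_profile(x, bandwidth_ms = 0), "positive")
})

test_that("generators are reproducible bit-for-bit under a fixed seed", {
  a <- simulate_spike_data(5000, "gamma", rate_hz = 50, shape = 2, seed = 9)
  b <- simulate_spike_data(5000, "gamma", rate_hz = 50, shape = 2, seed = 9)
  expect_identical(a$time_ms, b$time_ms)
})
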