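test_that("ISI histogram reflects interval structure and dead-times", {
  reg <- spike_data(seq(5, 995, by = 10.4), t_stop = 1000)
  h <- isi_histogram(reg, resolution_ms = 1)
  expect_equal(sum(h$count > 0), 1L)
  expect_equal(h$lag_ms[h$count > 0], 10.5) # 10.4 ms falls in bin [10, 11)

  p <- simulate_spike_data(5e4, "ppd", rate_hz = 60, dead_time_ms = 1.6,
                           seed = 1)
  hp <- isi_histogram(p, resolution_ms = 0.5)
  expect_equal(sum(hp$count[hp$lag_ms < 1.5]), 0L)

  # Poisson: exponential decay, rate recoverable from the mean ISI
  x <- simulate_spike_data(1e5, "poisson", rate_hz = 60, seed = 2)
  expect_equal(1000 / mean(isi_values(x)$isi_ms), 60, tolerance = 0.03)

  expect_error(isi_histogram(spike_data(5, t_stop = 10)), "2 spikes")
})

test_that("CV and CV2 follow their defining formulas", {
  const <- spike_data(seq(10, 490, by = 10), t_stop = 500)
  expect_equal(cv_isi(const)$cv, 0)
  expect_equal(cv2_isi(const)$cv2, 0)

  # alternating ISIs a, b: every CV2 term is 2|a-b|/(a+b)
  alt <- spike_data(cumsum(rep(c(10, 30), 20)), t_stop = 1000)
  expect_equal(cv2_isi(alt)$cv2, 2 * abs(30 - 10) / 40)

  x <- simulate_spike_data(2e5, "poisson", rate_hz = 60, seed = 3)
  expect_equal(cv_isi(x)$cv, 1, tolerance = 0.03)
  expect_equal(cv2_isi(x)$cv2, 1, tolerance = 0.03)

  expect_error(cv_isi(spike_data(5, t_stop = 10)), "2 spikes")
  expect_error(cv2_isi(spike_data(c(2, 5), t_stop = 10)), "3 spikes")
})

test_that("correlation histograms: peaks, baselines, and shapes", {
  reg <- spike_data(seq(5, 9995, by = 10.4), t_stop = 10000)
  a <- correlation_histogram(reg, max_lag_ms = 25, lag_bin_ms = 1)
  peaks <- a$lag_ms[a$count > 500]
  expect_true(all(abs(peaks) %in% c(10.5, 20.5))) # multiples of 10.4 ms
  expect_equal(a$count[abs(a$lag_ms) == 0.5], c(0, 0)) # self pairs excluded
  expect_equal(a$count, rev(a$count)) # symmetry

  # independent Poisson pair: flat at the product-of-rates baseline
  x <- simulate_spike_data(2e5, "poisson", rate_hz = 40, seed = 4)
  y <- simulate_spike_data(2e5, "poisson", rate_hz = 40, seed = 5)
  cc <- correlation_histogram(x, y, max_lag_ms = 25, lag_bin_ms = 5)
  baseline <- 0.04 * 0.04 * 2e5 * 5
  expect_equal(mean(cc$count), baseline, tolerance = 0.05)
  expect_lt(diff(range(cc$count)) / baseline, 0.2)

  # original vs UD surrogate: excess mass confined to [-dither, dither]
  s <- surrogate_uniform_dither(x, dither_ms = 10, seed = 6)
  cs <- correlation_histogram(x, s, max_lag_ms = 25, lag_bin_ms = 5)
  inside <- cs$count[abs(cs$lag_ms) < 10]
  outside <- cs$count[abs(cs$lag_ms) > 10]
  expect_gt(min(inside), max(outside))

  expect_error(
    correlation_histogram(x, spike_data(1, t_stop = 10)), "differ"
  )
  empty <- spike_data(numeric(0), t_stop = 2e5)
  expect_equal(sum(correlation_histogram(x, empty, 25)$count), 0)
})

test_that("moved-spike ratio implements min-count matching with the swap rule", {
  x <- spike_data(c(2, 12, 22), t_stop = 30)
  expect_equal(moved_spike_ratio(x, x, 5), 0)

  # two spikes exchange bins: both count as not moved
  sw <- spike_data(c(3, 13, 22), t_stop = 30)
  sw$time_ms[1:2] <- c(13, 3)
  sw <- spike_data(tibble::as_tibble(sw), t_stop = 30)
  expect_equal(moved_spike_ratio(x, sw, 5), 0)

  # fully displaced spikes all count as moved
  far <- spike_data(c(7, 17, 27), t_stop = 30)
  expect_equal(moved_spike_ratio(x, far, 5), 1)

  expect_error(moved_spike_ratio(x, spike_data(1, t_stop = 50), 5),
               "differ")

  # decreases with firing rate for UD surrogates
  ratios <- vapply(c(20, 60, 100), function(r) {
    g <- simulate_spike_data(3e4, "gamma", rate_hz = r, shape = 1.23,
                             seed = r)
    moved_spike_ratio(g, surrogate_uniform_dither(g, 25, seed = r + 1), 5)
  }, 0.0)
  expect_true(all(diff(ratios) < 0))
})

test_that("PSTH recovers rates and surrogate smoothing of a rate step", {
  z <- spike_data(numeric(0), t_stop = 100)
  expect_equal(unique(psth(z, 10)$rate_hz), 0)

  prof <- make_rate_profile("step", 150, rate_from = 10, rate_to = 80,
                            step_at_ms = 75)
  x <- simulate_spike_data(150, "gamma", profile = prof, shape = 1.23,
                           n_trials = 4000, seed = 7)
  r <- psth(x, 1)
  expect_equal(mean(r$rate_hz[r$time_ms < 50]), 10, tolerance = 0.1)
  expect_equal(mean(r$rate_hz[r$time_ms > 100]), 80, tolerance = 0.05)

  # UD turns the step into a linear ramp on [step - dither, step + dither]:
  # the surrogate PSTH matches the step convolved with a 2*dither boxcar
  s <- surrogate_trial_shift(x, dither_ms = 25, seed = 8) # rigid shifts wrap
  su <- surrogate_uniform_dither(concatenate_trials(x), dither_ms = 25,
                                 seed = 8)
  ru <- psth(split_into_trials(su, 150), 5)
  expected <- vapply(ru$time_ms, function(t) {
    lo <- max(t - 25, 0); hi <- min(t + 25, 150)
    (stats::integrate(function(u) ifelse(u < 75, 10, 80), lo, hi)$value) /
      (hi - lo)
  }, 0.0)
  mid <- ru$time_ms > 25 & ru$time_ms < 125
  expect_lt(mean(abs(ru$rate_hz[mid] - expected[mid])), 2.5)
  # ramp starts before the step: rate at step - 20 ms already above 10 Hz
  expect_gt(mean(ru$rate_hz[ru$time_ms > 50 & ru$time_ms < 61]), 12)
})

test_that("spike-count reduction: closed form, Monte-Carlo agreement, ordering", {
  expect_equal(analytic_poisson_reduction(100, 5),
               1 - (1 - exp(-0.5)) / 0.5)
  expect_lt(analytic_poisson_reduction(1e-6, 5), 1e-8) # vanishes at low rate
  expect_error(analytic_poisson_reduction(0, 5), "positive")

  # analytic vs empirical within 3 Monte-Carlo SEs across rates
  for (r in c(10, 50, 100)) {
    em <- expected_spike_count_reduction(r, 5, "poisson", n_spikes = 5e4,
                                         seed = r)
    expect_lt(abs(em$reduction - analytic_poisson_reduction(r, 5)),
              3 * em$se + 1e-3)
  }

  # dead-time and regularity reduce the loss: PPD(3ms) < Gamma(2.5) < Poisson
  red <- function(model, ...) {
    expected_spike_count_reduction(100, 5, model, ..., n_spikes = 5e4,
                                   seed = 9)$reduction
  }
  r_ppd <- red("ppd", dead_time_ms = 3)
  r_gam <- red("gamma", shape = 2.5)
  r_poi <- red("poisson")
  expect_lt(r_ppd, r_gam)
  expect_lt(r_gam, r_poi)

  # UD surrogates of a PPD process lose more spikes than the PPD itself
  r_ud <- expected_spike_count_reduction(100, 5, "ppd", dead_time_ms = 3,
                                         surrogate = "ud", n_spikes = 5e4,
                                         seed = 10)$reduction
  expect_gt(r_ud, r_ppd)

  expect_error(expected_spike_count_reduction(60, 5, "gamma",
                                              mode = "analytic"),
               "Poisson")
})

test_that("reduction increases with rate for models and surrogates", {
  for (m in c("poisson", "ppd", "gamma")) {
    reds <- vapply(c(20, 60, 100), function(r) {
      expected_spike_count_reduction(
        r, 5, m, dead_time_ms = 1.6, shape = 1.23,
        n_spikes = 3e4, seed = r
      )$reduction
    }, 0.0)
    expect_true(all(diff(reds) > 0), label = m)
  }
})
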