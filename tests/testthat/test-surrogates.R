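ppd_train <- function(n_ms = 5e4, seed = 1) {
  simulate_spike_data(n_ms, "ppd", rate_hz = 60, dead_time_ms = 1.6,
                      seed = seed)
}

test_that("uniform dithering preserves count and draws uniform displacements", {
  x <- simulate_spike_data(5e4, "poisson", rate_hz = 60, seed = 1)
  s <- surrogate_uniform_dither(x, dither_ms = 25, seed = 2)
  expect_equal(nrow(s), nrow(x))
  expect_true(all(s$time_ms >= 0 & s$time_ms < 5e4))

  # tiny dither approximates the identity
  s0 <- surrogate_uniform_dither(x, dither_ms = 1e-6, seed = 3)
  expect_lt(max(abs(sort(s0$time_ms) - sort(x$time_ms))), 1e-5)

  # displacement distribution of interior spikes is uniform on [-25, 25]:
  # use a sparse regular train so spike identities survive re-sorting
  reg <- spike_data(seq(100, 2e6, by = 100), t_stop = 2e6 + 100)
  sreg <- surrogate_uniform_dither(reg, dither_ms = 25, seed = 4)
  disp <- sreg$time_ms - reg$time_ms
  expect_true(all(abs(disp) <= 25))
  expect_gt(suppressWarnings(
    stats::ks.test(disp, "punif", -25, 25)
  )$p.value, 0.01)

  # applied to a dead-time train, UD fills in sub-dead-time intervals
  p <- ppd_train(seed = 6)
  sp <- surrogate_uniform_dither(p, 25, seed = 7)
  expect_lt(min(diff(sp$time_ms)), 1.6)
})

test_that("UDD keeps all surrogate ISIs at or above the dead-time, preserving order", {
  p <- ppd_train(seed = 8)
  s <- surrogate_udd(p, dither_ms = 25, dead_time_ms = 1.6, seed = 9)
  expect_equal(nrow(s), nrow(p))
  expect_gte(min(diff(s$time_ms)), 1.6)

  # isolated spike is uniformly dithered on [-dither, dither]
  iso <- spike_data(c(500), t_stop = 1000)
  d <- vapply(1:500, function(k) {
    surrogate_udd(iso, 25, dead_time_ms = 2, seed = k)$time_ms - 500
  }, 0.0)
  expect_true(all(abs(d) <= 25))
  expect_gt(suppressWarnings(stats::ks.test(d, "punif", -25, 25))$p.value, 0.01)

  # with d = 0 spikes never cross (UD spikes may)
  x <- simulate_spike_data(2e4, "poisson", rate_hz = 80, seed = 10)
  s0 <- surrogate_udd(x, 25, dead_time_ms = 0, seed = 11)
  expect_true(all(diff(s0$time_ms) >= 0))

  # dead-time larger than some ISI is clipped with a warning
  expect_warning(surrogate_udd(x, 25, dead_time_ms = 10, seed = 12),
                 "clipping")
})

test_that("JISI-D and ISI-D preserve count, order, dead-time and regularity", {
  p <- ppd_train(n_ms = 1e5, seed = 13)
  for (m in c("jisi", "isi")) {
    s <- make_surrogate(p, m, dither_ms = 25, seed = 14)
    expect_equal(nrow(s), nrow(p))
    expect_gte(min(diff(s$time_ms)), 1.6 - 1e-9)
    # spikes moved by at most the dither width
    expect_lte(max(abs(s$time_ms - p$time_ms)), 25 + 1e-9)
  }

  # regular Gamma input: surrogate CV close to the original CV
  g <- simulate_spike_data(2e5, "gamma", rate_hz = 60, shape = 6.25, seed = 15)
  for (m in c("jisi", "isi")) {
    s <- make_surrogate(g, m, dither_ms = 25, seed = 16)
    expect_equal(cv_isi(s)$cv, cv_isi(g)$cv, tolerance = 0.05)
  }

  # Poisson input: adjacent ISIs are independent, so both modes agree
  x <- simulate_spike_data(1e5, "poisson", rate_hz = 60, seed = 17)
  sj <- make_surrogate(x, "jisi", dither_ms = 25, seed = 18)
  si <- make_surrogate(x, "isi", dither_ms = 25, seed = 19)
  ks <- suppressWarnings(stats::ks.test(diff(sj$time_ms), diff(si$time_ms)))
  expect_gt(ks$p.value, 0.01)

  # too few ISIs is an explicit error
  tiny <- spike_data(c(1, 5, 9), t_stop = 100)
  expect_error(surrogate_isi_dither(tiny, "jisi"), "too few|< 50|only")
})

test_that("trial shifting is a rigid per-train shift with circular wrap", {
  x <- simulate_spike_data(500, "ppd", rate_hz = 60, dead_time_ms = 1.6,
                           n_trials = 20, n_units = 3, seed = 20)
  s <- surrogate_trial_shift(x, dither_ms = 25, seed = 21)
  expect_equal(nrow(s), nrow(x)) # wrap preserves the count exactly

  # within-trial ISI multiset preserved up to the single wrap interval
  for (tr in 1:5) {
    a <- sort(x$time_ms[x$trial_id == tr & x$unit_id == "u01"])
    b <- sort(s$time_ms[s$trial_id == tr & s$unit_id == "u01"])
    if (length(a) >= 3) {
      common <- intersect(round(diff(a), 9), round(diff(b), 9))
      expect_gte(length(common), length(a) - 1 - 2)
    }
  }

  # CV identity across regular and bursty regimes
  for (cv in c(0.4, 0.8, 1.2)) {
    g <- simulate_spike_data(1e5, "gamma", rate_hz = 60,
                             shape = cv_to_shape(cv), seed = 22 + round(10 * cv))
    gs <- split_into_trials(g, 500)
    ss <- surrogate_trial_shift(gs, 25, seed = 23)
    expect_equal(cv_isi(ss)$cv, cv_isi(gs)$cv, tolerance = 0.02)
  }

  # continuous data must be segmented first
  cont <- simulate_spike_data(2000, "poisson", rate_hz = 50, seed = 24)
  expect_error(surrogate_trial_shift(cont, 25), "segment")

  # spill-and-drop alternative only loses spikes at the borders
  sdrop <- surrogate_trial_shift(x, 25, wrap = FALSE, seed = 25)
  expect_lte(nrow(sdrop), nrow(x))
})

test_that("window shuffling permutes binned counts within exclusive windows", {
  x <- simulate_spike_data(10000, "poisson", rate_hz = 60, seed = 26)
  s <- surrogate_window_shuffle(x, dither_ms = 25, bin_ms = 5, seed = 27)
  co <- binarize(x, 5)$counts[[1]]
  cs <- binarize(s, 5)$counts[[1]]
  expect_equal(sum(co), sum(cs)) # binned count preserved
  # counts are a permutation of the originals within every 50 ms window
  for (w0 in seq(1, 2000, by = 10)) {
    idx <- w0:(w0 + 9)
    expect_equal(sort(co[1, idx]), sort(cs[1, idx]))
  }

  # window = bin: occupancy unchanged, only within-bin jitter
  s1 <- surrogate_window_shuffle(x, bin_ms = 5, window_ms = 5, seed = 28)
  expect_identical(binarize(s1, 5)$counts[[1]], co)

  expect_error(surrogate_window_shuffle(x, bin_ms = 5, window_ms = 12),
               "multiple")
})

test_that("all six methods conserve the (binned) spike count", {
  x <- simulate_spike_data(500, "ppd", rate_hz = 60, dead_time_ms = 1.6,
                           n_trials = 10, n_units = 2, seed = 29)
  xc <- concatenate_trials(x)
  for (m in c("ud", "udd", "jisi", "isi")) {
    expect_equal(nrow(make_surrogate(xc, m, dither_ms = 25, seed = 30)),
                 nrow(xc), label = m)
  }
  expect_equal(nrow(surrogate_trial_shift(x, 25, seed = 31)), nrow(x))
  ws <- surrogate_window_shuffle(xc, 25, bin_ms = 5, seed = 32)
  expect_equal(binarize(ws, 5)$n_spikes, binarize(xc, 5)$n_spikes)
})

test_that("surrogate streams are reproducible and lazily consumable", {
  x <- simulate_spike_data(2000, "poisson", rate_hz = 40, seed = 33)
  a <- make_surrogates(x, 3, "ud", dither_ms = 25, seed = 34)
  b <- make_surrogates(x, 3, "ud", dither_ms = 25, seed = 34)
  expect_identical(lapply(a, function(s) s$time_ms),
                   lapply(b, function(s) s$time_ms))
  expect_false(identical(a[[1]]$time_ms, a[[2]]$time_ms))
  expect_identical(make_surrogates(x, 0, "ud"), list())

  counts <- make_surrogates(x, 4, "ud", dither_ms = 25, seed = 35,
                            .f = function(s, r) nrow(s))
  expect_equal(unlist(counts), rep(nrow(x), 4))
})
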