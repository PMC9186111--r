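test_that("a planted pattern is recovered with its exact signature", {
  x <- planted_pattern_data(n_occ = 5)
  pats <- mine_patterns(binarize(x, 5), window_bins = 4, min_size = 3,
                        min_occ = 5)
  expect_equal(nrow(pats), 1L)
  expect_equal(pats$z, 3L)
  expect_equal(pats$c, 5L)
  expect_equal(pats$d, 3L)
  expect_equal(pats$units[[1]], c("u1", "u2", "u3"))
  expect_equal(pats$lags[[1]], c(0L, 1L, 3L))
  expect_equal(nrow(pats$anchors[[1]]), 5L)

  expect_error(mine_patterns(binarize(x, 5), window_bins = 1000), "exceeds")
})

test_that("the miner agrees with a brute-force enumerator on random instances", {
  for (seed in 1:12) {
    n_units <- sample(3:6, 1)
    n_bins <- sample(30:80, 1)
    x <- random_occupancy_data(n_units, n_bins, p = 0.22, seed = seed)
    b <- binarize(x, 5)
    w <- sample(2:4, 1)
    occ <- occupancy(b)
    pats <- mine_patterns(b, w, min_size = 2, max_size = 4, min_occ = 3,
                          closed = TRUE)
    oracle <- bf_mine(occ, w, min_size = 2, max_size = 4, min_occ = 3,
                      closed = TRUE)
    expect_same_patterns(pats, oracle, n_units)
  }
})

test_that("no closed pattern is a strict subset of another with identical support", {
  x <- random_occupancy_data(5, 60, p = 0.3, seed = 99)
  pats <- mine_patterns(binarize(x, 5), 3, min_size = 2, min_occ = 3,
                        closed = TRUE)
  keys <- lapply(seq_len(nrow(pats)), function(i) {
    paste(pats$units[[i]], pats$lags[[i]])
  })
  for (i in seq_len(nrow(pats))) {
    for (j in seq_len(nrow(pats))) {
      if (i != j && pats$c[i] == pats$c[j]) {
        expect_false(all(keys[[i]] %in% keys[[j]]) &&
                       length(keys[[i]]) < length(keys[[j]]))
      }
    }
  }
})

test_that("the exhaustive triplet counter matches the miner at fixed size 3", {
  for (seed in 1:6) {
    x <- random_occupancy_data(5, 70, p = 0.3, seed = 100 + seed)
    b <- binarize(x, 5)
    spec_fast <- pattern_spectrum(x, 5, 4, min_size = 3, max_size = 3,
                                  min_occ = 2)
    pats <- mine_patterns(b, 4, min_size = 3, max_size = 3, min_occ = 2,
                          closed = FALSE)
    spec_slow <- build_spectrum(pats)
    expect_equal(
      dplyr::arrange(tibble::as_tibble(spec_fast), z, d, c),
      dplyr::arrange(tibble::as_tibble(spec_slow), z, d, c)
    )
  }
})

test_that("the pattern spectrum pools signatures and conserves pattern counts", {
  x <- random_occupancy_data(6, 80, p = 0.3, seed = 7)
  pats <- mine_patterns(binarize(x, 5), 3, min_size = 2, min_occ = 4)
  spec <- build_spectrum(pats)
  expect_equal(sum(spec$count), nrow(pats))
  expect_true(all(spec$count >= 1))

  # empty data give an empty spectrum
  e <- spike_data(numeric(0), t_stop = 500)
  expect_equal(nrow(pattern_spectrum(e, 5, 3)), 0L)

  # two planted patterns with identical signature pool into one entry
  two <- spike_data(tibble::tibble(
    trial_id = 1L,
    unit_id = rep(c("a", "b", "c", "d"), each = 4),
    time_ms = c(
      seq(2, 152, by = 50), seq(7, 157, by = 50), # a->b at 1 bin, 4 times
      seq(202, 352, by = 50), seq(207, 357, by = 50) # c->d, same signature
    )
  ), t_stop = 400)
  sp2 <- pattern_spectrum(two, 5, 2, min_size = 2, max_size = 2, min_occ = 4)
  expect_equal(sp2$count[sp2$z == 2 & sp2$c == 4 & sp2$d == 1], 2L)
})

test_that("min_occ default follows the 10-or-30%-of-trials rule", {
  expect_equal(min_occ_default(36), 11L)
  expect_equal(min_occ_default(10), 10L)
  expect_equal(min_occ_default(100), 30L)
  expect_equal(min_occ_default(1), 10L)
})

test_that("p-value spectrum is a cumulative surrogate statistic", {
  x <- simulate_spike_data(1500, "poisson", rate_hz = 60, n_units = 5,
                           seed = 11)
  pv <- pvalue_spectrum(x, "ud", n_surrogates = 40, bin_ms = 5,
                        window_bins = 4, min_occ = 3, dither_ms = 25,
                        seed = 12)
  expect_true(all(pv$p >= 0 & pv$p <= 1))
  # non-increasing in c at fixed (z, d)
  mono <- pv |>
    dplyr::group_by(z, d) |>
    dplyr::summarise(ok = all(diff(p) <= 1e-12), .groups = "drop")
  expect_true(all(mono$ok))

  # p-values are multiples of 1/R
  expect_true(all(abs(pv$p * 40 - round(pv$p * 40)) < 1e-9))

  # same master seed reproduces the spectrum exactly
  pv2 <- pvalue_spectrum(x, "ud", n_surrogates = 40, bin_ms = 5,
                         window_bins = 4, min_occ = 3, dither_ms = 25,
                         seed = 12)
  expect_identical(tibble::as_tibble(pv), tibble::as_tibble(pv2))
})

test_that("p-value spectrum equals a naive per-surrogate re-mining oracle", {
  x <- simulate_spike_data(250, "poisson", rate_hz = 70, n_units = 4,
                           seed = 13)
  R <- 60
  w <- 4
  pv <- pvalue_spectrum(x, "ud", n_surrogates = R, bin_ms = 5,
                        window_bins = w, min_occ = 3, dither_ms = 25,
                        seed = 14)
  # oracle: regenerate the same surrogate stream, brute-force mine each one,
  # and cumulate indicators by hand
  seeds <- spikesurr:::surrogate_seeds(14, R)
  maxc <- matrix(0L, R, w)
  for (r in seq_len(R)) {
    s <- surrogate_uniform_dither(x, dither_ms = 25, seed = seeds[r])
    found <- bf_mine(occupancy(binarize(s, 5)), w, min_size = 3, max_size = 3,
                     min_occ = 3, closed = FALSE)
    for (o in found) {
      maxc[r, o$d + 1] <- max(maxc[r, o$d + 1], o$c)
    }
  }
  for (i in seq_len(nrow(pv))) {
    expect_equal(pv$p[i], mean(maxc[, pv$d[i] + 1] >= pv$c[i]))
  }
})

test_that("PSF applies BH over boundary signatures only", {
  spec <- spikesurr:::new_pattern_spectrum(
    tibble::tibble(z = 3L, c = c(10L, 11L, 12L, 15L), d = 0L,
                   count = c(5L, 3L, 1L, 1L)),
    window_bins = 3, min_occ = 10, bin_ms = 5
  )
  # all p = 1: nothing significant
  pv1 <- structure(
    tibble::tibble(z = 3L, d = 0L, c = 10:16, p = 1),
    n_surrogates = 100, min_occ = 10, window_bins = 3, bin_ms = 5,
    class = c("pvalue_spectrum", class(tibble::tibble()))
  )
  r1 <- psf(spec, pv1)
  # boundary test set: c = 12 (13 unoccupied) and c = 15
  expect_equal(sort(r1$tests$c), c(12L, 15L))
  expect_equal(nrow(r1$significant), 0L)
  expect_equal(glance(r1)$n_tests, 2L)

  # a signature never seen in surrogates is significant, and the cumulated
  # smaller signatures fall below the BH threshold with it
  pv2 <- pv1
  pv2$p <- c(1, 1, 1, 1, 1, 0.0, 0.0) # p(c >= 15) = 0
  r2 <- psf(spec, pv2)
  expect_true(15L %in% r2$significant$c)
  expect_equal(r2$p_threshold, 0)

  # single-test case reports the plain alpha threshold
  spec1 <- spikesurr:::new_pattern_spectrum(
    tibble::tibble(z = 3L, c = 10L, d = 0L, count = 1L), 3, 10, 5
  )
  pv3 <- pv1[pv1$c == 10, ]
  attr(pv3, "window_bins") <- 3; attr(pv3, "bin_ms") <- 5
  class(pv3) <- class(pv1)
  pv3$p <- 0.04
  r3 <- psf(spec1, pv3, alpha = 0.05)
  expect_equal(nrow(r3$tests), 1L)
  expect_true(r3$tests$significant)
  expect_equal(tidy(r3)$c, 10L)
})

test_that("p-value lookups fall back to zero beyond the stored range", {
  x <- simulate_spike_data(800, "poisson", rate_hz = 60, n_units = 4,
                           seed = 15)
  pv <- pvalue_spectrum(x, "ud", 20, bin_ms = 5, window_bins = 3,
                        min_occ = 3, dither_ms = 25, seed = 16)
  expect_equal(pspec_p(pv, 3, max(pv$c) + 50, 0), 0)
  expect_true(is.na(pspec_p(pv, 3, 5, 99)))
})
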