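# The six surrogate generation methods. Each consumes a spike_data object and
# returns a surrogate spike_data of the same shape; spike displacement happens
# independently per (trial, unit) train unless stated otherwise.

# ---- per-train workers ------------------------------------------------------

ud_train <- function(times, t0, t1, dither, boundary = "redraw") {
  n <- length(times)
  if (!n) return(times)
  new <- times + runif(n, -dither, dither)
  bad <- new < t0 | new >= t1
  if (boundary == "redraw") {
    while (any(bad)) {
      new[bad] <- times[bad] + runif(sum(bad), -dither, dither)
      bad <- new < t0 | new >= t1
    }
  } else if (boundary == "clip") {
    new <- pmin(pmax(new, t0), t1 - 1e-9)
  } else { # discard
    new <- new[!bad]
  }
  sort(new)
}

udd_train <- function(times, t0, t1, dither, dead_time) {
  n <- length(times)
  if (n <= 1) return(ud_train(times, t0, t1, dither))
  isis <- diff(times)
  if (any(isis < dead_time)) {
    rlang::warn(sprintf(
      "Original ISIs below dead_time; clipping dead_time from %g to %g ms.",
      dead_time, min(isis)
    ))
    dead_time <- min(isis)
  }
  res <- udd_dither_cpp(times, t0, t1, dither, dead_time)
  structure(res$times, n_stuck = res$n_stuck)
}

# Gaussian histogram smoothing (kernel truncated at 4 sd, zero boundary):
# implemented as a banded smoothing operator so 1-d and 2-d cases are plain
# matrix products
smoothing_operator <- function(n, sigma_bins) {
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  d <- outer(seq_len(n), seq_len(n), `-`)
  K <- matrix(0, n, n)
  inside <- abs(d) <= half
  K[inside] <- k[d[inside] + half + 1L]
  K
}

gaussian_smooth_1d <- function(v, sigma_bins) {
  if (sigma_bins <= 0) return(v)
  as.numeric(smoothing_operator(length(v), sigma_bins) %*% v)
}

gaussian_smooth_2d <- function(m, sigma_bins) {
  if (sigma_bins <= 0) return(m)
  K <- smoothing_operator(nrow(m), sigma_bins)
  K %*% m %*% t(K)
}

# Build the (smoothed) joint-ISI matrix of one unit from pooled within-trial
# ISIs. mode "isi" uses the outer product of the smoothed 1-d ISI histogram
# with itself. After smoothing, histogram mass below the unit's dead-time
# (cutoff_ms, estimated as the minimal observed ISI) is removed on both axes
# so that sampled intervals never undercut the dead-time.
build_jisi <- function(isis_prev, isis_next, all_isis, mode, hist_bin, sigma,
                       cutoff_ms = 0, max_isi_ms = 250) {
  max_isi <- min(max(all_isis), max_isi_ms)
  nb <- max(2L, ceiling(max_isi / hist_bin) + 1L)
  sigma_bins <- sigma / hist_bin
  if (mode == "isi") {
    idx <- pmin(floor(all_isis / hist_bin) + 1L, nb)
    p1 <- gaussian_smooth_1d(tabulate(idx, nbins = nb), sigma_bins)
    if (cutoff_ms > 0) p1[((seq_len(nb)) - 0.5) * hist_bin < cutoff_ms] <- 0
    J <- outer(p1, p1)
  } else {
    i1 <- pmin(floor(isis_prev / hist_bin) + 1L, nb)
    i2 <- pmin(floor(isis_next / hist_bin) + 1L, nb)
    J <- matrix(tabulate((i2 - 1L) * nb + i1, nbins = nb * nb), nrow = nb)
    J <- gaussian_smooth_2d(J, sigma_bins)
    if (cutoff_ms > 0) {
      kcut <- ((seq_len(nb)) - 0.5) * hist_bin < cutoff_ms
      J[kcut, ] <- 0
      J[, kcut] <- 0
    }
  }
  list(J = J, nb = nb, hist_bin = hist_bin, cutoff = cutoff_ms)
}

# Dither the interior spikes of one train along the anti-diagonal of J.
# Spikes are processed left to right: the preceding interval tau is measured
# to the already-dithered predecessor, the following interval tau' to the
# original successor, and the new position preserves their sum. The new
# interval pair is sampled from the discretized conditional of J along the
# anti-diagonal, restricted to |displacement| <= dither and to keeping at
# least the dead-time cutoff to both neighbors, by inverse CDF; zero-mass
# conditionals leave the spike in place. Order and spike count are preserved.
jisi_dither_train <- function(times, jisi, dither) {
  if (length(times) < 3) return(times)
  res <- jisi_dither_cpp(times, jisi$J, jisi$hist_bin, jisi$cutoff %||% 0,
                         dither)
  structure(res$times, n_stuck = res$n_stuck)
}

win_shuffle_train <- function(times, t0, t1, bin_ms, window_bins) {
  n_bins <- floor((t1 - t0) / bin_ms + 1e-9)
  rel <- times - t0
  keep <- rel < n_bins * bin_ms
  bin <- floor(rel[keep] / bin_ms) # 0-based
  counts <- tabulate(bin + 1L, nbins = n_bins)
  # independent uniform permutation of the bins within each window: order by
  # (window index, random key); window positions are contiguous, so the
  # reordered counts land back in their own window
  wi <- (seq_len(n_bins) - 1L) %/% window_bins
  new_counts <- counts[order(wi, runif(n_bins))]
  reps <- rep(seq_len(n_bins) - 1L, new_counts)
  sort(t0 + (reps + runif(length(reps))) * bin_ms)
}

# ---- exported surrogate methods --------------------------------------------

#' Uniform dithering (UD)
#'
#' Displaces each spike independently by a uniform random jitter
#' `U[-dither_ms, +dither_ms]` around its original position. Destroys
#' correlations on the fine timescale while preserving the rate profile on
#' scales coarser than the dither width; does not preserve dead-times or
#' regularity. Displacements that would leave the observation interval are
#' redrawn by default (preserving the spike count without distorting the
#' displacement distribution); alternatives are clipping to the boundary or
#' discarding the spike.
#'
#' @param x A `spike_data` object.
#' @param dither_ms Dither half-width in ms (default 25).
#' @param boundary `"redraw"` (default), `"clip"` or `"discard"`.
#' @param seed Optional integer seed.
#' @return A surrogate `spike_data` object.
#' @export
surrogate_uniform_dither <- function(x, dither_ms = 25,
                                     boundary = c("redraw", "clip", "discard"),
                                     seed = NULL) {
  stopifnot(inherits(x, "spike_data"), dither_ms > 0)
  boundary <- match.arg(boundary)
  t0 <- t_start(x)
  t1 <- t_stop(x)
  run <- function() {
    # displacement is independent per spike, so dither all trains at once
    out <- tibble::as_tibble(x)
    tmp <- out$time_ms + runif(nrow(out), -dither_ms, dither_ms)
    if (boundary == "redraw") {
      bad <- tmp < t0 | tmp >= t1
      while (any(bad)) {
        tmp[bad] <- out$time_ms[bad] + runif(sum(bad), -dither_ms, dither_ms)
        bad <- tmp < t0 | tmp >= t1
      }
      out$time_ms <- tmp
    } else if (boundary == "clip") {
      out$time_ms <- pmin(pmax(tmp, t0), t1 - 1e-9)
    } else { # discard
      keep <- tmp >= t0 & tmp < t1
      out <- out[keep, ]
      out$time_ms <- tmp[keep]
    }
    new_spike_data(out, t0, t1, trial_ids = trials_of(x),
                   unit_ids = units_of(x))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Uniform dithering with dead-time (UDD)
#'
#' Like uniform dithering, but no two dithered spikes may come closer than the
#' dead-time `d`: spike `i` is displaced uniformly within
#' `[max(s'_{i-1} + d, s_i - dither), min(s_{i+1} - d, s_i + dither)]`,
#' processed left to right against the already-dithered predecessor and the
#' original successor. Spike order and count are preserved; a spike whose
#' admissible window is empty stays in place (the number of such spikes is
#' recorded in the `n_stuck` attribute of the result).
#'
#' @inheritParams surrogate_uniform_dither
#' @param dead_time_ms Dead-time in ms; `NULL` (default) estimates it per unit
#'   with [estimate_deadtime()].
#' @param d_max_ms Cap for the estimated dead-time.
#' @return A surrogate `spike_data` object.
#' @export
surrogate_udd <- function(x, dither_ms = 25, dead_time_ms = NULL,
                          d_max_ms = 4, seed = NULL) {
  stopifnot(inherits(x, "spike_data"), dither_ms > 0)
  if (is.null(dead_time_ms)) {
    dt_tbl <- estimate_deadtime(x, d_max_ms)
    d_of <- stats::setNames(dt_tbl$dead_time_ms, dt_tbl$unit_id)
  } else {
    d_of <- NULL
  }
  stuck <- 0L
  run <- function() map_trains(x, function(times, t0, t1, unit, ...) {
    d <- if (is.null(d_of)) dead_time_ms else unname(d_of[unit])
    res <- udd_train(times, t0, t1, dither_ms, d)
    stuck <<- stuck + (attr(res, "n_stuck") %||% 0L)
    as.numeric(res)
  })
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "n_stuck") <- stuck
  out
}

#' Joint-ISI and ISI dithering (JISI-D / ISI-D)
#'
#' Displaces each spike according to the unit's (joint) inter-spike-interval
#' distribution, sampled from the data. The joint-ISI histogram of
#' (preceding ISI, following ISI) pairs is built at `hist_bin_ms` resolution
#' and smoothed with an isotropic 2-d Gaussian of width `sigma_ms`
#' (mode `"isi"` instead uses the outer product of the smoothed 1-d ISI
#' histogram with itself, i.e. it assumes adjacent ISIs independent). Each
#' spike is then redrawn along the anti-diagonal of that distribution:
#' processing left to right, its new position preserves the sum of the
#' interval to the already-dithered predecessor and the interval to the
#' original successor, restricted to a displacement of at most `dither_ms`
#' and to keeping at least the dead-time to both neighbors, sampled by
#' inverse CDF on the discretized conditional. Spike order and count are
#' preserved, and on dead-time data no surrogate ISI undercuts the dead-time.
#' Zero-mass conditionals leave the spike in place (counted in the `n_stuck`
#' attribute). The first and last spike of a train have no adjacent ISI pair
#' and stay in place.
#'
#' @inheritParams surrogate_uniform_dither
#' @param mode `"jisi"` (joint histogram) or `"isi"` (independent-ISI product).
#' @param hist_bin_ms Histogram resolution in ms (default 1).
#' @param sigma_ms Gaussian smoothing width in ms (default 2, i.e. of the
#'   order of milliseconds).
#' @param cutoff Remove smoothed histogram mass below the unit's minimal
#'   observed ISI (its estimated dead-time) so that the surrogate preserves
#'   the dead-time (default `TRUE`).
#' @param max_isi_ms Truncation limit of the histogram support in ms; longer
#'   intervals are lumped into the top bin (default 250).
#' @param min_isis Minimum number of ISIs required to populate the histogram.
#' @return A surrogate `spike_data` object.
#' @export
surrogate_isi_dither <- function(x, mode = c("jisi", "isi"), dither_ms = 25,
                                 hist_bin_ms = 1, sigma_ms = 2, cutoff = TRUE,
                                 max_isi_ms = 250, min_isis = 50,
                                 seed = NULL) {
  stopifnot(inherits(x, "spike_data"), dither_ms > 0, sigma_ms > 0)
  mode <- match.arg(mode)
  # pool within-trial ISIs (and adjacent-ISI pairs) per unit in one pass
  isis <- x |>
    dplyr::group_by(.data$unit_id, .data$trial_id) |>
    dplyr::reframe(
      isi = diff(.data$time_ms),
      prev_ok = c(rep(TRUE, max(length(.data$time_ms) - 2, 0)), FALSE),
      nxt_ok = c(FALSE, rep(TRUE, max(length(.data$time_ms) - 2, 0)))
    )
  jisi_of <- list()
  for (u in units_of(x)) {
    sub <- isis[isis$unit_id == u, ]
    all <- sub$isi
    prev <- sub$isi[sub$prev_ok]
    nxt <- sub$isi[sub$nxt_ok]
    if (length(all) < min_isis) {
      rlang::abort(sprintf(
        "Unit %s has only %d ISIs (< %d); too few to estimate the %s histogram. Consider mode = \"isi\" or a larger sigma_ms.",
        u, length(all), min_isis, toupper(mode)
      ))
    }
    jisi_of[[u]] <- build_jisi(prev, nxt, all, mode, hist_bin_ms, sigma_ms,
                               cutoff_ms = if (cutoff) min(all) else 0,
                               max_isi_ms = max_isi_ms)
  }
  stuck <- 0L
  run <- function() map_trains(x, function(times, t0, t1, unit, ...) {
    res <- jisi_dither_train(times, jisi_of[[unit]], dither_ms)
    stuck <<- stuck + (attr(res, "n_stuck") %||% 0L)
    as.numeric(res)
  })
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "n_stuck") <- stuck
  out
}

#' Trial shifting (TR-SHIFT)
#'
#' Shifts all spike times of one (unit, trial) train identically by a random
#' uniform amount `U[-dither_ms, +dither_ms]`, drawn independently neuron by
#' neuron and trial by trial. The entire within-trial spike train structure
#' (ISIs, regularity, dead-time) is kept intact; only across-train
#' coordination is destroyed. Spikes shifted past a trial boundary are wrapped
#' circularly within the trial by default, preserving the spike count exactly
#' (alternative: `wrap = FALSE` drops them). Requires trial structure; use
#' [split_into_trials()] to cut a continuous recording into segments first.
#'
#' @inheritParams surrogate_uniform_dither
#' @param wrap Wrap shifted spikes circularly at the trial boundaries
#'   (default `TRUE`).
#' @return A surrogate `spike_data` object.
#' @export
surrogate_trial_shift <- function(x, dither_ms = 25, wrap = TRUE, seed = NULL) {
  stopifnot(inherits(x, "spike_data"), dither_ms > 0)
  if (length(trials_of(x)) < 2) {
    rlang::abort(paste(
      "Trial shifting needs trial structure;",
      "cut the recording into segments first (see split_into_trials())."
    ))
  }
  dur <- trial_duration(x)
  t0 <- t_start(x)
  run <- function() {
    out <- tibble::as_tibble(x)
    # one shift per (trial, unit), drawn in a fixed group order
    key <- factor(paste(out$trial_id, out$unit_id, sep = "\r"))
    shifts <- runif(nlevels(key), -dither_ms, dither_ms)
    shifted <- out$time_ms - t0 + shifts[as.integer(key)]
    if (wrap) {
      out$time_ms <- t0 + (shifted %% dur)
    } else {
      keep <- shifted >= 0 & shifted < dur
      out <- out[keep, ]
      out$time_ms <- t0 + shifted[keep]
    }
    new_spike_data(out, t0, t0 + dur, trial_ids = trials_of(x),
                   unit_ids = units_of(x))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Window shuffling (WIN-SHUFF)
#'
#' Divides each train into successive exclusive windows of duration
#' `window_ms` (a multiple of the bin width `bin_ms`), bins the spikes, and
#' randomly permutes the bins within each window; each spike then gets a
#' uniform random time inside its (new) bin. The binned spike count is
#' preserved exactly within every window by construction; the rate profile
#' becomes locally stationary at the window scale. The window defaults to
#' twice the dither width used by the other methods.
#'
#' @inheritParams surrogate_uniform_dither
#' @param bin_ms Bin width in ms.
#' @param window_ms Shuffle window in ms; must be a multiple of `bin_ms`
#'   (default `2 * dither_ms`).
#' @return A surrogate `spike_data` object.
#' @export
surrogate_window_shuffle <- function(x, dither_ms = 25, bin_ms = 5,
                                     window_ms = 2 * dither_ms, seed = NULL) {
  stopifnot(inherits(x, "spike_data"), bin_ms > 0)
  wb <- window_ms / bin_ms
  if (abs(wb - round(wb)) > 1e-9 || wb < 1) {
    rlang::abort("`window_ms` must be a positive multiple of `bin_ms`.")
  }
  run <- function() map_trains(x, function(times, t0, t1, ...) {
    win_shuffle_train(times, t0, t1, bin_ms, as.integer(round(wb)))
  })
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate one surrogate by method name
#'
#' Thin dispatcher over the six surrogate methods, convenient for
#' configuration-driven pipelines.
#'
#' @param x A `spike_data` object.
#' @param method One of `"ud"`, `"udd"`, `"jisi"`, `"isi"`, `"trshift"`,
#'   `"winshuff"`.
#' @param ... Passed to the method (e.g. `dither_ms`, `dead_time_ms`,
#'   `bin_ms`).
#' @param seed Optional integer seed.
#' @return A surrogate `spike_data` object.
#' @export
make_surrogate <- function(x, method, ..., seed = NULL) {
  method <- match.arg(method, surrogate_methods())
  switch(method,
    ud = surrogate_uniform_dither(x, ..., seed = seed),
    udd = surrogate_udd(x, ..., seed = seed),
    jisi = surrogate_isi_dither(x, mode = "jisi", ..., seed = seed),
    isi = surrogate_isi_dither(x, mode = "isi", ..., seed = seed),
    trshift = surrogate_trial_shift(x, ..., seed = seed),
    winshuff = surrogate_window_shuffle(x, ..., seed = seed)
  )
}

#' @rdname make_surrogate
#' @export
surrogate_methods <- function() {
  c("ud", "udd", "jisi", "isi", "trshift", "winshuff")
}

#' Stream many surrogate realizations
#'
#' Generates `n` independent surrogates of `x`. The seed of surrogate `r` is
#' derived deterministically from the master seed (a counter-based draw), so
#' the stream is bit-for-bit reproducible and any single surrogate can be
#' regenerated in isolation. When `.f` is supplied it is applied to each
#' surrogate as it is produced and only the results are kept, so arbitrarily
#' many surrogates can be processed without materializing them all.
#'
#' @inheritParams make_surrogate
#' @param n Number of surrogates (>= 0).
#' @param .f Optional function `(surrogate, index) -> value`.
#' @param seed Master seed.
#' @return A list of `n` surrogates, or of `.f` results.
#' @export
make_surrogates <- function(x, n, method, ..., .f = NULL, seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(list())
  seeds <- surrogate_seeds(seed, n)
  lapply(seq_len(n), function(r) {
    s <- make_surrogate(x, method, ..., seed = seeds[r])
    if (is.null(.f)) s else .f(s, r)
  })
}

surrogate_seeds <- function(seed, n) {
  if (is.null(seed)) return(sample.int(.Machine$integer.max - 1L, n))
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
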