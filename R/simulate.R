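# Renewal point-process generators (Poisson, Poisson-with-dead-time, Gamma),
# stationary and nonstationary, plus the estimators linking data to model
# parameters. All times in ms, rates in Hz.

#' Construct a sampled firing-rate profile
#'
#' A rate profile is a tibble with columns `time_ms` (uniform grid, starting
#' at the interval onset) and `rate_hz` (nonnegative), of class
#' `rate_profile`. Its cumulative integral (the operational time
#' \eqn{\Lambda(t)}, in expected spike counts) is available through
#' [cumulative_rate()].
#'
#' @param time_ms Uniformly spaced sample times in ms (first sample = interval
#'   onset).
#' @param rate_hz Nonnegative rates in Hz, same length as `time_ms`.
#' @return A `rate_profile` tibble.
#' @export
rate_profile <- function(time_ms, rate_hz) {
  stopifnot(length(time_ms) == length(rate_hz), length(time_ms) >= 2)
  dt <- diff(time_ms)
  if (any(abs(dt - dt[1]) > 1e-8 * dt[1])) {
    rlang::abort("`time_ms` must be a uniform grid.")
  }
  if (any(!is.finite(rate_hz)) || any(rate_hz < 0)) {
    rlang::abort("`rate_hz` must be finite and nonnegative.")
  }
  structure(
    tibble::tibble(time_ms = as.double(time_ms), rate_hz = as.double(rate_hz)),
    dt = dt[1],
    class = c("rate_profile", class(tibble::tibble()))
  )
}

#' Cumulative rate (operational time) of a profile
#'
#' Trapezoidal integral of the rate, converted to expected spike counts;
#' starts at 0 at the first grid point and is nondecreasing.
#'
#' @param profile A `rate_profile`.
#' @return Numeric vector of \eqn{\Lambda(t)} on the profile grid.
#' @export
cumulative_rate <- function(profile) {
  stopifnot(inherits(profile, "rate_profile"))
  dt <- attr(profile, "dt")
  r <- profile$rate_hz / 1000 # spikes per ms
  c(0, cumsum((r[-1] + r[-length(r)]) / 2 * dt))
}

#' Build standard rate profiles
#'
#' Constant, step, or smooth band-limited random profiles ("experimental":
#' a sum of a few low-frequency cosine components rescaled into a stated rate
#' band, emulating the slow rate modulations of cortical recordings for
#' false-positive calibration studies).
#'
#' @param kind One of `"constant"`, `"step"`, `"experimental"`.
#' @param duration_ms Profile duration in ms.
#' @param rate_hz Rate for `kind = "constant"` (Hz).
#' @param rate_from,rate_to,step_at_ms Step parameters: the rate jumps from
#'   `rate_from` to `rate_to` at `step_at_ms`.
#' @param rate_range Two-element rate band (Hz) for `kind = "experimental"`.
#' @param n_components Number of random low-frequency components.
#' @param max_freq_hz Highest component frequency (Hz); defaults to 4 Hz so
#'   modulations live on the ~100 ms-and-slower timescale.
#' @param dt_ms Grid step in ms.
#' @param seed Optional integer seed for the random profile.
#' @return A `rate_profile`.
#' @export
make_rate_profile <- function(kind = c("constant", "step", "experimental"),
                              duration_ms,
                              rate_hz = 60,
                              rate_from = 10, rate_to = 80,
                              step_at_ms = duration_ms / 2,
                              rate_range = c(5, 80),
                              n_components = 4,
                              max_freq_hz = 4,
                              dt_ms = 1,
                              seed = NULL) {
  kind <- match.arg(kind)
  tms <- seq(0, duration_ms, by = dt_ms)
  r <- switch(kind,
    constant = rep(rate_hz, length(tms)),
    step = ifelse(tms < step_at_ms, rate_from, rate_to),
    experimental = {
      draw <- function() {
        freq <- runif(n_components, 0.2, max_freq_hz) / 1000 # cycles per ms
        phase <- runif(n_components, 0, 2 * pi)
        amp <- runif(n_components, 0.3, 1)
        y <- colSums(amp * t(sapply(seq_len(n_components), function(k) {
          cos(2 * pi * freq[k] * tms + phase[k])
        })))
        lo <- min(y); hi <- max(y)
        rate_range[1] + (y - lo) / (hi - lo) * diff(rate_range)
      }
      if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    }
  )
  if (any(r < 0)) rlang::abort("Negative rates are not allowed.")
  rate_profile(tms, r)
}

# interpolate profile rate at arbitrary times (ms, relative to grid origin)
profile_rate_at <- function(profile, t) {
  approx(profile$time_ms, profile$rate_hz, xout = t, rule = 2)$y
}

# inverse operational time: map Lambda values back to real time by monotone
# linear interpolation on the grid
op_time_inverse <- function(profile) {
  lam <- cumulative_rate(profile)
  tms <- profile$time_ms
  keep <- c(TRUE, diff(lam) > 0)
  lam_u <- lam[keep]; tms_u <- tms[keep]
  function(v) approx(lam_u, tms_u, xout = v, rule = 2)$y
}

# ---- single-train generators (numeric vector of times on [0, duration)) ----

renewal_times <- function(duration_ms, mean_isi_ms, draw_isi, burn_isis = 10) {
  # The process is started a number of mean intervals before the observation
  # window, so that the window sees the (approximately) equilibrium process
  # rather than the ordinary-renewal start transient. ISIs are drawn in
  # chunks until the train covers the duration.
  burn <- burn_isis * mean_isi_ms
  total <- duration_ms + burn
  n_guess <- max(16, ceiling(total / mean_isi_ms * 1.1 +
                               4 * sqrt(total / mean_isi_ms)))
  times <- cumsum(draw_isi(n_guess))
  while (length(times) && times[length(times)] < total) {
    times <- c(times, times[length(times)] + cumsum(draw_isi(n_guess)))
  }
  times <- times - burn
  times[times >= 0 & times < duration_ms]
}

sim_poisson_stat <- function(rate_hz, duration_ms) {
  if (rate_hz == 0) return(numeric(0))
  n <- rpois(1, rate_hz / 1000 * duration_ms)
  sort(runif(n, 0, duration_ms))
}

sim_ppd_stat <- function(rate_hz, dead_time_ms, duration_ms) {
  if (rate_hz == 0) return(numeric(0))
  r <- rate_hz / 1000
  if (r * dead_time_ms >= 1) {
    rlang::abort("Infeasible dead-time process: rate * dead_time >= 1.")
  }
  r_eff <- r / (1 - r * dead_time_ms)
  renewal_times(duration_ms, 1 / r,
                function(n) dead_time_ms + rexp(n, r_eff))
}

sim_gamma_stat <- function(rate_hz, shape, duration_ms) {
  if (shape <= 0) rlang::abort("Gamma shape must be positive.")
  if (rate_hz == 0) return(numeric(0))
  r <- rate_hz / 1000
  renewal_times(duration_ms, 1 / r,
                function(n) rgamma(n, shape = shape, rate = shape * r))
}

thin_to_profile <- function(times, profile, rate_max) {
  if (!length(times)) return(times)
  p <- profile_rate_at(profile, times) / rate_max
  times[runif(length(times)) < p]
}

sim_poisson_profile <- function(profile, duration_ms) {
  rate_max <- max(profile$rate_hz)
  thin_to_profile(sim_poisson_stat(rate_max, duration_ms), profile, rate_max)
}

## nonstationary PPD: stationary PPD at the temporal maximum rate, then
## rejection of single spikes with probability 1 - lambda(t)/lambda_max
sim_ppd_profile <- function(profile, dead_time_ms, duration_ms) {
  rate_max <- max(profile$rate_hz)
  thin_to_profile(sim_ppd_stat(rate_max, dead_time_ms, duration_ms),
                  profile, rate_max)
}

## nonstationary Gamma: unit-rate Gamma renewal process in operational time,
## transformed back to real time through the inverse cumulative rate
sim_gamma_profile <- function(profile, shape, duration_ms) {
  if (shape <= 0) rlang::abort("Gamma shape must be positive.")
  lam <- cumulative_rate(profile)
  total <- lam[length(lam)]
  if (total == 0) return(numeric(0))
  op_times <- renewal_times(total, 1,
                            function(n) rgamma(n, shape = shape, rate = shape))
  inv <- op_time_inverse(profile)
  t_real <- inv(op_times)
  t_real[t_real < duration_ms]
}

#' Simulate parallel spike trains from renewal point-process models
#'
#' Generates `n_units` x `n_trials` independent spike trains from a Poisson,
#' Poisson-with-dead-time (PPD), or Gamma renewal model, either stationary
#' (scalar `rate_hz`) or nonstationary (a [rate_profile()]; Poisson/PPD via
#' thinning of a process at the temporal maximum rate, Gamma via generation in
#' operational time). Renewal processes are started several mean intervals
#' before the observation window, so the window sees the equilibrium process
#' without a start transient.
#'
#' @param duration_ms Trial duration in ms.
#' @param model `"poisson"`, `"ppd"` or `"gamma"`.
#' @param rate_hz Stationary firing rate in Hz (ignored when `profile` given).
#' @param profile Optional `rate_profile` covering `[0, duration_ms]`.
#' @param dead_time_ms Dead time `d` in ms (PPD).
#' @param shape Gamma shape parameter; `shape = 1` is Poisson, `shape > 1`
#'   regular. Bursty trains (`shape < 1`, CV > 1) are supported for
#'   diagnostics such as the CV map, but the regular regime is the primary
#'   use case.
#' @param n_units,n_trials Grid size.
#' @param seed Optional integer seed (reproducible bit-for-bit).
#' @return A `spike_data` tibble.
#' @examples
#' x <- simulate_spike_data(1000, model = "ppd", rate_hz = 60,
#'                          dead_time_ms = 1.6, seed = 1)
#' min(diff(x$time_ms)) >= 1.6
#' @export
simulate_spike_data <- function(duration_ms,
                                model = c("poisson", "ppd", "gamma"),
                                rate_hz = 60,
                                profile = NULL,
                                dead_time_ms = 0,
                                shape = 1,
                                n_units = 1,
                                n_trials = 1,
                                seed = NULL) {
  model <- match.arg(model)
  gen <- function() {
    one <- function() {
      if (is.null(profile)) {
        switch(model,
          poisson = sim_poisson_stat(rate_hz, duration_ms),
          ppd = sim_ppd_stat(rate_hz, dead_time_ms, duration_ms),
          gamma = sim_gamma_stat(rate_hz, shape, duration_ms)
        )
      } else {
        switch(model,
          poisson = sim_poisson_profile(profile, duration_ms),
          ppd = sim_ppd_profile(profile, dead_time_ms, duration_ms),
          gamma = sim_gamma_profile(profile, shape, duration_ms)
        )
      }
    }
    units <- sprintf("u%02d", seq_len(n_units))
    grid <- expand.grid(trial_id = seq_len(n_trials), unit_id = units,
                        stringsAsFactors = FALSE)
    rows <- purrr::pmap_dfr(grid, function(trial_id, unit_id) {
      tibble::tibble(trial_id = as.integer(trial_id), unit_id = unit_id,
                     time_ms = one())
    })
    new_spike_data(rows, 0, duration_ms,
                   trial_ids = seq_len(n_trials), unit_ids = units)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# ---- estimators -------------------------------------------------------------

#' Estimate per-unit dead-times
#'
#' The dead-time of a unit is estimated as the minimum inter-spike interval
#' across all trials, capped at `d_max_ms`: if the minimal ISI exceeds
#' `d_max_ms` (e.g. at very low rates) the estimate is set to `d_max_ms`.
#' Units with fewer than two spikes in every trial get `d_max_ms` with a
#' warning.
#'
#' @param x A `spike_data` object.
#' @param d_max_ms Maximal admissible dead-time in ms (default 4).
#' @return A tibble with `unit_id`, `min_isi_ms` (NA when no ISI observed) and
#'   `dead_time_ms`.
#' @export
estimate_deadtime <- function(x, d_max_ms = 4) {
  stopifnot(inherits(x, "spike_data"))
  out <- x |>
    dplyr::group_by(.data$unit_id, .data$trial_id) |>
    dplyr::summarise(
      min_isi = if (dplyr::n() >= 2) min(diff(.data$time_ms)) else NA_real_,
      .groups = "drop_last"
    ) |>
    dplyr::summarise(min_isi_ms = suppressWarnings(min(.data$min_isi, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::mutate(
      min_isi_ms = ifelse(is.finite(.data$min_isi_ms), .data$min_isi_ms, NA_real_),
      dead_time_ms = pmin(dplyr::coalesce(.data$min_isi_ms, Inf), d_max_ms)
    )
  if (anyNA(out$min_isi_ms)) {
    rlang::warn("Some units have < 2 spikes in every trial; using d_max for them.")
  }
  out
}

#' Map between ISI coefficient of variation and Gamma shape
#'
#' For a stationary Gamma renewal process the ISI coefficient of variation is
#' `CV = 1/sqrt(gamma)`; these helpers convert in both directions
#' (`gamma = 1/CV^2`).
#'
#' @param cv,shape Positive scalars or vectors.
#' @return The converted value(s).
#' @examples
#' cv_to_shape(0.4) # 6.25
#' @export
cv_to_shape <- function(cv) {
  if (any(cv <= 0)) rlang::abort("`cv` must be positive.")
  1 / cv^2
}

#' @rdname cv_to_shape
#' @export
shape_to_cv <- function(shape) {
  if (any(shape <= 0)) rlang::abort("`shape` must be positive.")
  1 / sqrt(shape)
}

#' Estimate trial-averaged firing-rate profiles by kernel smoothing
#'
#' Gaussian kernel density estimate of the trial-averaged firing rate of each
#' unit, on a uniform grid. The kernel has a fixed user-set bandwidth (sd, in
#' ms); the integral of the profile over a trial approximates the mean spike
#' count per trial (edge mass is renormalized by the kernel mass inside the
#' interval).
#'
#' @param x A `spike_data` object.
#' @param bandwidth_ms Kernel standard deviation in ms (> 0, default 50).
#' @param dt_ms Output grid step in ms.
#' @return A tibble `unit_id, time_ms, rate_hz`; use
#'   [as_rate_profile()] to extract one unit's profile.
#' @export
estimate_rate_profile <- function(x, bandwidth_ms = 50, dt_ms = 1) {
  stopifnot(inherits(x, "spike_data"))
  if (bandwidth_ms <= 0) rlang::abort("`bandwidth_ms` must be positive.")
  dur <- trial_duration(x)
  grid <- seq(0, dur, by = dt_ms)
  n_trials <- length(trials_of(x))
  purrr::map_dfr(units_of(x), function(u) {
    s <- x$time_ms[x$unit_id == u] - t_start(x)
    if (!length(s)) {
      return(tibble::tibble(unit_id = u, time_ms = grid, rate_hz = 0))
    }
    # edge correction: renormalize each kernel by its mass inside [0, dur]
    mass <- stats::pnorm(dur, s, bandwidth_ms) - stats::pnorm(0, s, bandwidth_ms)
    dens <- vapply(grid, function(g) {
      sum(dnorm(g, mean = s, sd = bandwidth_ms) / mass)
    }, 0.0)
    tibble::tibble(unit_id = u, time_ms = grid,
                   rate_hz = 1000 * dens / n_trials)
  })
}

#' Extract one unit's profile from a rate-profile table
#'
#' @param x A tibble as returned by [estimate_rate_profile()].
#' @param unit Unit id; defaults to the only unit present.
#' @return A `rate_profile`.
#' @export
as_rate_profile <- function(x, unit = NULL) {
  if (inherits(x, "rate_profile")) return(x)
  if (is.null(unit)) {
    us <- unique(x$unit_id)
    if (length(us) != 1) rlang::abort("Multiple units present; supply `unit`.")
    unit <- us
  }
  sub <- x[x$unit_id == unit, ]
  rate_profile(sub$time_ms, sub$rate_hz)
}
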