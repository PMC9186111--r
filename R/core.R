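#' @useDynLib spikesurr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn
#' @importFrom stats rexp rgamma runif rpois sd approx dnorm p.adjust quantile
#' @importFrom utils head tail
NULL

#' Create a spike-data table
#'
#' The central container of the package: a long-format tibble of spike times
#' with one row per spike and columns `trial_id`, `unit_id` and `time_ms`,
#' carrying the common observation interval `[t_start, t_stop)` (in ms,
#' relative to trial onset) as attributes. All trials share the same duration
#' (a rectangular trial x unit grid); spike times are validated to be finite
#' and strictly inside the observation interval and are stored sorted within
#' each (trial, unit).
#'
#' @param x A data frame with columns `time_ms` and optionally `trial_id`
#'   (defaults to 1) and `unit_id` (defaults to `"u1"`). A bare numeric vector
#'   of spike times is also accepted.
#' @param t_start,t_stop Observation interval bounds in ms. `t_start` defaults
#'   to 0; `t_stop` is required unless `x` is already a `spike_data` object.
#' @return A tibble of class `spike_data`.
#' @examples
#' sd1 <- spike_data(c(10, 35.2, 80), t_stop = 100)
#' n_spikes(sd1)
#' @export
spike_data <- function(x, t_start = 0, t_stop = NULL) {
  default_grid <- is.numeric(x)
  if (default_grid) {
    x <- tibble::tibble(trial_id = 1L, unit_id = "u1", time_ms = as.double(x))
  }
  x <- tibble::as_tibble(x)
  if (!"time_ms" %in% names(x)) abort("`x` must have a `time_ms` column.")
  if (!"trial_id" %in% names(x)) x$trial_id <- 1L
  if (!"unit_id" %in% names(x)) x$unit_id <- "u1"
  if (is.null(t_stop)) {
    t_stop <- attr(x, "t_stop")
    if (is.null(t_stop)) abort("`t_stop` must be supplied.")
    t_start <- attr(x, "t_start") %||% t_start
  }
  x <- x[, c("trial_id", "unit_id", "time_ms")]
  x$trial_id <- as.integer(x$trial_id)
  x$unit_id <- as.character(x$unit_id)
  x$time_ms <- as.double(x$time_ms)
  out <- new_spike_data(x, t_start = as.double(t_start), t_stop = as.double(t_stop),
                        trial_ids = if (default_grid) 1L else NULL,
                        unit_ids = if (default_grid) "u1" else NULL)
  validate_spike_data(out)
}

new_spike_data <- function(x, t_start, t_stop, trial_ids = NULL, unit_ids = NULL) {
  x <- dplyr::arrange(x, .data$trial_id, .data$unit_id, .data$time_ms)
  structure(x,
    t_start = t_start, t_stop = t_stop,
    trial_ids = sort(unique(c(trial_ids, x$trial_id))),
    unit_ids = sort(unique(c(unit_ids, x$unit_id))),
    class = c("spike_data", class(tibble::tibble()))
  )
}

validate_spike_data <- function(x) {
  t_start <- t_start(x)
  t_stop <- t_stop(x)
  if (!is.finite(t_start) || !is.finite(t_stop) || t_stop <= t_start) {
    abort("Invalid observation interval: need finite t_start < t_stop.")
  }
  bad <- !is.finite(x$time_ms) | x$time_ms < t_start | x$time_ms >= t_stop
  if (any(bad)) {
    off <- unique(x[bad, c("trial_id", "unit_id")])
    abort(paste0(
      "Spike times outside [t_start, t_stop) or non-finite in ",
      paste0("trial ", off$trial_id, " unit ", off$unit_id, collapse = "; "), "."
    ))
  }
  x
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf(
    "# spike_data: %d spikes, %d unit(s), %d trial(s), interval [%g, %g) ms\n",
    nrow(x), dplyr::n_distinct(x$unit_id), dplyr::n_distinct(x$trial_id),
    t_start(x), t_stop(x)
  ))
  NextMethod()
}

#' Observation interval accessors
#'
#' @param x A `spike_data` or `binned_spikes` object.
#' @return Scalar interval bound in ms (`t_start()`, `t_stop()`) or the trial
#'   duration `t_stop - t_start` (`trial_duration()`).
#' @export
t_start <- function(x) attr(x, "t_start")

#' @rdname t_start
#' @export
t_stop <- function(x) attr(x, "t_stop")

#' @rdname t_start
#' @export
trial_duration <- function(x) t_stop(x) - t_start(x)

#' @rdname t_start
#' @export
n_spikes <- function(x) {
  if (inherits(x, "binned_spikes")) return(x$n_spikes)
  nrow(x)
}

## the unit/trial grid is carried as attributes so that units or trials that
## happen to contain zero spikes are not silently dropped
units_of <- function(x) attr(x, "unit_ids") %||% sort(unique(x$unit_id))
trials_of <- function(x) attr(x, "trial_ids") %||% sort(unique(x$trial_id))

`%||%` <- function(a, b) if (is.null(a)) b else a

## Apply f(times, t_start, t_stop, unit_id, trial_id) -> numeric times to each
## (trial, unit) train, preserving the grid (units/trials with zero spikes are
## kept only if they had rows; absent combinations stay absent).
map_trains <- function(x, f) {
  key <- paste(x$trial_id, x$unit_id, sep = "\r")
  groups <- split(seq_len(nrow(x)), key)
  ts <- t_start(x)
  te <- t_stop(x)
  pieces <- lapply(groups, function(idx) {
    new_times <- f(x$time_ms[idx], ts, te, x$unit_id[idx[1]], x$trial_id[idx[1]])
    tibble::tibble(
      trial_id = rep(x$trial_id[idx[1]], length(new_times)),
      unit_id = rep(x$unit_id[idx[1]], length(new_times)),
      time_ms = sort(as.double(new_times))
    )
  })
  out <- dplyr::bind_rows(pieces)
  if (!nrow(out)) out <- x[0, ]
  validate_spike_data(new_spike_data(out, ts, te,
                                     trial_ids = trials_of(x),
                                     unit_ids = units_of(x)))
}

#' Extract an analysis window from every trial
#'
#' Cuts `[window_start, window_start + window_len)` out of each trial and
#' re-references the spike times so the new trials start at 0 ms. This is the
#' segmentation step used to restrict parallel recordings to an epoch of
#' interest before concatenation or surrogate generation.
#'
#' @param x A `spike_data` object.
#' @param window_start Window onset in ms (relative to `t_start`).
#' @param window_len Window length in ms.
#' @return A `spike_data` object with interval `[0, window_len)`.
#' @export
segment_trials <- function(x, window_start, window_len) {
  stopifnot(inherits(x, "spike_data"), window_len > 0)
  w0 <- t_start(x) + window_start
  w1 <- w0 + window_len
  if (w0 < t_start(x) || w1 > t_stop(x)) {
    abort(sprintf(
      "Window [%g, %g) exceeds the trial interval [%g, %g).",
      w0, w1, t_start(x), t_stop(x)
    ))
  }
  keep <- x$time_ms >= w0 & x$time_ms < w1
  out <- x[keep, , drop = FALSE]
  out$time_ms <- out$time_ms - w0
  new_spike_data(tibble::as_tibble(out), 0, window_len,
                 trial_ids = trials_of(x), unit_ids = units_of(x))
}

#' Concatenate trials end-to-end into one continuous trial
#'
#' Stacks all trials of each unit back-to-back (trial k is offset by
#' `(k - 1) * trial_duration`), yielding a single-trial `spike_data` whose
#' duration is `n_trials * trial_duration`. Spike counts are conserved.
#'
#' @param x A `spike_data` object.
#' @return A single-trial `spike_data` object.
#' @export
concatenate_trials <- function(x) {
  stopifnot(inherits(x, "spike_data"))
  trials <- trials_of(x)
  dur <- trial_duration(x)
  offset <- (match(x$trial_id, trials) - 1) * dur
  out <- tibble::tibble(
    trial_id = 1L, unit_id = x$unit_id,
    time_ms = x$time_ms - t_start(x) + offset
  )
  new_spike_data(out, 0, length(trials) * dur,
                 trial_ids = 1L, unit_ids = units_of(x))
}

#' Split one continuous trial into equal segments
#'
#' The inverse of [concatenate_trials()]: cuts a single-trial recording into
#' consecutive segments of `segment_len` ms which become the trials of the
#' result. Used e.g. to give trial structure to a continuous recording before
#' trial shifting.
#'
#' @param x A single-trial `spike_data` object.
#' @param segment_len Segment length in ms; must divide the duration.
#' @return A `spike_data` object with `duration / segment_len` trials.
#' @export
split_into_trials <- function(x, segment_len) {
  stopifnot(inherits(x, "spike_data"))
  if (dplyr::n_distinct(x$trial_id) != 1) {
    abort("`x` must contain a single trial; concatenate first.")
  }
  dur <- trial_duration(x)
  n_seg <- dur / segment_len
  if (abs(n_seg - round(n_seg)) > 1e-9) {
    abort("`segment_len` must divide the trial duration.")
  }
  rel <- x$time_ms - t_start(x)
  seg <- pmin(floor(rel / segment_len), round(n_seg) - 1)
  out <- tibble::tibble(
    trial_id = as.integer(seg + 1),
    unit_id = x$unit_id,
    time_ms = rel - seg * segment_len
  )
  new_spike_data(out, 0, segment_len,
                 trial_ids = seq_len(round(n_seg)), unit_ids = units_of(x))
}

# ---- binarization -----------------------------------------------------------

#' Binarize spike trains (binning + clipping)
#'
#' Discretizes each (trial, unit) spike train into half-open bins
#' `[t_start + k*b, t_start + (k+1)*b)` of width `bin_ms`, counting spikes per
#' bin, and clips counts to 0/1 occupancy. The spikes lost by clipping are the
#' spike-count reduction `1 - N_clip / N`, where `N` is the continuous-time
#' spike count and `N_clip` the number of occupied bins. A trailing partial
#' bin (when `bin_ms` does not divide the duration) is dropped with a warning;
#' spikes falling into it are excluded from both `N` and `N_clip`.
#'
#' @param x A `spike_data` object.
#' @param bin_ms Bin width in ms (> 0).
#' @return A `binned_spikes` object: a list with per-trial count matrices
#'   (units x bins), the unit/trial index, `bin_ms`, `t_start`, `n_bins`,
#'   total spike count `n_spikes` and clipped count `n_clip`.
#' @examples
#' b <- binarize(spike_data(c(1, 2, 3, 12), t_stop = 15), bin_ms = 5)
#' spike_count_reduction(b) # 0.5: three spikes share the first bin
#' @export
binarize <- function(x, bin_ms) {
  stopifnot(inherits(x, "spike_data"))
  if (!is.numeric(bin_ms) || length(bin_ms) != 1 || bin_ms <= 0) {
    abort("`bin_ms` must be a positive scalar.")
  }
  dur <- trial_duration(x)
  n_bins <- floor(dur / bin_ms + 1e-9)
  if (n_bins < 1) abort("`bin_ms` exceeds the trial duration.")
  if (abs(n_bins * bin_ms - dur) > 1e-6 * bin_ms) {
    warn(sprintf(
      "bin_ms = %g does not divide the duration %g ms; dropping the trailing partial bin.",
      bin_ms, dur
    ))
  }
  units <- units_of(x)
  trials <- trials_of(x)
  span <- n_bins * bin_ms
  counts <- lapply(trials, function(tr) {
    m <- matrix(0L, nrow = length(units), ncol = n_bins,
                dimnames = list(units, NULL))
    sub <- x[x$trial_id == tr, ]
    rel <- sub$time_ms - t_start(x)
    keep <- rel < span
    bin <- floor(rel[keep] / bin_ms)
    ui <- match(sub$unit_id[keep], units)
    if (length(bin)) {
      m[] <- tabulate(bin * length(units) + ui,
                      nbins = length(units) * n_bins)
    }
    m
  })
  names(counts) <- as.character(trials)
  n_sp <- sum(vapply(counts, sum, 0L))
  n_clip <- sum(vapply(counts, function(m) sum(m > 0L), 0L))
  structure(
    list(
      counts = counts, units = units, trials = trials,
      bin_ms = bin_ms, t_start = t_start(x), n_bins = n_bins,
      n_spikes = n_sp, n_clip = n_clip
    ),
    t_start = t_start(x), t_stop = t_start(x) + span,
    class = "binned_spikes"
  )
}

#' @export
print.binned_spikes <- function(x, ...) {
  cat(sprintf(
    "# binned_spikes: %d unit(s) x %d bin(s) x %d trial(s), b = %g ms, N = %d, N_clip = %d\n",
    length(x$units), x$n_bins, length(x$trials), x$bin_ms, x$n_spikes, x$n_clip
  ))
  invisible(x)
}

#' Per-trial 0/1 occupancy matrices
#'
#' @param x A `binned_spikes` object.
#' @return A list (one per trial) of integer 0/1 matrices, units x bins.
#' @export
occupancy <- function(x) {
  stopifnot(inherits(x, "binned_spikes"))
  lapply(x$counts, function(m) (m > 0L) * 1L)
}

#' Spike-count reduction caused by binarization
#'
#' `1 - N_clip / N`: the fraction of spikes lost when per-bin counts are
#' clipped to 0/1. Defined as 0 for an empty train so that aggregate curves
#' stay well-defined.
#'
#' @param x A `binned_spikes` object (empirical mode); see
#'   [analytic_poisson_reduction()] for the closed form under a stationary
#'   Poisson process.
#' @return Scalar in `[0, 1]`.
#' @export
spike_count_reduction <- function(x) {
  stopifnot(inherits(x, "binned_spikes"))
  if (x$n_spikes == 0) return(0)
  1 - x$n_clip / x$n_spikes
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a binned spike object
#'
#' @param x A `binned_spikes` object.
#' @param ... Unused.
#' @return A tibble with one row per (trial, unit, bin) holding `count` and
#'   0/1 `occupied`.
#' @export
tidy.binned_spikes <- function(x, ...) {
  purrr::map2_dfr(x$counts, x$trials, function(m, tr) {
    tibble::tibble(
      trial_id = tr,
      unit_id = rep(rownames(m), times = ncol(m)),
      bin = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
      count = as.integer(m)
    )
  }) |>
    dplyr::mutate(occupied = as.integer(.data$count > 0L))
}

#' @rdname tidy.binned_spikes
#' @export
glance.binned_spikes <- function(x, ...) {
  tibble::tibble(
    n_units = length(x$units), n_trials = length(x$trials),
    n_bins = x$n_bins, bin_ms = x$bin_ms,
    n_spikes = x$n_spikes, n_clip = x$n_clip,
    reduction = spike_count_reduction(x)
  )
}

#' Reconstruct a spike train from bin centers of the occupancy
#'
#' Places one spike at the center of every occupied bin. Binarizing the result
#' with the same bin width reproduces the occupancy exactly.
#'
#' @param x A `binned_spikes` object.
#' @return A `spike_data` object.
#' @export
spikes_from_occupancy <- function(x) {
  stopifnot(inherits(x, "binned_spikes"))
  occ <- occupancy(x)
  out <- purrr::map2_dfr(occ, x$trials, function(m, tr) {
    idx <- which(m > 0L, arr.ind = TRUE)
    tibble::tibble(
      trial_id = tr,
      unit_id = rownames(m)[idx[, 1]],
      time_ms = x$t_start + (idx[, 2] - 0.5) * x$bin_ms
    )
  })
  new_spike_data(out, x$t_start, x$t_start + x$n_bins * x$bin_ms,
                 trial_ids = x$trials, unit_ids = x$units)
}

# ---- file I/O ---------------------------------------------------------------

#' Read and write spike data as long-format CSV
#'
#' The CSV dialect has columns `trial_id, unit_id, time_ms` plus two comment
#' header lines carrying the observation interval
#' (`# t_start: <ms>` / `# t_stop: <ms>`). The round trip is lossless to full
#' double precision.
#'
#' @param path File path.
#' @param x A `spike_data` object.
#' @return `read_spike_csv()` returns a `spike_data` object;
#'   `write_spike_csv()` returns `x` invisibly.
#' @examples
#' path <- system.file("extdata", "planted_pattern.csv", package = "spikesurr")
#' read_spike_csv(path)
#' @export
read_spike_csv <- function(path) {
  meta <- read_meta_lines(path)
  # base read.csv parses doubles with strtod (correctly rounded), which keeps
  # the round trip exact to the last ulp
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("integer", "character", "double"))
  spike_data(df, t_start = meta[["t_start"]], t_stop = meta[["t_stop"]])
}

#' @rdname read_spike_csv
#' @export
write_spike_csv <- function(x, path) {
  stopifnot(inherits(x, "spike_data"))
  header <- c(
    sprintf("# t_start: %.17g", t_start(x)),
    sprintf("# t_stop: %.17g", t_stop(x))
  )
  body <- c(
    "trial_id,unit_id,time_ms",
    sprintf("%d,%s,%.17g", x$trial_id, x$unit_id, x$time_ms)
  )
  writeLines(c(header, body), path)
  invisible(x)
}

read_meta_lines <- function(path) {
  lines <- readLines(path, n = 10)
  lines <- grep("^#", lines, value = TRUE)
  pick <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (!length(ln)) abort(sprintf("Missing '# %s:' header in %s", key, path))
    as.double(sub(paste0("^#\\s*", key, ":\\s*"), "", ln[1]))
  }
  c(t_start = pick("t_start"), t_stop = pick("t_stop"))
}

#' Read and write spike data as JSON
#'
#' JSON dialect equivalent to the CSV one: an object with `t_start`, `t_stop`
#' and a `spikes` table of `trial_id`/`unit_id`/`time_ms`.
#'
#' @inheritParams read_spike_csv
#' @return `read_spike_json()` returns a `spike_data` object.
#' @export
read_spike_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spike_data(tibble::as_tibble(obj$spikes),
             t_start = obj$t_start, t_stop = obj$t_stop)
}

#' @rdname read_spike_json
#' @export
write_spike_json <- function(x, path) {
  stopifnot(inherits(x, "spike_data"))
  obj <- list(
    t_start = t_start(x), t_stop = t_stop(x),
    spikes = as.data.frame(x)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(x)
}

#' Export occupancy as a dense 0/1 matrix CSV
#'
#' Writes the clipped matrix of a single-trial binned object as a dense CSV
#' (one row per unit), preceded by comment header lines with the bin width,
#' `t_start` and the unit order.
#'
#' @param x A `binned_spikes` object with a single trial.
#' @param path File path.
#' @export
write_binned_csv <- function(x, path) {
  stopifnot(inherits(x, "binned_spikes"), length(x$trials) == 1)
  occ <- occupancy(x)[[1]]
  header <- c(
    sprintf("# bin_ms: %g", x$bin_ms),
    sprintf("# t_start: %g", x$t_start),
    sprintf("# units: %s", paste(x$units, collapse = ","))
  )
  body <- apply(occ, 1, paste, collapse = ",")
  writeLines(c(header, body), path)
  invisible(x)
}
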