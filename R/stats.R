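# Single-train statistics used to quantify how surrogates distort spike data:
# interval histograms, correlograms, regularity measures, moved-spike ratio,
# PSTH, and spike-count-reduction curves (empirical, analytic, Monte-Carlo).

#' Within-trial inter-spike intervals
#'
#' @param x A `spike_data` object.
#' @return A tibble `unit_id, trial_id, isi_ms` of successive within-trial
#'   spike-time differences.
#' @export
isi_values <- function(x) {
  stopifnot(inherits(x, "spike_data"))
  x |>
    dplyr::group_by(.data$unit_id, .data$trial_id) |>
    dplyr::reframe(isi_ms = diff(.data$time_ms))
}

#' ISI histogram
#'
#' Histogram of within-trial inter-spike intervals per unit, at a fixed
#' resolution (default 1 ms), as counts and as a normalized density.
#'
#' @param x A `spike_data` object.
#' @param resolution_ms Bin width in ms.
#' @param max_isi_ms Upper limit of the histogram; defaults to the largest
#'   observed ISI.
#' @return A tibble of class `isi_histogram` with columns `unit_id`,
#'   `lag_ms` (bin center), `count` and `density` (integrates to 1 per unit).
#' @export
isi_histogram <- function(x, resolution_ms = 1, max_isi_ms = NULL) {
  isis <- isi_values(x)
  if (!nrow(isis)) rlang::abort("Need at least 2 spikes in some trial.")
  lim <- max_isi_ms %||% max(isis$isi_ms)
  nb <- max(1L, ceiling(lim / resolution_ms))
  out <- isis |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::reframe({
      idx <- floor(.data$isi_ms / resolution_ms) + 1L
      keep <- idx >= 1L & idx <= nb
      cnt <- tabulate(idx[keep], nbins = nb)
      tibble::tibble(
        lag_ms = (seq_len(nb) - 0.5) * resolution_ms,
        count = cnt,
        density = if (sum(cnt)) cnt / (sum(cnt) * resolution_ms) else 0
      )
    })
  structure(out, resolution_ms = resolution_ms,
            class = c("isi_histogram", class(out)))
}

#' Cross- and auto-correlation histograms
#'
#' Counts of spike-time differences `y - x` falling into lag bins on
#' `[-max_lag_ms, max_lag_ms]`. With `y = NULL` the auto-correlation of `x` is
#' computed and the zero-lag self pairs are excluded. Both objects must hold a
#' single continuous train (one unit, one trial) on the same observation
#' interval; concatenate or segment first otherwise. Counts are raw by
#' default (`normalize = TRUE` divides by the number of reference spikes and
#' the bin width, giving a rate in Hz).
#'
#' @param x,y `spike_data` objects with one unit and one trial each.
#' @param max_lag_ms Maximal lag in ms.
#' @param lag_bin_ms Lag resolution in ms.
#' @param normalize Return a conditional rate instead of raw counts.
#' @return A tibble of class `corr_histogram` with `lag_ms` (bin center) and
#'   `count` (and `rate_hz` if normalized).
#' @export
correlation_histogram <- function(x, y = NULL, max_lag_ms = 50,
                                  lag_bin_ms = 1, normalize = FALSE) {
  auto <- is.null(y)
  if (auto) y <- x
  stopifnot(inherits(x, "spike_data"), inherits(y, "spike_data"))
  for (obj in list(x, y)) {
    if (dplyr::n_distinct(obj$trial_id) > 1 || dplyr::n_distinct(obj$unit_id) > 1) {
      rlang::abort("correlation_histogram() expects single-train objects; concatenate first.")
    }
  }
  if (abs(t_start(x) - t_start(y)) > 1e-9 || abs(t_stop(x) - t_stop(y)) > 1e-9) {
    rlang::abort("Observation intervals of `x` and `y` differ.")
  }
  xs <- x$time_ms
  ys <- y$time_ms
  nb <- 2L * ceiling(max_lag_ms / lag_bin_ms)
  edges <- seq(-nb / 2, nb / 2) * lag_bin_ms
  if (!length(xs) || !length(ys)) {
    counts <- integer(nb)
  } else {
    # cumulative counts of y below x_i + edge_k, one findInterval per edge
    cum <- vapply(edges, function(e) sum(findInterval(xs + e, ys)), 0.0)
    counts <- diff(cum)
  }
  if (auto && length(xs)) {
    # bins are right-closed (edge_k, edge_{k+1}]; the self pairs at lag 0
    # land in the bin whose right edge is 0
    z <- findInterval(0, edges) - 1L
    if (z >= 1) counts[z] <- counts[z] - length(xs)
  }
  out <- tibble::tibble(
    lag_ms = (edges[-1] + edges[-length(edges)]) / 2,
    count = counts
  )
  if (normalize) out$rate_hz <- 1000 * out$count / (max(length(xs), 1) * lag_bin_ms)
  structure(out, auto = auto, lag_bin_ms = lag_bin_ms,
            class = c("corr_histogram", class(out)))
}

#' ISI coefficient of variation and local CV2
#'
#' `cv_isi()` computes per unit the coefficient of variation
#' `sd(ISI)/mean(ISI)` of the within-trial ISIs pooled over trials.
#' `cv2_isi()` computes the local regularity measure CV2: the average over
#' successive within-trial ISI pairs of `2|ISI_{i+1} - ISI_i| /
#' (ISI_{i+1} + ISI_i)` (Holt-style successive-pair statistic), which
#' compensates for slow firing-rate nonstationarities. For a Poisson process
#' both are approximately 1; regular trains give values below 1.
#'
#' @param x A `spike_data` object.
#' @return A tibble per unit: `cv_isi()` gives `n_isis` and `cv`; `cv2_isi()`
#'   gives `n_pairs` and `cv2`.
#' @export
cv_isi <- function(x) {
  isis <- isi_values(x)
  if (!nrow(isis)) rlang::abort("Need at least 2 spikes in some trial.")
  isis |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(n_isis = dplyr::n(),
                     cv = sd(.data$isi_ms) / mean(.data$isi_ms),
                     .groups = "drop")
}

#' @rdname cv_isi
#' @export
cv2_isi <- function(x) {
  isis <- isi_values(x)
  pairs <- isis |>
    dplyr::group_by(.data$unit_id, .data$trial_id) |>
    dplyr::reframe(
      cv2_term = if (dplyr::n() >= 2) {
        a <- .data$isi_ms[-dplyr::n()]
        b <- .data$isi_ms[-1]
        2 * abs(b - a) / (b + a)
      } else numeric(0)
    )
  if (!nrow(pairs)) rlang::abort("Need at least 3 spikes in some trial.")
  pairs |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(n_pairs = dplyr::n(), cv2 = mean(.data$cv2_term),
                     .groups = "drop")
}

#' Ratio of moved spikes between original and surrogate
#'
#' Fraction of spikes displaced from their original bin. With per-bin
#' (unclipped) counts `c_o` and `c_s` of original and surrogate, the number of
#' not-moved spikes is `sum_k min(c_o[k], c_s[k])` (so two spikes exchanging
#' their bins count as not moved, and multi-spike bins are matched
#' spike-by-spike), and the ratio is `1 - not_moved / N`.
#'
#' @param orig,surr `spike_data` objects on the same observation interval.
#' @param bin_ms Bin width in ms.
#' @return Scalar ratio in `[0, 1]`.
#' @export
moved_spike_ratio <- function(orig, surr, bin_ms = 5) {
  stopifnot(inherits(orig, "spike_data"), inherits(surr, "spike_data"))
  if (abs(t_start(orig) - t_start(surr)) > 1e-9 ||
      abs(t_stop(orig) - t_stop(surr)) > 1e-9) {
    rlang::abort("Observation intervals of `orig` and `surr` differ.")
  }
  bo <- binarize(orig, bin_ms)
  bs <- binarize(surr, bin_ms)
  n <- bo$n_spikes
  if (n == 0) return(0)
  not_moved <- 0L
  for (tr in as.character(bo$trials)) {
    mo <- bo$counts[[tr]]
    ms <- bs$counts[[tr]]
    common <- intersect(rownames(mo), rownames(ms))
    not_moved <- not_moved +
      sum(pmin(mo[common, , drop = FALSE], ms[common, , drop = FALSE]))
  }
  1 - not_moved / n
}

#' Peristimulus time histogram (PSTH)
#'
#' Trial-averaged firing rate in Hz: spike counts per time bin pooled over
#' trials (the realizations), divided by the number of trials and the bin
#' width. Units are pooled; supply a single-unit object for per-unit rates.
#'
#' @param x A `spike_data` object whose trials are the realizations.
#' @param bin_ms Bin width in ms (default 1).
#' @return A [rate_profile()] sampled at the bin centers.
#' @export
psth <- function(x, bin_ms = 1) {
  stopifnot(inherits(x, "spike_data"))
  b <- binarize(x, bin_ms)
  n_real <- length(b$trials) * length(b$units)
  counts <- Reduce(`+`, lapply(b$counts, colSums))
  rate_profile((seq_len(b$n_bins) - 0.5) * bin_ms,
               1000 * counts / (n_real * bin_ms))
}

#' Closed-form binarization loss of a stationary Poisson process
#'
#' For a stationary Poisson process with rate `lambda` binned at width `b`,
#' the expected number of spikes is `lambda * b` per bin while the expected
#' number of occupied bins is `1 - exp(-lambda * b)`, so the expected
#' spike-count reduction after clipping is
#' `1 - (1 - exp(-lambda b)) / (lambda b)`.
#'
#' @param rate_hz Firing rate(s) in Hz (> 0).
#' @param bin_ms Bin width in ms (> 0).
#' @return Expected reduction(s) in `[0, 1)`.
#' @examples
#' analytic_poisson_reduction(100, 5) # ~0.213
#' @export
analytic_poisson_reduction <- function(rate_hz, bin_ms) {
  mu <- rate_hz * bin_ms / 1000
  if (any(mu <= 0)) rlang::abort("`rate_hz * bin_ms` must be positive.")
  1 - (1 - exp(-mu)) / mu
}

#' Expected spike-count reduction of renewal models and their surrogates
#'
#' Estimates the binarization loss `1 - N_clip/N` for a stationary renewal
#' model (Poisson, PPD, or Gamma), optionally after applying a surrogate
#' method. Mode `"analytic"` is the closed form for the Poisson process
#' ([analytic_poisson_reduction()]); mode `"numeric"` is a Monte-Carlo
#' estimate from a simulated train with a target expected spike count, which
#' is the in-package ground truth for PPD/Gamma and for all surrogates, and
#' carries its Monte-Carlo standard error.
#'
#' @param rate_hz Stationary firing rate in Hz.
#' @param bin_ms Bin width in ms.
#' @param model `"poisson"`, `"ppd"`, or `"gamma"`.
#' @param mode `"numeric"` (Monte-Carlo) or `"analytic"` (Poisson only).
#' @param dead_time_ms,shape Model parameters.
#' @param surrogate Optional surrogate method name (see
#'   [surrogate_methods()]) applied before binarization.
#' @param dither_ms Dither half-width for the surrogate.
#' @param n_spikes Target expected spike count of the Monte-Carlo train.
#' @param seed Optional integer seed.
#' @param ... Extra arguments for the surrogate method.
#' @return A one-row tibble: `rate_hz`, `model`, `surrogate`, `mode`,
#'   `reduction`, `se` (NA for analytic).
#' @export
expected_spike_count_reduction <- function(rate_hz, bin_ms,
                                           model = c("poisson", "ppd", "gamma"),
                                           mode = c("numeric", "analytic"),
                                           dead_time_ms = 0, shape = 1,
                                           surrogate = NULL, dither_ms = 25,
                                           n_spikes = 1e5, seed = NULL, ...) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  if (mode == "analytic") {
    if (model != "poisson" || !is.null(surrogate)) {
      rlang::abort("Analytic mode is available for the plain Poisson process only.")
    }
    return(tibble::tibble(
      rate_hz = rate_hz, model = model, surrogate = NA_character_,
      mode = mode, reduction = analytic_poisson_reduction(rate_hz, bin_ms),
      se = NA_real_
    ))
  }
  duration <- ceiling(n_spikes / rate_hz * 1000 / bin_ms) * bin_ms
  x <- simulate_spike_data(duration, model = model, rate_hz = rate_hz,
                           dead_time_ms = dead_time_ms, shape = shape,
                           seed = seed)
  if (!is.null(surrogate)) {
    sseed <- if (is.null(seed)) NULL else seed + 1L
    args <- list(x, surrogate, dither_ms = dither_ms, ..., seed = sseed)
    if (surrogate == "winshuff") args$bin_ms <- bin_ms
    x <- do.call(make_surrogate, args)
  }
  b <- binarize(x, bin_ms)
  p <- spike_count_reduction(b)
  tibble::tibble(
    rate_hz = rate_hz, model = model,
    surrogate = surrogate %||% NA_character_, mode = mode,
    reduction = p,
    se = sqrt(p * (1 - p) / max(b$n_spikes, 1))
  )
}
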