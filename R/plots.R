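# ggplot2 front-ends for the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_col
#'   geom_tile geom_point geom_abline labs facet_wrap scale_fill_viridis_c
NULL

#' @export
ggplot2::autoplot

#' Plot an ISI histogram
#'
#' @param object An `isi_histogram`.
#' @param ... Unused.
#' @return A ggplot object (density vs lag, one panel per unit).
#' @export
autoplot.isi_histogram <- function(object, ...) {
  ggplot(object, aes(x = .data$lag_ms, y = .data$density)) +
    geom_step() +
    facet_wrap(~unit_id) +
    labs(x = "inter-spike interval (ms)", y = "density (1/ms)")
}

#' Plot a correlation histogram
#'
#' @param object A `corr_histogram`.
#' @param ... Unused.
#' @return A ggplot object (counts vs lag).
#' @export
autoplot.corr_histogram <- function(object, ...) {
  ggplot(object, aes(x = .data$lag_ms, y = .data$count)) +
    geom_step() +
    labs(x = "time lag (ms)", y = "count",
         title = if (isTRUE(attr(object, "auto"))) "auto-correlation"
                 else "cross-correlation")
}

#' Plot a rate profile
#'
#' @param object A `rate_profile`.
#' @param ... Unused.
#' @return A ggplot object (rate vs time).
#' @export
autoplot.rate_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$time_ms, y = .data$rate_hz)) +
    geom_line() +
    labs(x = "time (ms)", y = "firing rate (Hz)")
}

#' Plot a p-value spectrum slice
#'
#' Tile plot of the p-values over occurrence count and duration for one
#' pattern size, the standard way to read significance isolines.
#'
#' @param object A `pvalue_spectrum`.
#' @param z Pattern size to slice at (default: smallest present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pvalue_spectrum <- function(object, z = NULL, ...) {
  z <- z %||% min(object$z)
  ggplot(dplyr::filter(object, .data$z == !!z),
         aes(x = .data$c, y = .data$d, fill = .data$p)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "occurrences c", y = "duration d (bins)", fill = "p",
         title = sprintf("p-value spectrum, size z = %d", z))
}

#' Plot a pattern spectrum slice
#'
#' @param object A `pattern_spectrum`.
#' @param z Pattern size to slice at (default: smallest present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pattern_spectrum <- function(object, z = NULL, ...) {
  z <- z %||% (if (nrow(object)) min(object$z) else 3L)
  ggplot(dplyr::filter(object, .data$z == !!z),
         aes(x = .data$c, y = .data$d, fill = .data$count)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "occurrences c", y = "duration d (bins)", fill = "patterns",
         title = sprintf("pattern spectrum, size z = %d", z))
}

#' Plot a CV map (original vs surrogate regularity)
#'
#' @param cv_map A tibble with columns `cv_orig`, `cv_surr`, `method`
#'   (as produced by [run_statistics_suite()]).
#' @return A ggplot object with the identity diagonal for reference.
#' @export
plot_cv_map <- function(cv_map) {
  ggplot(cv_map, aes(x = .data$cv_orig, y = .data$cv_surr,
                     colour = .data$method)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "CV of original", y = "CV of surrogate")
}

#' Plot moved-spike-ratio curves
#'
#' @param moved A tibble with columns `rate_hz`, `moved`, `method`
#'   (as produced by [run_statistics_suite()]).
#' @return A ggplot object.
#' @export
plot_moved_ratio <- function(moved) {
  ggplot(moved, aes(x = .data$rate_hz, y = .data$moved,
                    colour = .data$method)) +
    geom_line() +
    geom_point() +
    labs(x = "firing rate (Hz)", y = "ratio of moved spikes")
}

#' Plot spike-count-reduction curves
#'
#' @param reduction A tibble with columns `rate_hz`, `reduction` and a
#'   grouping column `method` or `model`.
#' @return A ggplot object.
#' @export
plot_spike_loss <- function(reduction) {
  grp <- if ("method" %in% names(reduction)) "method" else "model"
  ggplot(reduction, aes(x = .data$rate_hz, y = .data$reduction,
                        colour = .data[[grp]])) +
    geom_line() +
    geom_point() +
    labs(x = "firing rate (Hz)", y = "spike count reduction 1 - Nclip/N")
}
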