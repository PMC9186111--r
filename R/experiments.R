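# Seeded experiment drivers reproducing the package's computational studies
# at configurable scale: the surrogate statistics suite, the spike-loss
# curves, the p-value-spectrum comparison, and the false-positive study on
# synthetic nonstationary populations. Every run is a pure function of its
# arguments and the master seed, and every report records the scale knobs.

surrogate_for <- function(x, method, dither_ms, bin_ms, trial_len_ms, seed) {
  # TR-SHIFT needs trial structure: cut continuous trains into segments,
  # shift, and re-concatenate so downstream analyses see the original shape.
  if (method == "trshift" && length(attr(x, "trial_ids")) < 2) {
    xx <- split_into_trials(x, trial_len_ms)
    return(concatenate_trials(surrogate_trial_shift(xx, dither_ms, seed = seed)))
  }
  if (method == "winshuff") {
    return(surrogate_window_shuffle(x, dither_ms, bin_ms = bin_ms, seed = seed))
  }
  make_surrogate(x, method, dither_ms = dither_ms, seed = seed)
}

#' Surrogate statistics suite
#'
#' Computes, for stationary Poisson / PPD / Gamma reference processes, the
#' battery of distortion statistics: ISI histograms of original and surrogate
#' trains, original-vs-surrogate cross-correlograms, auto-correlograms, the
#' CV map of original against surrogate CV over a grid of Gamma
#' regularities, the moved-spike ratio as a function of firing rate with an
#' independent-realization baseline, and the PSTH of a 10-to-80 Hz rate step
#' under each surrogate.
#'
#' @param n_spikes Expected spike count of the long stationary trains.
#' @param rate_hz Reference firing rate (Hz).
#' @param dead_time_ms PPD dead-time (ms).
#' @param gamma_shape Gamma shape of the reference Gamma train.
#' @param dither_ms Dither half-width (ms).
#' @param bin_ms Bin width for binned statistics (ms).
#' @param trial_len_ms Segment length used for trial shifting (ms; the
#'   500 ms default matches typical trial epochs and keeps the wrap-point
#'   fraction of intervals negligible).
#' @param cv_grid CV grid for the CV map.
#' @param rates Firing-rate grid for the moved-spike ratio (Hz).
#' @param moved_shape Gamma shape used in the moved-spike analysis.
#' @param step_n_realizations,step_duration_ms,step_rates,step_at_ms
#'   Rate-step PSTH parameters.
#' @param methods Surrogate methods to include.
#' @param seed Master seed.
#' @return A list of tidy tibbles (`isi`, `crosscorr`, `autocorr`, `cv_map`,
#'   `moved`, `rate_step`) plus the parameter list.
#' @export
run_statistics_suite <- function(n_spikes = 5e5, rate_hz = 60,
                                 dead_time_ms = 1.6, gamma_shape = 1.23,
                                 dither_ms = 25, bin_ms = 5,
                                 trial_len_ms = 500,
                                 cv_grid = seq(0.4, 1.2, by = 0.05),
                                 rates = seq(10, 100, by = 10),
                                 moved_shape = 1.23,
                                 step_n_realizations = 10000,
                                 step_duration_ms = 150,
                                 step_rates = c(10, 80), step_at_ms = 75,
                                 methods = surrogate_methods(),
                                 seed = 1) {
  seeds <- surrogate_seeds(seed, 6L)
  dur <- round(n_spikes / rate_hz * 1000 / trial_len_ms) * trial_len_ms

  originals <- list(
    poisson = simulate_spike_data(dur, "poisson", rate_hz, seed = seeds[1]),
    ppd = simulate_spike_data(dur, "ppd", rate_hz, dead_time_ms = dead_time_ms,
                              seed = seeds[1] + 1L),
    gamma = simulate_spike_data(dur, "gamma", rate_hz, shape = gamma_shape,
                                seed = seeds[1] + 2L)
  )

  isi <- purrr::imap_dfr(originals, function(x, model) {
    dplyr::bind_rows(
      dplyr::mutate(isi_histogram(x, 1, 200), model = model, method = "original"),
      purrr::map_dfr(methods, function(m) {
        s <- surrogate_for(x, m, dither_ms, bin_ms, trial_len_ms, seeds[2])
        dplyr::mutate(isi_histogram(s, 1, 200), model = model, method = m)
      })
    )
  })

  corr <- purrr::imap_dfr(originals, function(x, model) {
    dplyr::bind_rows(
      dplyr::mutate(correlation_histogram(x, max_lag_ms = 2 * dither_ms),
                    model = model, method = "original", kind = "auto"),
      purrr::map_dfr(methods, function(m) {
        s <- surrogate_for(x, m, dither_ms, bin_ms, trial_len_ms, seeds[3])
        dplyr::bind_rows(
          dplyr::mutate(correlation_histogram(x, s, max_lag_ms = 2 * dither_ms),
                        model = model, method = m, kind = "cross"),
          dplyr::mutate(correlation_histogram(s, max_lag_ms = 2 * dither_ms),
                        model = model, method = m, kind = "auto")
        )
      })
    )
  })

  cv_map <- purrr::map_dfr(cv_grid, function(cv) {
    x <- simulate_spike_data(dur, "gamma", rate_hz, shape = cv_to_shape(cv),
                             seed = seeds[4] + round(100 * cv))
    purrr::map_dfr(methods, function(m) {
      s <- surrogate_for(x, m, dither_ms, bin_ms, trial_len_ms,
                         seeds[4] + round(100 * cv) + 1L)
      tibble::tibble(cv_orig = cv, method = m,
                     cv_measured = cv_isi(x)$cv, cv_surr = cv_isi(s)$cv)
    })
  })

  moved <- purrr::map_dfr(rates, function(r) {
    dr <- round(n_spikes / r * 1000 / trial_len_ms) * trial_len_ms
    x <- simulate_spike_data(dr, "gamma", r, shape = moved_shape,
                             seed = seeds[5] + r)
    x2 <- simulate_spike_data(dr, "gamma", r, shape = moved_shape,
                              seed = seeds[5] + r + 1L)
    dplyr::bind_rows(
      tibble::tibble(rate_hz = r, method = "independent",
                     moved = moved_spike_ratio(x, x2, bin_ms)),
      purrr::map_dfr(methods, function(m) {
        s <- surrogate_for(x, m, dither_ms, bin_ms, trial_len_ms,
                           seeds[5] + r + 2L)
        tibble::tibble(rate_hz = r, method = m,
                       moved = moved_spike_ratio(x, s, bin_ms))
      })
    )
  })

  profile <- make_rate_profile("step", step_duration_ms,
                               rate_from = step_rates[1],
                               rate_to = step_rates[2],
                               step_at_ms = step_at_ms)
  step_x <- simulate_spike_data(step_duration_ms, "gamma",
                                profile = profile, shape = moved_shape,
                                n_trials = step_n_realizations,
                                seed = seeds[6])
  rate_step <- dplyr::bind_rows(
    dplyr::mutate(psth(step_x, 1), method = "original"),
    purrr::map_dfr(methods, function(m) {
      s <- if (m == "trshift") {
        surrogate_trial_shift(step_x, dither_ms, seed = seeds[6] + 1L)
      } else {
        surrogate_for(concatenate_trials(step_x), m, dither_ms, bin_ms,
                      trial_len_ms, seeds[6] + 1L)
      }
      if (length(attr(s, "trial_ids")) == 1) {
        s <- split_into_trials(s, step_duration_ms)
      }
      dplyr::mutate(psth(s, 1), method = m)
    })
  )

  list(isi = isi, crosscorr = dplyr::filter(corr, .data$kind == "cross"),
       autocorr = dplyr::filter(corr, .data$kind == "auto"),
       cv_map = cv_map, moved = moved, rate_step = rate_step,
       params = list(n_spikes = n_spikes, rate_hz = rate_hz,
                     dead_time_ms = dead_time_ms, gamma_shape = gamma_shape,
                     dither_ms = dither_ms, bin_ms = bin_ms,
                     step_n_realizations = step_n_realizations, seed = seed))
}

#' Spike-count-reduction curves for models and surrogates
#'
#' Empirical binarization-loss curves (`1 - N_clip/N`) as a function of the
#' firing rate for the Poisson, PPD and Gamma models and each surrogate
#' method, with the Poisson closed form and Monte-Carlo renewal estimates for
#' several dead-times and shape factors, with and without uniform dithering.
#'
#' @param rates Firing-rate grid (Hz).
#' @param n_spikes Expected spikes per curve point.
#' @param bin_ms Bin width (ms).
#' @param dead_time_ms,gamma_shape Parameters of the reference PPD / Gamma
#'   processes in the surrogate comparison.
#' @param ppd_deadtimes,gamma_shapes Parameter sets for the model-family
#'   overlay curves.
#' @param dither_ms Dither half-width (ms).
#' @param trial_len_ms Segment length for trial shifting (ms).
#' @param methods Surrogate methods to include.
#' @param seed Master seed.
#' @return A list of tibbles: `surrogates` (per model x method x rate) and
#'   `model_families` (overlay curves, original vs uniform-dithered), plus
#'   parameters.
#' @export
run_spike_loss_experiment <- function(rates = seq(10, 100, by = 10),
                                      n_spikes = 1e4, bin_ms = 5,
                                      dead_time_ms = 1.6, gamma_shape = 1.23,
                                      ppd_deadtimes = c(1.5, 2, 2.5, 3),
                                      gamma_shapes = c(1, 1.5, 2, 2.5),
                                      dither_ms = 25, trial_len_ms = 100,
                                      methods = surrogate_methods(),
                                      seed = 1) {
  models <- list(poisson = list(), ppd = list(dead_time_ms = dead_time_ms),
                 gamma = list(shape = gamma_shape))
  surr <- purrr::imap_dfr(models, function(pars, model) {
    purrr::map_dfr(rates, function(r) {
      dur <- round(n_spikes / r * 1000 / trial_len_ms) * trial_len_ms
      x <- do.call(simulate_spike_data,
                   c(list(dur, model, rate_hz = r, seed = seed + r), pars))
      dplyr::bind_rows(
        tibble::tibble(model = model, method = "original", rate_hz = r,
                       reduction = spike_count_reduction(binarize(x, bin_ms))),
        purrr::map_dfr(methods, function(m) {
          s <- surrogate_for(x, m, dither_ms, bin_ms, trial_len_ms, seed + r + 1L)
          tibble::tibble(model = model, method = m, rate_hz = r,
                         reduction = spike_count_reduction(binarize(s, bin_ms)))
        })
      )
    })
  })

  fam <- dplyr::bind_rows(
    purrr::map_dfr(ppd_deadtimes, function(d) {
      purrr::map_dfr(rates, function(r) {
        dplyr::bind_rows(
          expected_spike_count_reduction(r, bin_ms, "ppd", dead_time_ms = d,
                                         n_spikes = n_spikes, seed = seed + r),
          expected_spike_count_reduction(r, bin_ms, "ppd", dead_time_ms = d,
                                         surrogate = "ud", dither_ms = dither_ms,
                                         n_spikes = n_spikes, seed = seed + r)
        ) |> dplyr::mutate(param = d)
      })
    }),
    purrr::map_dfr(gamma_shapes, function(g) {
      purrr::map_dfr(rates, function(r) {
        dplyr::bind_rows(
          expected_spike_count_reduction(r, bin_ms, "gamma", shape = g,
                                         n_spikes = n_spikes, seed = seed + r),
          expected_spike_count_reduction(r, bin_ms, "gamma", shape = g,
                                         surrogate = "ud", dither_ms = dither_ms,
                                         n_spikes = n_spikes, seed = seed + r)
        ) |> dplyr::mutate(param = g)
      })
    }),
    purrr::map_dfr(rates, function(r) {
      dplyr::mutate(expected_spike_count_reduction(r, bin_ms, "poisson",
                                                   mode = "analytic"),
                    param = NA_real_)
    })
  )

  list(surrogates = surr, model_families = fam,
       params = list(rates = rates, n_spikes = n_spikes, bin_ms = bin_ms,
                     dither_ms = dither_ms, seed = seed))
}

#' P-value-spectrum comparison between surrogate methods
#'
#' Generates independent stationary PPD populations, builds for each
#' realization the size-3 pattern spectrum of the original data and the
#' surrogate-based p-value spectrum for each requested method, averages the
#' p-value spectra over realizations, applies pattern spectrum filtering with
#' Benjamini-Hochberg correction over the occupied signatures pooled across
#' realizations, and reports per duration the minimal occurrence count
#' crossing the raw `alpha` isoline and the BH-corrected isoline.
#'
#' @param n_realizations Number of independent population realizations.
#' @param n_units Parallel independent trains per realization.
#' @param duration_ms Train duration (ms).
#' @param rate_hz,dead_time_ms PPD parameters.
#' @param bin_ms Bin width (ms).
#' @param window_bins Context-window length in bins (durations up to
#'   `window_bins - 1`).
#' @param methods Surrogate methods to compare.
#' @param n_surrogates Surrogates per p-value spectrum.
#' @param dither_ms Dither half-width (ms).
#' @param trial_len_ms Segment length for trial shifting (ms).
#' @param alpha Significance level.
#' @param min_occ Minimal occurrence count.
#' @param seed Master seed.
#' @return A list with `thresholds` (per method and duration: `c_alpha`,
#'   `c_bh`), `pvals` (averaged p-value spectra), `spectrum` (pooled occupied
#'   signatures) and the parameter list.
#' @export
run_pvalue_spectrum_experiment <- function(n_realizations = 20, n_units = 20,
                                           duration_ms = 2000, rate_hz = 60,
                                           dead_time_ms = 1.6, bin_ms = 5,
                                           window_bins = 13,
                                           methods = c("ud", "trshift"),
                                           n_surrogates = 500, dither_ms = 25,
                                           trial_len_ms = 100, alpha = 0.05,
                                           min_occ = 10, seed = 1) {
  seeds <- surrogate_seeds(seed, n_realizations)
  real <- purrr::map(seq_len(n_realizations), function(k) {
    x <- simulate_spike_data(duration_ms, "ppd", rate_hz,
                             dead_time_ms = dead_time_ms,
                             n_units = n_units, seed = seeds[k])
    spec <- pattern_spectrum(x, bin_ms, window_bins, min_occ = min_occ)
    pv <- purrr::map(methods, function(m) {
      pvalue_spectrum(x, m, n_surrogates, bin_ms = bin_ms,
                      window_bins = window_bins, min_occ = min_occ,
                      dither_ms = dither_ms,
                      trial_len_ms = if (m == "trshift") trial_len_ms else NULL,
                      seed = seeds[k] + 1L)
    })
    names(pv) <- methods
    list(spec = spec, pv = pv)
  })

  # pool occupied signatures over realizations (counts summed)
  spec_all <- purrr::map_dfr(real, ~ tibble::as_tibble(.x$spec)) |>
    dplyr::group_by(.data$z, .data$c, .data$d) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  spec_all <- new_pattern_spectrum(spec_all, window_bins, min_occ, bin_ms)

  # average p-value spectra over realizations on the union grid (a spectrum
  # reports p = 0 beyond its stored count range)
  avg_pv <- purrr::map(methods, function(m) {
    tabs <- purrr::map(real, ~ tibble::as_tibble(.x$pv[[m]]))
    grid <- dplyr::distinct(dplyr::bind_rows(tabs), .data$z, .data$d, .data$c)
    acc <- purrr::map(tabs, function(tb) {
      dplyr::left_join(grid, tb, by = c("z", "d", "c")) |>
        dplyr::mutate(p = dplyr::coalesce(.data$p, 0))
    })
    out <- grid
    out$p <- rowMeans(do.call(cbind, purrr::map(acc, "p")))
    structure(dplyr::arrange(out, .data$z, .data$d, .data$c),
              n_surrogates = n_surrogates, min_occ = min_occ,
              window_bins = window_bins, bin_ms = bin_ms, method = m,
              class = c("pvalue_spectrum", class(tibble::tibble())))
  })
  names(avg_pv) <- methods

  thresholds <- purrr::map_dfr(methods, function(m) {
    res <- psf(spec_all, avg_pv[[m]], alpha = alpha)
    iso_a <- min_significant_count(avg_pv[[m]], alpha)
    iso_b <- min_significant_count(avg_pv[[m]], res$p_threshold)
    dplyr::full_join(
      dplyr::rename(iso_a, c_alpha = "c_min"),
      dplyr::rename(iso_b, c_bh = "c_min"),
      by = c("z", "d")
    ) |> dplyr::mutate(method = m, p_threshold = res$p_threshold)
  })

  list(thresholds = thresholds, pvals = avg_pv, spectrum = spec_all,
       params = list(n_realizations = n_realizations, n_units = n_units,
                     duration_ms = duration_ms, rate_hz = rate_hz,
                     dead_time_ms = dead_time_ms, bin_ms = bin_ms,
                     window_bins = window_bins, n_surrogates = n_surrogates,
                     dither_ms = dither_ms, trial_len_ms = trial_len_ms,
                     alpha = alpha, min_occ = min_occ, seed = seed))
}

#' Synthetic nonstationary population for false-positive calibration
#'
#' Builds a population of independent nonstationary spike trains with
#' experimental-like, band-limited rate profiles (one profile per unit,
#' repeated over trials) from a PPD or Gamma renewal model, with per-unit
#' dead-times or regularities drawn from stated ranges. Since all units are
#' independent, every significant pattern found in such data is a false
#' positive.
#'
#' @param model `"ppd"` or `"gamma"`.
#' @param n_units Number of units.
#' @param n_trials Number of trials.
#' @param trial_ms Trial duration (ms).
#' @param rate_range Rate band of the profiles (Hz).
#' @param deadtime_range Per-unit dead-time range (ms, PPD).
#' @param cv_range Per-unit CV range (Gamma; shapes are `1/CV^2`).
#' @param seed Master seed.
#' @return A `spike_data` object with `n_trials` trials.
#' @export
simulate_fp_population <- function(model = c("ppd", "gamma"), n_units = 20,
                                   n_trials = 36, trial_ms = 500,
                                   rate_range = c(10, 70),
                                   deadtime_range = c(1.2, 2),
                                   cv_range = c(0.5, 0.85), seed = 1) {
  model <- match.arg(model)
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(n_units), function(u) {
      prof <- make_rate_profile("experimental", trial_ms,
                                rate_range = rate_range)
      par <- if (model == "ppd") {
        list(dead_time_ms = runif(1, deadtime_range[1], deadtime_range[2]))
      } else {
        list(shape = cv_to_shape(runif(1, cv_range[1], cv_range[2])))
      }
      purrr::map_dfr(seq_len(n_trials), function(tr) {
        times <- do.call(simulate_spike_data,
                         c(list(trial_ms, model, profile = prof), par))
        tibble::tibble(trial_id = tr, unit_id = sprintf("u%02d", u),
                       time_ms = times$time_ms)
      })
    })
    spike_data(rows, t_stop = trial_ms)
  })
}

#' False-positive study on synthetic nonstationary populations
#'
#' Runs the full pattern-spectrum pipeline (binarization, size-3 mining,
#' surrogate p-value spectrum, BH-corrected pattern spectrum filtering) on
#' independent nonstationary PPD and Gamma populations with each surrogate
#' method, and tabulates the significant (hence false-positive) patterns per
#' surrogate, together with firing-rate and CV2 summaries of the units
#' involved.
#'
#' @param models Point-process models to simulate.
#' @param n_datasets Independent datasets per model.
#' @param n_units,n_trials,trial_ms,rate_range,deadtime_range,cv_range
#'   Population parameters (see [simulate_fp_population()]).
#' @param bin_ms Bin width (ms).
#' @param window_bins Context-window length in bins.
#' @param methods Surrogate methods.
#' @param n_surrogates Surrogates per p-value spectrum.
#' @param dither_ms Dither half-width (ms).
#' @param alpha Significance level.
#' @param seed Master seed.
#' @return A list with `fp_counts` (per model x method: total FP patterns and
#'   per-dataset means), `fp_units` (rate and CV2 of units involved in FPs vs
#'   all units) and parameters.
#' @export
run_fp_study <- function(models = c("ppd", "gamma"), n_datasets = 2,
                         n_units = 20, n_trials = 36, trial_ms = 500,
                         rate_range = c(10, 70), deadtime_range = c(1.2, 2),
                         cv_range = c(0.5, 0.85), bin_ms = 5, window_bins = 13,
                         methods = surrogate_methods(), n_surrogates = 300,
                         dither_ms = 25, alpha = 0.05, seed = 1) {
  min_occ <- min_occ_default(n_trials)
  runs <- purrr::map_dfr(models, function(model) {
    purrr::map_dfr(seq_len(n_datasets), function(k) {
      pop <- simulate_fp_population(model, n_units, n_trials, trial_ms,
                                    rate_range, deadtime_range, cv_range,
                                    seed = seed + 97L * k +
                                      1000L * match(model, models))
      xc <- concatenate_trials(pop)
      spec <- pattern_spectrum(xc, bin_ms, window_bins, min_occ = min_occ)
      stats <- dplyr::left_join(
        dplyr::rename(cv_isi(pop)[, c("unit_id", "cv")], cv = "cv"),
        dplyr::rename(cv2_isi(pop)[, c("unit_id", "cv2")], cv2 = "cv2"),
        by = "unit_id"
      )
      stats$rate_hz <- vapply(stats$unit_id, function(u) {
        1000 * sum(pop$unit_id == u) / (n_trials * trial_ms)
      }, 0.0)
      purrr::map_dfr(methods, function(m) {
        x_m <- if (m == "trshift") pop else xc
        pv <- pvalue_spectrum(x_m, m, n_surrogates, bin_ms = bin_ms,
                              window_bins = window_bins, min_occ = min_occ,
                              dither_ms = dither_ms, seed = seed + 7L * k)
        res <- psf(spec, pv, alpha = alpha)
        fp_units <- character(0)
        n_fp <- 0L
        if (nrow(res$significant)) {
          cmin_by_d <- min_significant_count(pv, res$p_threshold)
          trip <- triplets_above(occupancy(binarize(xc, bin_ms)), window_bins,
                                 min(res$significant$c))
          if (nrow(trip)) {
            dur <- pmax(trip[, "lag2"], trip[, "lag3"])
            keep <- vapply(seq_len(nrow(trip)), function(i) {
              cm <- cmin_by_d$c_min[cmin_by_d$d == dur[i]]
              length(cm) == 1 && !is.na(cm) && trip[i, "support"] >= cm
            }, TRUE)
            trip <- trip[keep, , drop = FALSE]
            n_fp <- nrow(trip)
            fp_units <- unique(units_of(pop)[
              1L + as.vector(trip[, c("unit1", "unit2", "unit3")])])
          }
        }
        tibble::tibble(model = model, dataset = k, method = m,
                       n_fp = n_fp, fp_units = list(fp_units),
                       unit_stats = list(stats))
      })
    })
  })

  fp_counts <- runs |>
    dplyr::group_by(.data$model, .data$method) |>
    dplyr::summarise(total_fp = sum(.data$n_fp),
                     mean_fp_per_dataset = mean(.data$n_fp), .groups = "drop")

  fp_units <- runs |>
    dplyr::mutate(stats = purrr::map2(.data$unit_stats, .data$fp_units,
      function(st, fu) dplyr::mutate(st, in_fp = .data$unit_id %in% fu))) |>
    dplyr::select("model", "dataset", "method", "stats") |>
    tidyr::unnest("stats")

  list(fp_counts = fp_counts, fp_units = fp_units,
       params = list(models = models, n_datasets = n_datasets,
                     n_units = n_units, n_trials = n_trials,
                     trial_ms = trial_ms, bin_ms = bin_ms,
                     window_bins = window_bins, n_surrogates = n_surrogates,
                     dither_ms = dither_ms, alpha = alpha, min_occ = min_occ,
                     seed = seed))
}

#' Write the deterministic fixture bundle
#'
#' Generates the small datasets used in examples and tests: a
#' planted-pattern dataset (a size-3 pattern injected into otherwise empty
#' data), stationary Poisson / PPD / Gamma trains at reference parameters,
#' and a 10-to-80 Hz step-profile realization, all written as spike CSV files
#' to `dir`. Byte-identical for identical seeds.
#'
#' @param dir Output directory (created if missing).
#' @param seed Master seed.
#' @return Invisibly, the vector of file paths written.
#' @export
generate_fixtures <- function(dir = tempdir(), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  put <- function(x, name) {
    p <- file.path(dir, name)
    write_spike_csv(x, p)
    paths <<- c(paths, p)
  }
  put(planted_pattern_data(), "planted_pattern.csv")
  put(simulate_spike_data(2000, "poisson", 60, n_units = 3, seed = seed),
      "poisson_60hz.csv")
  put(simulate_spike_data(2000, "ppd", 60, dead_time_ms = 1.6, n_units = 3,
                          seed = seed + 1L), "ppd_60hz.csv")
  put(simulate_spike_data(2000, "gamma", 60, shape = 6.25, n_units = 3,
                          seed = seed + 2L), "gamma_cv04_60hz.csv")
  prof <- make_rate_profile("step", 150, rate_from = 10, rate_to = 80,
                            step_at_ms = 75)
  put(simulate_spike_data(150, "poisson", profile = prof, n_trials = 50,
                          seed = seed + 3L), "step_profile.csv")
  invisible(paths)
}

#' A tiny dataset with a planted spatiotemporal pattern
#'
#' Three units carrying the pattern (u1 at lag 0, u2 at 1 bin, u3 at 3 bins
#' of 5 ms) planted `n_occ` times in otherwise empty data; used to validate
#' the miner end to end.
#'
#' @param n_occ Number of planted occurrences.
#' @param bin_ms Bin width the lags refer to (ms).
#' @return A `spike_data` object.
#' @export
planted_pattern_data <- function(n_occ = 5, bin_ms = 5) {
  anchors <- (seq_len(n_occ) - 1) * 50 + 2.5
  spike_data(tibble::tibble(
    trial_id = 1L,
    unit_id = rep(c("u1", "u2", "u3"), each = n_occ),
    time_ms = c(anchors, anchors + bin_ms, anchors + 3 * bin_ms)
  ), t_stop = n_occ * 50)
}
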