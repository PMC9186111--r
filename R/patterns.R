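# Pattern mining and the surrogate-based pattern-spectrum significance test:
# mine repeating spatiotemporal patterns from binarized parallel spike trains,
# pool them into the 3-d pattern spectrum over signatures (z, c, d), derive a
# p-value spectrum from surrogates, and filter signatures with a
# Benjamini-Hochberg-corrected test (pattern spectrum filtering).

# ---- transactions -----------------------------------------------------------

# item encoding: item = lag * U + unit_index, 1-based in R (lag 0-based),
# so the lag-0 items are 1..U and sort first.
item_unit <- function(item, U) ((item - 1L) %% U) + 1L
item_lag <- function(item, U) (item - 1L) %/% U

# tid-lists per item over pooled per-trial sliding windows
build_tidlists <- function(binned, window_bins) {
  occ <- occupancy(binned)
  U <- length(binned$units)
  w <- window_bins
  if (w > binned$n_bins) rlang::abort("`window_bins` exceeds the data length.")
  M <- U * w
  tids <- vector("list", M)
  for (i in seq_len(M)) tids[[i]] <- integer(0)
  offset <- 0L
  tid_map <- list()
  for (k in seq_along(occ)) {
    m <- occ[[k]]
    n_starts <- ncol(m) - w + 1L
    for (u in seq_len(U)) {
      cols <- which(m[u, ] > 0L)
      for (lag in 0:(w - 1L)) {
        s <- cols - lag
        s <- s[s >= 1L & s <= n_starts]
        if (length(s)) {
          item <- lag * U + u
          tids[[item]] <- c(tids[[item]], offset + s)
        }
      }
    }
    tid_map[[k]] <- tibble::tibble(
      trial_id = binned$trials[k],
      start_bin = seq_len(n_starts) - 1L,
      tid = offset + seq_len(n_starts)
    )
    offset <- offset + n_starts
  }
  list(tids = lapply(tids, sort), U = U, w = w, M = M,
       n_transactions = offset, tid_map = dplyr::bind_rows(tid_map))
}

# ---- mining -----------------------------------------------------------------

#' Mine repeating spatiotemporal patterns from binarized data
#'
#' Slides a `window_bins`-wide context window over every start bin of the
#' occupancy matrix (per trial; supports are pooled over trials). Each window
#' position yields a transaction of items (unit, lag in bins); frequent
#' itemsets with support at least `min_occ` that contain at least one lag-0
#' item are mined by a depth-first tid-list search. A pattern's signature is
#' `(z, c, d)`: its size (number of items), occurrence count (number of
#' distinct window start positions containing it), and duration (maximal lag
#' in bins). With `closed = TRUE` only closed itemsets are reported (no
#' strict superset has identical support), i.e. patterns that cannot be
#' explained as part of a larger pattern with the same occurrences.
#'
#' @param binned A `binned_spikes` object (see [binarize()]).
#' @param window_bins Context-window length in bins; the maximal pattern
#'   duration is `window_bins - 1`.
#' @param min_size,max_size Pattern size bounds (`min_size >= 2`).
#' @param min_occ Minimal occurrence count (see [min_occ_default()]).
#' @param closed Report only closed patterns (default `TRUE`).
#' @return A tibble of class `pattern_set`: one row per pattern with list
#'   columns `units` and `lags`, signature columns `z`, `c`, `d`, and a list
#'   column `anchors` (tibble of `trial_id`, `start_bin` per occurrence).
#' @export
mine_patterns <- function(binned, window_bins, min_size = 2, max_size = Inf,
                          min_occ = 10, closed = TRUE) {
  stopifnot(inherits(binned, "binned_spikes"), min_size >= 2)
  tl <- build_tidlists(binned, window_bins)
  tids <- tl$tids
  U <- tl$U
  M <- tl$M
  supports <- lengths(tids)
  frequent <- which(supports >= min_occ)
  out <- list()

  emit <- function(items, tset) {
    if (length(items) < min_size) return()
    if (closed) {
      others <- setdiff(frequent, items)
      for (e in others) {
        if (length(intersect(tset, tids[[e]])) == length(tset)) return()
      }
    }
    out[[length(out) + 1L]] <<- list(items = items, tids = tset)
  }

  recurse <- function(items, tset) {
    emit(items, tset)
    if (length(items) >= max_size) return()
    last <- items[length(items)]
    ext <- frequent[frequent > last]
    for (e in ext) {
      ts2 <- intersect(tset, tids[[e]])
      if (length(ts2) >= min_occ) recurse(c(items, e), ts2)
    }
  }

  roots <- frequent[frequent <= U] # itemsets must contain a lag-0 item
  for (r in roots) recurse(r, tids[[r]])

  rows <- purrr::map_dfr(out, function(p) {
    lag_vec <- item_lag(p$items, U)
    tibble::tibble(
      units = list(binned$units[item_unit(p$items, U)]),
      lags = list(as.integer(lag_vec)),
      z = length(p$items),
      c = length(p$tids),
      d = as.integer(max(lag_vec)),
      anchors = list(tl$tid_map[match(p$tids, tl$tid_map$tid),
                                c("trial_id", "start_bin")])
    )
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(units = list(), lags = list(),
                           z = integer(), c = integer(), d = integer(),
                           anchors = list())
  }
  structure(rows,
            window_bins = window_bins, min_occ = min_occ,
            bin_ms = binned$bin_ms,
            class = c("pattern_set", class(tibble::tibble())))
}

#' Default minimal occurrence count
#'
#' The minimum number of occurrences for a pattern to be considered:
#' at least 10, and at least 30% of the number of trials.
#'
#' @param n_trials Number of trials (>= 1).
#' @return An integer: `max(10, ceiling(0.3 * n_trials))`.
#' @examples
#' min_occ_default(36) # 11
#' @export
min_occ_default <- function(n_trials) {
  stopifnot(n_trials >= 1)
  max(10L, as.integer(ceiling(0.3 * n_trials)))
}

#' Rough Poisson estimate of chance pattern counts
#'
#' For independent stationary Poisson units with a common rate, the expected
#' number of window positions containing one specific size-z pattern is
#' `n_starts * p^z` with `p = 1 - exp(-rate * bin)` the bin occupation
#' probability. Multiplied by the number of distinct size-z item
#' combinations, this gives a rough estimate of the number of chance
#' patterns, usable to pick a `min_occ` larger than the printed default.
#'
#' @param n_units Number of units.
#' @param rate_hz Average firing rate in Hz.
#' @param bin_ms Bin width in ms.
#' @param n_bins Number of bins.
#' @param window_bins Context-window length in bins.
#' @param z Pattern size.
#' @return A tibble with the expected support of one specific pattern and the
#'   number of candidate patterns.
#' @export
expected_chance_patterns <- function(n_units, rate_hz, bin_ms, n_bins,
                                     window_bins, z = 3) {
  p <- 1 - exp(-rate_hz * bin_ms / 1000)
  n_starts <- n_bins - window_bins + 1
  n_candidates <- choose(n_units, z) * factorial(z) / z *
    window_bins^(z - 1) # one item pinned at lag 0
  tibble::tibble(
    occupation_prob = p,
    expected_support = n_starts * p^z,
    n_candidate_patterns = n_candidates
  )
}

# ---- spectra ----------------------------------------------------------------

new_pattern_spectrum <- function(df, window_bins, min_occ, bin_ms) {
  structure(df, window_bins = window_bins, min_occ = min_occ, bin_ms = bin_ms,
            class = c("pattern_spectrum", class(tibble::tibble())))
}

#' Build the pattern spectrum from mined patterns
#'
#' Pools patterns by signature: the spectrum is a sparse 3-d histogram over
#' `(z, c, d)` whose entries count the patterns carrying that signature.
#'
#' @param patterns A `pattern_set` from [mine_patterns()].
#' @return A tibble of class `pattern_spectrum` with columns `z`, `c`, `d`,
#'   `count`.
#' @export
build_spectrum <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_set"))
  df <- patterns |>
    dplyr::count(.data$z, .data$c, .data$d, name = "count") |>
    dplyr::arrange(.data$z, .data$d, .data$c)
  new_pattern_spectrum(df, attr(patterns, "window_bins"),
                       attr(patterns, "min_occ"), attr(patterns, "bin_ms"))
}

# size-3 spectrum via the exhaustive C++ triplet counter (all size-3 itemsets
# with a lag-0 item; no closedness filtering)
spectrum_z3 <- function(binned, window_bins, min_occ) {
  H <- count_triplet_supports(occupancy(binned), window_bins)
  idx <- which(H > 0, arr.ind = TRUE)
  df <- tibble::tibble(
    z = 3L, c = as.integer(idx[, 2]), d = as.integer(idx[, 1] - 1L),
    count = H[idx]
  ) |>
    dplyr::filter(.data$c >= min_occ) |>
    dplyr::arrange(.data$z, .data$d, .data$c)
  new_pattern_spectrum(df, window_bins, min_occ, binned$bin_ms)
}

# per-duration maximal support of size-3 patterns (0 where none)
max_support_z3 <- function(binned, window_bins) {
  H <- count_triplet_supports(occupancy(binned), window_bins)
  vapply(seq_len(nrow(H)), function(d) {
    nz <- which(H[d, ] > 0)
    if (length(nz)) as.integer(max(nz)) else 0L
  }, 0L)
}

#' Pattern spectrum of a dataset
#'
#' Convenience wrapper: binarizes, mines, and pools patterns into the
#' spectrum. When the mining is restricted to size-3 patterns
#' (`min_size = max_size = 3`, the default) an exhaustive C++ triplet counter
#' is used, which enumerates every size-3 itemset with a lag-0 item
#' (closedness is not applied at fixed size); otherwise the general closed
#' miner runs.
#'
#' @param x A `spike_data` object.
#' @param bin_ms Bin width in ms.
#' @param window_bins Context-window length in bins.
#' @param min_size,max_size Pattern size bounds.
#' @param min_occ Minimal occurrence count.
#' @return A `pattern_spectrum` tibble.
#' @export
pattern_spectrum <- function(x, bin_ms = 5, window_bins = 12,
                             min_size = 3, max_size = 3, min_occ = 10) {
  binned <- binarize(x, bin_ms)
  if (min_size == 3 && max_size == 3) {
    spectrum_z3(binned, window_bins, min_occ)
  } else {
    build_spectrum(mine_patterns(binned, window_bins, min_size = min_size,
                                 max_size = max_size, min_occ = min_occ,
                                 closed = FALSE))
  }
}

# ---- p-value spectrum -------------------------------------------------------

#' Surrogate-based p-value spectrum
#'
#' Estimates, for every signature `(z, c, d)`, the probability under the
#' surrogate null that the data contain at least one pattern with size >= `z`
#' and occurrence count >= `c` at duration exactly `d`: each of the `R`
#' surrogate datasets is mined like the original, its pattern spectrum is
#' binarized to 0/1, cumulated by the partial order over size and occurrences
#' (duration matched exactly), and the indicators are averaged over the
#' surrogate realizations. With `R` surrogates the smallest attainable
#' nonzero p-value is `1/R`; an entry of 0 means "below `1/R`".
#'
#' @param x A `spike_data` object (the original data).
#' @param method Surrogate method name (see [surrogate_methods()]).
#' @param n_surrogates Number of surrogate datasets `R >= 1`.
#' @param bin_ms,window_bins,min_size,max_size,min_occ Mining parameters, as
#'   in [pattern_spectrum()].
#' @param dither_ms Dither half-width for the surrogate method.
#' @param trial_len_ms For `method = "trshift"` on continuous data: segment
#'   length used to cut each train into trials before shifting.
#' @param seed Master seed; surrogate `r` uses a seed derived from it.
#' @param ... Extra arguments passed to the surrogate method.
#' @return A tibble of class `pvalue_spectrum` with columns `z`, `d`, `c`,
#'   `p`, for `c` from `min_occ` to one past the largest surrogate count
#'   (p-values are 0 beyond; use [pspec_p()] for lookups).
#' @export
pvalue_spectrum <- function(x, method, n_surrogates, bin_ms = 5,
                            window_bins = 12, min_size = 3, max_size = 3,
                            min_occ = 10, dither_ms = 25,
                            trial_len_ms = NULL, seed = NULL, ...) {
  stopifnot(inherits(x, "spike_data"), n_surrogates >= 1)
  z3 <- min_size == 3 && max_size == 3
  z_levels <- seq(min_size, max_size)

  x_for <- x
  if (method == "trshift" && !is.null(trial_len_ms)) {
    x_for <- split_into_trials(concatenate_trials(x), trial_len_ms)
  }

  maxc_one <- function(s) {
    # re-reference trial-shift segments back to the continuous train so the
    # mining sees the same geometry as the original data
    if (method == "trshift" && !is.null(trial_len_ms)) s <- concatenate_trials(s)
    b <- binarize(s, bin_ms)
    if (z3) {
      matrix(max_support_z3(b, window_bins), nrow = 1)
    } else {
      pats <- mine_patterns(b, window_bins, min_size = min_size,
                            max_size = max_size, min_occ = min_occ,
                            closed = FALSE)
      m <- matrix(0L, nrow = length(z_levels), ncol = window_bins)
      if (nrow(pats)) {
        for (zi in seq_along(z_levels)) {
          sub <- pats[pats$z >= z_levels[zi], ]
          if (nrow(sub)) {
            agg <- tapply(sub$c, sub$d, max)
            m[zi, as.integer(names(agg)) + 1L] <- as.integer(agg)
          }
        }
      }
      m
    }
  }

  args <- list(x_for, n = n_surrogates, method = method,
               dither_ms = dither_ms, .f = function(s, r) maxc_one(s),
               seed = seed)
  if (method == "winshuff") args$bin_ms <- bin_ms
  maxc <- do.call(make_surrogates, args)

  c_max <- max(1L, max(vapply(maxc, max, 0L)))
  c_grid <- seq(min_occ, max(c_max + 1L, min_occ))
  rows <- purrr::map_dfr(seq_along(z_levels), function(zi) {
    purrr::map_dfr(0:(window_bins - 1), function(dd) {
      vals <- vapply(maxc, function(m) m[zi, dd + 1L], 0L)
      tibble::tibble(
        z = z_levels[zi], d = dd, c = c_grid,
        p = vapply(c_grid, function(cc) mean(vals >= cc), 0.0)
      )
    })
  })
  structure(rows,
            n_surrogates = n_surrogates, min_occ = min_occ,
            window_bins = window_bins, bin_ms = bin_ms, method = method,
            class = c("pvalue_spectrum", class(tibble::tibble())))
}

#' Look up p-values in a p-value spectrum
#'
#' @param pvals A `pvalue_spectrum` (or a tibble with columns `z, d, c, p`).
#' @param z,c,d Signature components (vectorized).
#' @return p-values; 0 beyond the stored count range (no surrogate reached
#'   such counts), NA for signatures outside the mined size/duration range.
#' @export
pspec_p <- function(pvals, z, c, d) {
  n <- max(length(z), length(c), length(d))
  z <- rep_len(z, n); c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    sub <- pvals$p[pvals$z == z[i] & pvals$d == d[i] & pvals$c == c[i]]
    if (length(sub)) return(sub[1])
    zd <- pvals[pvals$z == z[i] & pvals$d == d[i], ]
    if (!nrow(zd)) return(NA_real_)
    if (c[i] > max(zd$c)) 0.0 else NA_real_
  }, 0.0)
}

# ---- pattern spectrum filtering --------------------------------------------

#' Pattern spectrum filtering (PSF) with Benjamini-Hochberg correction
#'
#' Tests the occupied signatures of a pattern spectrum against the
#' surrogate-based p-value spectrum. The multiple-testing burden is the
#' number of occupied signatures `(z, c, d)` for which `(z, c + 1, d)` is not
#' occupied (testing a signature implies the cumulated test of all smaller
#' ones); over exactly this test set the Benjamini-Hochberg procedure is run
#' at level `alpha`. All occupied signatures whose p-value is at or below the
#' resulting threshold are significant, together with any patterns carrying
#' them.
#'
#' @param spectrum A `pattern_spectrum`.
#' @param pvals A `pvalue_spectrum` computed with the same mining parameters.
#' @param alpha Significance level (default 0.05).
#' @param patterns Optional `pattern_set` to attach significant patterns.
#' @return An object of class `psf_result`: a list with `tests` (the test-set
#'   tibble with raw and adjusted p-values), `p_threshold` (largest raw
#'   p-value declared significant; 0 when none is), `significant` (occupied
#'   signatures passing the threshold), and `significant_patterns` (when
#'   `patterns` was supplied).
#' @export
psf <- function(spectrum, pvals, alpha = 0.05, patterns = NULL) {
  stopifnot(inherits(spectrum, "pattern_spectrum"))
  for (a in c("window_bins", "bin_ms")) {
    sa <- attr(spectrum, a); pa <- attr(pvals, a)
    if (!is.null(sa) && !is.null(pa) && !isTRUE(all.equal(sa, pa))) {
      rlang::abort(sprintf("`%s` differs between spectrum and p-value spectrum.", a))
    }
  }
  occ <- tibble::as_tibble(spectrum)
  if (!nrow(occ)) {
    res <- list(tests = occ, p_threshold = 0,
                significant = occ, significant_patterns = NULL, alpha = alpha)
    return(structure(res, class = "psf_result"))
  }
  keyed <- paste(occ$z, occ$c, occ$d)
  boundary <- !(paste(occ$z, occ$c + 1L, occ$d) %in% keyed)
  tests <- occ[boundary, ]
  tests$p <- pspec_p(pvals, tests$z, tests$c, tests$d)
  tests$p_adj <- p.adjust(tests$p, method = "BH")
  tests$significant <- tests$p_adj <= alpha
  p_threshold <- if (any(tests$significant)) max(tests$p[tests$significant]) else 0
  occ$p <- pspec_p(pvals, occ$z, occ$c, occ$d)
  significant <- occ[!is.na(occ$p) & occ$p <= p_threshold & any(tests$significant), ]
  sig_pats <- NULL
  if (!is.null(patterns) && nrow(significant)) {
    key_sig <- paste(significant$z, significant$c, significant$d)
    sig_pats <- patterns[paste(patterns$z, patterns$c, patterns$d) %in% key_sig, ]
  }
  structure(
    list(tests = tests, p_threshold = p_threshold, significant = significant,
         significant_patterns = sig_pats, alpha = alpha),
    class = "psf_result"
  )
}

#' @export
print.psf_result <- function(x, ...) {
  cat(sprintf(
    "# psf_result: %d test(s), BH threshold %.4g, %d significant signature(s)\n",
    nrow(x$tests), x$p_threshold, nrow(x$significant)
  ))
  invisible(x)
}

#' Tidy and glance methods for PSF results
#'
#' @param x A `psf_result`.
#' @param ... Unused.
#' @return `tidy()` returns the significant signatures; `glance()` a one-row
#'   summary.
#' @export
tidy.psf_result <- function(x, ...) tibble::as_tibble(x$significant)

#' @rdname tidy.psf_result
#' @export
glance.psf_result <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$tests), alpha = x$alpha,
    p_threshold = x$p_threshold, n_significant = nrow(x$significant)
  )
}

#' Minimal significant occurrence count per duration
#'
#' Reads the significance isolines off a p-value spectrum: for each size and
#' duration, the smallest occurrence count whose p-value is at or below
#' `level` (e.g. the raw `alpha`, or the BH threshold from [psf()]).
#'
#' @param pvals A `pvalue_spectrum`.
#' @param level Significance level to cross.
#' @return A tibble `z, d, c_min` (NA where no stored count crosses the
#'   level... counts above the stored range always cross, so NA only occurs
#'   when `level < 0`).
#' @export
min_significant_count <- function(pvals, level) {
  pvals |>
    dplyr::group_by(.data$z, .data$d) |>
    dplyr::summarise(
      c_min = {
        ok <- .data$p <= level
        if (any(ok)) min(.data$c[ok]) else NA_integer_
      },
      .groups = "drop"
    )
}
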