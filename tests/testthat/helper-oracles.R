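# Independent oracles used by the tests: a brute-force pattern miner and a
# naive resampling p-value spectrum, both written against the same window /
# item conventions as the package but sharing no code with it.

# transactions as a list of sorted integer item vectors (item = lag * U + u,
# 1-based), built directly from the occupancy matrices
bf_transactions <- function(occ_list, w) {
  U <- nrow(occ_list[[1]])
  out <- list()
  for (m in occ_list) {
    n_starts <- ncol(m) - w + 1
    for (t in seq_len(n_starts)) {
      items <- integer(0)
      for (lag in 0:(w - 1)) {
        items <- c(items, lag * U + which(m[, t + lag] > 0))
      }
      out[[length(out) + 1]] <- items
    }
  }
  out
}

bf_support <- function(trans, items) {
  sum(vapply(trans, function(tr) all(items %in% tr), TRUE))
}

# exhaustive enumeration of frequent itemsets with >= 1 lag-0 item
bf_mine <- function(occ_list, w, min_size = 2, max_size = 4, min_occ = 2,
                    closed = TRUE) {
  U <- nrow(occ_list[[1]])
  trans <- bf_transactions(occ_list, w)
  all_items <- sort(unique(unlist(trans)))
  res <- list()
  for (k in min_size:min(max_size, length(all_items))) {
    combs <- utils::combn(all_items, k, simplify = FALSE)
    for (set in combs) {
      if (!any(set <= U)) next # no lag-0 item
      supp <- bf_support(trans, set)
      if (supp < min_occ) next
      if (closed) {
        ext <- setdiff(all_items, set)
        if (any(vapply(ext, function(e) {
          bf_support(trans, c(set, e)) == supp
        }, TRUE))) next
      }
      lags <- (set - 1) %/% U
      res[[length(res) + 1]] <- list(
        items = set, z = k, c = supp, d = max(lags)
      )
    }
  }
  res
}

# canonical string key of a mined pattern for set comparison
bf_key <- function(items) paste(sort(items), collapse = "-")

pkg_pattern_keys <- function(pats, U) {
  vapply(seq_len(nrow(pats)), function(i) {
    units <- match(pats$units[[i]], sprintf("u%02d", seq_len(U)))
    bf_key(pats$lags[[i]] * U + units)
  }, "")
}

# small random parallel binary data as spike_data (one spike per occupied bin)
random_occupancy_data <- function(n_units, n_bins, bin_ms = 5, p = 0.25,
                                  seed = 1) {
  withr::with_seed(seed, {
    occ <- matrix(stats::runif(n_units * n_bins) < p, n_units, n_bins)
    idx <- which(occ, arr.ind = TRUE)
    spike_data(tibble::tibble(
      trial_id = 1L,
      unit_id = sprintf("u%02d", idx[, 1]),
      time_ms = (idx[, 2] - 0.5) * bin_ms
    ), t_stop = n_bins * bin_ms)
  })
}

expect_same_patterns <- function(pats, oracle, U) {
  got <- sort(pkg_pattern_keys(pats, U))
  want <- sort(vapply(oracle, function(o) bf_key(o$items), ""))
  expect_identical(got, want)
  if (length(oracle)) {
    ord_got <- order(pkg_pattern_keys(pats, U))
    ord_want <- order(vapply(oracle, function(o) bf_key(o$items), ""))
    expect_identical(pats$c[ord_got],
                     as.integer(vapply(oracle, `[[`, 0, "c"))[ord_want])
    expect_identical(pats$d[ord_got],
                     as.integer(vapply(oracle, `[[`, 0, "d"))[ord_want])
  }
}
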