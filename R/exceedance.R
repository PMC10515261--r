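#' Conditional exceedance function estimate
#'
#' Estimates the conditional exceedance function on a grid of levels lambda:
#' the probability that an event exceeds lambda given that the previous
#' `k - 1` events did not.  For `k = 1` this is the unconditional empirical
#' exceedance rate (the empirical survival function); larger `k` absorbs
#' serial clustering of exceedances.  For each level,
#'
#' * `numer` counts positions `j` in `k..N` with `R[j] > lambda` and all of
#'   `R[j-1], ..., R[j-k+1] <= lambda`;
#' * `denom` counts positions `j` in `k..N` with `R[j-1], ..., R[j-k+1] <=
#'   lambda` (all of `N` when `k = 1`);
#' * `estimate = numer / denom`, `NA` where `denom = 0`.
#'
#' Ties (`R[j] == lambda`) count as non-exceedance: the exceedance relation
#' is strictly greater-than throughout.  Pointwise confidence bounds use the
#' normal approximation `estimate * (1 +/- z / sqrt(numer))`, floored to
#' `[0, 1]` and `NA` where `numer = 0`.
#'
#' @param merged A `riskcast_merged` series or bare numeric vector of event
#'   values in time order.
#' @param k Conditioning number, an integer `>= 1` and `<= N`.
#' @param grid Increasing numeric vector of levels; by default `grid_size`
#'   equally spaced levels from `cut_on` (or `min(R)`) to `max(R)`.
#' @param cut_on Lower end of the default grid.
#' @param grid_size Number of default grid points.
#' @param conf Confidence level of the pointwise bounds.
#' @return A `riskcast_acer` object: a tibble with columns `lambda`, `numer`,
#'   `denom`, `estimate`, `ci_lo`, `ci_hi` and attributes `k`, `n_events`,
#'   `conf`.
#' @export
estimate_acer <- function(merged, k = 1, grid = NULL, cut_on = NULL,
                          grid_size = 100, conf = 0.95) {
  r <- merged_values(merged)
  r <- r[!is.na(r)]
  n <- length(r)
  if (n == 0) stop_riskcast("merged series is empty", "riskcast_empty_error")
  k <- as.integer(k)
  if (k < 1) stop_riskcast("k must be >= 1", "riskcast_window_error")
  if (k > n) {
    stop_riskcast(sprintf("k = %d exceeds the number of events N = %d", k, n),
                  "riskcast_window_error")
  }
  if (is.null(grid)) {
    lo <- cut_on %||% min(r)
    grid <- seq(lo, max(r), length.out = grid_size)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_riskcast("grid must be strictly increasing", "riskcast_config_error")
  }
  j <- k:n
  counts <- vapply(grid, function(lam) {
    below <- r <= lam
    cb <- c(0, cumsum(below))
    # number of the k-1 predecessors of j that sit at or below lam
    prev_ok <- (cb[j] - cb[j - k + 1]) == (k - 1)
    c(sum(prev_ok & r[j] > lam), sum(prev_ok))
  }, numeric(2))
  numer <- counts[1, ]
  denom <- counts[2, ]
  est <- ifelse(denom > 0, numer / denom, NA_real_)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z / sqrt(numer)
  ci_lo <- ifelse(numer > 0, pmax(0, est * (1 - half)), NA_real_)
  ci_hi <- ifelse(numer > 0, pmin(1, est * (1 + half)), NA_real_)
  out <- tibble::tibble(
    lambda = grid, numer = numer, denom = denom,
    estimate = est, ci_lo = ci_lo, ci_hi = ci_hi
  )
  structure(out, k = k, n_events = n, conf = conf,
            class = c("riskcast_acer", class(out)))
}

#' Convergence of the exceedance function in the conditioning number
#'
#' Computes the conditional exceedance estimate for `k = 1, ..., k_max` on a
#' common grid and reports, for each `k < k_max`, the largest relative
#' discrepancy `|p_{k+1} - p_k| / p_k` over usable grid points (both
#' denominators positive and `p_k > 0`).  The smallest `k` whose discrepancy
#' is within `tol` is the converged conditioning number; for independent
#' events every `k` agrees with `k = 1`, while serial clustering inflates the
#' unconditional rate and pushes convergence to larger `k`.
#'
#' @inheritParams estimate_acer
#' @param k_max Largest conditioning number to examine (`>= 2`).
#' @param tol Relative tolerance for declaring convergence.
#' @return A `riskcast_k_convergence` list: `converged` (smallest converged
#'   `k`, or `NA` with a non-convergence report), `profile` (tibble of `k`,
#'   `max_rel_diff`, `n_points`), and the per-`k` estimates.
#' @export
check_k_convergence <- function(merged, k_max = 5, grid = NULL, cut_on = NULL,
                                grid_size = 100, tol = 0.1) {
  if (k_max < 2) stop_riskcast("k_max must be >= 2", "riskcast_config_error")
  r <- merged_values(merged)
  r <- r[!is.na(r)]
  if (is.null(grid)) {
    lo <- cut_on %||% min(r)
    grid <- seq(lo, max(r), length.out = grid_size)
  }
  acers <- lapply(seq_len(k_max), function(k) estimate_acer(r, k = k, grid = grid))
  prof <- lapply(seq_len(k_max - 1), function(k) {
    a <- acers[[k]]
    b <- acers[[k + 1]]
    ok <- a$denom > 0 & b$denom > 0 & !is.na(a$estimate) & a$estimate > 0 &
      !is.na(b$estimate)
    d <- if (any(ok)) max(abs(b$estimate[ok] - a$estimate[ok]) / a$estimate[ok]) else NA_real_
    tibble::tibble(k = k, max_rel_diff = d, n_points = sum(ok))
  })
  prof <- dplyr::bind_rows(prof)
  conv <- prof$k[!is.na(prof$max_rel_diff) & prof$max_rel_diff <= tol]
  structure(
    list(
      converged = if (length(conv) > 0) min(conv) else NA_integer_,
      profile = prof, tol = tol, grid = grid, acers = acers
    ),
    class = "riskcast_k_convergence"
  )
}

#' @export
print.riskcast_k_convergence <- function(x, ...) {
  if (is.na(x$converged)) {
    cat(sprintf("<k convergence> no k <= %d converged at tol = %g\n",
                max(x$profile$k), x$tol))
  } else {
    cat(sprintf("<k convergence> converged at k = %d (tol = %g)\n",
                x$converged, x$tol))
  }
  print(x$profile)
  invisible(x)
}
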