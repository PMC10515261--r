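#' Second-order difference plot (SODP) summary
#'
#' A Poincare-plot derivative used for dataset quality control: the scatter
#' of consecutive first differences `(d_n, d_{n+1})` with `d_n = x_{n+1} -
#' x_n`, plus dispersion descriptors along the identity diagonal and its
#' perpendicular (the usual SD1/SD2 construction): the sample standard
#' deviations of `(d_{n+1} - d_n) / sqrt(2)` and `(d_{n+1} + d_n) / sqrt(2)`.
#' Differences are shift-invariant, so the summary depends only on the
#' series' variation, not its level.
#'
#' @param x Numeric series (length `>= 3` after removing missing values) or a
#'   `riskcast_merged` series.
#' @return A `riskcast_sodp` list: `points` (tibble `d1`, `d2`), `centroid`,
#'   `sd1` (perpendicular dispersion), `sd2` (diagonal dispersion), `n`.
#' @export
sodp_points <- function(x) {
  x <- as.numeric(merged_values(x))
  x <- x[!is.na(x)]
  if (length(x) < 3) {
    stop_riskcast("need at least 3 observed values for an SODP",
                  "riskcast_length_error")
  }
  d <- diff(x)
  pts <- tibble::tibble(d1 = d[-length(d)], d2 = d[-1])
  perp <- (pts$d2 - pts$d1) / sqrt(2)
  diag <- (pts$d2 + pts$d1) / sqrt(2)
  # single point: sample sd undefined, dispersion is 0 by convention
  sd_or_zero <- function(v) if (length(v) >= 2) stats::sd(v) else 0
  structure(
    list(
      points = pts,
      centroid = c(d1 = mean(pts$d1), d2 = mean(pts$d2)),
      sd1 = sd_or_zero(perp),
      sd2 = sd_or_zero(diag),
      n = nrow(pts)
    ),
    class = "riskcast_sodp"
  )
}

#' @export
print.riskcast_sodp <- function(x, ...) {
  cat(sprintf("<riskcast_sodp> %d points, centroid (%.4g, %.4g), SD1=%.4g SD2=%.4g\n",
              x$n, x$centroid[1], x$centroid[2], x$sd1, x$sd2))
  invisible(x)
}
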