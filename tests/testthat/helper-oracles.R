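# Independent oracles, deliberately distinct from the package's estimators.

# Conditional exceedance counts by explicit window enumeration: for each
# position j, the predecessor window is checked through its running maximum.
brute_acer_windowmax <- function(r, k, grid) {
  n <- length(r)
  j <- k:n
  prevmax <- vapply(j, function(jj) {
    if (k == 1) -Inf else max(r[(jj - k + 1):(jj - 1)])
  }, numeric(1))
  t(vapply(grid, function(lam) {
    ok <- prevmax <= lam
    c(numer = sum(ok & r[j] > lam), denom = sum(ok))
  }, numeric(2)))
}

# Same counts by fully naive nested loops (tiny inputs only).
brute_acer_loops <- function(r, k, grid) {
  n <- length(r)
  out <- matrix(0, length(grid), 2, dimnames = list(NULL, c("numer", "denom")))
  for (g in seq_along(grid)) {
    lam <- grid[g]
    for (j in k:n) {
      ok <- TRUE
      if (k > 1) {
        for (i in 1:(k - 1)) if (r[j - i] > lam) { ok <- FALSE; break }
      }
      if (ok) {
        out[g, "denom"] <- out[g, "denom"] + 1
        if (r[j] > lam) out[g, "numer"] <- out[g, "numer"] + 1
      }
    }
  }
  out
}

# Columnwise maximum of a panel, straight from the long data.
brute_pointwise_max <- function(panel) {
  d <- panel$data[!is.na(panel$data$value), ]
  yrs <- sort(unique(d$year))
  vapply(yrs, function(y) max(d$value[d$year == y]), numeric(1))
}
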