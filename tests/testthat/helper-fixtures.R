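# Small in-code fixtures shared across test files.

write_panel_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(Entity = r[[1]], Code = r[[2]], Year = r[[3]], Deaths = r[[4]],
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  path
}

tiny_panel <- function() {
  as_panel(tibble::tibble(
    region = rep(c("A", "B"), each = 3),
    year = rep(1990:1992, 2),
    value = c(0.1, 0.5, 0.3, 0.3, 0.2, 0.6)
  ), units = "percent")
}

random_panel <- function(n_regions, n_years, seed, missing_frac = 0) {
  set.seed(seed)
  df <- expand.grid(region = sprintf("G%02d", seq_len(n_regions)),
                    year = seq(2000, length.out = n_years),
                    stringsAsFactors = FALSE)
  df$value <- rexp(nrow(df))
  if (missing_frac > 0) {
    df$value[sample(nrow(df), round(missing_frac * nrow(df)))] <- NA
  }
  as_panel(tibble::as_tibble(df), units = "percent")
}

iid_exp_series <- function(n, seed) {
  cfg <- sim_config(n_regions = 1, years = seq_len(n),
                    marginal = list(family = "exponential", location = 0, scale = 1),
                    cross_corr = 0, ar1 = 0, trend = 0, seed = seed)
  merge_pointwise_max(simulate_panel(cfg))
}

ar1_exp_series <- function(n, phi, seed) {
  cfg <- sim_config(n_regions = 1, years = seq_len(n),
                    marginal = list(family = "exponential", location = 0, scale = 1),
                    cross_corr = 0, ar1 = phi, trend = 0, seed = seed)
  merge_pointwise_max(simulate_panel(cfg))
}
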