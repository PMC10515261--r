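test_that("simulation is reproducible and respects the requested structure", {
  cfg <- sim_config(n_regions = 3, years = 2000:2010, seed = 99)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$data, p2$data)
  expect_equal(length(panel_regions(p1)), 3)
  expect_equal(panel_year_range(p1), c(2000L, 2010L))
  expect_true(all(p1$data$value >= 0))
})

test_that("independent regions show near-zero sample cross-correlation", {
  cfg <- sim_config(n_regions = 2, years = seq_len(10000),
                    marginal = list(family = "gumbel", location = 0, scale = 1),
                    cross_corr = 0, ar1 = 0, seed = 5)
  p <- simulate_panel(cfg)
  wide <- tidyr::pivot_wider(p$data[c("region", "year", "value")],
                             names_from = "region", values_from = "value")
  expect_lt(abs(cor(wide$R001, wide$R002)), 0.03)
})

test_that("exponential marginal reproduces its mean at large n", {
  cfg <- sim_config(n_regions = 1, years = seq_len(10000),
                    marginal = list(family = "exponential", location = 0, scale = 1),
                    cross_corr = 0, ar1 = 0, seed = 8)
  p <- simulate_panel(cfg)
  expect_lt(abs(mean(p$data$value) - 1), 0.04)
})

test_that("average pairwise correlation increases with rho", {
  avg_cor <- function(rho) {
    cfg <- sim_config(n_regions = 4, years = seq_len(4000),
                      marginal = list(family = "gumbel", location = 0, scale = 1),
                      cross_corr = rho, ar1 = 0, seed = 21)
    wide <- tidyr::pivot_wider(simulate_panel(cfg)$data[c("region", "year", "value")],
                               names_from = "region", values_from = "value")
    cm <- cor(as.matrix(wide[-1]))
    mean(cm[upper.tri(cm)])
  }
  cors <- vapply(c(0.1, 0.5, 0.9), avg_cor, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("true_return_level matches closed-form quantiles", {
  exp_cfg <- sim_config(n_regions = 1, years = 1:10,
                        marginal = list(family = "exponential", location = 0, scale = 1),
                        cross_corr = 0, ar1 = 0, seed = 1)
  expect_equal(true_return_level(exp_cfg, 100, 1), log(100), tolerance = 1e-12)

  gum_cfg <- sim_config(n_regions = 1, years = 1:10,
                        marginal = list(family = "gumbel", location = 0, scale = 1),
                        cross_corr = 0, ar1 = 0, seed = 1)
  expect_equal(true_return_level(gum_cfg, 100, 1), -log(-log(0.99)),
               tolerance = 1e-12)

  # T = 1, one event per year: exceedance probability 1, the lower bound
  expect_equal(true_return_level(exp_cfg, 1, 1), 0)

  dep_cfg <- sim_config(n_regions = 1, years = 1:10, ar1 = 0.5, seed = 1)
  expect_error(true_return_level(dep_cfg, 100), class = "riskcast_oracle_error")
})

test_that("exceedances of the true return level occur at the nominal rate", {
  n <- 50000
  merged <- iid_exp_series(n, seed = 14)
  cfg <- sim_config(n_regions = 1, years = seq_len(n),
                    marginal = list(family = "exponential", location = 0, scale = 1),
                    cross_corr = 0, ar1 = 0, trend = 0, seed = 14)
  for (T in c(50, 200)) {
    lvl <- true_return_level(cfg, T, 1)
    p_hat <- mean(merged_values(merged) > lvl)
    p_true <- 1 / T
    expect_lt(abs(p_hat - p_true), 4 * sqrt(p_true * (1 - p_true) / n))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(marginal = list(family = "gumbel", scale = -1)),
               class = "riskcast_config_error")
  expect_error(sim_config(cross_corr = 1), class = "riskcast_config_error")
  expect_error(sim_config(ar1 = 1.2), class = "riskcast_config_error")
})
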