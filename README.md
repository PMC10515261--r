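# riskcast

Reliability-based return-level forecasting for multi-region health panels.

## What problem this solves

Public-health surveillance produces one annual series per region — for
example national cause-specific death rates for ~200 countries over three
decades.  Planners want tail forecasts from such panels: *what annual death
rate, as a percent of local population, is associated with a 100-year return
period anywhere in the system, and how uncertain is that level?*  Classical
extreme-value tools answer this one series at a time; the joint distribution
of hundreds of correlated regional maxima is not estimable from 30 annual
observations.

riskcast implements a multi-degree-of-freedom reliability approach for this
setting.  Regional series \(X(t), Y(t), Z(t), \dots\) are scaled by their
hazard limits \(\eta_r\) (so all components share critical level 1), their
local maxima are merged into one temporally non-decreasing synthetic vector
\(\vec R = (R_1, \dots, R_N)\), and the conditional exceedance function

\[
\hat p_k(\lambda) = \Pr\{R_j > \lambda \mid R_{j-1} \le \lambda, \dots,
R_{j-k+1} \le \lambda\}
\]

is estimated on a level grid with pointwise confidence intervals.  The
conditioning number \(k\) absorbs serial clustering and is chosen at the
smallest value where \(\hat p_k\) stabilises.  Above a cut-on \(\lambda_0\)
the tail is summarised by the sub-asymptotic form

\[
p(\lambda) \approx q \exp\{-a(\lambda - b)^c\},\qquad
a > 0,\; b < \lambda_0,\; c > 0,\; q \le 1,
\]

fitted by weighted least squares on the log scale and inverted at the target
probability \(1/(T \times \text{events/yr})\) to give the \(T\)-year return
level; confidence bands come from re-fitting the same form to the empirical
interval curves.  A classical Gumbel block-maxima fit provides the 1-DOF
comparator, and a second-order difference plot (SODP, a Poincaré-plot
derivative) provides dataset quality control.  A Gaussian-copula simulator
with closed-form return-level oracles makes every stage testable.

## Worked example

A synthetic world-scale panel (195 regions, 1990–2020, rates in percent of
local population, strong cross-region correlation and temporal persistence):

```r
library(riskcast)
cfg    <- sim_config(seed = 1)           # 195 regions, 1990-2020
panel  <- simulate_panel(cfg)
merged <- merge_pointwise_max(panel)     # synthetic maxima vector, N = 31
acer   <- estimate_acer(merged, k = 3, cut_on = 0.026)
fit    <- fit_tail(acer, cut_on = 0.026)
forecast_return_level(fit, return_period = 100, events_per_year = 1)
#> <riskcast_forecast> level 0.037687 [NA, 0.054629] at exceedance prob 0.01

gum <- fit_gumbel(annual_block_maxima(merged), "mle")
gumbel_return_level(gum, 100)
#> <riskcast_gumbel_forecast> T=100 level 0.037048 [0.033977, 0.040119] (95% CI)

sodp_points(merged)
#> <riskcast_sodp> 29 points, centroid (2.655e-05, 0.0002672), SD1=0.003253 SD2=0.003374
```

Reading the output: the advocated method extrapolates the merged exceedance
tail to a 100-year annual death rate of about 0.038% of local population,
with an upper 95% bound of 0.055% (the lower band is unavailable at this
sample size — with 31 annual events the lower confidence curve degenerates
to zero; see the vignette).  The Gumbel baseline lands close by at 0.037%.
The SODP summary describes the year-to-year variability structure of the
merged series.

The same run as one reproducible pipeline, with all artefacts written to
disk:

```r
res <- run_pipeline(run_config(sim = sim_config(seed = 1), k = 3,
                               return_period = 100, seed = 1,
                               out_dir = "out"))
```

writes `merged.csv`, `acer.csv`, `forecast.json`, `gumbel.json`, `sodp.csv`
and a human-readable `report.txt` recording the merge strategy, `k`, cut-on
and events-per-year actually used.  Real panels enter through
`load_panel()` (long country–year CSV, `Entity`/`Code`/`Year` columns),
`normalize_to_percent()` and `exclude_regions()`.

A thin command-line wrapper is installed under `exec/`:

```sh
riskcast simulate --regions 195 --years 31 --seed 1 --out panel.csv
riskcast merge    --in panel.csv --out merged.csv
riskcast acer     --in merged.csv --k 3 --out acer.csv
riskcast predict  --in acer.csv --return-period 100 --out forecast.json
riskcast run      --config run.yaml
```

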