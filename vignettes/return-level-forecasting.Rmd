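---
title: "Reliability-based return-level forecasting for multi-region health panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability-based return-level forecasting for multi-region health panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskcast)
```

## The problem and the model

National cause-specific death rates form a high-dimensional dynamic system:
one annual series per region, strongly cross-correlated, observed for only a
few decades.  The question riskcast answers is a reliability question: what
outcome magnitude (here, an annual death rate as percent of local
population) is associated with a long return period — say 100 years — for
the system as a whole, and how uncertain is that level?

Estimating the joint distribution of all regional maxima directly is
hopeless at this dimensionality.  riskcast instead follows the
multi-degree-of-freedom reliability route:

1. **Scaling.**  Each regional series is divided by its hazard limit
   $\eta_r$, so every component is non-dimensional with a common critical
   level of 1.  For percent-of-population panels the natural limit is the
   whole population, $\eta_r = 100$; analyses can equally be run on the raw
   percent scale, and the package operates on whichever units the merged
   series carries.
2. **Merging.**  The per-region maxima are assembled into a single
   temporally non-decreasing synthetic vector $R_1, \dots, R_N$.  Two merge
   strategies are provided.  The *interleave* strategy orders all regional
   events by time, collapsing simultaneous events from different regions
   into one event carrying the componentwise maximum and all source labels.
   The *pointwise-max* strategy takes, for each year, the maximum across all
   regions observed that year.  For a synchronous annual panel the
   interleave strategy degenerates to the pointwise maximum, which is why
   pointwise is the default for annual panels; interleaving matters for
   asynchronous or denser series.
3. **Conditional exceedance.**  On the merged vector the conditional
   exceedance function $\hat p_k(\lambda)$ is estimated: the fraction of
   positions whose previous $k-1$ events sit at or below $\lambda$ in which
   the current event exceeds $\lambda$.  $k = 1$ is the empirical survival
   function; larger $k$ absorbs serial clustering so that the per-event
   hazard is not overstated for persistent series.  The working $k$ is the
   smallest one at which $\hat p_k$ stabilises, checked with
   `check_k_convergence()`; $k = 3$ is the pipeline default for annual
   mortality panels.
4. **Tail fit and extrapolation.**  Above a cut-on level $\lambda_0$ the
   empirical tail is summarised by the four-parameter sub-asymptotic form
   $p(\lambda) = q\,\exp\{-a(\lambda-b)^c\}$, fitted by weighted least
   squares on the log scale and inverted at the target exceedance
   probability $1/(T \times \text{events per year})$ to give the $T$-year
   return level.  At $c = 1$ the form has a pure exponential (Gumbel-like)
   tail; free $c$ captures the sub-asymptotic curvature that a limiting
   extreme-value fit imposed at finite levels would miss.
5. **Baseline and QC.**  A classical Gumbel block-maxima fit
   (`fit_gumbel()`, `gumbel_return_level()`) answers the same question as a
   1-DOF comparator, and the second-order difference plot (`sodp_points()`)
   summarises the dataset's consecutive-difference structure for quality
   control.

## Parameters that matter

* **Hazard limits** (`scale_components()`): same units as the panel values;
  after scaling the common limit is 1.  Default in the pipeline is no
  scaling (work on the percent scale); pass `limits = 100` for
  percent-of-population data to move to the non-dimensional scale.
* **Conditioning number `k`** (default 3): window length of the
  conditioning.  Choose by `check_k_convergence()`; for independent annual
  events any `k` agrees with `k = 1`.
* **Cut-on `cut_on`**: level where tail fitting starts, in the merged
  series' units.  The pipeline default is the 0.75 quantile of the merged
  values — low enough to keep dozens of grid points, high enough that the
  parametric tail form is plausible.  It is a modelling choice, not an
  estimate; sensitivity to it should be checked on real data.
* **Grid** (default 100 levels from the cut-on to the sample maximum):
  resolution of the exceedance table.
* **Return period and events per year**: the target probability is
  $1/(T \times \text{events per year})$.  A pointwise-max annual merge has
  1 event per year; an interleaved merge has $N/\text{span}$.  Both
  translations are exposed because the appropriate one depends on whether
  "100-year" is meant per system-year or per event.
* **Ties**: an event exactly at a grid level counts as a non-exceedance
  (strict `>`), one convention applied everywhere.

## Confidence bands

Pointwise bounds on $\hat p_k$ use the normal approximation
$\hat p\,(1 \pm z/\sqrt{\text{numer}})$, floored to $[0,1]$ and undefined
where the numerator is zero.  The extrapolated interval is obtained by
re-fitting the same parametric form to the lower and upper empirical bound
curves and inverting each at the target probability — this keeps the bands
monotone and mirrors how the central fit treats the data, rather than
relying on a delta-method linearisation.

Two small-sample consequences are worth knowing.  First, the lower bound is
positive only where the numerator is at least 4 (else $1 - z/\sqrt{n} < 0$),
so for very short merged series — e.g. 31 annual events at `k = 3` — the
lower band degenerates to zero everywhere and the forecast's lower bound is
reported as `NA`.  Second, the fit weights
$w_j = (\log \text{ci}_{hi} - \log \text{ci}_{lo})^{-2}$ are undefined at
such points; they receive zero weight, and if fewer than four weighted
points remain the fit falls back to unit weights.

## Numerical choices

* For fixed $(b, c)$ the log-model is linear in $(\log q, a)$ and solved by
  closed-form weighted least squares, with $\log q$ capped at 0 (so
  $q \le 1$) and fits with $a \le 0$ rejected.  The outer search over
  $(b, c)$ runs Nelder-Mead from a deterministic ladder of starts
  ($c_0 \in \{0.5, 1, 2\}$, several $b_0$ below the cut-on including one
  just below zero on the rate scale), with $b < \lambda_0$ enforced through
  a log transform and $c$ kept in $[0.1, 10]$ through a logistic transform.
  The whole procedure is deterministic given the data.
* Exceedance counting is vectorised through cumulative sums of the
  below-threshold indicator, $O(N)$ per grid level; it is verified
  exactly against two independent brute-force enumerators in the tests.
* Empirically, $\hat p_1(\lambda)$ is non-increasing in $\lambda$ by
  construction; for $k \ge 2$ monotonicity is typical but not guaranteed in
  finite samples (the denominator grows with $\lambda$ too), so it is not
  asserted as an invariant.
* Gumbel MLE uses Nelder-Mead from the moment initialiser and reports the
  covariance from the inverse observed information; moment-fit intervals
  use a seeded parametric bootstrap.

## What the simulator emulates — and what it does not

`simulate_panel()` draws a latent Gaussian field with exchangeable
cross-region correlation $\rho$, AR(1) temporal persistence $\varphi$ and an
optional linear drift on the Gaussian scale, then maps each margin through
the Gaussian copula to the requested marginal family (Gumbel, lognormal or
exponential).  The defaults — 195 regions, years 1990–2020, a Gumbel
marginal with location 0.012% and scale 0.003% of population, $\rho = 0.6$,
$\varphi = 0.7$, no drift — emulate a world-scale annual mortality panel:
rates of a few hundredths of a percent, strong cross-country correlation,
substantial year-to-year persistence.  Drift is off by default so that the
marginal family stays interpretable; a trend can be switched on explicitly.

Because the copula construction gives *exact* marginals, the i.i.d. case
($\varphi = 0$, trend 0) has closed-form return levels
(`true_return_level()`), which is what makes end-to-end accuracy and
coverage testable.  What the simulator does **not** reproduce: age
structure, cohort effects, reporting artefacts, non-exchangeable
(e.g. spatially graded) dependence, or nonstationarity in the tail itself.
Passing tests therefore demonstrate correctness of the estimators under a
controlled dependence structure, not epidemiological realism.

## Problem sizes used in the test-suite studies

The package's simulation studies use: $10^5$ events for tail-recovery and
$k$-invariance checks, 200 replicates of 20,000 events for band coverage
(against the 100-year level of a 195-events-per-year system, a genuine
extrapolation beyond the sample range), 100 random sequences up to
$N = 1000$ for exact oracle agreement, and a 195-region, 31-year panel for
the end-to-end pipeline.  These sizes give Monte-Carlo error comfortably
below the asserted tolerances.

## Known limitations

* The conditional-exceedance estimator treats the merged series as a
  per-event process; converting to calendar time is entirely through the
  `events_per_year` factor.
* The sub-asymptotic tail form is an assumption; it nests exponential-type
  tails well but heavy power-law tails only through large $c$ excursions,
  and the fit should be inspected (`plot_acer()`) before trusting a deep
  extrapolation.
* The normal-approximation bands are poor at numerators below ~4 (see
  above); for 31-point annual panels the advocated method's lower band is
  unavailable, while its central estimate and upper band remain usable.
* On very short merged series (a few dozen events) the four tail parameters
  are barely identifiable: the empirical exceedance curve has only a handful
  of distinct steps, the CI-based weights can all degenerate (the fit then
  falls back to unit weights, recorded in the fit's `weighting` field), and
  the shape exponent $c$ may run to a bound, in which case the extrapolated
  level is unreliable.  Inspect the fit, and prefer replicated or pooled
  analyses at such sample sizes.
* Outlier regions are removed by an explicit blocklist
  (`exclude_regions()`), not detected automatically: surveillance-data
  outliers are usually known a priori, and an automatic rule would be a
  modelling decision of its own.
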