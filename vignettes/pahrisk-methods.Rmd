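---
title: "Methods: probabilistic PAH inhalation risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic PAH inhalation risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahrisk)
```

## The risk model

`pahrisk` assesses the incremental lifetime cancer risk (ILCR) of
atmospheric PAH inhalation. The deterministic core is

$$\mathrm{ILCR} = \frac{\mathrm{BaP_{eq}} \cdot 10^{-6} \cdot IR \cdot EF
\cdot ED \cdot CSF}{BW \cdot AT}, \qquad
\mathrm{BaP_{eq}} = \sum_i C_i \cdot TEF_i ,$$

with $C_i$ the congener concentrations (ng·m⁻³) in the gaseous and
particulate phases (summed by default; per-phase risks are available by
passing single-phase profiles), $IR$ in m³·day⁻¹ and $BW$ in kg. The
10⁻⁶ factor is carried explicitly in `exposure_constants()` so the
ng-to-mg conversion in the dose is auditable rather than hidden in the
slope factor. Defaults are an adult-resident scenario: $EF = 365$
day·yr⁻¹, $ED = 53$ yr, $AT = 70 \times 365$ day, $CSF = 3.14$
(mg·kg⁻¹·day⁻¹)⁻¹. Risk classes follow the usual regulatory bands:
below 10⁻⁶ acceptable, 10⁻⁴ and above serious; both boundaries are
assigned upward (10⁻⁶ counts as exceeding, 10⁻⁴ as serious).

The default TEF table is a Nisbet–LaGoy-style scheme over the fifteen
priority congeners, with dibenz(a,h)anthracene capped at 1 (the widely
used conservative variant of that scheme). TEFs are study-specific in
practice, so every function accepting a TEF table takes a replacement, and
`read_tef_csv()` loads one from a two-column file.

## Distribution fitting

All stochastic inputs are lognormal; parameters $(a, b)$ are the mean and
SD of the **natural-log**-transformed variable. The natural-log convention
is forced by internal consistency: $\exp(4.169) \approx 64.6$ kg is a
plausible adult body weight, whereas a base-10 reading is not. Two fitting
routes are provided:

* **From samples** (`fit_lognormal_samples()`): samples are ranked,
  assigned plotting positions $p_i = r_i/(n+1)$ (averaged ranks on ties —
  the convention is not dictated by the formula, so we chose the one that
  keeps tied observations exchangeable), and the Gaussian CDF
  $\Phi((\log x - a)/b)$ is least-squares fitted to the
  (log value, position) pairs by Nelder–Mead started at the log-moment
  estimates (relative tolerance 10⁻¹², 2000 iterations). The reported
  $R^2$ is computed on the CDF values. A log-moment MLE route is available
  behind `method = "mle"`; the CDF route is the default because it is the
  procedure used for site monitoring data. Degenerate inputs (all values
  numerically equal) and non-positive values are rejected.
* **From handbook quantiles** (`fit_lognormal_quantiles()`): ordinary
  least squares of $\log q_p$ on $\Phi^{-1}(p)$. For pairs lying exactly
  on a lognormal this inverts the quantile function exactly, which the
  tests exploit as a round-trip oracle.

`normality_gate()` applies the Shapiro–Wilk test (via
`stats::shapiro.test`) to the log data and flags acceptance at
$p > 0.05$.

The IR–BW dependence is fitted by OLS of $\log IR$ on $\log BW$
(`fit_ir_bw_regression()`). The exponent is invariant to the log base and
is the only part of the published relationship we treat as anchored; the
intercept of the packaged reference power law is instead **calibrated** so
that the whole-population median body weight maps onto the whole-population
median inhalation rate ($c = 2.788 - 0.679 \times 4.169 \approx -0.043$ in
natural logs, IR in m³·day⁻¹), because the published intercept is not
reproducible under any log-base/unit combination of the published
parameter tables.

Where a measured inhalation rate is missing, `estimate_ir_from_bmr()`
estimates it from the basal metabolic rate: Schofield-type sex- and
age-banded linear equations in body weight give BMR (MJ·day⁻¹), scaled by
a physical activity level (PAL) and converted to ventilation through the
oxygen-uptake coefficient $h$ (L O₂ per kJ) and ventilatory equivalent
$VQ$ (L air per L O₂): $IR = BMR \cdot PAL \cdot h \cdot VQ$. The defaults
(PAL 2.0, $h$ 0.05, $VQ$ 30) are round mid-range literature values chosen
once to describe an occupationally active adult population; for a 67.7 kg,
171 cm male of 30 they give about 14 L·min⁻¹, consistent with measured
adult male means in this population class. They are configuration entries,
not constants of the method.

## The Monte Carlo engine

`run_mcs()` implements four variants sharing one code path into
`compute_ilcr()`:

* *traditional* and *concentration-adjusted* draw C, BW, IR independently;
  the two differ only in which concentration lognormal the caller supplies
  (site-fitted vs individual-exposure-fitted);
* *age-stratified* splits the iteration budget over age strata by
  largest-remainder rounding (`allocate_iterations()`, so counts always
  sum exactly to the total; remaining iterations go to the largest
  fractional remainders), then pools the per-stratum draws;
* *correlated* draws only C and BW and computes IR deterministically from
  the power law. A lognormal residual can be switched on
  (`residual_sd > 0`) for sensitivity exploration but is off by default,
  matching the deterministic-substitution design.

Reproducibility: each run seeds R's RNG once from the config seed;
age-stratified runs derive one substream seed per stratum from the master
seed, so changing one stratum's allocation cannot reshuffle another's
draws. Identical configs give bit-identical results. Zero-variance
parameter sets (`sdlog = 0`) are deliberately legal: they collapse a run
to its deterministic point estimate, which anchors both the convergence
check and the engine's unit tests.

`convergence_check()` reruns the configured variant over an ascending
iteration grid (default 5,000–50,000 in steps of 5,000) with a common
seed and declares convergence when every successive relative change of the
mean stays below the tolerance (default 2%).

`sensitivity_spearman()` reports the Spearman rank correlation (averaged
ranks) of each input with the ILCR, ranked by absolute value; a constant
input has no defined rank correlation and is reported `NA`. Under
independent lognormal inputs the log-scale correlation between an input
and the risk is $\pm\sigma_i / \sqrt{\sum_j \sigma_j^2}$ and the implied
Spearman value is $(6/\pi)\arcsin(\rho/2)$; the test suite uses this
closed form as an independent referee. One caveat is intrinsic to the
correlated variant: with the deterministic substitution, IR is an
increasing function of BW while the risk decreases in BW, so IR's rank
correlation necessarily equals BW's (negative). The familiar
"BW negative, IR positive" sensitivity pattern therefore applies to the
three variants that draw IR as an input, and the tests check it there.

## Individual assessment and model grading

`assess_individuals()` assigns each participant the annual BaP$_{eq}$ of
the Euclidean-nearest monitoring site (ties broken deterministically by
the smallest site id), converts the measured or BMR-estimated inhalation
rate to m³·day⁻¹ (1 L·min⁻¹ = 1.44 m³·day⁻¹), and evaluates the ILCR.
Longitude/latitude inputs are projected by a local equirectangular
approximation — at city scale only relative distances matter. IDW
interpolation (`idw_surface()`) uses weights $d^{-p}$ and returns a site's
own value exactly at its location.

`goodness_of_fit()` grades a simulated risk distribution against the
individually assessed one by the simulated/actual ratios of mean, median
and SD, plus the difference of range spans in $\log_{10}$ units
(matching the "orders of magnitude" idiom of the field).
`gof_panel()` ranks several models by $|\text{mean ratio} - 1|$.
Multimodality of the empirical distribution is described, not tested:
`risk_density()` reports kernel-density modes on the $\log_{10}$ scale
(Sheather–Jones bandwidth) with no formal mode count, since no defensible
peak-membership rule exists for these data.

## What the synthetic scenario emulates

`scenario_spec()` + `gen_sites()` / `gen_participants()` generate the
study conditions the pipeline assumes:

* 25 sites in 3 spatial clusters. Cluster log-concentration offsets are
  equally spaced and scaled so that, combined with the within-cluster
  log-SD (default 0.5), the pooled site marginal reproduces
  LN(2.21, 1.01). Three clusters mirror the three-peak shape of observed
  individual-risk distributions in spatially heterogeneous cities; the
  count is configurable.
* 2,740 participants allocated to the low/mid/high clusters with weights
  741/1594/405 of 2,740 — the peak populations observed empirically —
  and placed close to a random site of their cluster, so nearest-site
  assignment induces clustered, multimodal exposure. Because sites are
  weighted equally in the site-level fit but participants are not spread
  equally over clusters, the site-fitted and individual-exposure
  concentration distributions differ — exactly the mechanism the
  concentration-adjusted variant corrects.
* Ages drawn by the census-proportional stratum weights 19379/8172/2449
  of 30,000; per-stratum body-weight lognormals; sex as a location shift
  of $\log(67.7/56.9)$ in log-BW with the within-sex SD shrunk so the
  pooled stratum SD is preserved; the high-exposure cluster is labelled
  rural and the low urban, giving the urban/rural contrast signal.
* IR either from per-stratum lognormals or (default) from the power law
  with exponent 0.679 and Gaussian log-residual SD 0.1 — a value chosen
  once to keep the BW–IR correlation strong while leaving realistic
  scatter, since no residual spread is published.

What it does **not** emulate: congener-level seasonal chemistry (sites
carry annual BaP$_{eq}$ directly; congener profiles are supported as a
pass-through for the TEF arithmetic), participant-frequency detail per
site, measurement error in BW/height, and any non-lognormal tail
behaviour of real exposure. Passing tests on this scenario therefore
demonstrate that the pipeline's statistical machinery behaves as designed
under its own assumptions, not that those assumptions hold in any
particular city.

## Problem sizes and numerical choices

The packaged analyses use 30,000 iterations per variant (stratified runs
allocate 19,379/8,172/2,449), 25-site networks, and 2,740-participant
populations; replicated checks use 200 site replicates and 20 regression
populations. Convergence tolerance is 2% relative; summary percentiles
default to 5/25/50/75/95. Weighted-average weights must sum to 1 within
10⁻⁹; annual averaging defaults to equal weights over the sampling
periods. All validation errors are raised early, at object construction,
so simulation code never sees inconsistent inputs.

## Known limitations

* Inhalation route only; no dermal or ingestion pathways, and no
  two-dimensional (uncertainty × variability) simulation.
* The lognormal family is fixed by design; no alternative distributions
  are fitted.
* The BMR coefficients and activity/ventilation factors are a documented
  surrogate for population-specific measurement protocols.
* The default TEF table is a stand-in for study-specific toxicology and
  should be replaced when a study provides its own.
* Mean ratios compare distributions generated under the package's own
  synthetic assumptions; they quantify the relative behaviour of the four
  simulation strategies, not absolute risks for any real population.
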