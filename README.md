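# pahrisk

Probabilistic carcinogenic risk assessment for inhalation exposure to
polycyclic aromatic hydrocarbons (PAHs).

Population-level risk assessments usually run Monte Carlo simulation (MCS)
over assumed input distributions, but the results are hard to validate and
are sensitive to how the exposure concentration is fitted, how the
population is stratified, and whether correlated inputs are sampled
independently. `pahrisk` implements the full workflow needed to study these
questions: deterministic individual risk assessment from monitored
concentrations, distribution fitting, four MCS variants, sensitivity
analysis, and quantitative model-vs-actual comparison — together with a
synthetic scenario generator so that every stage runs end to end without
external data. It is aimed at exposure scientists and risk assessors who
want to compare simulation strategies against individually assessed risks.

## The model

The incremental lifetime cancer risk (ILCR) of inhalation exposure is

```
ILCR = BaP_eq × 10⁻⁶ × IR × EF × ED × CSF / (BW × AT)
BaP_eq = Σᵢ Cᵢ × TEFᵢ
```

where `BaP_eq` is the benzo(a)pyrene-equivalent concentration (ng·m⁻³)
obtained by weighting each of the 15 priority PAH congener concentrations
`Cᵢ` by its toxic equivalency factor `TEFᵢ`, `IR` is the inhalation rate
(m³·day⁻¹), `BW` body weight (kg), `EF` exposure frequency (365 day·yr⁻¹),
`ED` exposure duration (53 yr), `AT` averaging time (70 × 365 day), `CSF`
the BaP inhalation cancer slope factor (3.14 per mg·kg⁻¹·day⁻¹), and 10⁻⁶
converts ng to mg. Risks below 10⁻⁶ are conventionally acceptable; 10⁻⁴ or
above is serious.

All stochastic inputs are modelled as lognormals `LN(a, b)` on the natural
log scale. Parameters are estimated either from raw samples — plotting
positions `rank/(n+1)` followed by a least-squares Gaussian CDF fit — or
from handbook quantile tables via the normal-quantile regression
`log q_p = a + b·Φ⁻¹(p)`. Four simulation variants propagate the inputs:

* **traditional** — C, BW, IR drawn independently from whole-population
  lognormals (C fitted from equally weighted monitoring sites);
* **concentration-adjusted** — identical, but C is refit from the
  population-weighted individual exposures (nearest-site assignment);
* **age-stratified** — iterations are split across age strata (18–44,
  45–59, 60–70) by census-proportional weights, each stratum sampling its
  own BW/IR lognormals;
* **correlated-parameter** — IR is replaced by the fitted power law
  `log IR = 0.679·log BW + c`, so only C and BW are sampled.

Sensitivity is quantified by Spearman rank correlation between each input
and the ILCR; simulation quality by the mean/median/SD ratios and the
range-span difference between the simulated and the individually assessed
("actual") risk distributions.

## Worked example

```r
library(pahrisk)

# TEF-weighted BaP equivalent: 2·1 + 1·1 + 10·0.01
p <- pah_profile("S01", "particulate", "annual",
                 c(BaP = 2.0, DahA = 1.0, Chr = 10.0))
compute_bap_eq(p)
#> [1] 3.1

# ILCR of one adult: 10 ng/m3, 16 m3/day, 64 kg
compute_ilcr(10, 16, 64)
#> [1] 5.943571e-06
classify_risk(compute_ilcr(10, 16, 64))
#> [1] exceeds_acceptable

# full pipeline on the packaged reference scenario
res <- run_pipeline(scenario_spec(seed = 1), iterations = 30000)
res
#> <pipeline_result> 25 sites, 2740 participants, seed 1
#>   actual ILCR: mean 7.976e-06, median 5.167e-06, range [6.847e-07, 3.699e-05]
#> <gof_panel> simulated vs actual (ratios simulated / actual)
#>                    model mean_ratio median_ratio sd_ratio span_difference rank
#> 1            traditional      1.756        1.097    4.583           3.126    3
#> 2 concentration_adjusted      1.167        1.031    1.854           1.887    1
#> 3         age_stratified      1.787        1.115    4.246           2.830    4
#> 4             correlated      1.661        1.088    3.797           2.744    2

res$sensitivity$traditional
#> <sensitivity_result> Spearman rank correlation with ILCR
#>   input     rho rank
#> 1  conc  0.9735    1
#> 2    bw -0.1561    2
#> 3    ir  0.1488    3
```

The panel reads: the traditional simulation overestimates the actual mean
risk by 76% and its spread by a factor of 4.6; refitting the concentration
from individual exposures (`concentration_adjusted`) brings the mean ratio
closest to 1; substituting the IR–BW power law (`correlated`) also improves
on the traditional model; age stratification alone changes essentially
nothing. Concentration dominates the sensitivity ranking, body weight acts
negatively and inhalation rate positively — the pattern that motivates the
concentration-focused adjustments.

A thin CLI over the same functions lives in `inst/cli/pahrisk`
(subcommands `synth`, `assess`, `simulate`, `compare`, `pipeline`).

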