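# indexbias

Correction of index event (collider) bias in genome-wide association
studies of disease prognosis, severity and survival.

## The problem

GWAS of prognosis are run among disease cases. Selecting on disease
status makes the disease a collider: independent causes of incidence
become correlated among cases, so a variant that raises incidence picks
up a spurious association with prognosis through every unmeasured
common cause of the two traits. With a sufficiently strong
susceptibility effect the bias can reverse the apparent direction of a
survival association.

The package implements the regression-based adjustment for this bias.
Writing $\hat\beta_{GX}$ for a variant's estimated effect on incidence
and $\hat\beta'_{GY}$ for its estimated effect on prognosis conditional
on incidence, the collider bias is linear in the incidence effect with
a genome-wide constant slope $b$:

$$\beta'_{GY} = \beta_{GY} + b\,\beta_{GX}.$$

The slope is estimated by regressing $\hat\beta'_{GY}$ on
$\hat\beta_{GX}$ across an LD-pruned set of variants, corrected for
regression dilution (Hedges–Olkin moment correction, or simulation
extrapolation — SIMEX — with a bootstrap confidence interval), and the
corrected effects $\hat\beta_{GY} = \hat\beta'_{GY} - \hat
b\,\hat\beta_{GX}$ are reported for every variant with propagated
standard errors

$$\mathrm{se}^2 = \sigma_{GY}^2 + \hat b^2\sigma_{GX}^2
  + \hat\beta_{GX}^2\,\mathrm{var}(\hat b)
  + \sigma_{GX}^2\,\mathrm{var}(\hat b)$$

and normal-approximation p-values, with an empirical bootstrap
alternative for variants with extreme incidence effects. A simulation
engine (individual-level and a fast summary-level variant) reproduces
the adjustment's operating characteristics — type-1 error, power,
family-wise error, bias — under quantitative, liability-threshold
case/control, and survival designs.

Who this is for: analysts running or re-analysing GWAS of subsequent
events from summary statistics, and methodologists studying collider
adjustments.

## Worked example

Simulate a confounded study at reduced scale, estimate the slope, and
adjust (the fifth variant is a pure incidence variant, so its adjusted
prognosis effect should be near zero):

```r
library(indexbias)

scenario <- simulation_scenario(
  m_total = 20000, m_inc_only = 1000, m_prog_only = 1000, m_both = 1000,
  n_individuals = 20000)          # confounder explains 40% of each trait
rep1 <- simulate_summary_level(scenario, n_reps = 1, seed = 7)[[1]]
pairs <- rep1$pairs               # harmonised summary statistics

slope <- estimate_slope(pairs, method = "hedges_olkin")
print(slope)
#> Confounding slope fit (hedges_olkin)
#>   raw slope b*        : -0.119238 (robust se 0.01521)
#>   corrected slope b   : -0.379432
#>   var(b)              : 0.002247
#>   95% CI              : (-0.472340, -0.286523)
#>   intercept           : -8.378e-05
#>   variants in fit     : 20000

adjusted <- adjust_effects(pairs, slope)
head(adjusted[, c("variant_id", "beta_gy_prime", "beta_gy_adj", "p")], 3)
#>   variant_id beta_gy_prime  beta_gy_adj         p
#> 1       snp1   0.020144573  0.007586413 0.4507231
#> 2       snp2   0.009452880 -0.005613950 0.6542676
#> 3       snp3   0.006303949  0.008425772 0.6746086

genomic_inflation(adjusted$p)
#> [1] 1.144498
#> attr(,"n")
#> [1] 20000
```

The analytic slope for this design is
`analytic_b(scenario_params(scenario))` = −0.4: the raw regression
slope (−0.119) is attenuated to about a third by sampling noise in the
incidence estimates, and the dilution correction restores it (its 95%
interval covers −0.4). The genomic inflation factor of the adjusted
scan sits well above 1 here only because 15% of the simulated variants
carry real prognosis effects at this reduced scale; on null variants
the adjusted statistics are calibrated, which is what the simulation
metrics below measure. At the full 100,000-variant design the
corrected slope concentrates tightly around −0.4.

From the shell, the same pipeline runs on summary-statistics files:

```sh
exec/indexbias adjust --incidence incidence.tsv --prognosis prognosis.tsv \
  --prune-list pruned_ids.txt --method simex --seed 1 --out adjusted.tsv
exec/indexbias simulate --scenario scenario.yaml --reps 100 --seed 1 \
  --out metrics.tsv
```

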