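---
title: "Correcting index event bias in GWAS of prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting index event bias in GWAS of prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A genome-wide association study of prognosis, severity or survival is
conducted among people who already have the disease. Selecting on
disease status turns the disease into a collider: independent causes of
disease become negatively correlated among cases, so any variant that
raises incidence becomes spuriously associated with every other cause of
incidence — including those that also drive prognosis. The result is a
biased estimate of each variant's direct effect on prognosis, and in
unfavourable settings a sign reversal: a strong susceptibility allele
can masquerade as protective for survival.

## Model

For one variant with coded genotype $G$, write incidence and prognosis
as linear in $G$, a composite confounder $U$ (all common causes of the
two traits, polygenic background included), and trait-specific
residuals:

$$X = \beta_{GX} G + \beta_{UX} U + E_X, \qquad
  Y = \beta_{GY} G + \beta_{UY} U + \beta_{XY} X + E_Y.$$

The estimand reported by a prognosis GWAS is the effect of $G$ on $Y$
conditional on $X$ but not on $U$, written $\beta'_{GY}$. Working
through the two-predictor least-squares projection,

$$\beta'_{GY} = \beta_{GY} + b\,\beta_{GX}, \qquad
  b = -\frac{\mathrm{var}(U)\,\beta_{UX}\beta_{UY}}
           {\mathrm{var}(U)\,\beta_{UX}^2 + \mathrm{var}(E_X)},$$

implemented in `analytic_b()`. The slope $b$ is negative when the
confounder pushes both traits the same way. Crucially, $b$ does not
depend on the variant: under a polygenic architecture, where no single
variant contributes materially to the shared basis of the two traits,
the same $b$ applies to every variant. It can therefore be estimated by
regressing estimated prognosis effects on estimated incidence effects
across the genome, and the residuals of that regression (plus its
intercept) are the corrected effects:

$$\hat\beta_{GY} = \hat\beta'_{GY} - \hat b\,\hat\beta_{GX}.$$

One point deserves emphasis because it is easy to get wrong when
mapping a whole-genome simulation onto the single-variant algebra: from
the viewpoint of one variant, the polygenic background of *other*
variants belongs to $U$ (shared part) and $E_X$ (incidence-specific
part). With unit-variance traits this makes the denominator of $b$
essentially $\mathrm{var}(X) \approx 1$, so the slope equals minus the
confounder-plus-genetic covariance of the traits, not the larger value
obtained by plugging in only the single-variant residual.
`scenario_params()` encodes this mapping: for the default scenario
(confounder share 0.4 in each trait) it gives $b = -0.4$.

## The procedure

1. Obtain harmonised per-variant estimates
   $(\hat\beta_{GX}, \sigma_{GX})$ and
   $(\hat\beta'_{GY}, \sigma_{GY})$ (`read_sumstats()`,
   `harmonize()`, `filter_pairs()`).
2. Regress $\hat\beta'_{GY}$ on $\hat\beta_{GX}$, with intercept, over
   an LD-pruned subset (`greedy_ld_prune()` or an external list via
   `set_pruned()`), giving the raw slope $\hat b^*$
   (`fit_raw_slope()`). Residual heteroscedasticity — variants in high
   LD or with extreme frequencies have noisier marginal effects — is
   handled with an HC1 sandwich standard error.
3. Correct $\hat b^*$ for regression dilution (below), giving $\hat b$.
4. Adjust every variant (not only the pruned subset) and attach
   $$\mathrm{se}^2 = \sigma_{GY}^2 + \hat b^2\sigma_{GX}^2 +
     \hat\beta_{GX}^2\,\mathrm{var}(\hat b) +
     \sigma_{GX}^2\,\mathrm{var}(\hat b)$$
   (`adjust_effects()`).
5. Refer $\hat\beta_{GY}/\mathrm{se}$ to the standard normal. For
   variants with extreme incidence effects, where the product
   $\hat b\,\hat\beta_{GX}$ is visibly non-normal,
   `bootstrap_snp_inference()` gives an empirical p-value and
   percentile interval instead, optionally feeding in the SIMEX
   bootstrap slope distribution.

## Regression dilution

Sampling error in $\hat\beta_{GX}$ attenuates the slope towards zero by
the factor
$\mathrm{var}(\beta_{GX})/\mathrm{var}(\hat\beta_{GX})$. Two
corrections are provided.

**Hedges–Olkin** (`hedges_olkin_correct()`): the true-effect variance
is estimated by the method of moments as the observed variance minus the
mean squared standard error. When that difference is not positive the
correction would flip the slope's sign — impossible for a genuine ratio
of variances — and the function refuses rather than return a
sign-flipped slope; SIMEX is the fallback. For
$\mathrm{var}(\hat b)$ the default is the influence-function (sandwich)
variance of the moment-ratio estimator. The naive alternative —
correction factor squared times the raw slope's robust variance — is
also available (`var_method = "scaled"`), but it ignores that the raw
slope and the correction factor are both driven by the observed effect
variance and are strongly negatively correlated; in replicated runs the
influence-function estimate matches the realized variance of
$\hat b$ to a few percent while the scaled estimate sits about 20%
low.

**SIMEX** (`simex_correct()`): re-noise $\hat\beta_{GX}$ with variance
$\lambda\sigma_{GX}^2$ for a grid of $\lambda$, average the refitted
slopes at each $\lambda$, fit a quadratic (or linear) trend and
extrapolate to $\lambda = -1$, the point of no measurement error.
Defaults: $\lambda \in \{0, 0.25, \ldots, 2\}$, 100 re-noised datasets
per $\lambda$, quadratic extrapolation — standard SIMEX practice. The
uncertainty of $\hat b$ comes from a nonparametric bootstrap over
variants (default 200 resamples): percentile interval, variance of the
bootstrap slopes, and the bootstrap distribution itself is kept in the
diagnostics for empirical per-variant inference. The bootstrap supports
the strongly asymmetric intervals that arise when individual standard
errors are large, which a curvature-based interval would not. With a
single-point grid, or no measurement error, the procedure degenerates
to the raw slope by construction.

The slope regression includes an intercept, and the correction applies
the slope only; the intercept absorbs any directional mean of the
prognosis effects and is reported in the fit. Whether to add the
intercept back into adjusted effects is a genuinely open convention;
subtracting only $\hat b\hat\beta_{GX}$ keeps the null variant's
estimate centred on its own conditional estimate and is the convention
used throughout.

## The simulation engines

`run_scenario()` reproduces operating characteristics (per-category
type-1 error, power, family-wise error at the Bonferroni threshold
$0.05/m_{\text{inc-only}}$, absolute bias, MSE) for adjusted and
unadjusted analyses under a `simulation_scenario()`. Two engines share
one analysis path.

**Individual level**: Hardy–Weinberg genotypes with frequencies uniform
on (0.01, 0.49); quantitative traits built from the structural
equations with a standard-normal confounder; per-variant scans by
linear regression (prognosis conditional on incidence), logistic
regression (liability-threshold disease, top 20% affected, 10,000
cases/10,000 controls, case-only analysis of the median-split
prognosis), or Cox regression on exponential survival times with the
prognosis trait as log hazard. The same individuals serve both scans,
as in real re-uses of susceptibility case collections; the regression
framework absorbs the resulting phenotype correlation into $U$.

**Summary level**: the per-variant estimates are drawn directly from
their asymptotic sampling distributions — normal around
$\beta_{GX}$ and around $\beta_{GY} + b\,\beta_{GX}$ with standard
errors $\sqrt{(1-\beta_{GX}^2 v)/(n v)}$ and
$\sqrt{(1-\rho^2-\beta'^2_{GY} v)/(n v)}$, where $v = 2p(1-p)$ and
$\rho$ is the realized trait covariance. This is exact to the order the
per-variant effects are small and lets the full 100,000-variant design
replicate in tens of milliseconds. Its agreement with the
individual-level engine is itself a test (standardized errors have unit
spread within 5%).

Three generator choices matter and are fixed package-wide:

* *Effect-size scale.* Effects are drawn iid normal on the
  standardized genotype scale, so each causal variant contributes the
  same expected heritability share regardless of frequency (the
  classical polygenic architecture used by GCTA/LDSC). Under this
  architecture the unadjusted type-1 error of the confounded design has
  the closed form $2\Phi(-1.96/\sqrt{1 + b^2 h^2_{\text{share}} n /
  (1-\rho^2)}) = 7.24\%$, which the engine reproduces; a
  dosage-scale-iid architecture gives 7.30% and was rejected on that
  ground. Vectors are rescaled so the realized genetic variance equals
  the target heritability exactly, which stabilises reduced-scale runs.
* *Binary designs.* Liability effects map to the log-odds scale with
  the standard observed-scale factor $\phi(t)/(K(1-K))$ at threshold
  $t = \Phi^{-1}(1-K)$. Selecting cases ($X > t$) attenuates the
  collider slope by $\lambda(\lambda - t)$ — the derivative of the
  truncated-normal mean, with $\lambda = \phi(t)/K$ the inverse Mills
  ratio — and the median split of prognosis among cases contributes
  $\phi(0)/(0.25\,\mathrm{sd}(Y \mid \text{case}))$. Balanced
  case/control standard errors are $2/\sqrt{N v}$.
* *Slope variance in the simulation protocol.* The reference protocol
  for these operating characteristics corrects the slope by the moment
  estimator, for which no $\mathrm{var}(\hat b)$ is defined, and so
  treats the corrected slope as known when forming per-variant
  standard errors. `run_scenario()` follows that protocol by default
  (`slope_var = "none"`); with 100,000 independent variants
  $\mathrm{var}(\hat b) \approx 0.003$ and including it shifts the
  adjusted type-1 error by roughly −0.15 percentage points. The
  data-analysis interface always propagates the slope fit's variance.

What the generator deliberately does not emulate: linkage
disequilibrium between simulated variants (the pruned-regression theory
assumes independence; real data are pruned first), imputation error,
gene–environment interaction, censoring (the survival scan accepts
event indicators, but the generator produces none), or population
structure. Passing tests therefore demonstrate
the estimator's behaviour under its stated assumptions, not robustness
to these violations.

## Monte-Carlo accounting in the acceptance suite

The reference operating characteristics were produced from 1000
replicates sharing a single draw of the genetic architecture (its
per-variant extreme statistics require a fixed draw). A reproduction
that redraws the architecture each replicate must therefore compare
category means allowing for the architecture-draw variance on the
reference side. The acceptance tests estimate that component by pairing
free replicates with fixed-architecture replicates
(`run_scenario(arch_seed = ...)`) and use three combined Monte-Carlo
standard errors as the comparison tolerance. Problem sizes: the full
100,000-variant, 20,000-individual design, 200 replicates per scenario
(500 where the family-wise error is measured), which keeps each
scenario under a minute.

## Numerical choices and degenerate inputs

* Slope regressions refuse fewer than 10 variants or a constant
  predictor; SIMEX discards re-noised datasets with degenerate designs
  and fails if more than 10% are discarded.
* Missing info/frequency metadata passes a filter only when that
  filter's threshold is zero.
* Palindromic variants are dropped during harmonisation by default:
  without reliable frequencies, strand cannot be resolved, and a wrong
  resolution silently flips signs in the slope regression.
* Empirical p-values are floored at 1/draws and should be read as
  order bounds at the floor.
* Zero-variance genotype columns are excluded from pruning
  (correlation undefined) and flagged `NA` in the scans.
* `write_adjusted()` prints 17 significant digits so values round-trip
  exactly, including p-values near the underflow limit.

## Limitations

The correction assumes direct incidence and prognosis effects are
uncorrelated across the variants entering the slope regression; under
genetic correlation the residual bias is proportional to it (the
engine's `slope_target` makes the expected shortfall explicit), and
simulations show reduced — not eliminated — inflation. The adjusted
effects are by construction uncorrelated with incidence effects, so
genetic-correlation analyses of adjusted statistics are circular and
should not be attempted. Selection acting on a precursor trait rather
than a subsequent one is a different structure and is out of scope, as
are survival-until-recruitment bias and informative censoring.
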