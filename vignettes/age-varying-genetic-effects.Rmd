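---
title: "Detecting age-varying genetic effects and propagating them into MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting age-varying genetic effects and propagating them into MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agevarmr)
```

## The model

`agevarmr` targets a middle-aged cohort (ages 40–69) in which a
quantitative trait $X$ may have genetic effects that change linearly with
age at measurement:

$$X_i = \beta_0 + \beta_{age} A_i
      + \sum_j \left(\beta_{g,j} + \theta_j (A_i - a_{ref})\right) G_{ij}
      + \beta_u U_i + u_i$$

where $A_i$ is age in years, $G_{ij} \in \{0,1,2\}$ a dosage, $U_i$ an
unobserved confounder and $u_i \sim N(0, \sigma^2)$. The target of
inference is $\theta_j$, the change in the per-allele effect per year.

The detection strategy is deliberately summary-level. The cohort is
split into 15 two-year age strata; an ordinary least-squares scan in each
stratum produces per-SNP estimates $\hat\pi_{ja}$ with standard errors;
and a fixed-effects meta-regression per SNP,

$$\hat\pi_{ja} = \omega_j + \delta_j \bar A_a + \epsilon_{ja},
  \qquad w_a = 1/\mathrm{se}_{ja}^2,$$

estimates $\hat\delta_j$ with its standard error from the weighted normal
equations, treating the stratum sampling variances as known. Nothing in
the per-stratum scans constrains the shape of the age relationship; only
the meta-regression imposes linearity. This is why the framework suits
consortium settings where only stratified summary statistics can be
shared.

Interaction slopes feed two downstream consumers. *Inclusion sets*
classify variants: discovery variants (full-range scan, $p < 5\times
10^{-8}$, clumped at $r^2 < 0.01$) with interaction $p < 0.05$ form
Inclusion 1; independent variants genome-wide with interaction $p <
5\times 10^{-5}$ form Inclusion 2; thresholds are strict inequalities
throughout. *Modified IVW* replaces each variant's exposure association
by its age slope in the usual inverse-variance weighted regression
through the origin, so the estimand becomes the effect on the outcome of
the rate of change of the genetically predicted exposure with age.

## Parameters that matter

* `maf` — allele frequencies in $(0, 0.5]$; the selection study uses the
  classical 0.4.
* `theta` — interaction slopes, trait units per allele per year. With 15
  strata of roughly 2,000 individuals, slopes of magnitude 0.01 are
  comfortably detectable; the calibration runs below use
  $\theta \sim N(0, 0.01^2)$.
* `reference_stratum` (default 7) — the stratum whose size caps all
  others. Volunteer cohorts skew old, so capping stops the oldest strata
  from dominating the meta-regression weights.
* `p1 = 0.05`, `p2 = 5\times10^{-5}`, `r2 = 0.01`, `gw = 5\times10^{-8}`
  — the inclusion thresholds. They deliberately favour signal detection
  over strict type-I control; interaction power after stratification is
  limited, and some nominal interactions are expected to be false
  positives.
* `overdispersion` — IVW/Egger standard errors default to the
  multiplicative random-effects convention, inflating the fixed-effect SE
  by $\max(1, \sqrt{Q/(n-k)})$; a `"fixed"` mode is available since
  software defaults differ on this point.
* `n_boot = 2000` — weighted-median parametric-bootstrap resamples; the
  estimator has no closed-form SE, and the bootstrap SE is stable to a
  few percent at this size.

## Design choices where the design was open

**Intercept in the meta-regression.** The compact display of the model
($\hat\pi_{jt} = \delta_j \bar A_a + \omega_j$) can be read as a
no-intercept regression. Forcing the line through the origin of the
moderator scale is not meaningful for ages 40–69 and contradicts standard
meta-regression practice, so an intercept is included by default;
`intercept = FALSE` reproduces the literal no-intercept fit.

**z-based inference.** Fixed-effects meta-regression conventionally uses
a normal reference for $\hat\delta/\mathrm{se}$; no Knapp–Hartung
small-sample adjustment is applied. With 15 strata the difference is
minor, and the calibration study below verifies the operating
characteristics empirically.

**Integer ages.** Ages are generated as integers uniform on 40–69,
matching the two-year stratification grid exactly, so stratum membership
is unambiguous and stratum mean ages are exact sample means (the
moderator uses the post-capping sample mean, not the bin midpoint).

**Within-stratum covariates.** Per-stratum scans adjust for age (within
the two-year window), sex and genotyping array, mirroring the discovery
covariates; the covariate list is an argument, since reasonable analysts
differ on whether to adjust for age inside so narrow a window.

**Mixed models replaced by OLS.** Synthetic cohorts carry no relatedness
or population structure, so the random effect of a mixed-model
association method has nothing to absorb; ordinary least squares is the
exact analogue here and is oracle-checked against `lm`. This is the one
intentional methodological substitution in the scan stage.

**Selection direction.** Descriptions of rank-based selection differ on
whether the top half of the score is "selected" or "set to missing"; both
are supported via `direction`, with highest-score-missing as the default
operational convention.

**Capping drawn once.** The stratum-size cap is drawn once per cohort
(not redrawn per trait), keeping all traits of a cohort on identical
samples.

**Missingness variance decomposition.** The proportion of variance in
missingness explained by $G$ and by $A$ is computed marginally (one
single-predictor regression each, squared correlation), not by joint
partitioning; $G$ and $A$ both act partly through $X$, so the two
marginal $R^2$ values are not expected to sum to anything in particular.

## The selection-bias study and its conditions

Selection operates on
$S_i = \delta_1 A_i + \delta_2 A_i X_i + \delta_3 X_i + \delta_4 U_i + v_i$,
$v_i \sim N(0,1)$, with the top half of $S$ set to missing. The observed
sample is split into four equal-width age groups and the genetic effect
re-estimated per group from $X = \gamma_0 + \gamma_1 G + \gamma_2 A +
\omega$.

The default grids are expressed per year of age, because the generator
produces ages in years: $\delta_1 \in \{0, 0.005\}$,
$\delta_2 \in \{0, 0.0167\}$ (one half spread over the 30-year span),
$\delta_3 \in \{0, 0.5\}$, $\delta_4 = 0.2$, crossed with
$\beta_g \in \{0, 0.3\}$, minor allele frequency 0.4, $n = 50{,}000$ per
replicate and 200 replicates per grid point. Two scale considerations
fixed these values. First, an additive age effect on selection of 0.5
*per year* would make selection essentially deterministic in age and
empty the older groups, so the additive coefficient must be modest on the
yearly scale. Second, with a large $\delta_1$ the overall 50% cut lands
at different selection quantiles in different age groups, and truncating
a trait-dependent score at different depths perturbs the per-group
estimates even without any age-by-trait interaction; $\delta_1 = 0.005$
keeps that differential-truncation artefact well below Monte-Carlo
resolution, which is the regime in which the no-interaction control
behaves as described (equal estimates in every age group). The three
qualitative phenomena the study demonstrates are: (i) with
$\delta_2 = 0$, all age groups estimate the same association; (ii) with
$\beta_g = 0$, no bias appears anywhere regardless of the selection
mechanism; (iii) with $\delta_2 \neq 0$ and $\beta_g \neq 0$, the bias
varies monotonically across age groups — an apparent age-varying genetic
effect created purely by selection.

## What the synthetic generator does and does not emulate

The generator reproduces the statistical structure the analyses consume:
uniform integer ages, binomial hard-call dosages, a linear SNP×Age trait
model, heteroskedastic stratum-level estimation noise (which arises
naturally from finite stratum sizes), rank-based selection, logistic
repeat-assessment attendance, and outcome summary statistics responding
to a level and a rate-of-change component. It does *not* emulate linkage
disequilibrium (variants are independent, so clumping tests construct
their own $r^2$ structures), relatedness, population structure,
imputation uncertainty (the INFO field is a pass-through), genotyping
batch effects, or non-linear age trajectories. Passing tests therefore
certify the estimators and their calibration under the stated model, not
robustness to the full messiness of biobank data.

## Numerical choices

* Per-SNP OLS scans residualise the trait and all dosages on the
  covariate design once (Frisch–Waugh–Lovell) and then solve each
  single-SNP regression in closed form; this is exactly the full-model
  OLS fit (oracle-checked to $10^{-10}$) at a fraction of the cost.
* Monomorphic or covariate-collinear variants yield flagged null records;
  degenerate designs never crash a scan.
* Clumping ranks by p-value with ties broken by variant id; the
  selection-score rank cut breaks ties by ascending individual id. Both
  choices exist purely for determinism.
* Logistic attendance fits use iteratively reweighted least squares with
  deviance tolerance $10^{-8}$ and at most 50 iterations; separation is
  flagged (`separation_or_nonconvergence`), never silently truncated, and
  interaction terms that are inestimable in a bin (e.g. constant age) are
  flagged `not_estimable`.
* Every stage seed derives from one master seed by a fixed affine
  counter (`derive_seed`), keeping all seeds below $2^{31}$; reruns are
  byte-identical, verified by digest comparison.

## Problem sizes used in the shipped studies

The calibration and coverage studies use 500 variants across 15 strata of
about 2,000 individuals (30,000 per cohort) — large enough that a
binomial band of $\pm 1.9$ percentage points around the nominal 5% level
is informative, and matching the per-stratum scale at which the
meta-regression framework is recommended to operate. The modified-IVW
recovery study uses 200 variants with outcome SE 0.05 and a generating
rate coefficient of 0.8; its null-coverage companion uses 500 replicates.
The selection study runs its full $2^3 \times 2$ factorial with 200
replicates of $n = 50{,}000$. These sizes were chosen as the smallest at
which each Monte-Carlo check has meaningful resolution.

## Known limitations

Only linear age trajectories are modelled; acute mid-life peaks need a
different moderator basis. The meta-regression treats stratum variances
as known, which is accurate at thousands of individuals per stratum but
optimistic for very small strata. The weighted-median SE is a parametric
bootstrap and inherits its assumptions. Real attendance and participation
mechanisms are far richer than the single-score selection model; the
study demonstrates a mechanism, not a measurement of real cohort bias.
Estimated slopes used as modified-IVW exposures carry estimation noise,
which attenuates the estimate slightly when instrument sets are small (a
NOME violation the reported SEs do not correct).
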