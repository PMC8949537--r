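---
title: "Mediation and Mendelian randomization for macronutrient–disease analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediation and Mendelian randomization for macronutrient–disease analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrimedmr)
```

## What the package models

Observational associations between macronutrient intake (carbohydrate,
sugar, fat, protein, usually expressed as percent of total energy, E%)
and cardiometabolic outcomes (type 2 diabetes, cardiovascular disease,
lipid and glycemic traits) are confounded and partly transmitted
through intermediate traits — above all adiposity (BMI) and physical
activity. `nutrimedmr` implements the two complementary causal lenses
used to probe such associations:

1. **Mediation path models** on individual-level cohort data, which
   decompose a total diet–outcome effect into the direct part and the
   parts transmitted through one or two mediators; and
2. **Two-sample Mendelian randomization (MR)** on GWAS summary
   statistics, which uses genetic variants as instrumental variables to
   estimate a causal diet–outcome effect free of classical confounding,
   together with a battery of pleiotropy-robust estimators.

Both arms are exercised end to end on data from the package's own
synthetic generator, whose known ground truth makes every stage testable
by parameter recovery.

## The mediation model

For exposure $X$, mediator $M$ and outcome $Y$ the pairwise system is

$$Y = i_1 + cX + \epsilon_1, \qquad
  Y = i_2 + c'X + bM + \epsilon_2, \qquad
  M = i_3 + aX + \epsilon_3.$$

Under sequential ignorability (no unmeasured confounding of the
$X$–$Y$ and $M$–$Y$ relations given covariates), substituting the third
equation into the second gives
$Y = i_2 + b i_3 + (c' + ab)X + \epsilon_2 + b\epsilon_3$: the total
effect $c$ splits into the direct effect $c'$ and the indirect effect
$ab$. With two mediators the parallel configuration adds
$a_2 b_2$, and the serial configuration ($X \to M_1 \to M_2 \to Y$)
additionally transmits $a_1 d\, b_2$ through the inter-mediator path
$d$.

Estimation is equation by equation: least squares for mediator
equations and continuous outcomes, maximum-likelihood logistic
regression for binary outcome equations. For a recursive
observed-variable system this coincides with joint maximum likelihood in
the linear case, and it makes the decomposition *exact*: on any
complete-case sample the fitted total effect equals direct plus indirect
to machine precision and equals the coefficient of the one-step
regression (the package asserts agreement to $10^{-10}$). That exactness
is the central invariant of the mediation arm and holds with any set of
confounders included in all equations.

Inference uses the nonparametric bootstrap, resampling whole participant
rows so the joint $X$–$M$–$Y$ dependence is preserved, with percentile
intervals; the conventional 5000 draws is the default
(`mediation_spec(boot = 5000)`). Draws in which a resampled design
degenerates (a constant or collinear column) are skipped and counted,
and more than 10% of skipped draws aborts the analysis rather than
silently reporting unstable intervals.

For binary outcomes the product $ab$ lives on the logit scale, which is
rarely what a reader wants. `indirect_binary_effects()` therefore
computes probability-scale average mediation and direct effects by the
potential-outcomes simulation estimator: coefficient vectors are drawn
from their asymptotic normal distribution, mediator values are simulated
under exposure levels $x$ and $x+1$ including residual noise, and the
implied outcome probabilities are averaged over participants and draws.
Both scales are reported, because the choice of scale for a logistic
"total effect" is genuinely open; emitting both avoids baking in either
convention.

Model comparison and screening follow standard practice: a
likelihood-ratio chi-squared difference test on 1 df compares the
partial-mediation model against the nested full-mediation model with
$c' = 0$ (for these recursive systems, where the direct path is the sole
difference, this equals the structural-equation-level test); variance
inflation factors flag covariates above 10; and p-values across an
exposure × mediator × outcome grid are adjusted by Benjamini–Hochberg
with discoveries declared at adjusted p < 0.05. Grid cells for composite
cardiovascular outcomes take an extra tobacco covariate, reflecting how
smoking confounds that outcome specifically.

## Dietary preprocessing

The preprocessing helpers mirror what a nutritional-epidemiology
pipeline does before modelling, each with its conventional constant:

* `log_shift_transform()` — $\ln(x + 0.1)$; the 0.1 shift admits true
  zero intakes while correcting right skew.
* `energy_residual_adjust()` — the residual method: residuals of
  (transformed) nutrient on total energy intake, re-centered at the
  nutrient mean. The transform is applied first, then the adjustment.
  Output is exactly uncorrelated with energy intake (tested to
  $10^{-10}$).
* `energy_percent()` — E% via metabolizable-energy factors; Atwater
  values (4/4/9/7 kcal/g for protein/carbohydrate/fat/alcohol) are the
  default since the package must choose some concrete set.
* `derive_sugars()` — added sugar = sucrose + monosaccharides −
  fruit/vegetable sugars, clamped at zero (a negative intake is
  physically meaningless; the clamp is this package's choice); total
  sugar = mono- + disaccharides.
* `friedewald_ldl()` — LDL = TC − HDL − TG/2.2 (mmol/L), invalid at
  TG ≥ 4.5 mmol/L by default (the conventional validity bound; the
  bound is configurable).
* `lipid_medication_correct()` — adds the published treated-patient
  constants (+0.208 TG, +1.347 TC, −0.060 HDL, +1.290 LDL mmol/L) to
  flagged rows only, so the correction is idempotent once flags are
  cleared.
* `nutrient_pattern_pca()` — correlation-matrix PCA of intakes;
  three components are retained by default, the scale at which broad
  dietary patterns typically concentrate.
* `exclude_records()` — range/flag exclusions driven by a configuration
  table, not constants, because admissible ranges are a per-cohort
  decision; a documented default YAML ships with the package.

## The two-sample MR model

For variant $j$, let $\hat\beta_{Xj}$ ($\sigma_{Xj}$) and
$\hat\beta_{Yj}$ ($\sigma_{Yj}$) be the exposure and outcome
associations from two non-overlapping GWAS. A valid instrument affects
the outcome only through the exposure, giving the per-variant Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$. The battery:

* **IVW** (main analysis): weighted regression of $\hat\beta_Y$ on
  $\hat\beta_X$ through the origin, weights $\sigma_Y^{-2}$. The SE uses
  multiplicative random effects with the residual scale floored at 1 —
  heterogeneity can widen but never narrow the fixed-effect interval.
  With $k=1$ it reduces exactly to the Wald ratio.
* **MR-Egger**: the same regression with an intercept, after orienting
  all variants to $\hat\beta_X \ge 0$ (without that orientation the
  intercept is not identifiable). Under the InSIDE assumption the
  intercept estimates mean directional pleiotropy; the slope remains a
  consistent causal estimate. Needs $k \ge 3$.
* **Weighted median**: inverse-variance-weighted median of the Wald
  ratios with linear interpolation at cumulative weight 0.5; consistent
  while valid instruments carry ≥ 50% of the weight. SE by seeded
  parametric bootstrap (1000 draws by default).
* **MR-RAPS**: maximizes the profile likelihood treating
  $\hat\beta_{Xj}$ as noisy and allowing overdispersion $\tau^2 \ge 0$,
  with an optional Huber loss; suited to the weaker instruments that a
  relaxed selection threshold admits. Implemented as nested
  golden-section searches (profile $\tau^2$ out at each $\theta$), which
  cannot fail a line search; SE from the sandwich information.
* **MR-PRESSO**: simulation-based global, outlier and distortion tests
  on leave-one-out residual sums of squares, with the outlier-corrected
  IVW estimate.
* Diagnostics: Cochran's Q for IVW ($k-1$ df) and Egger ($k-2$ df),
  per-variant and median F statistics, and leave-one-out IVW with
  variants flagged when their omission moves the estimate by more than
  one SE.

Instrument processing follows GWAS conventions. Selection keeps
variants with p < 5×10⁻⁶ — the relaxed threshold appropriate when
genome-wide-significant diet variants are scarce — then greedily clumps
within ±1000 kb at r² ≥ 0.2 when an LD matrix is supplied; without LD
information clumping is skipped with a message rather than silently
assumed. Harmonization aligns the outcome study on the exposure's
effect allele, flipping swapped records (directly or by strand
complement) exactly once and removing palindromic A/T and C/G variants
outright, with a per-variant action log. `build_adjusted_instrument()`
implements the union-minus-overlap rule for composite instruments
(e.g. carbohydrate adjusted for sugar), dropping variants shared by both
component exposures as cross-trait pleiotropy risks.

`run_mr()` chains the stages and renders a verdict by triangulation: an
association is declared significant only when IVW, weighted median and
MR-Egger agree in direction, IVW p < 0.05, and the PRESSO global test
finds no pleiotropy (p > 0.05). For binary outcomes whose betas are log
odds ratios, estimates are also reported as ORs with exp-transformed
intervals.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws from the recursive linear system with
standard-normal exposure and confounders, configurable path
coefficients, unit residual SD, and a logistic link for binary outcomes
(intercept −2.2, i.e. ≈ 10% baseline prevalence, typical of type 2
diabetes in a middle-aged cohort). `generate_gwas_pair()` draws
per-variant summary statistics with standard errors from the standard
GWAS approximation $\sigma \approx 1/\sqrt{2N\,\mathrm{maf}(1-\mathrm{maf})}$,
so instrument strength is controlled through sample size; pleiotropy
regimes cover none/balanced/directional/InSIDE-violating, and a
configurable fraction of palindromic variants (default 0.1) exercises
the harmonization filters. Everything is seed-reproducible bit for bit.

What passing tests on these data do **not** show: real diets are
measured with error by food-frequency questionnaires, confounders are
non-Gaussian and correlated, effects are nonlinear, instruments sit in
LD blocks rather than independent loci, and GWAS samples overlap. The
generator deliberately omits all of that (LD only enters through a
user-supplied matrix), so recovery results certify the *estimators*, not
the epidemiology of any particular cohort.

## Numerical choices and degenerate inputs

* Zero-variance exposures abort with a clear error instead of returning
  NaN paths; rank-deficient designs and non-converging or separated
  logistic fits are reported, never silently regularized.
* Bootstrap CIs that fail to bracket the point estimate trigger a logged
  warning, never a silent pass; runs with fewer usable draws than the
  percentile level supports are flagged low-precision.
* Empirical p-values in PRESSO use the add-one rule
  $(\#\{\cdot\}+1)/(n_{sim}+1)$, so they are never exactly zero.
* Wald ratio SEs use the first-order delta method; the second-order term
  is negligible at the instrument strengths the selection threshold
  admits.
* RAPS reports $\hat\tau^2$ at the boundary 0 when the profile optimum
  lies there; the boundary is checked explicitly against the interior
  optimum.

## Problem sizes used in the shipped checks

The package's acceptance checks run: 200 cohorts of n = 5000 with 1000
bootstrap draws for path-recovery bias and CI coverage; 500 null cohorts
of n = 1000 for the chi-squared difference test's type-I error; 500
replicates of k = 50 instruments for the estimator battery (with a
parallel directional-pleiotropy arm for the Egger intercept); 100
planted-outlier and 200 null replicates of k = 20 at 500 simulated nulls
for PRESSO; and a 200-variant synthetic consortium-scale pipeline run at
the default thresholds. These sizes give Monte-Carlo standard errors
comfortably below the tolerances being asserted while keeping a full run
in the minutes range on one core.

## Known limitations

Latent-variable structural models, measurement-error corrections,
multilevel mediation, multivariable MR, colocalization and LD-score
methods are out of scope. The mediation arm assumes sequential
ignorability, which no amount of bootstrapping can test; the MR arm's
verdict rule is a heuristic triangulation, not a formal test of the
exclusion restriction. Proxy-variant lookup requires a user-supplied LD
matrix; without one, variants missing from the outcome study are simply
dropped and logged.
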