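---
title: "Nonlinear Mendelian randomization for vitamin D and sarcopenia: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear Mendelian randomization for vitamin D and sarcopenia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The scientific problem

Serum 25-hydroxyvitamin D (25(OH)D) below 20 ng/mL is common, and observational
cohorts consistently associate it with sarcopenia — age-related loss of muscle
mass and strength — while randomized trials of supplementation, run almost
entirely in replete participants, have been null. The open question is the
*shape* of the causal dose-response: is there a threshold near 20 ng/mL below
which raising 25(OH)D lowers sarcopenia risk, with no benefit above it?

Mendelian randomization (MR) addresses the confounding that plagues
observational vitamin D studies by using germline genetic variants as
instruments: alleles are assigned at meiosis, before lifestyle or disease can
influence them. A weighted allele score built from variants associated with
25(OH)D serves as a single instrument `Z`. Standard MR estimates one slope and
so cannot see a threshold; *nonlinear* MR stratifies the cohort, estimates a
localized causal effect in each stratum, and reconstructs the curve from those
local effects.

`vitdmr` implements this pipeline end to end, together with a synthetic cohort
generator whose true causal curve is known, so every stage can be validated
against ground truth — something impossible with access-controlled biobank
data.

## The causal model and the estimators

Individuals carry exposure \(X\) (25(OH)D, ng/mL), outcome \(Y\) (sarcopenia,
or a continuous index), instrument \(Z\) (the weighted allele score), and an
unobserved confounder \(U\). The generator simulates

\[
X = \mu + c\,(Z - \bar Z) + k_x U + \varepsilon, \qquad
\operatorname{logit} P(Y = 1 \mid X, U) = \alpha + h(X) + k_y U ,
\]

with \(Z \perp U\) by construction. The target of inference is \(h(x)\), the
causal dose-response on the log-odds scale.

**Ratio estimates.** Within any subgroup, regressing \(X\) on \(Z\) gives
\(\hat\beta_x\), regressing \(Y\) on \(Z\) gives \(\hat\beta_y\), and the IV
(Wald) estimate is \(\hat\beta_y / \hat\beta_x\), with a first-order
delta-method standard error
\(\sqrt{se_y^2 + r^2 se_x^2 - 2 r \rho\, se_x se_y}\,/\,|\hat\beta_x|\)
(`ratio_estimate()`). The acceptance checks verify this SE against a
Monte-Carlo oracle to within 5% at moderate instrument strength.

**Residual stratification.** Stratifying directly on \(X\) would condition on
a collider: within a band of raw exposure, individuals with high genetic score
must have low \(U + \varepsilon\), which induces a spurious dependence between
the instrument and the confounder and distorts \(\hat\beta_x\) stratum by
stratum. Instead we stratify on the *instrument-free residual*
\(R = X - \hat E[X \mid Z] + \bar X\) (`exposure_residuals()`), recentred by
the overall mean so the clinical 10/20/30 ng/mL cutpoints stay meaningful.
The package's property tests confirm the mechanism: under a null causal curve,
the instrument-exposure coefficient is homogeneous across ten residual-strata
(heterogeneity p > 0.05 in ≈97% of replicates at n = 100 000) but grossly
heterogeneous across raw-exposure strata (homogeneous in ≈0%).

**LACE.** Within stratum \(k\), the localized average causal effect is the
ratio estimate of that stratum (`lace_estimates()`), interpreted as
\(h'(\bar x_k)\), the derivative of the causal curve at the stratum's mean
exposure. Rare-event strata that defeat maximum likelihood fall back to Firth
penalized logistic regression, flagged per stratum.

**Fractional-polynomial curve.** With derivative estimates
\(\hat L_k \approx h'(\bar x_k)\) in hand, `fit_fp()` models
\(h(x) = \sum_j \theta_j b_j(x)\) over fractional-polynomial bases with powers
from \(\{-2,-1,-0.5,0,0.5,1,2,3\}\) (0 = log; repeated powers use the
log-multiplied basis), estimating \(\theta\) by inverse-variance-weighted
least squares of \(\hat L_k\) on the derivative basis and selecting the
maximum-likelihood power combination. The curve is anchored at the reference
exposure (20 ng/mL = 50 nmol/L), so `or_curve()` reports
\(OR(x) = \exp\{h(x) - h(20)\}\) with delta-method bands; the OR at the
reference is exactly 1 with zero width.

**Nonlinearity tests** (`nonlinearity_tests()`). Three statistics are
reported side by side, since reports of a single "nonlinear P" rarely say
which was used:

* Cochran's Q of the LACEs about their inverse-variance-weighted mean
  (df = K − 1) — a linear curve implies a common LACE;
* the Wald p of the slope in the weighted meta-regression of LACE on stratum
  mean exposure ("quadratic" test);
* the fractional-polynomial test: the weighted-RSS improvement of the best
  degree-1 fractional polynomial over the one-parameter linear model,
  referred to chi-square(1). Because the linear model is the power-1 member
  of the candidate family, the statistic is nonnegative by construction. The
  selection over eight highly correlated candidates makes the chi-square(1)
  reference slightly liberal; measured type-I error at the package's
  reference scale is ≈0.03–0.06, inside the 0.03–0.08 acceptance band.

**Sensitivity estimators** (`ivw()`, `weighted_median()`, `mr_egger()`,
`mr_presso()`, `radial_mr()`). These consume per-variant summary statistics
(`snv_summary_stats()`), oriented to the exposure-increasing allele, and are
implemented from first principles; unit tests pin each to an independent
oracle (weighted least squares via `stats::lm`, brute-force cumulative-weight
interpolation, exact line recovery) and to their published equivalences
(radial MR with first-order weights equals fixed-effect IVW to 1e-10). The
one-sample caveat applies: both coefficient sets come from the same cohort,
and the estimators ignore the resulting sampling correlation, as is standard
practice in single-cohort applications.

## What the generator emulates — and what it does not

The generator (`simulate_cohort()`) reproduces the statistical features that
matter for validating the method:

* right-skewed positive exposure (centred gamma noise, shape 4; mean 20, SD 8
  ng/mL by default; values floored at 0.5 ng/mL, the working lower assay
  bound);
* Hardy-Weinberg genotypes at 35 variants with per-allele weights in ng/mL
  and a score calibrated to explain exactly `grs_r2` of exposure variance
  (default 5%, the upper range plausible for a 35-variant 25(OH)D score);
* a single standard-normal latent confounder acting on both exposure
  (2 ng/mL per SD) and outcome (0.5 log-odds per SD) — one strong confounder
  is sufficient to exercise the collider-bias machinery;
* binary outcomes with a numerically calibrated intercept hitting a target
  prevalence, plus continuous outcomes sharing the same causal term;
* a configurable truth `h(x)`: null, linear, L-shaped threshold, or an
  arbitrary fractional polynomial. The threshold default (change point
  20 ng/mL, slope −0.0554 per ng/mL below, flat above) is anchored so that
  the odds ratio for 10 vs 20 ng/mL is 1.74.

It deliberately does **not** emulate population structure, relatedness,
linkage disequilibrium between variants, imputation dosages, assay batch
effects, or selection into the cohort. Passing tests therefore demonstrate
that the estimators recover the causal curve under the model's own
assumptions — not that those assumptions hold in any particular biobank.

### Reference conditions and prevalence

Sarcopenia by a strict definition is very rare (≈0.16% in the motivating
cohort; available as `preset = "empirical_rare"`), which makes per-stratum
logistic fits unstable at simulation scale. The generator default is 5%. The
package's *power studies* (`preset = "power"`) use n = 100 000, ten residual
strata, and prevalence 10% — the lower end of the 10–27% prevalence reported
for adults over 60, the population actually at risk. These conditions were
fixed by a design-stage power analysis targeting ≈90% power for the
fractional-polynomial nonlinearity test under the anchored threshold truth,
and the acceptance suite then measures: rejection in ≥80% of 100 replicates
under the threshold truth (observed ≈0.92), rejection rate within
[0.03, 0.08] under a linear truth over 500 replicates, and a fitted curve
that is essentially flat above the change point (mean absolute slope on
(25, 35) below a quarter of that on (5, 15)).

## Numerical choices and edge cases

* **Boundary convention.** Exposure categories are half-open, lower-inclusive
  (`[10, 20)` etc.): a value of exactly 10.0 ng/mL belongs to the 10.0–19.9
  band. Printed band labels such as "10.0–19.9" are ambiguous at the
  boundary; one convention had to be fixed and documented.
* **Crude odds ratios** come from 2×2 cross-products with Woolf (log-normal)
  intervals, not from logistic fits — numerically identical for the
  saturated model (a unit test verifies agreement to 6 significant figures)
  but exactly reproducible from printed counts. Zero cells raise an error
  rather than silently applying a continuity correction.
* **Quantile strata** are rank-based, sized within one individual of `n/K`,
  ties broken by original order.
* **Weighted median** interpolates linearly between bracketing ratios at
  cumulative weight 0.5; its SE is parametric-bootstrap.
* **MR-PRESSO resolution.** Empirical p-values have floor `1/(1+n_sim)`; with
  the Bonferroni outlier threshold `alpha/J`, no variant can be flagged
  unless `n_sim > J/alpha`. The function emits a message when asked to run
  below that resolution. Note also an intrinsic power ceiling: a variant
  whose direct effect is `m` times its SE presents an observed z of
  `m + N(0,1)`, so even a perfect detector at the |z| ≈ 3.2 Bonferroni cut
  (J = 35) detects a 5-SE outlier in at most ≈95–96% of replicates.
* **Radial MR** iterates the modified second-order weights from a
  first-order start (cap 10 iterations, tolerance 1e-12) and removes
  outliers one at a time, largest Q contribution first, ties to the lower
  index, refitting until no contribution exceeds the chi-square(1) critical
  value.
* **Harmonization** treats a swapped allele coding as the `2 − g` dosage
  substitution, implemented as weight negation plus a recorded constant
  offset so scores match the substitution exactly; palindromic (A/T, C/G)
  variants are excluded with a warning rather than guessed.
* **Firth fallback** for per-stratum logistic fits triggers on
  non-convergence or quasi-separation (Wald SE > 1000 or |coef| > 50) and is
  flagged in the `firth` column.
* **Degree selection.** `fit_fp(degree = "auto")` keeps degree 1 unless the
  degree-2 fit improves the weighted RSS significantly at the 0.05 level
  (chi-square, 1 df). The observational `fp_dose_response()` defaults to
  degree 2, the usual choice for descriptive curves; the nonlinear MR curve
  defaults to degree 1, which is identified from ten strata with margin.

## Design choices where the field leaves latitude

* **Number of strata.** Ten residual quantile strata by default — enough
  resolution to localize a change point near the exposure median without
  starving stratum-level logistic fits; the 4-band clinical categorization
  is available as `mode = "categories"`.
* **Recentring.** Residuals are recentred by the overall exposure mean. Any
  constant works mathematically; this choice keeps the clinical cutpoints
  interpretable on the residual scale.
* **Stratum floors.** Strata below 50 individuals or 5 events are excluded
  (configurable) and logged with machine-readable reason codes.
* **Units.** ng/mL everywhere internally; `NMOL_PER_NGML` (2.496) is applied
  only at input/output boundaries.
* **One causal term for all outcomes.** The generator adds the same `h(X)`
  to every outcome's linear predictor. For the continuous outcomes this
  makes the causal contribution small relative to their noise SDs — which is
  realistic for grip strength, and immaterial for the method tests, which
  target the binary pipeline.
* **Command-line surface.** The package's functions are the primary
  interface; a thin `Rscript` wrapper (`inst/cli/vitd-mr`) exposes
  `run`/`fixtures` subcommands with exit codes 0/2/3 for shell pipelines.

## Known limitations

* The LACE-as-derivative formulation assumes the instrument effect on the
  exposure is homogeneous across strata (guaranteed here by construction;
  testable via the collider diagnostics in real data).
* Delta-method bands for the OR curve are first-order; a parametric
  bootstrap cross-check is part of the test suite (agreement within 2% on
  the fixtures) but wide-SE, few-strata settings may need the bootstrap.
* The fractional-polynomial family cannot represent a sharp kink exactly;
  under the threshold truth the fitted curve smooths the corner, which
  attenuates point contrasts such as OR(10 vs 20) toward 1 relative to the
  generating truth (visible in the acceptance outputs).
* No linkage disequilibrium, no doubly-ranked stratification, no
  within-family designs, and no multivariable MR — deliberately out of
  scope.
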