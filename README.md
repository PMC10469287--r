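# vitdmr

Nonlinear Mendelian randomization (MR) of serum 25-hydroxyvitamin D
(25(OH)D) and sarcopenia risk, for biostatisticians and genetic
epidemiologists who want the full pipeline — and a ground-truth simulator to
validate it — in one tested R package.

Low vitamin D status (25(OH)D < 20 ng/mL) is observationally associated with
sarcopenia, but supplementation trials in replete participants are null. The
question is the *shape* of the causal dose-response: a threshold near
20 ng/mL would mean correction helps only below it. Standard MR estimates a
single slope; nonlinear MR recovers the curve. The core model: with
instrument *Z* (a weighted allele score), exposure *X*, and causal curve
*h(x)* on the log-odds scale, the cohort is stratified on the
**instrument-free exposure residual** (avoiding collider bias), each
stratum's **localized average causal effect** (LACE) is the ratio estimate
β̂\_y/β̂\_x ≈ *h′(x̄ₖ)*, and the curve is rebuilt by inverse-variance-weighted
least squares of the LACEs on the derivative of a **fractional-polynomial
basis** (powers {−2, −1, −0.5, 0, 0.5, 1, 2, 3}), anchored so OR = 1 at
20 ng/mL (50 nmol/L). Nonlinearity is tested by Cochran's Q, a weighted
meta-regression slope, and the best-FP1-vs-linear chi-square(1) test.
Pleiotropy-robust sensitivity estimators — IVW, weighted median, MR-Egger,
MR-PRESSO, radial MR with modified second-order weights — are implemented
from first principles on per-variant summary statistics.

## Worked example

```r
library(vitdmr)

# crude odds ratio from published four-band contingency counts:
# events 84/29887 in the <10 ng/mL band vs 107/79432 in the reference band
contingency_or(84, 29887, 107, 79432)
#> OR 2.09 (95% CI 1.57-2.78)

# simulate a cohort with a known L-shaped causal curve (change point 20 ng/mL,
# OR 1.74 for 10 vs 20 ng/mL), then recover the curve by nonlinear MR
cohort <- simulate_cohort(sim_config(preset = "power", seed = 7))
fit <- nlmr_analysis(cohort, "y_sarcopenia", K = 10)
fit$tests
#> Cochran Q = 19.28 (df 9, p = 0.0229); quadratic p = 0.000885; fractional-polynomial p = 0.000677
or_curve(fit$model, c(10, 20, 30))[, c("x", "or", "lo", "hi")]
#>    x    or    lo    hi
#> 1 10 1.485 1.312 1.680
#> 2 20 1.000 1.000 1.000
#> 3 30 0.839 0.795 0.887

# standard (linear) MR with the summary-statistic estimators
ss <- snv_summary_stats(cohort, "y_sarcopenia", family = "logistic")
ivw(ss)$estimate
#> [1] -0.032
```

Reading the output: the fractional-polynomial p of 7e-4 rejects a linear
dose-response; the fitted curve shows elevated odds below the reference
(OR 1.49 at 10 ng/mL) and near-flat behavior above it — the L-shape the
simulation planted (the smooth basis rounds the sharp kink, attenuating the
10 vs 20 contrast toward 1). The IVW slope (−0.032 log-odds per ng/mL) is a
single-slope summary that averages the steep and flat regions.

A config-driven end-to-end run (simulate → score → observational models →
residual-stratified LACEs → nonlinear MR → sensitivity estimators), writing
TSV/JSON outputs plus an MD5 manifest:

```r
run_pipeline(default_run_config(seed = 1, out_dir = "run1"))
```

or from a shell: `inst/cli/vitd-mr run --config run.yaml --out run1`.

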