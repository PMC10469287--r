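#' Fit a fractional-polynomial causal curve to stratum LACEs
#'
#' Each stratum's localized average causal effect is modeled as the
#' derivative of the candidate fractional-polynomial curve evaluated at the
#' stratum's mean exposure. For every power combination of the stated degree,
#' the curve coefficients are estimated by inverse-variance-weighted least
#' squares of the LACEs on the derivative basis (weights `1/se_ratio^2`), and
#' the maximum-likelihood candidate is returned. The fitted curve is anchored
#' so that its value at `reference_x` is zero on the linear-predictor scale
#' (odds ratio exactly 1 at the reference).
#'
#' @param strata A `lace_estimates` data.frame (needs `mean_exposure`,
#'   `ratio`, `se_ratio`).
#' @param degree 1, 2, or `"auto"` (degree 2 only if it improves on the best
#'   degree-1 model at the 0.05 level).
#' @param powers Candidate exponents, default [fp_power_set()].
#' @param reference_x Reference exposure, ng/mL (default 20, i.e. 50 nmol/L).
#' @return Object of class `fp_model`: `degree`, `powers`, `coefficients`,
#'   `vcov`, `reference_x`, `rssw` (weighted residual sum of squares),
#'   `logLik`, `support` (observed exposure range), `strata` (the inputs
#'   used), `candidates`.
#' @export
fit_fp <- function(strata, degree = 1, powers = fp_power_set(), reference_x = 20) {
  use <- is.finite(strata$ratio) & is.finite(strata$se_ratio) & strata$se_ratio > 0
  st <- strata[use, , drop = FALSE]
  if (identical(degree, "auto")) {
    f1 <- fit_fp(st, 1, powers, reference_x)
    f2 <- tryCatch(fit_fp(st, 2, powers, reference_x), error = function(e) NULL)
    if (!is.null(f2)) {
      p <- stats::pchisq(max(f1$rssw - f2$rssw, 0), df = 1, lower.tail = FALSE)
      if (p < 0.05) {
        return(f2)
      }
    }
    return(f1)
  }
  if (!degree %in% c(1, 2)) vd_stop("degree must be 1, 2 or 'auto'", "vitdmr_config_error")
  if (nrow(st) < degree + 2) {
    vd_stop(
      sprintf(
        "%d usable strata cannot identify a degree-%d curve (need at least %d)",
        nrow(st), degree, degree + 2
      ),
      "vitdmr_identification_error"
    )
  }
  w <- 1 / st$se_ratio^2
  cands <- fp_candidates(degree, powers)
  fits <- lapply(cands, function(pw) wls(fp_deriv(st$mean_exposure, pw), st$ratio, w))
  rssw <- vapply(fits, function(f) if (is.null(f)) Inf else f$rssw, 0)
  best <- which.min(rssw)
  fit <- fits[[best]]
  # Gaussian weighted log-likelihood (SEs treated as known)
  ll <- -0.5 * (fit$rssw + sum(log(2 * pi * st$se_ratio^2)))
  structure(
    list(
      degree = degree, powers = cands[[best]],
      coefficients = fit$beta, vcov = fit$vcov,
      reference_x = reference_x,
      rssw = fit$rssw, logLik = ll,
      support = if (all(c("x_min", "x_max") %in% names(st))) {
        c(min(st$x_min), max(st$x_max))
      } else {
        range(st$mean_exposure)
      },
      strata = st,
      candidates = data.frame(
        powers = vapply(cands, paste, "", collapse = ","),
        rssw = rssw
      )
    ),
    class = "fp_model"
  )
}

#' Evaluate a fitted causal curve
#'
#' Curve value at `x` minus its value at the model's reference exposure, on
#' the linear-predictor scale.
#'
#' @param model An `fp_model` from [fit_fp()].
#' @param x Exposure values, ng/mL.
#' @return Numeric vector; zero at the reference by construction.
#' @export
fp_predict <- function(model, x) {
  stopifnot(inherits(model, "fp_model"))
  B <- fp_basis(x, model$powers)
  Bref <- fp_basis(model$reference_x, model$powers)
  drop((B - matrix(Bref, nrow(B), ncol(B), byrow = TRUE)) %*% model$coefficients)
}

#' Tests of nonlinearity of the causal dose-response
#'
#' Three complementary tests computed from the stratum LACEs:
#'
#' * `cochran_q`: Cochran heterogeneity Q of the LACEs about their
#'   inverse-variance-weighted mean (df = strata - 1). Under a linear causal
#'   curve all strata share the same LACE, so heterogeneity is evidence of
#'   nonlinearity (or of residual stratification failure).
#' * `quadratic_p`: Wald p-value of the slope in the inverse-variance-weighted
#'   meta-regression of LACE on stratum mean exposure.
#' * `fp_p`: chi-square(1) comparison of the best-fitting degree-1 fractional
#'   polynomial against the one-parameter linear model (the power-1 member of
#'   the same family), on the weighted residual sum of squares scale.
#'
#' @param strata A `lace_estimates` data.frame with at least 4 usable strata.
#' @param powers Candidate exponents for the fractional-polynomial test.
#' @return List of class `nonlinearity_tests`: `cochran_q`, `q_df`, `q_p`,
#'   `quadratic_slope`, `quadratic_p`, `fp_stat`, `fp_p`, `fp_powers`.
#' @export
nonlinearity_tests <- function(strata, powers = fp_power_set()) {
  use <- is.finite(strata$ratio) & is.finite(strata$se_ratio) & strata$se_ratio > 0
  st <- strata[use, , drop = FALSE]
  K <- nrow(st)
  if (K < 4) vd_stop("nonlinearity tests need at least 4 strata", "vitdmr_identification_error")
  l <- st$ratio
  w <- 1 / st$se_ratio^2
  m <- sum(w * l) / sum(w)
  q <- sum(w * (l - m)^2)
  q_p <- stats::pchisq(q, df = K - 1, lower.tail = FALSE)

  meta <- wls(cbind(1, st$mean_exposure), l, w)
  slope <- meta$beta[2]
  slope_se <- sqrt(meta$vcov[2, 2])
  quadratic_p <- 2 * stats::pnorm(abs(slope / slope_se), lower.tail = FALSE)

  # best FP1 vs the constant-derivative (linear-curve) model; the linear model
  # is the power-1 candidate, so the statistic is >= 0 by construction
  rssw <- vapply(
    fp_candidates(1, powers),
    function(pw) {
      f <- wls(fp_deriv(st$mean_exposure, pw), l, w)
      if (is.null(f)) Inf else f$rssw
    },
    0
  )
  fp_stat <- q - min(rssw)
  fp_p <- stats::pchisq(fp_stat, df = 1, lower.tail = FALSE)
  structure(
    list(
      cochran_q = q, q_df = K - 1, q_p = q_p,
      quadratic_slope = slope, quadratic_p = quadratic_p,
      fp_stat = fp_stat, fp_p = fp_p,
      fp_powers = fp_candidates(1, powers)[[which.min(rssw)]],
      n_strata = K
    ),
    class = "nonlinearity_tests"
  )
}

#' @export
print.nonlinearity_tests <- function(x, ...) {
  cat(sprintf(
    "Cochran Q = %.2f (df %d, p = %.3g); quadratic p = %.3g; fractional-polynomial p = %.3g\n",
    x$cochran_q, x$q_df, x$q_p, x$quadratic_p, x$fp_p
  ))
  invisible(x)
}

#' Odds-ratio curve against a reference exposure
#'
#' Expresses a fitted causal curve as odds ratios `OR(x) = exp(curve(x) -
#' curve(reference))` over a grid, with delta-method confidence intervals from
#' the coefficient covariance of the basis-difference contrast. At the
#' reference the OR is exactly 1 with zero CI width. Grid points outside the
#' observed exposure support are dropped with a warning.
#'
#' @param model An `fp_model` from [fit_fp()].
#' @param grid Exposure grid, ng/mL; defaults to 100 points over the model
#'   support.
#' @param reference_x Reference exposure (defaults to the model's).
#' @param ci_level Confidence level.
#' @return `data.frame`: `x`, `log_or`, `se`, `or`, `lo`, `hi`.
#' @export
or_curve <- function(model, grid = NULL, reference_x = model$reference_x,
                     ci_level = 0.95) {
  stopifnot(inherits(model, "fp_model"))
  if (is.null(grid)) grid <- seq(model$support[1], model$support[2], length.out = 100)
  outside <- grid < model$support[1] | grid > model$support[2]
  if (any(outside)) {
    warning(
      sprintf(
        "%d grid point(s) outside the observed exposure support [%.2f, %.2f] dropped",
        sum(outside), model$support[1], model$support[2]
      ),
      call. = FALSE
    )
    grid <- grid[!outside]
  }
  p <- length(model$coefficients)
  Cmat <- fp_basis(grid, model$powers) -
    matrix(fp_basis(reference_x, model$powers), length(grid), p, byrow = TRUE)
  est <- drop(Cmat %*% model$coefficients)
  se <- sqrt(pmax(rowSums((Cmat %*% model$vcov) * Cmat), 0))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  data.frame(
    x = grid, log_or = est, se = se,
    or = exp(est), lo = exp(est - z * se), hi = exp(est + z * se)
  )
}

#' Residual-stratified nonlinear MR in one call
#'
#' Convenience wrapper running the full nonlinear MR pipeline on a cohort:
#' instrument-free residuals ([exposure_residuals()]), stratification
#' ([stratify()]), per-stratum LACEs ([lace_estimates()]), curve fit
#' ([fit_fp()]) and nonlinearity tests ([nonlinearity_tests()]).
#'
#' @inheritParams lace_estimates
#' @param mode,K,cutpoints Stratification controls (see [stratify()]);
#'   default 10 quantile strata.
#' @param degree,reference_x Curve controls (see [fit_fp()]).
#' @return List of class `nlmr_result`: `model`, `tests`, `strata`,
#'   `assignments`, `residuals`.
#' @export
nlmr_analysis <- function(cohort, outcome, family = c("logistic", "linear"),
                          exposure = "exposure_ngml", instrument = "grs",
                          covariates = NULL,
                          mode = "quantile", K = 10, cutpoints = c(10, 20, 30),
                          degree = 1, reference_x = 20,
                          min_n = 50, min_events = 5) {
  family <- match.arg(family)
  res <- exposure_residuals(
    cohort[[exposure]], cohort[[instrument]],
    if (!is.null(covariates)) as.matrix(cohort[covariates])
  )
  assignments <- stratify(res, mode = mode, K = K, cutpoints = cutpoints)
  strata <- lace_estimates(cohort, assignments, outcome,
    family = family,
    exposure = exposure, instrument = instrument, covariates = covariates,
    min_n = min_n, min_events = min_events
  )
  model <- fit_fp(strata, degree = degree, reference_x = reference_x)
  tests <- nonlinearity_tests(strata)
  structure(
    list(
      model = model, tests = tests, strata = strata,
      assignments = assignments, residuals = res
    ),
    class = "nlmr_result"
  )
}

#' Age-stratified nonlinear MR
#'
#' Runs the full residual-stratification and fractional-polynomial pipeline
#' independently within age bands (younger than `age_cut`, and `age_cut` or
#' older). A band that cannot be analyzed (too few individuals or events)
#' is reported as not estimable; the other band is still returned.
#'
#' @inheritParams nlmr_analysis
#' @param age_cut Age cut in years (default 65).
#' @param age_col Age column name (default `cov_age`).
#' @return List of class `age_stratified_nlmr` with elements `younger` and
#'   `older` (each an `nlmr_result`, or a list with `estimable = FALSE` and
#'   `reason`), and `age_cut`.
#' @export
age_stratified_nlmr <- function(cohort, outcome, family = c("logistic", "linear"),
                                age_cut = 65, age_col = "cov_age", ...) {
  family <- match.arg(family)
  if (!age_col %in% names(cohort)) {
    vd_stop(sprintf("age column '%s' not found", age_col), "vitdmr_config_error")
  }
  run_band <- function(sub) {
    if (nrow(sub) == 0) {
      return(list(estimable = FALSE, reason = "empty age band"))
    }
    tryCatch(
      nlmr_analysis(sub, outcome, family = family, ...),
      vitdmr_error = function(e) list(estimable = FALSE, reason = conditionMessage(e))
    )
  }
  young <- cohort[cohort[[age_col]] < age_cut, , drop = FALSE]
  old <- cohort[cohort[[age_col]] >= age_cut, , drop = FALSE]
  structure(
    list(younger = run_band(young), older = run_band(old), age_cut = age_cut),
    class = "age_stratified_nlmr"
  )
}
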