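#' Categorize exposure values at clinical cutpoints
#'
#' Assigns each exposure value to a half-open category `[lo, hi)`. With the
#' default cutpoints 10/20/30 ng/mL the categories are `<10.0`, `10.0-19.9`,
#' `20.0-29.9` and `>=30.0`; boundaries belong to the upper category (10.0
#' falls in `10.0-19.9`). The clinical reference band is `20.0-29.9`.
#'
#' @param x Positive exposure values, ng/mL.
#' @param cutpoints Strictly increasing cut points, ng/mL.
#' @return Factor with one level per category, in increasing order, carrying a
#'   `reference` attribute (the band containing `cutpoints[2]`, i.e.
#'   `20.0-29.9` by default).
#' @export
categorize <- function(x, cutpoints = c(10, 20, 30)) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    vd_stop("exposure values must be positive and finite", "vitdmr_domain_error")
  }
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    vd_stop("cutpoints must be strictly increasing", "vitdmr_config_error")
  }
  k <- length(cutpoints)
  labels <- c(
    sprintf("<%.1f", cutpoints[1]),
    if (k > 1) sprintf("%.1f-%.1f", cutpoints[-k], cutpoints[-1] - 0.1),
    sprintf(">=%.1f", cutpoints[k])
  )
  idx <- findInterval(x, cutpoints) + 1L
  out <- factor(labels[idx], levels = labels)
  ref <- labels[findInterval(cutpoints[min(2, k)], cutpoints) + 1L]
  attr(out, "reference") <- ref
  out
}

#' Crude odds ratio from a 2x2 contingency table
#'
#' Cross-product odds ratio for an index exposure category against the
#' reference category, with the Woolf (log-scale normal) confidence interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. All four cells must be
#' positive; no continuity correction is applied silently.
#'
#' @param events_index,total_index Events and total count in the index
#'   category.
#' @param events_ref,total_ref Events and total count in the reference
#'   category.
#' @param ci_level Confidence level (default 0.95).
#' @return A list of class `contingency_or`: `or`, `lo`, `hi`, `log_or`, `se`.
#' @examples
#' # lowest 25(OH)D band vs the 20.0-29.9 ng/mL reference
#' contingency_or(84, 29887, 107, 79432)
#' @export
contingency_or <- function(events_index, total_index, events_ref, total_ref,
                           ci_level = 0.95) {
  a <- events_index
  b <- total_index - events_index
  c <- events_ref
  d <- total_ref - events_ref
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) vd_stop("negative cell count", "vitdmr_domain_error")
  if (any(cells == 0)) {
    vd_stop(
      sprintf(
        "zero cell(s) in 2x2 table (%s); odds ratio undefined without a continuity correction",
        paste(names(cells)[cells == 0], collapse = ", ")
      ),
      "vitdmr_zero_cell_error"
    )
  }
  log_or <- log((a / b) / (c / d))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(
      or = exp(log_or), lo = exp(log_or - z * se), hi = exp(log_or + z * se),
      log_or = log_or, se = se, ci_level = ci_level
    ),
    class = "contingency_or"
  )
}

#' @export
print.contingency_or <- function(x, ...) {
  cat(sprintf(
    "OR %.2f (%d%% CI %.2f-%.2f)\n", x$or, round(100 * x$ci_level), x$lo, x$hi
  ))
  invisible(x)
}

#' Per-category regression estimates against the reference band
#'
#' Fits a logistic (binary outcome) or linear (continuous outcome) regression
#' of the outcome on the exposure category, optionally adjusted for
#' covariates, and reports per-category odds ratios or mean differences with
#' Wald confidence intervals against the reference category. Without
#' covariates and with a binary outcome, the model is saturated in the
#' category factor, so each OR equals the 2x2 cross-product OR exactly.
#'
#' @param outcome Numeric vector: 0/1 for `family = "logistic"`, continuous
#'   for `family = "linear"`.
#' @param categories Factor from [categorize()] (or any factor).
#' @param covariates Optional numeric matrix / data.frame of adjusters.
#' @param family `"logistic"` or `"linear"`.
#' @param reference Reference level; defaults to the factor's `reference`
#'   attribute, else the clinical band `20.0-29.9`.
#' @param ci_level Confidence level.
#' @return `data.frame` with one row per non-reference category: `category`,
#'   `estimate` (OR or beta), `lo`, `hi`, `p`. The fitted model is attached as
#'   attribute `model`.
#' @export
fit_category_model <- function(outcome, categories, covariates = NULL,
                               family = c("logistic", "linear"),
                               reference = NULL, ci_level = 0.95) {
  family <- match.arg(family)
  reference <- reference %||% attr(categories, "reference") %||% "20.0-29.9"
  if (!reference %in% levels(categories)) {
    vd_stop(sprintf("reference category '%s' not present", reference), "vitdmr_config_error")
  }
  cat_f <- stats::relevel(factor(categories, levels = levels(categories)), ref = reference)
  dat <- data.frame(.y = outcome, .cat = cat_f)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
  }
  fml <- stats::as.formula(paste(".y ~ .cat", if (!is.null(covariates)) {
    paste("+", paste(names(covariates), collapse = " + "))
  } else {
    ""
  }))
  fit <- if (family == "logistic") {
    stats::glm(fml, data = dat, family = stats::binomial())
  } else {
    stats::lm(fml, data = dat)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) vd_stop("model design is rank deficient", "vitdmr_rank_error")
  se_all <- sqrt(diag(stats::vcov(fit)))
  if (family == "logistic" && any(abs(cf) > 25 | se_all > 1e3)) {
    vd_stop("separation detected in logistic category model", "vitdmr_separation_error")
  }
  keep <- grep("^\\.cat", names(cf))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  est <- cf[keep]
  se <- se_all[keep]
  out <- data.frame(
    category = sub("^\\.cat", "", names(cf)[keep]),
    estimate = if (family == "logistic") exp(est) else est,
    lo = if (family == "logistic") exp(est - z * se) else est - z * se,
    hi = if (family == "logistic") exp(est + z * se) else est + z * se,
    p = 2 * stats::pnorm(abs(est / se), lower.tail = FALSE),
    row.names = NULL
  )
  attr(out, "model") <- fit
  attr(out, "reference") <- reference
  out
}

#' Fractional-polynomial dose-response fit (observational)
#'
#' Searches all fractional-polynomial bases of the stated degree over the
#' power grid and returns the maximum-likelihood logistic or linear model of
#' the outcome on the transformed exposure (plus covariates). Degree 1 has 8
#' candidate bases, degree 2 has 36 (repeated powers use the log-multiplied
#' basis).
#'
#' @param x Positive exposure values, ng/mL.
#' @param outcome Outcome vector (0/1 or continuous).
#' @param covariates Optional adjusters (matrix / data.frame).
#' @param family `"logistic"` or `"linear"`.
#' @param degree 1 or 2.
#' @param powers Candidate exponent set, default [fp_power_set()].
#' @return Object of class `fp_fit`: `powers` (selected), `coefficients` (the
#'   basis coefficients), `vcov` (their covariance), `logLik`, `family`,
#'   `candidates` (search table), `support` (range of `x`), and the full
#'   fitted `model`.
#' @seealso [fp_curve()] to evaluate the fitted curve against a reference
#'   exposure.
#' @export
fp_dose_response <- function(x, outcome, covariates = NULL,
                             family = c("logistic", "linear"),
                             degree = 2, powers = fp_power_set()) {
  family <- match.arg(family)
  if (any(!is.finite(x)) || any(x <= 0)) {
    vd_stop(
      "fractional polynomials need strictly positive exposures; shift or rescale x first",
      "vitdmr_domain_error"
    )
  }
  if (!degree %in% c(1, 2)) vd_stop("degree must be 1 or 2", "vitdmr_config_error")
  covariates <- if (!is.null(covariates)) as.matrix(covariates)
  cands <- fp_candidates(degree, powers)
  best <- NULL
  ll <- numeric(length(cands))
  for (i in seq_along(cands)) {
    B <- fp_basis(x, cands[[i]])
    X <- cbind(B, covariates)
    dat <- data.frame(.y = outcome, X)
    # extreme candidate bases (e.g. x^3) can push logistic fits to the
    # boundary; such candidates lose the likelihood comparison anyway
    fit <- suppressWarnings(if (family == "logistic") {
      stats::glm(.y ~ ., data = dat, family = stats::binomial())
    } else {
      stats::lm(.y ~ ., data = dat)
    })
    ll[i] <- as.numeric(stats::logLik(fit))
    if (is.null(best) || ll[i] > best$logLik) {
      best <- list(fit = fit, powers = cands[[i]], logLik = ll[i], nbasis = ncol(B))
    }
  }
  cf <- stats::coef(best$fit)
  vc <- stats::vcov(best$fit)
  bi <- 1 + seq_len(best$nbasis) # basis coefficients follow the intercept
  structure(
    list(
      powers = best$powers,
      coefficients = cf[bi],
      vcov = vc[bi, bi, drop = FALSE],
      logLik = best$logLik,
      family = family,
      degree = degree,
      candidates = data.frame(
        powers = vapply(cands, paste, "", collapse = ","),
        logLik = ll
      ),
      support = range(x),
      model = best$fit
    ),
    class = "fp_fit"
  )
}

#' Evaluate a fitted dose-response curve against a reference exposure
#'
#' Returns the fitted curve contrast `lp(x) - lp(reference)` on the linear
#' predictor scale (log-odds for logistic fits) with pointwise delta-method
#' confidence intervals; covariate terms cancel in the contrast.
#'
#' @param fit An `fp_fit` from [fp_dose_response()].
#' @param grid Exposure values at which to evaluate the curve.
#' @param reference Reference exposure, ng/mL (default 20).
#' @param ci_level Confidence level.
#' @param exponentiate If `TRUE` (default for logistic fits) report odds
#'   ratios instead of log-odds differences.
#' @return `data.frame`: `x`, `estimate`, `lo`, `hi`.
#' @export
fp_curve <- function(fit, grid, reference = 20, ci_level = 0.95,
                     exponentiate = fit$family == "logistic") {
  stopifnot(inherits(fit, "fp_fit"))
  Cmat <- fp_basis(grid, fit$powers) -
    matrix(fp_basis(reference, fit$powers), length(grid), length(fit$coefficients), byrow = TRUE)
  est <- drop(Cmat %*% fit$coefficients)
  se <- sqrt(rowSums((Cmat %*% fit$vcov) * Cmat))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- data.frame(x = grid, estimate = est, lo = est - z * se, hi = est + z * se)
  if (exponentiate) out[c("estimate", "lo", "hi")] <- exp(out[c("estimate", "lo", "hi")])
  out
}
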