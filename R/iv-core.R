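#' Ratio-of-coefficients (Wald ratio) instrumental-variable estimate
#'
#' Combines an instrument-outcome coefficient and an instrument-exposure
#' coefficient into the IV ratio `beta_y / beta_x`, with a first-order
#' delta-method standard error
#' `sqrt((se_y^2 + ratio^2 se_x^2 - 2 ratio rho se_x se_y)) / |beta_x|`,
#' which reduces to `se_y / |beta_x|` when `beta_y = 0`. `rho` is the sampling
#' correlation between the two coefficients (0 in the two-sample setting;
#' generally nonzero when both are estimated in one sample).
#'
#' @param beta_y,se_y Instrument-outcome coefficient and SE (log-odds or
#'   outcome units per score unit).
#' @param beta_x,se_x Instrument-exposure coefficient and SE (ng/mL per score
#'   unit).
#' @param rho Sampling correlation between `beta_y` and `beta_x` (default 0).
#' @param ci_level Confidence level.
#' @return List of class `ratio_estimate`: `ratio`, `se`, `lo`, `hi`, `p`,
#'   plus the inputs.
#' @export
ratio_estimate <- function(beta_y, se_y, beta_x, se_x, rho = 0, ci_level = 0.95) {
  if (!is_scalar(beta_x) || beta_x == 0) {
    vd_stop("beta_x is zero: instrument carries no exposure signal (weak instrument)",
      class = "vitdmr_weak_instrument_error"
    )
  }
  if (se_y <= 0 || se_x <= 0) vd_stop("standard errors must be positive", "vitdmr_domain_error")
  beta_y <- unname(beta_y)
  beta_x <- unname(beta_x)
  ratio <- beta_y / beta_x
  v <- (se_y^2 + ratio^2 * se_x^2 - 2 * ratio * rho * se_x * se_y) / beta_x^2
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(
      ratio = ratio, se = se, lo = ratio - z * se, hi = ratio + z * se,
      p = 2 * stats::pnorm(abs(ratio / se), lower.tail = FALSE),
      beta_y = beta_y, se_y = se_y, beta_x = beta_x, se_x = se_x, rho = rho
    ),
    class = "ratio_estimate"
  )
}

#' Instrument-free exposure residuals for collider-safe stratification
#'
#' Regresses the exposure on the instrument (and optional covariates) by
#' least squares and returns the residuals recentred by the overall exposure
#' mean, so the clinical ng/mL cutpoints remain meaningful on the residual
#' scale. Stratifying on these residuals, rather than on the raw exposure,
#' avoids collider bias: raw-exposure strata condition on a common effect of
#' the instrument and the confounders, which distorts the
#' instrument-exposure association within strata.
#'
#' Zero-variance regressors are dropped (an all-constant design returns the
#' exposure unchanged).
#'
#' @param x Exposure, ng/mL.
#' @param z Instrument (allele score).
#' @param covariates Optional adjusters.
#' @return Numeric vector of recentred residuals, same length as `x`.
#' @export
exposure_residuals <- function(x, z, covariates = NULL) {
  D <- cbind(z = z, covariates)
  keep <- apply(D, 2, function(col) stats::var(col) > 0)
  D <- D[, keep, drop = FALSE]
  if (ncol(D) == 0) {
    return(x)
  }
  if (length(x) <= ncol(D) + 1) {
    vd_stop("more regressors than observations", "vitdmr_rank_error")
  }
  X <- cbind(1, D)
  fit <- lm.fit(X, x)
  if (fit$rank < ncol(X)) vd_stop("design matrix is rank deficient", "vitdmr_rank_error")
  fit$residuals + mean(x)
}

#' Assign individuals to exposure strata
#'
#' Two modes: `"quantile"` splits into `K` rank-based strata of near-equal
#' size (within one individual of `n/K`; ties broken by original order), and
#' `"categories"` uses fixed cutpoints (half-open intervals, lower-inclusive)
#' — the 10/20/30 ng/mL clinical bands by default. Empty category bands are
#' dropped with a warning and the remaining strata renumbered consecutively.
#'
#' @param values Values to stratify on (typically residuals from
#'   [exposure_residuals()]).
#' @param mode `"quantile"` or `"categories"`.
#' @param K Number of quantile strata (>= 2).
#' @param cutpoints Cutpoints for category mode.
#' @return Integer vector of stratum ids (1-based, increasing with `values`),
#'   with attributes `mode`, `bounds` (per-stratum value range) and, in
#'   category mode, `dropped` (labels of empty bands).
#' @export
stratify <- function(values, mode = c("quantile", "categories"), K = 10,
                     cutpoints = c(10, 20, 30)) {
  mode <- match.arg(mode)
  n <- length(values)
  if (mode == "quantile") {
    if (!is_count(K) || K < 2) vd_stop("K must be an integer >= 2", "vitdmr_config_error")
    if (K > n) vd_stop("more strata than observations", "vitdmr_config_error")
    ord <- order(values)
    sizes <- diff(round(seq(0, n, length.out = K + 1)))
    out <- integer(n)
    out[ord] <- rep.int(seq_len(K), sizes)
    dropped <- character(0)
  } else {
    if (is.unsorted(cutpoints, strictly = TRUE)) {
      vd_stop("cutpoints must be strictly increasing", "vitdmr_config_error")
    }
    raw <- findInterval(values, cutpoints) + 1L
    present <- sort(unique(raw))
    k <- length(cutpoints)
    labels <- c(
      sprintf("<%.1f", cutpoints[1]),
      if (k > 1) sprintf("%.1f-%.1f", cutpoints[-k], cutpoints[-1] - 0.1),
      sprintf(">=%.1f", cutpoints[k])
    )
    dropped <- labels[setdiff(seq_len(k + 1L), present)]
    if (length(dropped)) {
      warning(
        sprintf("dropping empty stratum band(s): %s", paste(dropped, collapse = ", ")),
        call. = FALSE
      )
    }
    out <- match(raw, present)
  }
  bounds <- t(vapply(
    seq_len(max(out)),
    function(k) range(values[out == k]), numeric(2)
  ))
  colnames(bounds) <- c("lo", "hi")
  structure(out, mode = mode, bounds = bounds, dropped = dropped)
}

#' Per-stratum instrumental-variable (LACE) estimates
#'
#' Within each stratum, estimates the instrument-exposure coefficient
#' (`beta_x`, linear regression of exposure on the allele score plus
#' covariates) and the instrument-outcome coefficient (`beta_y`, logistic or
#' linear regression of the outcome on the score plus covariates), and
#' combines them with [ratio_estimate()] into the stratum's localized average
#' causal effect (LACE). Strata below the size or event floors are excluded
#' with a logged reason; rare-event logistic fits that fail to converge fall
#' back to Firth penalized likelihood (flagged in the output).
#'
#' @param cohort Cohort `data.frame`.
#' @param assignments Stratum ids from [stratify()].
#' @param outcome Outcome column name.
#' @param family `"logistic"` or `"linear"`.
#' @param exposure,instrument Column names (defaults `exposure_ngml`, `grs`).
#' @param covariates Optional character vector of covariate column names.
#' @param min_n,min_events Inclusion floors per stratum (defaults 50 and, for
#'   logistic outcomes, 5 events).
#' @param ci_level Confidence level passed to [ratio_estimate()].
#' @return `data.frame` of class `lace_estimates`, one row per included
#'   stratum: `stratum`, `lo`, `hi` (stratification-value range),
#'   `mean_exposure`, `x_min`, `x_max`, `n`, `events`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y`, `ratio`, `se_ratio`, `firth`. Excluded strata are
#'   recorded in attribute `excluded` (stratum, reason).
#' @export
lace_estimates <- function(cohort, assignments, outcome,
                           family = c("logistic", "linear"),
                           exposure = "exposure_ngml", instrument = "grs",
                           covariates = NULL,
                           min_n = 50, min_events = 5, ci_level = 0.95) {
  family <- match.arg(family)
  for (col in c(outcome, exposure, instrument, covariates)) {
    if (!col %in% names(cohort)) {
      vd_stop(sprintf("column '%s' not found in cohort", col), "vitdmr_config_error")
    }
  }
  x <- cohort[[exposure]]
  z <- cohort[[instrument]]
  y <- cohort[[outcome]]
  covs <- if (!is.null(covariates)) as.matrix(cohort[covariates])
  bounds <- attr(assignments, "bounds")
  ids <- sort(unique(assignments))

  rows <- list()
  excluded <- data.frame(stratum = integer(0), reason = character(0))
  for (k in ids) {
    i <- assignments == k
    nk <- sum(i)
    events <- if (family == "logistic") sum(y[i]) else NA_integer_
    if (nk < min_n) {
      excluded <- rbind(excluded, data.frame(stratum = k, reason = "too_few_individuals"))
      next
    }
    if (family == "logistic" && events < min_events) {
      excluded <- rbind(excluded, data.frame(stratum = k, reason = "too_few_events"))
      next
    }
    ck <- if (!is.null(covs)) covs[i, , drop = FALSE]
    fx <- fit_linear(x[i], z[i], ck)
    fy <- if (family == "logistic") {
      fit_logistic(y[i], z[i], ck)
    } else {
      c(fit_linear(y[i], z[i], ck), firth = FALSE)
    }
    re <- ratio_estimate(fy$beta, fy$se, fx$beta, fx$se, ci_level = ci_level)
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = k,
      lo = if (!is.null(bounds)) bounds[k, "lo"] else min(x[i]),
      hi = if (!is.null(bounds)) bounds[k, "hi"] else max(x[i]),
      mean_exposure = mean(x[i]),
      x_min = min(x[i]), x_max = max(x[i]),
      n = nk, events = events,
      beta_x = fx$beta, se_x = fx$se,
      beta_y = fy$beta, se_y = fy$se,
      ratio = re$ratio, se_ratio = re$se,
      firth = isTRUE(fy$firth)
    )
  }
  if (!length(rows)) {
    vd_stop("no stratum passed the inclusion floors", "vitdmr_stratum_error")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "family") <- family
  class(out) <- c("lace_estimates", "data.frame")
  out
}
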