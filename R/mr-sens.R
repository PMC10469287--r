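#' Per-variant summary statistics for two-sample-style MR estimators
#'
#' For every dosage column, regresses the exposure and the outcome on the
#' dosage (plus optional covariates) and collects the per-variant coefficient
#' pairs that feed the summary-statistic estimators. Monomorphic variants are
#' excluded with a logged reason. All variants are oriented to the
#' exposure-increasing allele (pairs with a negative exposure coefficient
#' have both coefficients sign-flipped), as MR-Egger requires.
#'
#' These are one-sample summary statistics (both regressions from the same
#' cohort); the estimators below ignore the resulting correlation between
#' `beta_x` and `beta_y`, as is conventional when they are applied in a
#' single cohort.
#'
#' @param cohort Cohort `data.frame`.
#' @param outcome Outcome column name.
#' @param family `"logistic"` or `"linear"`.
#' @param exposure Exposure column name.
#' @param dosage_pattern Regular expression selecting dosage columns.
#' @param covariates Optional character vector of covariate columns.
#' @return `data.frame` of class `snv_summary_stats`: `rsid`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`, `flipped`; excluded variants in attribute
#'   `excluded`.
#' @export
snv_summary_stats <- function(cohort, outcome, family = c("logistic", "linear"),
                              exposure = "exposure_ngml",
                              dosage_pattern = "^g_", covariates = NULL) {
  family <- match.arg(family)
  cols <- grep(dosage_pattern, names(cohort), value = TRUE)
  if (!length(cols)) vd_stop("no dosage columns match the pattern", "vitdmr_config_error")
  x <- cohort[[exposure]]
  y <- cohort[[outcome]]
  covs <- if (!is.null(covariates)) as.matrix(cohort[covariates])
  rows <- list()
  excluded <- data.frame(rsid = character(0), reason = character(0))
  for (col in cols) {
    g <- cohort[[col]]
    if (stats::var(g) == 0) {
      excluded <- rbind(excluded, data.frame(rsid = col, reason = "monomorphic"))
      next
    }
    fx <- fit_linear(x, g, covs)
    fy <- if (family == "logistic") fit_logistic(y, g, covs) else fit_linear(y, g, covs)
    flip <- fx$beta < 0
    s <- if (flip) -1 else 1
    rows[[length(rows) + 1L]] <- data.frame(
      rsid = col,
      beta_x = s * fx$beta, se_x = fx$se,
      beta_y = s * fy$beta, se_y = fy$se,
      flipped = flip
    )
  }
  if (!length(rows)) vd_stop("all variants are monomorphic", "vitdmr_config_error")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("snv_summary_stats", "data.frame")
  out
}

check_ss <- function(ss, min_snvs, method) {
  if (nrow(ss) < min_snvs) {
    vd_stop(
      sprintf("%s needs at least %d variants (got %d)", method, min_snvs, nrow(ss)),
      "vitdmr_identification_error"
    )
  }
  if (any(ss$se_x <= 0) || any(ss$se_y <= 0)) {
    vd_stop("standard errors must be positive", "vitdmr_domain_error")
  }
}

#' Inverse-variance-weighted estimate
#'
#' Pools the per-variant Wald ratios with weights `beta_x^2 / se_y^2` —
#' equivalently, the weighted regression of `beta_y` on `beta_x` through the
#' origin with weights `1/se_y^2`. Under the multiplicative random-effects
#' model the standard error is inflated by `sqrt(Q/(J-1))` when the Cochran Q
#' exceeds its degrees of freedom.
#'
#' @param ss An `snv_summary_stats` table.
#' @param model `"random"` (default) or `"fixed"`.
#' @param ci_level Confidence level.
#' @return List of class `mr_result`: `method`, `estimate`, `se`, `lo`, `hi`,
#'   `p`, `q`, `q_df`, `n_snvs`.
#' @export
ivw <- function(ss, model = c("random", "fixed"), ci_level = 0.95) {
  model <- match.arg(model)
  check_ss(ss, if (model == "random") 2 else 1, "IVW")
  if (all(ss$beta_x == 0)) vd_stop("all exposure coefficients are zero", "vitdmr_weak_instrument_error")
  w <- 1 / ss$se_y^2
  est <- sum(w * ss$beta_x * ss$beta_y) / sum(w * ss$beta_x^2)
  se <- sqrt(1 / sum(w * ss$beta_x^2))
  q <- sum(w * (ss$beta_y - est * ss$beta_x)^2)
  df <- nrow(ss) - 1
  if (model == "random" && df > 0) se <- se * max(1, sqrt(q / df))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(
      method = paste0("ivw_", model), estimate = est, se = se,
      lo = est - z * se, hi = est + z * se,
      p = 2 * stats::pnorm(abs(est / se), lower.tail = FALSE),
      q = q, q_df = df, n_snvs = nrow(ss)
    ),
    class = "mr_result"
  )
}

# 50th percentile of the weighted empirical ratio distribution with linear
# interpolation between bracketing ratios
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) {
    return(r[1])
  }
  if (0.5 >= p[length(p)]) {
    return(r[length(r)])
  }
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The value at the 50th percentile of the inverse-variance-weighted
#' empirical distribution of the per-variant Wald ratios (weights
#' `beta_x^2/se_y^2`, linear interpolation between bracketing ratios).
#' Consistent when at least half of the total weight comes from valid
#' instruments. The standard error is obtained by parametric resampling of
#' the per-variant coefficients from their sampling distributions.
#'
#' @param ss An `snv_summary_stats` table (>= 3 variants).
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed for the resampling.
#' @param ci_level Confidence level.
#' @return List of class `mr_result`.
#' @export
weighted_median <- function(ss, n_boot = 1000, seed = 1, ci_level = 0.95) {
  check_ss(ss, 3, "weighted median")
  w <- ss$beta_x^2 / ss$se_y^2
  est <- weighted_median_point(ss$beta_y / ss$beta_x, w)
  J <- nrow(ss)
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(J, ss$beta_x, ss$se_x)
    by <- stats::rnorm(J, ss$beta_y, ss$se_y)
    weighted_median_point(by / bx, bx^2 / ss$se_y^2)
  }, 0)
  se <- stats::sd(boot)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(
      method = "weighted_median", estimate = est, se = se,
      lo = est - z * se, hi = est + z * se,
      p = 2 * stats::pnorm(abs(est / se), lower.tail = FALSE),
      n_snvs = J, n_boot = n_boot
    ),
    class = "mr_result"
  )
}

#' MR-Egger regression
#'
#' Inverse-variance-weighted regression of the outcome coefficients on the
#' exposure coefficients *with* an intercept, after orienting all variants to
#' the exposure-increasing allele. The slope is the pleiotropy-adjusted
#' causal estimate; a nonzero intercept indicates directional pleiotropy.
#' Standard errors carry the multiplicative overdispersion factor
#' `max(1, sqrt(RSS/(J-2)))`; tests use the t distribution with `J - 2`
#' degrees of freedom.
#'
#' @param ss An `snv_summary_stats` table (>= 3 variants).
#' @param ci_level Confidence level.
#' @return List of class `mr_egger`: slope (`estimate`, `se`, `lo`, `hi`,
#'   `p`) and intercept (`intercept`, `intercept_se`, `intercept_lo`,
#'   `intercept_hi`, `intercept_p`).
#' @export
mr_egger <- function(ss, ci_level = 0.95) {
  check_ss(ss, 3, "MR-Egger")
  s <- ifelse(ss$beta_x < 0, -1, 1) # defensive: orientation should already hold
  bx <- s * ss$beta_x
  by <- s * ss$beta_y
  w <- 1 / ss$se_y^2
  fit <- wls(cbind(1, bx), by, w)
  if (is.null(fit)) vd_stop("Egger design is singular", "vitdmr_rank_error")
  J <- nrow(ss)
  disp <- max(1, sqrt(fit$rssw / (J - 2)))
  se <- sqrt(diag(fit$vcov)) * disp
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = J - 2)
  pv <- 2 * stats::pt(abs(fit$beta / se), df = J - 2, lower.tail = FALSE)
  structure(
    list(
      method = "mr_egger",
      estimate = fit$beta[2], se = se[2],
      lo = fit$beta[2] - tq * se[2], hi = fit$beta[2] + tq * se[2], p = pv[2],
      intercept = fit$beta[1], intercept_se = se[1],
      intercept_lo = fit$beta[1] - tq * se[1], intercept_hi = fit$beta[1] + tq * se[1],
      intercept_p = pv[1],
      overdispersion = disp, n_snvs = J
    ),
    class = c("mr_egger", "mr_result")
  )
}

ivw_fixed_est <- function(bx, by, sey) {
  w <- 1 / sey^2
  sum(w * bx * by) / sum(w * bx^2)
}

#' MR-PRESSO: global, outlier and distortion tests
#'
#' Simulation-based pleiotropy diagnostics. The *global* test compares the
#' observed leave-one-out weighted residual sum of squares of the IVW fit
#' with its null distribution, obtained by re-drawing each variant's
#' coefficients from their sampling distributions under the fitted
#' no-pleiotropy model. The *outlier* test compares each variant's observed
#' residual contribution with its simulated distribution, Bonferroni-adjusted
#' across variants. The *distortion* test asks whether removing the flagged
#' outliers changes the IVW estimate more than removing randomly chosen
#' non-outlier sets of the same size.
#'
#' @param ss An `snv_summary_stats` table (>= 4 variants).
#' @param n_sim Number of simulated null datasets (>= 100; p-value resolution
#'   is `1/n_sim`).
#' @param alpha Significance level for the outlier test (Bonferroni-adjusted
#'   to `alpha / J` per variant).
#' @param seed Integer seed.
#' @return List of class `mr_presso`: `global_stat`, `global_p`,
#'   `outlier_p` (per variant), `outlier_indices`, `distortion_coef`,
#'   `distortion_p`, `raw` and `corrected` IVW estimates. With no flagged
#'   outliers the corrected estimate equals the raw one exactly.
#' @export
mr_presso <- function(ss, n_sim = 1000, alpha = 0.05, seed = 1) {
  check_ss(ss, 4, "MR-PRESSO")
  if (n_sim < 100) {
    vd_stop("n_sim below 100 gives unstable p-values; refusing", "vitdmr_config_error")
  }
  J <- nrow(ss)
  if (1 / (1 + n_sim) >= alpha / J) {
    message(sprintf(
      "mr_presso: n_sim = %d cannot resolve the Bonferroni outlier threshold %.2g/%d; no variant can be flagged (outlier detection needs n_sim > %d)",
      n_sim, alpha, J, ceiling(J / alpha)
    ))
  }
  bx <- ss$beta_x
  by <- ss$beta_y
  w <- 1 / ss$se_y^2
  Sxx <- sum(w * bx^2)
  Sxy <- sum(w * bx * by)
  b_loo <- (Sxy - w * bx * by) / (Sxx - w * bx^2)
  res_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res_obs)

  set.seed(as.integer(seed))
  BX <- matrix(stats::rnorm(n_sim * J, rep(bx, each = n_sim), rep(ss$se_x, each = n_sim)), n_sim, J)
  BY <- matrix(stats::rnorm(n_sim * J, rep(b_loo * bx, each = n_sim), rep(ss$se_y, each = n_sim)), n_sim, J)
  W <- matrix(w, n_sim, J, byrow = TRUE)
  Sxx_s <- rowSums(W * BX^2)
  Sxy_s <- rowSums(W * BX * BY)
  BLOO <- (Sxy_s - W * BX * BY) / (Sxx_s - W * BX^2)
  RES <- W * (BY - BLOO * BX)^2
  rss_sim <- rowSums(RES)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)
  outlier_p <- vapply(
    seq_len(J),
    function(j) (1 + sum(RES[, j] >= res_obs[j])) / (1 + n_sim), 0
  )
  flagged <- which(outlier_p < alpha / J)

  raw <- ivw_fixed_est(bx, by, ss$se_y)
  corrected <- if (length(flagged) && length(flagged) < J - 1) {
    ivw_fixed_est(bx[-flagged], by[-flagged], ss$se_y[-flagged])
  } else {
    raw
  }
  distortion_coef <- distortion_p <- NA_real_
  if (length(flagged) && length(flagged) < J - 1) {
    distortion_coef <- 100 * (raw - corrected) / abs(corrected)
    inliers <- setdiff(seq_len(J), flagged)
    d_sim <- vapply(seq_len(n_sim), function(i) {
      drop_set <- sample(inliers, length(flagged), replace = length(flagged) > length(inliers))
      keep <- setdiff(seq_len(J), drop_set)
      b <- ivw_fixed_est(bx[keep], by[keep], ss$se_y[keep])
      100 * (raw - b) / abs(b)
    }, 0)
    distortion_p <- (1 + sum(abs(d_sim) >= abs(distortion_coef))) / (1 + n_sim)
  }
  structure(
    list(
      method = "mr_presso",
      global_stat = rss_obs, global_p = global_p,
      outlier_p = outlier_p, outlier_indices = flagged,
      distortion_coef = distortion_coef, distortion_p = distortion_p,
      raw = raw, corrected = corrected,
      n_sim = n_sim, alpha = alpha, n_snvs = J
    ),
    class = "mr_presso"
  )
}

#' Radial MR with modified second-order weights
#'
#' Radial (Galbraith) reformulation of IVW: the per-variant Wald ratios are
#' regressed through the origin after scaling by the square root of their
#' weights, so each variant contributes a chi-square(1) distance `Q_j` to the
#' total heterogeneity. *Modified second-order* weights account for
#' uncertainty in both coefficient estimates,
#' `w_j = 1 / (se_y^2/beta_x^2 + beta^2 se_x^2 / beta_x^2)`, with the causal
#' estimate `beta` updated iteratively (first-order IVW start, iteration cap
#' 10). Variants whose `Q_j` exceeds the chi-square(1) critical value at
#' `alpha` are flagged and removed one at a time (largest contribution first;
#' ties broken toward the lower index) and the model refitted until no new
#' flags appear.
#'
#' @param ss An `snv_summary_stats` table (>= 3 variants).
#' @param weights `"modified_second_order"` (default), `"second_order"`, or
#'   `"first_order"`. With first-order weights the radial slope equals the
#'   fixed-effect IVW estimate exactly.
#' @param alpha Significance level for flagging outliers.
#' @param max_iter Cap on the weight-update iterations.
#' @param ci_level Confidence level.
#' @return List of class `radial_mr`: `estimate` (after outlier removal),
#'   `se`, `lo`, `hi`, `p`, `initial_estimate` (all variants), `q_total`,
#'   `q_contributions` (all variants, from the initial fit; sums exactly to
#'   `q_total`), `outlier_indices`, `converged`, `iterations`.
#' @export
radial_mr <- function(ss, weights = c("modified_second_order", "second_order", "first_order"),
                      alpha = 0.05, max_iter = 10, ci_level = 0.95) {
  weights <- match.arg(weights)
  check_ss(ss, 3, "radial MR")
  ratio <- ss$beta_y / ss$beta_x

  radial_fit <- function(idx) {
    bx <- ss$beta_x[idx]
    sey <- ss$se_y[idx]
    sex <- ss$se_x[idx]
    r <- ratio[idx]
    beta <- ivw_fixed_est(bx, ss$beta_y[idx], sey) # first-order start
    w <- bx^2 / sey^2
    converged <- TRUE
    iters <- 0L
    if (weights == "second_order") {
      w <- 1 / (sey^2 / bx^2 + r^2 * sex^2 / bx^2)
      beta <- sum(w * r) / sum(w)
    } else if (weights == "modified_second_order") {
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        iters <- it
        w <- 1 / (sey^2 / bx^2 + beta^2 * sex^2 / bx^2)
        beta_new <- sum(w * r) / sum(w)
        if (abs(beta_new - beta) < 1e-12) {
          beta <- beta_new
          converged <- TRUE
          break
        }
        beta <- beta_new
      }
      if (!converged) {
        warning("modified second-order weights did not converge within the iteration cap; returning last iterate",
          call. = FALSE
        )
      }
    }
    list(
      beta = beta, w = w, q = w * (r - beta)^2,
      se = 1 / sqrt(sum(w)), converged = converged, iterations = iters
    )
  }

  full <- radial_fit(seq_len(nrow(ss)))
  crit <- stats::qchisq(1 - alpha, df = 1)
  active <- seq_len(nrow(ss))
  outliers <- integer(0)
  fit <- full
  repeat {
    qi <- fit$q
    if (max(qi) <= crit || length(active) <= 3) break
    worst <- active[which.max(qi)] # which.max takes the first (lowest index) on ties
    outliers <- c(outliers, worst)
    active <- setdiff(active, worst)
    fit <- radial_fit(active)
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(
      method = paste0("radial_", weights),
      estimate = fit$beta, se = fit$se,
      lo = fit$beta - z * fit$se, hi = fit$beta + z * fit$se,
      p = 2 * stats::pnorm(abs(fit$beta / fit$se), lower.tail = FALSE),
      initial_estimate = full$beta,
      q_total = sum(full$q), q_contributions = full$q,
      outlier_indices = sort(outliers),
      converged = full$converged, iterations = full$iterations,
      n_snvs = nrow(ss)
    ),
    class = "radial_mr"
  )
}
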