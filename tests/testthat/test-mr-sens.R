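test_that("per-variant summary statistics behave under duplication and exclusion", {
  ch <- quick_cohort(n = 2000, seed = 20, n_snvs = 8)
  ss <- snv_summary_stats(ch, "y_grip", family = "linear")
  expect_identical(nrow(ss), 8L)
  expect_true(all(ss$beta_x >= 0)) # oriented to the exposure-increasing allele

  # duplicating every row: identical estimates, SEs shrink by ~sqrt(2)
  ch2 <- rbind(ch, ch)
  class(ch2) <- class(ch)
  ss2 <- snv_summary_stats(ch2, "y_grip", family = "linear")
  expect_equal(ss2$beta_x, ss$beta_x, tolerance = 1e-10)
  expect_equal(ss2$se_x / ss$se_x, rep(1 / sqrt(2), 8), tolerance = 0.002)

  # monomorphic variant excluded with a reason
  ch$g_0003 <- 0L
  ss3 <- snv_summary_stats(ch, "y_grip", family = "linear")
  expect_identical(nrow(ss3), 7L)
  expect_identical(attr(ss3, "excluded")$rsid, "g_0003")
})

test_that("outcome z-scores are standard normal under the null", {
  z <- unlist(lapply(1:20, function(i) {
    ch <- quick_cohort(n = 1500, kind = "null", seed = 600 + i, n_snvs = 10)
    ss <- snv_summary_stats(ch, "y_grip", family = "linear")
    ss$beta_y / ss$se_y * ifelse(ss$flipped, -1, 1)
  }))
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("IVW reduces to the Wald ratio and matches a WLS-through-origin oracle", {
  one <- make_ss(J = 3)[1, ]
  class(one) <- c("snv_summary_stats", "data.frame")
  r <- ivw(one, model = "fixed")
  expect_equal(r$estimate, one$beta_y / one$beta_x, tolerance = 1e-12)

  # identical variants: estimate unchanged, SE shrinks by sqrt(J)
  same <- make_ss(J = 5)
  same[, c("beta_x", "beta_y", "se_x", "se_y")] <-
    same[rep(1, 5), c("beta_x", "beta_y", "se_x", "se_y")]
  r5 <- ivw(same, model = "fixed")
  expect_equal(r5$estimate, same$beta_y[1] / same$beta_x[1], tolerance = 1e-12)
  expect_equal(r5$se, ivw(same[c(1, 2), ], model = "fixed")$se * sqrt(2) / sqrt(5), tolerance = 1e-10)

  # 5-variant fixture vs stats::lm weighted regression through the origin
  ss <- make_ss(J = 5, slope = 0.3, noise = 0.05, seed = 2)
  fit <- lm(beta_y ~ beta_x - 1, data = ss, weights = 1 / ss$se_y^2)
  expect_equal(ivw(ss, model = "fixed")$estimate, unname(coef(fit)), tolerance = 1e-10)
  zero <- make_ss(J = 2)
  zero$beta_x <- 0
  expect_error(ivw(zero), class = "vitdmr_weak_instrument_error")
})

test_that("weighted median interpolates the weighted ratio distribution", {
  # all ratios identical
  ss <- make_ss(J = 4, slope = 0.7)
  expect_equal(weighted_median(ss, n_boot = 50, seed = 1)$estimate, 0.7, tolerance = 1e-12)

  # 3 variants, weights 1/1/2, ratios 1/2/3: brute-force cumulative oracle = 7/3
  ss3 <- data.frame(
    rsid = c("a", "b", "c"),
    beta_x = c(1, 1, sqrt(2)), se_x = 0.01,
    beta_y = c(1, 2, 3 * sqrt(2)), se_y = 1,
    flipped = FALSE
  )
  class(ss3) <- c("snv_summary_stats", "data.frame")
  # weights bx^2/se_y^2 = 1, 1, 2; ratios 1, 2, 3
  expect_equal(weighted_median(ss3, n_boot = 50, seed = 1)$estimate, 7 / 3, tolerance = 1e-12)

  expect_error(weighted_median(make_ss(J = 2)), class = "vitdmr_identification_error")
})

test_that("weighted median resists pleiotropy in half the variants where IVW breaks", {
  # half the variants are pleiotropic, but the valid half are the stronger
  # instruments, so a clear majority of the *weight* is valid — the stated
  # consistency condition of the estimator
  J <- 20
  theta <- 0.05
  set.seed(700)
  bx0 <- c(runif(10, 0.7, 1), runif(10, 0.3, 0.5))
  ok_med <- ok_ivw_biased <- logical(50)
  for (i in 1:50) {
    pl <- c(rep(0, 10), rep(0.4, 10))
    ss <- draw_ss(J = J, theta = theta, pleiotropy = pl, seed = 700 + i, bx0 = bx0)
    med <- weighted_median(ss, n_boot = 100, seed = i)
    iv <- ivw(ss, model = "fixed")
    ok_med[i] <- abs(med$estimate - theta) < 2 * med$se
    ok_ivw_biased[i] <- abs(iv$estimate - theta) > 2 * iv$se
  }
  expect_gte(mean(ok_med), 0.7)
  expect_gte(mean(ok_ivw_biased), 0.9)
})

test_that("Egger regression is exact on a line and matches a weighted lm oracle", {
  # exact line with intercept: recovered to machine precision
  ss <- make_ss(J = 6, slope = 0.4, intercept = 0.02)
  eg <- mr_egger(ss)
  expect_equal(eg$estimate, 0.4, tolerance = 1e-12)
  expect_equal(eg$intercept, 0.02, tolerance = 1e-12)

  # noisy 6-variant fixture vs stats::lm with weights
  ss2 <- make_ss(J = 6, slope = 0.4, intercept = 0.02, noise = 0.05, seed = 3)
  eg2 <- mr_egger(ss2)
  fit <- lm(beta_y ~ beta_x, data = ss2, weights = 1 / ss2$se_y^2)
  expect_equal(eg2$estimate, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(eg2$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  # overdispersion-scaled SEs: lm's sigma-rescaled SEs times max(1, sigma)/sigma
  sm <- summary(fit)
  expect_equal(eg2$se, unname(sm$coefficients[2, 2] / sm$sigma * max(1, sm$sigma)),
    tolerance = 1e-8
  )
  expect_error(mr_egger(make_ss(J = 2)), class = "vitdmr_identification_error")
})

test_that("Egger intercept test is calibrated under balanced pleiotropy", {
  reject <- vapply(1:500, function(i) {
    J <- 35
    set.seed(800 + i)
    pl <- rnorm(J, 0, 0.05) # balanced: mean-zero direct effects
    ss <- draw_ss(J = J, theta = 0.05, pleiotropy = pl, seed = 800 + i)
    mr_egger(ss)$intercept_p < 0.05
  }, NA)
  expect_gte(mean(reject), 0.02)
  expect_lte(mean(reject), 0.09)
})

test_that("MR-PRESSO flags an injected pleiotropic variant and is a no-op when clean", {
  # outlier-free data on an exact line: corrected estimate equals raw IVW exactly
  ss <- make_ss(J = 6, slope = 0.3)
  pr <- mr_presso(ss, n_sim = 200, seed = 1)
  expect_identical(pr$outlier_indices, integer(0))
  expect_identical(pr$corrected, pr$raw)

  expect_error(mr_presso(ss, n_sim = 50), "unstable")

  # a 5-SE direct effect on one variant is detected
  hits <- vapply(1:20, function(i) {
    ss <- draw_ss(J = 20, theta = 0.05, seed = 900 + i)
    ss$beta_y[7] <- ss$beta_y[7] + 5 * ss$se_y[7]
    7 %in% mr_presso(ss, n_sim = 500, seed = i)$outlier_indices
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("MR-PRESSO global p is roughly uniform under the no-pleiotropy null", {
  ps <- vapply(1:100, function(i) {
    ss <- draw_ss(J = 20, theta = 0.05, seed = 1000 + i)
    mr_presso(ss, n_sim = 300, seed = i)$global_p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("radial MR bookkeeping, first-order equivalence, and specificity hold", {
  ss <- draw_ss(J = 15, theta = 0.05, seed = 21)
  rad <- radial_mr(ss)
  expect_equal(rad$q_total, sum(rad$q_contributions), tolerance = 1e-12)
  expect_true(rad$converged)

  # first-order weights reproduce fixed-effect IVW exactly
  r1 <- radial_mr(ss, weights = "first_order")
  expect_equal(r1$initial_estimate, ivw(ss, model = "fixed")$estimate, tolerance = 1e-10)

  # homogeneous data: no flags at the Bonferroni level in most replicates
  flags <- vapply(1:30, function(i) {
    ss <- draw_ss(J = 20, theta = 0.05, seed = 1100 + i)
    length(radial_mr(ss, alpha = 0.05 / 20)$outlier_indices) == 0
  }, NA)
  expect_gte(mean(flags), 0.9)

  # an injected outlier is flagged and excluded from the final estimate
  ss2 <- draw_ss(J = 20, theta = 0.05, seed = 22)
  ss2$beta_y[5] <- ss2$beta_y[5] + 6 * ss2$se_y[5]
  r2 <- radial_mr(ss2)
  expect_true(5 %in% r2$outlier_indices)
})

test_that("estimators concord on a clean cohort-level simulation", {
  ch <- quick_cohort(
    n = 50000, kind = "linear", seed = 23,
    causal_params = list(slope = -0.03), outcome_prevalence = 0.1
  )
  ss <- snv_summary_stats(ch, "y_sarcopenia", family = "logistic")
  truth <- -0.03
  for (r in list(
    ivw(ss),
    weighted_median(ss, n_boot = 300, seed = 1),
    mr_egger(ss),
    radial_mr(ss)
  )) {
    expect_lt(abs(r$estimate - truth), 2.5 * r$se)
  }
  # outlier exclusion barely moves the IVW estimate on clean data
  pr <- mr_presso(ss, n_sim = 300, seed = 2)
  expect_lt(abs(pr$corrected - pr$raw), 0.5 * ivw(ss)$se)
})
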