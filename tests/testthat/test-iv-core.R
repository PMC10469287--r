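test_that("ratio estimate has the delta-method closed forms", {
  # zero numerator: se reduces to se_y / |beta_x|
  r0 <- ratio_estimate(0, 0.1, 0.5, 0.2)
  expect_equal(r0$ratio, 0)
  expect_equal(r0$se, 0.2)

  # scale invariance of the point estimate
  r1 <- ratio_estimate(0.3, 0.1, 0.6, 0.05)
  r2 <- ratio_estimate(0.6, 0.1, 1.2, 0.05)
  expect_equal(r1$ratio, r2$ratio)

  # identity ratio * beta_x = beta_y
  expect_equal(r1$ratio * 0.6, 0.3, tolerance = 1e-15)

  expect_error(ratio_estimate(0.3, 0.1, 0, 0.05), class = "vitdmr_weak_instrument_error")
  expect_error(ratio_estimate(0.3, -0.1, 0.5, 0.05), class = "vitdmr_domain_error")
})

test_that("delta-method ratio SE matches a Monte-Carlo oracle at moderate strength", {
  set.seed(11)
  beta_y <- 0.4
  se_y <- 0.05
  beta_x <- 1
  se_x <- 0.1
  r <- ratio_estimate(beta_y, se_y, beta_x, se_x)
  draws <- rnorm(1e5, beta_y, se_y) / rnorm(1e5, beta_x, se_x)
  expect_lt(abs(r$se / sd(draws) - 1), 0.05)
})

test_that("ratio estimate agrees with two-stage least squares for one instrument", {
  ch <- quick_cohort(n = 20000, kind = "linear", seed = 12)
  x <- ch$exposure_ngml
  z <- ch$grs
  y <- ch$y_grip
  bx <- lm(x ~ z)
  by <- lm(y ~ z)
  r <- ratio_estimate(
    coef(by)[2], summary(by)$coefficients[2, 2],
    coef(bx)[2], summary(bx)$coefficients[2, 2]
  )
  tsls <- cov(z, y) / cov(z, x) # single-instrument 2SLS closed form
  expect_equal(r$ratio, tsls, tolerance = 1e-6)
})

test_that("exposure residuals are instrument-free and recentred", {
  ch <- quick_cohort(n = 5000, seed = 13)
  res <- exposure_residuals(ch$exposure_ngml, ch$grs)
  expect_lt(abs(cov(res, ch$grs)), 1e-10)
  expect_equal(mean(res), mean(ch$exposure_ngml), tolerance = 1e-9)

  # degenerate regression: zero-variance instrument returns x unchanged
  expect_equal(exposure_residuals(ch$exposure_ngml, rep(1, 5000)), ch$exposure_ngml)

  expect_error(
    exposure_residuals(ch$exposure_ngml, ch$grs, cbind(ch$grs, 2 * ch$grs)),
    class = "vitdmr_rank_error"
  )
})

test_that("quantile stratification splits ranks into near-equal strata", {
  v <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10)
  s <- stratify(v, "quantile", K = 2)
  expect_identical(as.integer(s)[order(v)], rep(1:2, each = 5))

  # quantile boundaries equal a sort-based order-statistics oracle
  set.seed(14)
  v2 <- rnorm(1000)
  s2 <- stratify(v2, "quantile", K = 7)
  srt <- sort(v2)
  sizes <- diff(round(seq(0, 1000, length.out = 8)))
  oracle <- rep(1:7, sizes)
  expect_identical(as.integer(s2)[order(v2)], oracle)
  expect_true(all(abs(tabulate(s2) - 1000 / 7) <= 1))

  # every individual assigned exactly once
  expect_identical(length(s2), 1000L)
  expect_false(anyNA(s2))
})

test_that("category stratification drops empty bands with a warning", {
  v <- runif(50, 12, 18) # all in the 10-20 band
  expect_warning(s <- stratify(v, "categories"), "empty stratum")
  expect_identical(max(s), 1L)
  expect_identical(attr(s, "dropped"), c("<10.0", "20.0-29.9", ">=30.0"))
})

test_that("stratum LACEs are deterministic and respect inclusion floors", {
  ch <- quick_cohort(n = 4000, seed = 15)
  res <- exposure_residuals(ch$exposure_ngml, ch$grs)
  s <- stratify(res, "quantile", K = 4)
  lace <- lace_estimates(ch, s, "y_sarcopenia", min_events = 2)
  expect_s3_class(lace, "lace_estimates")
  expect_true(all(diff(lace$mean_exposure) > 0))
  expect_equal(lace$ratio * lace$beta_x, lace$beta_y, tolerance = 1e-12)

  # duplicated data: two identical strata give identical LACEs
  ch2 <- rbind(ch, ch)
  s2 <- c(rep(1L, nrow(ch)), rep(2L, nrow(ch)))
  lace2 <- lace_estimates(ch2, s2, "y_sarcopenia", min_events = 2)
  expect_equal(lace2$ratio[1], lace2$ratio[2], tolerance = 1e-12)
  expect_equal(lace2$se_ratio[1], lace2$se_ratio[2], tolerance = 1e-12)

  # floors: a tiny stratum is excluded with a logged reason
  s3 <- s
  idx1 <- which(s == 1)
  s3[idx1[-(1:10)]] <- 2L # leave stratum 1 with only 10 individuals
  lace3 <- lace_estimates(ch, s3, "y_sarcopenia", min_events = 2)
  excl <- attr(lace3, "excluded")
  expect_true(1 %in% excl$stratum)
  expect_match(excl$reason[excl$stratum == 1], "too_few")
})

test_that("LACEs are homogeneous under a linear truth and cover zero under the null", {
  q_ps <- numeric(10)
  cover <- logical(0)
  for (i in 1:10) {
    ch <- quick_cohort(
      n = 20000, kind = "linear", seed = 100 + i,
      causal_params = list(slope = -0.03), outcome_prevalence = 0.1
    )
    r <- nlmr_analysis(ch, "y_sarcopenia", K = 5, min_events = 3)
    q_ps[i] <- r$tests$q_p
  }
  expect_gte(mean(q_ps > 0.05), 0.8)
  for (i in 1:10) {
    ch <- quick_cohort(n = 20000, kind = "null", seed = 200 + i, outcome_prevalence = 0.1)
    r <- nlmr_analysis(ch, "y_sarcopenia", K = 5, min_events = 3)
    cover <- c(cover, r$strata$ratio - 1.96 * r$strata$se_ratio < 0 &
      r$strata$ratio + 1.96 * r$strata$se_ratio > 0)
  }
  expect_gt(mean(cover), 0.85)
})

test_that("residual strata keep the instrument-exposure slope homogeneous where raw strata do not", {
  hom_resid <- hom_raw <- logical(10)
  for (i in 1:10) {
    ch <- quick_cohort(n = 30000, kind = "null", seed = 300 + i)
    res <- exposure_residuals(ch$exposure_ngml, ch$grs)
    for (mode_raw in c(FALSE, TRUE)) {
      v <- if (mode_raw) ch$exposure_ngml else res
      s <- stratify(v, "quantile", K = 5)
      bx <- se <- numeric(5)
      for (k in 1:5) {
        f <- lm(ch$exposure_ngml[s == k] ~ ch$grs[s == k])
        bx[k] <- coef(f)[2]
        se[k] <- summary(f)$coefficients[2, 2]
      }
      w <- 1 / se^2
      q <- sum(w * (bx - sum(w * bx) / sum(w))^2)
      p <- pchisq(q, 4, lower.tail = FALSE)
      if (mode_raw) hom_raw[i] <- p > 0.05 else hom_resid[i] <- p > 0.05
    }
  }
  expect_gte(mean(hom_resid), 0.8) # residual strata: homogeneous
  expect_lte(mean(hom_raw), 0.2) # raw strata: collider-distorted
})
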