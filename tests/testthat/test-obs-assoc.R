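test_that("exposure categories are half-open with boundaries belonging upward", {
  x <- c(9.999, 10, 19.95, 20, 29.999, 30, 45)
  f <- categorize(x)
  expect_identical(
    as.character(f),
    c("<10.0", "10.0-19.9", "10.0-19.9", "20.0-29.9", "20.0-29.9", ">=30.0", ">=30.0")
  )
  expect_identical(attr(f, "reference"), "20.0-29.9")
  expect_error(categorize(c(-1, 5)), class = "vitdmr_domain_error")
  expect_error(categorize(5, cutpoints = c(10, 10)), class = "vitdmr_config_error")
})

test_that("crude odds ratio matches the Woolf formula computed independently", {
  o <- contingency_or(84, 29887, 107, 79432)
  # independent in-test computation of the cross-product OR and Woolf CI
  a <- 84
  b <- 29887 - 84
  c <- 107
  d <- 79432 - 107
  expect_equal(o$or, (a * d) / (b * c), tolerance = 1e-12)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  expect_equal(o$lo, exp(log(o$or) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(o$hi, exp(log(o$or) + qnorm(0.975) * se), tolerance = 1e-12)

  # equal risks in both arms: OR exactly 1
  eq <- contingency_or(10, 100, 20, 200)
  expect_equal(eq$or, 1)

  # log-scale symmetry of the Woolf interval
  expect_equal(log(o$lo) + log(o$hi), 2 * log(o$or), tolerance = 1e-12)

  expect_error(contingency_or(0, 100, 5, 100), class = "vitdmr_zero_cell_error")
})

test_that("unadjusted logistic category model reproduces the 2x2 cross-product OR", {
  counts <- sarcopenia_category_counts()
  # reconstruct individual-level data from the printed counts
  y <- unlist(mapply(
    function(n, e) c(rep(1, e), rep(0, n - e)),
    counts$n, counts$events,
    SIMPLIFY = FALSE
  ))
  cat_v <- factor(
    rep(counts$category, counts$n),
    levels = c("<10.0", "10.0-19.9", "20.0-29.9", ">=30.0")
  )
  fit <- fit_category_model(y, cat_v, family = "logistic", reference = "20.0-29.9")
  for (lv in c("<10.0", "10.0-19.9", ">=30.0")) {
    o <- contingency_or(
      counts$events[counts$category == lv], counts$n[counts$category == lv],
      107, 79432
    )
    est <- fit$estimate[fit$category == lv]
    expect_equal(est, o$or, tolerance = 1e-6)
  }
})

test_that("category coefficients are invariant to an orthogonal covariate (linear model)", {
  set.seed(4)
  n <- 2000
  cat_v <- categorize(runif(n, 1, 45))
  y <- rnorm(n) + 0.3 * (as.integer(cat_v) == 1)
  base <- fit_category_model(y, cat_v, family = "linear")
  # residualize a random covariate against the category dummies and outcome
  mm <- model.matrix(~cat_v)
  w <- rnorm(n)
  w_orth <- resid(lm(w ~ mm + y))
  adj <- fit_category_model(y, cat_v, covariates = data.frame(w = w_orth), family = "linear")
  expect_equal(adj$estimate, base$estimate, tolerance = 1e-8)
})

test_that("category-model CIs achieve nominal coverage under independence", {
  set.seed(5)
  n <- 4000
  cover <- vapply(1:200, function(i) {
    cat_v <- categorize(runif(n, 1, 45))
    y <- rnorm(n) # outcome independent of category
    fit <- fit_category_model(y, cat_v, family = "linear")
    all(fit$lo < 0 & fit$hi > 0)
  }, NA)
  # joint coverage of 3 intervals at 95% each: expect roughly 0.86-0.99
  expect_gt(mean(cover), 0.80)
})

test_that("rank deficiency and separation are named failures", {
  set.seed(6)
  cat_v <- categorize(runif(500, 1, 45))
  y <- rbinom(500, 1, 0.3)
  dup <- data.frame(d = as.integer(cat_v == "<10.0")) # collinear with a dummy
  expect_error(
    fit_category_model(y, cat_v, covariates = dup, family = "logistic"),
    class = "vitdmr_rank_error"
  )
  ysep <- as.integer(cat_v == "<10.0") # perfectly separated outcome
  suppressWarnings(expect_error(
    fit_category_model(ysep, cat_v, family = "logistic"),
    class = "vitdmr_separation_error"
  ))
})

test_that("fractional-polynomial fit recovers a log-shaped dose-response", {
  set.seed(7)
  n <- 20000
  x <- rgamma(n, 8, scale = 2.5)
  beta <- 0.8
  y <- beta * log(x) + rnorm(n)
  fit <- fp_dose_response(x, y, family = "linear", degree = 1)
  expect_equal(fit$powers, 0)
  se <- sqrt(diag(fit$vcov))[1]
  expect_lt(abs(fit$coefficients[1] - beta), 2 * se)
})

test_that("constant outcome yields a flat fitted curve", {
  x <- seq(1, 40, length.out = 200)
  fit <- suppressWarnings(fp_dose_response(x, rep(2, 200), family = "linear", degree = 1))
  expect_lt(max(abs(fit$coefficients)), 1e-8)
})

test_that("power selection matches an exhaustive-search oracle", {
  set.seed(8)
  n <- 400
  x <- runif(n, 1, 40)
  y <- 0.1 * x - 0.002 * x^2 + rnorm(n, 0, 0.5)
  for (deg in 1:2) {
    fit <- fp_dose_response(x, y, family = "linear", degree = deg)
    # oracle: independent exhaustive loop with stats::lm and logLik
    pows <- fp_power_set()
    cands <- if (deg == 1) as.list(pows) else fp_candidates(2, pows)
    ll <- vapply(cands, function(pw) {
      as.numeric(logLik(lm(y ~ fp_basis(x, pw))))
    }, 0)
    expect_equal(fit$powers, cands[[which.max(ll)]])
    expect_equal(fit$logLik, max(ll), tolerance = 1e-8)
  }
})

test_that("degree-2 maximized likelihood is never below the best degree-1", {
  set.seed(9)
  x <- runif(300, 1, 40)
  y <- -0.05 * x + rnorm(300)
  f1 <- fp_dose_response(x, y, family = "linear", degree = 1)
  f2 <- fp_dose_response(x, y, family = "linear", degree = 2)
  expect_gte(f2$logLik, f1$logLik - 1e-8)
})

test_that("non-positive exposures are rejected with advice", {
  expect_error(
    fp_dose_response(c(-1, 2, 3), c(1, 2, 3), family = "linear"),
    "shift or rescale"
  )
})

test_that("curve contrast is zero at the reference with covariates cancelling", {
  set.seed(10)
  n <- 3000
  x <- rgamma(n, 8, scale = 2.5)
  w <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 - 0.04 * x + 0.3 * w))
  fit <- fp_dose_response(x, y, covariates = data.frame(w = w), family = "logistic", degree = 1)
  cv <- fp_curve(fit, c(10, 20, 30), reference = 20)
  expect_equal(cv$estimate[cv$x == 20], 1)
  expect_equal(cv$lo[cv$x == 20], 1)
})
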