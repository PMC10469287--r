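# internal helpers: classed conditions, seed spawning, fast fitters

vd_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "vitdmr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# One master seed deterministically spawns per-stage seeds. Kept below
# .Machine$integer.max so spawned seeds are themselves valid seeds.
spawn_seeds <- function(master, n) {
  stopifnot(is_count(n))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

# OLS of y on (1, z [, covs]); returns coefficient and SE for column `which`
# (2 = the z column). Uses the QR factorization directly to stay fast inside
# per-stratum and per-SNV loops.
fit_linear <- function(y, z, covariates = NULL, which = 2L) {
  X <- cbind(1, z, covariates)
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    vd_stop("design matrix is rank deficient", "vitdmr_rank_error")
  }
  n <- length(y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - ncol(X))
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  list(
    beta = unname(fit$coefficients[which]),
    se = sqrt(sigma2 * XtXinv[which, which]),
    coefficients = fit$coefficients,
    residuals = fit$residuals
  )
}

# Logistic regression of y on (1, z [, covs]) via glm.fit, with a Firth
# penalized-likelihood fallback for separation / non-convergence (rare-event
# strata). Returns beta, se for column `which` and a flag saying whether the
# fallback was used.
fit_logistic <- function(y, z, covariates = NULL, which = 2L) {
  X <- cbind(1, z, covariates)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL
  )
  ok <- !is.null(fit) && fit$converged && all(is.finite(fit$coefficients))
  if (ok) {
    p <- ncol(X)
    cov <- tryCatch(chol2inv(qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]),
      error = function(e) NULL
    )
    se <- if (is.null(cov)) NA_real_ else sqrt(cov[which, which])
    # treat absurd Wald SEs as quasi-separation
    ok <- is.finite(se) && se < 1e3 && abs(fit$coefficients[which]) < 50
    if (ok) {
      return(list(
        beta = unname(fit$coefficients[which]), se = se,
        coefficients = fit$coefficients, firth = FALSE
      ))
    }
  }
  f <- firth_logistic(X, y)
  list(
    beta = unname(f$beta[which]), se = f$se[which],
    coefficients = f$beta, firth = TRUE
  )
}

# Firth (1993) penalized-likelihood logistic regression: Newton iterations on
# the modified score U*(b) = X'(y - p + h (1/2 - p)), h the leverages of the
# weighted design. Stable under separation; used as a logged fallback.
firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    sw <- sqrt(w)
    XW <- X * sw
    qrx <- qr(XW)
    Q <- qr.Q(qrx)
    h <- rowSums(Q^2)
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    I_inv <- chol2inv(qr.R(qrx))
    step <- drop(I_inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- plogis(eta) * (1 - plogis(eta))
  I_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  list(beta = beta, se = sqrt(diag(I_inv)))
}

# weighted least squares through the normal equations; returns coefficients,
# covariance (X'WX)^{-1} and weighted RSS
wls <- function(X, y, w) {
  X <- as.matrix(X)
  A <- crossprod(X * sqrt(w))
  b <- drop(crossprod(X, w * y))
  V <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(V)) {
    return(NULL)
  }
  beta <- drop(V %*% b)
  res <- y - drop(X %*% beta)
  list(beta = beta, vcov = V, rssw = sum(w * res^2), residuals = res)
}
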