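# shared builders for the test suite; everything is generated in code

quick_cohort <- function(n = 3000, kind = "threshold", seed = 1, ...) {
  simulate_cohort(sim_config(n_individuals = n, causal_kind = kind, seed = seed, ...))
}

# deterministic summary statistics: J variants on an exact line
# beta_y = intercept + slope * beta_x, with optional noise
make_ss <- function(J = 6, slope = 0.5, intercept = 0, se_x = 0.05, se_y = 0.1,
                    noise = 0, seed = 1) {
  set.seed(seed)
  beta_x <- seq(0.2, 1, length.out = J)
  beta_y <- intercept + slope * beta_x + if (noise > 0) rnorm(J, 0, noise) else 0
  out <- data.frame(
    rsid = sprintf("g_%04d", seq_len(J)),
    beta_x = beta_x,
    se_x = rep_len(se_x, J),
    beta_y = beta_y,
    se_y = rep_len(se_y, J),
    flipped = FALSE
  )
  class(out) <- c("snv_summary_stats", "data.frame")
  out
}

# summary-level draws around a true ratio, mimicking a clean instrument set
draw_ss <- function(J = 35, theta = 0.05, se_x = 0.02, se_y = 0.05,
                    pleiotropy = rep(0, J), seed = 1, bx0 = NULL) {
  set.seed(seed)
  if (is.null(bx0)) bx0 <- runif(J, 0.3, 1)
  bx <- rnorm(J, bx0, se_x)
  by <- rnorm(J, theta * bx0 + pleiotropy, se_y)
  out <- data.frame(
    rsid = sprintf("g_%04d", seq_len(J)),
    beta_x = bx, se_x = se_x, beta_y = by, se_y = se_y, flipped = FALSE
  )
  class(out) <- c("snv_summary_stats", "data.frame")
  out
}

# direct stratum-level LACE table from a known derivative function
make_strata <- function(mx, lace, se) {
  out <- data.frame(
    stratum = seq_along(mx), lo = mx - 1, hi = mx + 1,
    mean_exposure = mx, x_min = mx - 2, x_max = mx + 2,
    n = 1000L, events = 50L,
    beta_x = 1, se_x = 0.01, beta_y = lace, se_y = se,
    ratio = lace, se_ratio = se, firth = FALSE
  )
  class(out) <- c("lace_estimates", "data.frame")
  out
}
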