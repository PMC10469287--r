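#' The fractional-polynomial power set
#'
#' The conventional candidate exponents for fractional-polynomial regression:
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, where 0 denotes the natural logarithm.
#'
#' @return Numeric vector of the eight candidate powers.
#' @export
fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional-polynomial basis
#'
#' Builds the design columns of a fractional polynomial at exponents `powers`.
#' A power of 0 means `log(x)`; a repeated power follows the usual
#' log-multiplication rule, so powers `(p, p)` give `x^p` and `x^p * log(x)`
#' (and `(0, 0)` gives `log(x)` and `log(x)^2`).
#'
#' @param x Positive numeric vector (exposure, ng/mL).
#' @param powers Numeric vector of one or two exponents (non-decreasing).
#' @return Matrix with `length(powers)` columns.
#' @seealso [fp_deriv()] for the derivative basis used in nonlinear MR.
#' @export
fp_basis <- function(x, powers) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    vd_stop(
      "fractional-polynomial basis needs strictly positive x; shift or rescale the exposure",
      "vitdmr_domain_error"
    )
  }
  one <- function(p) if (p == 0) log(x) else x^p
  out <- matrix(NA_real_, length(x), length(powers))
  out[, 1] <- one(powers[1])
  if (length(powers) == 2) {
    out[, 2] <- if (powers[2] == powers[1]) out[, 1] * log(x) else one(powers[2])
  }
  colnames(out) <- paste0("fp", seq_along(powers), "_", powers)
  out
}

#' Derivative of the fractional-polynomial basis
#'
#' Column-wise derivative of [fp_basis()] with respect to `x`. In stratified
#' nonlinear MR each stratum-specific ratio estimate is modeled as the
#' derivative of the causal curve at the stratum's mean exposure, so the
#' coefficients of the curve are estimated by regressing the ratio estimates
#' on these derivative columns.
#'
#' @inheritParams fp_basis
#' @return Matrix with `length(powers)` columns.
#' @export
fp_deriv <- function(x, powers) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    vd_stop(
      "fractional-polynomial basis needs strictly positive x; shift or rescale the exposure",
      "vitdmr_domain_error"
    )
  }
  done <- function(p) if (p == 0) 1 / x else p * x^(p - 1)
  out <- matrix(NA_real_, length(x), length(powers))
  out[, 1] <- done(powers[1])
  if (length(powers) == 2) {
    out[, 2] <- if (powers[2] == powers[1]) {
      # d/dx [x^p log x] = x^(p-1) (p log x + 1); d/dx [log(x)^2] = 2 log(x)/x
      if (powers[1] == 0) 2 * log(x) / x else x^(powers[1] - 1) * (powers[1] * log(x) + 1)
    } else {
      done(powers[2])
    }
  }
  colnames(out) <- paste0("dfp", seq_along(powers), "_", powers)
  out
}

# all candidate power tuples of a given degree (non-decreasing, with repeats)
fp_candidates <- function(degree, powers = fp_power_set()) {
  if (degree == 1) {
    return(lapply(powers, function(p) p))
  }
  out <- list()
  for (i in seq_along(powers)) {
    for (j in i:length(powers)) {
      out[[length(out) + 1L]] <- c(powers[i], powers[j])
    }
  }
  out
}
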