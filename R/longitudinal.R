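#' Expected log2(PSA + 1) trajectory
#'
#' Subject-level mean of the PSA submodel:
#' `m(t) = (b0 + u0) + sum_p (bp + up) C_p(t) + b4 (age - age_center)`,
#' where `C` is the 3-df natural cubic spline basis. Times below the lower
#' boundary knot (e.g. `t - 1` with `t < 1`) are handled by the basis's
#' linear extrapolation.
#'
#' @param t numeric vector of times in years (any real value).
#' @param age age at entry in years.
#' @param params an [icjm_params()] object.
#' @param u random-effects vector (first 4 components are the PSA effects).
#' @return numeric vector of expected log2(PSA+1) values.
#' @export
psa_mean <- function(t, age, params, u = numeric(7)) {
  b <- params$beta_psa
  bu <- c(b[1L] + u[1L], b[2:4] + u[2:4])
  drop(cbind(1, ns_basis(t, params$knots)) %*% bu) +
    b[5L] * (age - params$age_center)
}

#' Expected yearly change in log2(PSA + 1)
#'
#' The association functional `m(t) - m(t - 1)`: the model-implied change in
#' the expected log2(PSA+1) over the year preceding `t`. For `t < 1` the
#' lagged value lies before entry and is obtained from the natural spline's
#' linear extrapolation.
#'
#' @inheritParams psa_mean
#' @export
psa_yearly_change <- function(t, age, params, u = numeric(7)) {
  psa_mean(t, age, params, u) - psa_mean(t - 1, age, params, u)
}

#' Expected core ratio on the logit scale
#'
#' Quadratic subject-level trend of the binomial core-ratio submodel:
#' `logit E(core ratio at t) = (b5 + u4) + (b6 + u5) t + (b7 + u6) t^2`.
#'
#' @param t numeric vector of times in years.
#' @param params an [icjm_params()] object with a core-ratio submodel.
#' @param u random-effects vector of length 7 (components 5-7 are the
#'   core-ratio effects).
#' @return numeric vector of logit-scale expected core ratios.
#' @export
cr_mean <- function(t, params, u = numeric(7)) {
  if (is.null(params$beta_cr))
    stop("params has no core-ratio submodel")
  b <- params$beta_cr
  (b[1L] + u[5L]) + (b[2L] + u[6L]) * t + (b[3L] + u[7L]) * t^2
}
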