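#' Construct the parameter set of an interval-censored cause-specific joint model
#'
#' Bundles every quantity the model needs: fixed effects of the two
#' longitudinal submodels, the random-effects covariance, the scale of the
#' t(3) PSA measurement error, and for each competing event (progression
#' `PRG`, early treatment `TRT`) the exogenous-covariate coefficient, the
#' association coefficients linking the biomarker trajectory to the hazard,
#' and the baseline log-hazard coefficients.
#'
#' The baseline hazard is log-linear in a design `d(t)`: for
#' `baseline_type = "weibull"`, `d(t) = (1, log t)` so that
#' `log h0(t) = c0 + c1 log t` (a Weibull hazard with shape `c1 + 1`); for
#' `"bspline"`, `d(t)` is a cubic B-spline basis (9 columns by default) on
#' `[0, horizon]`.
#'
#' @param beta_psa numeric(5): intercept, 3 natural-spline time coefficients,
#'   and the (age - `age_center`) coefficient of the log2(PSA+1) model.
#' @param beta_cr numeric(3) or NULL: intercept, linear and quadratic time
#'   coefficients of the logit core-ratio model (NULL for a PSA-only model).
#' @param omega random-effects covariance matrix, 4x4 (PSA-only) or 7x7
#'   (PSA + core ratio); must be symmetric positive definite.
#' @param sigma_eps positive scale of the t(3) PSA measurement error.
#' @param gamma named list `PRG`/`TRT`, each a numeric coefficient (log
#'   baseline PSA density).
#' @param alpha named list `PRG`/`TRT`, each numeric of length 2
#'   (`psa_value`, `psa_change`) or 3 (plus `cr_value`).
#' @param baseline named list `PRG`/`TRT` of baseline log-hazard coefficients.
#' @param baseline_type `"weibull"` or `"bspline"`.
#' @param baseline_knots full knot vector for the B-spline baseline (ignored
#'   for Weibull).
#' @param knots spline knot list for the PSA time trend, see [spline_knots()].
#' @param age_center centering constant for age in years (default 62, the
#'   cohort median).
#' @return an object of class `icjm_params`.
#' @export
icjm_params <- function(beta_psa, beta_cr = NULL, omega, sigma_eps,
                        gamma, alpha, baseline,
                        baseline_type = c("weibull", "bspline"),
                        baseline_knots = NULL,
                        knots, age_center = 62) {
  baseline_type <- match.arg(baseline_type)
  check_knots(knots)
  stopifnot(length(beta_psa) == 5L, is.null(beta_cr) || length(beta_cr) == 3L)
  omega <- as.matrix(omega)
  q <- nrow(omega)
  if (!q %in% c(4L, 7L) || ncol(omega) != q)
    stop("`omega` must be 4x4 (PSA-only) or 7x7 (PSA + core ratio)")
  if (q == 7L && is.null(beta_cr))
    stop("a 7x7 `omega` requires `beta_cr`")
  if (max(abs(omega - t(omega))) > 1e-8 * max(1, max(abs(omega))))
    stop("`omega` must be symmetric")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`omega` must be positive definite")
  if (!is.numeric(sigma_eps) || sigma_eps <= 0) stop("`sigma_eps` must be > 0")
  for (k in c("PRG", "TRT")) {
    if (is.null(gamma[[k]]) || is.null(alpha[[k]]) || is.null(baseline[[k]]))
      stop("gamma, alpha and baseline must each have PRG and TRT components")
    if (!length(alpha[[k]]) %in% c(2L, 3L))
      stop("alpha[['", k, "']] must have length 2 or 3")
  }
  if (baseline_type == "bspline" && is.null(baseline_knots))
    stop("`baseline_knots` required for a B-spline baseline")
  structure(list(beta_psa = as.numeric(beta_psa),
                 beta_cr = if (!is.null(beta_cr)) as.numeric(beta_cr),
                 omega = omega, sigma_eps = sigma_eps,
                 gamma = lapply(gamma, as.numeric),
                 alpha = lapply(alpha, as.numeric),
                 baseline = lapply(baseline, as.numeric),
                 baseline_type = baseline_type,
                 baseline_knots = baseline_knots,
                 knots = knots, age_center = age_center),
            class = "icjm_params")
}

#' @export
print.icjm_params <- function(x, ...) {
  q <- nrow(x$omega)
  cat("Interval-censored cause-specific joint model parameters\n")
  cat(sprintf("  longitudinal: %s, %d random effects\n",
              if (q == 7L) "PSA + core ratio" else "PSA only", q))
  cat(sprintf("  baseline hazard: %s\n", x$baseline_type))
  for (k in c("PRG", "TRT"))
    cat(sprintf("  %s: gamma = %s; alpha = %s\n", k,
                paste(signif(x$gamma[[k]], 3), collapse = ", "),
                paste(signif(x$alpha[[k]], 3), collapse = ", ")))
  invisible(x)
}

n_random_effects <- function(params) nrow(params$omega)

#' Default generating parameters for the simulator
#'
#' A complete, documented parameter set used as the simulator's generating
#' model. The survival log hazard ratios are set to the logs of published
#' point estimates for an active-surveillance cohort (progression: 1.66 for
#' log PSA density, 1.14 for the log2(PSA+1) value, 18.52 for its yearly
#' change; treatment: 1.25, 1.52, 9.13). The longitudinal fixed effects,
#' random-effects covariance and Weibull baseline coefficients are synthetic
#' substitutes calibrated so that marginal trajectories and event mixes look
#' like a slow-growing active-surveillance cohort: median PSA near 5 ng/ml
#' growing roughly 0.3 ng/ml per year, around 10% early-treatment events, and
#' roughly a third of subjects progressing within ten years.
#'
#' @param two_marker logical; include the core-ratio submodel (7 random
#'   effects) or the PSA-only model (4).
#' @return an `icjm_params` object.
#' @export
default_params <- function(two_marker = TRUE) {
  knots <- list(interior = c(1.5, 4), boundary = c(0, 11))
  # log2(PSA+1) trajectory ~ log2(6) + 0.04 t + 0.003 t^2 projected on the
  # natural-spline basis; age slope 0.01 per year.
  beta_psa <- c(2.5811, 0.2441, 0.6514, 0.7552, 0.010)
  beta_cr <- c(-1.7346, 0.10, -0.005)  # logit(0.15) intercept, slow rise
  sds <- c(0.65, 0.35, 0.45, 0.50, 0.90, 0.18, 0.03)
  cr_mat <- diag(7)
  cr_mat[1, 2:4] <- cr_mat[2:4, 1] <- 0.20
  cr_mat[2, 3] <- cr_mat[3, 2] <- 0.30
  cr_mat[2, 4] <- cr_mat[4, 2] <- 0.25
  cr_mat[3, 4] <- cr_mat[4, 3] <- 0.30
  cr_mat[5, 6] <- cr_mat[6, 5] <- -0.20
  cr_mat[1, 5] <- cr_mat[5, 1] <- 0.30
  omega <- diag(sds) %*% cr_mat %*% diag(sds)
  omega <- (omega + t(omega)) / 2
  if (!two_marker) omega <- omega[1:4, 1:4]
  icjm_params(
    beta_psa = beta_psa,
    beta_cr = if (two_marker) beta_cr,
    omega = omega,
    sigma_eps = 0.25,
    gamma = list(PRG = log(1.66), TRT = log(1.25)),
    alpha = list(PRG = c(psa_value = log(1.14), psa_change = log(18.52)),
                 TRT = c(psa_value = log(1.52), psa_change = log(9.13))),
    baseline = list(PRG = c(-2.85, 0.2), TRT = c(-5.00, 0.0)),
    baseline_type = "weibull",
    knots = knots)
}
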