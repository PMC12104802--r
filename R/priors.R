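#' Weakly informative default priors
#'
#' Returns the prior specification used by [icjm_fit()]. The choices are
#' deliberately weakly informative defaults: zero-mean normals with standard
#' deviation `coef_sd` on all regression-type coefficients (longitudinal
#' fixed effects, survival covariate coefficients, association coefficients,
#' baseline log-hazard coefficients), a half-t(3) prior on the t-error scale,
#' an inverse-Wishart prior on the random-effects covariance, and for a
#' B-spline baseline an additional second-order random-walk penalty on its
#' coefficients whose precision gets a Gamma hyperprior.
#'
#' @param coef_sd normal prior standard deviation for coefficients.
#' @param sigma_scale scale of the half-t(3) prior on `sigma_eps`.
#' @param omega_df degrees of freedom added to the minimal inverse-Wishart
#'   df (`q + 2` total with the default 2).
#' @param omega_scale diagonal of the inverse-Wishart scale matrix.
#' @param rw2_a,rw2_b Gamma hyperprior on the random-walk penalty precision.
#' @return a list of class `icjm_priors`.
#' @export
default_priors <- function(coef_sd = 10, sigma_scale = 2.5, omega_df = 2,
                           omega_scale = 0.1, rw2_a = 1, rw2_b = 0.005) {
  structure(list(coef_sd = coef_sd, sigma_scale = sigma_scale,
                 omega_df = omega_df, omega_scale = omega_scale,
                 rw2_a = rw2_a, rw2_b = rw2_b),
            class = "icjm_priors")
}

# log prior density of the half-t(3) scale, as a function of log(sigma)
# (includes the Jacobian of the log transform)
lprior_sigma <- function(lsig, scale) {
  stats::dt(exp(lsig) / scale, df = 3, log = TRUE) + lsig
}

lprior_normal <- function(x, sd) -0.5 * sum(x^2) / sd^2

# Draw from the inverse-Wishart prior on Omega (via rWishart on the
# precision matrix).
r_inv_wishart <- function(df, scale_inv_chol) {
  q <- nrow(scale_inv_chol)
  W <- stats::rWishart(1, df, crossprod(scale_inv_chol))[, , 1]
  chol2inv(chol(W))
}

#' Sample parameter sets from the prior
#'
#' Draws `n` parameter sets from the prior of a given model structure;
#' used for prior-predictive checks.
#'
#' @param n number of draws.
#' @param template an [icjm_params()] object fixing the model structure
#'   (knot placement, baseline type, number of random effects).
#' @param priors an [default_priors()] object.
#' @return list of `icjm_params` objects.
#' @export
sample_prior <- function(n, template, priors = default_priors()) {
  q <- n_random_effects(template)
  nb <- length(template$baseline$PRG)
  S0_inv_chol <- chol(solve(diag(priors$omega_scale, q)))
  lapply(seq_len(n), function(l) {
    omega <- r_inv_wishart(q + priors$omega_df, S0_inv_chol)
    sigma <- abs(stats::rt(1, 3)) * priors$sigma_scale
    rn <- function(k) stats::rnorm(k, 0, priors$coef_sd)
    p <- template
    p$beta_psa <- rn(5)
    if (!is.null(p$beta_cr)) p$beta_cr <- rn(3)
    p$omega <- omega
    p$sigma_eps <- sigma
    p$gamma <- list(PRG = rn(1), TRT = rn(1))
    na <- length(template$alpha$PRG)
    p$alpha <- list(PRG = rn(na), TRT = rn(na))
    p$baseline <- list(PRG = rn(nb), TRT = rn(nb))
    p
  })
}
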