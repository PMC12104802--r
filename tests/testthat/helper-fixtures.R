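# Shared fixtures: small parameter sets and toy subjects built in code.

test_knots <- list(interior = c(1.5, 4), boundary = c(0, 11))

# constant-hazard parameter set (Weibull with shape 1, no covariate or
# association effects): h_PRG = h1, h_TRT = h2
const_hazard_params <- function(h1, h2, sigma = 0.3, omega = diag(1e-12, 4)) {
  icjm_params(beta_psa = numeric(5), omega = omega, sigma_eps = sigma,
              gamma = list(PRG = 0, TRT = 0),
              alpha = list(PRG = c(0, 0), TRT = c(0, 0)),
              baseline = list(PRG = c(log(h1), 0), TRT = c(log(h2), 0)),
              baseline_type = "weibull", knots = test_knots)
}

# Weibull parameter set: h0_k(t) = lam_k rho_k t^(rho_k - 1), optional
# covariate/association effects
weibull_params <- function(lam1, rho1, lam2, rho2,
                           gamma = c(0, 0), alpha1 = c(0, 0),
                           alpha2 = c(0, 0), beta_psa = numeric(5),
                           omega = diag(0.1, 4), sigma = 0.3) {
  icjm_params(beta_psa = beta_psa, omega = omega, sigma_eps = sigma,
              gamma = list(PRG = gamma[1], TRT = gamma[2]),
              alpha = list(PRG = c(alpha1[1], alpha2[1]),
                           TRT = c(alpha1[2], alpha2[2])),
              baseline = list(PRG = c(log(lam1 * rho1), rho1 - 1),
                              TRT = c(log(lam2 * rho2), rho2 - 1)),
              baseline_type = "weibull", knots = test_knots)
}

# subject with no longitudinal data (event factor only)
event_only_subject <- function(delta, t_minus, t_upper, age = 62, lpd = 0) {
  icjm_subject(id = 1L, psa = data.frame(time = numeric(), psa = numeric()),
               cores = NULL, age = age, log_psa_density = lpd,
               delta = delta, t_prg_minus = t_minus, t_upper = t_upper)
}

empty_context <- function(t_b = 0, t_v = t_b, age = 62, lpd = 0) {
  prediction_context(psa = data.frame(time = numeric(), psa = numeric()),
                     age = age, log_psa_density = lpd, t_b = t_b, t_v = t_v)
}

# oracle: truncated-power natural cubic spline basis on knots
# (b0, k1, k2, b1); columns span {1, t, natural spline terms}
tp_natural_basis <- function(t, knots) {
  xi <- c(knots$boundary[1], knots$interior, knots$boundary[2])
  K <- length(xi)
  d <- function(j, t) {
    (pmax(t - xi[j], 0)^3 - pmax(t - xi[K], 0)^3) / (xi[K] - xi[j])
  }
  cols <- lapply(seq_len(K - 2), function(j) d(j, t) - d(K - 1, t))
  cbind(1, t, do.call(cbind, cols))
}

# small list of parameter draws scattered around the defaults, for tests
# that need a non-degenerate "posterior"
jittered_draws <- function(n = 20, seed = 42, two_marker = FALSE) {
  set.seed(seed)
  base <- default_params(two_marker = two_marker)
  lapply(seq_len(n), function(l) {
    p <- base
    p$beta_psa <- p$beta_psa + rnorm(5, 0, c(0.1, 0.05, 0.05, 0.05, 0.002))
    p$gamma <- lapply(p$gamma, function(g) g + rnorm(1, 0, 0.1))
    p$alpha <- lapply(p$alpha, function(a) a + rnorm(length(a), 0, 0.1))
    p$baseline <- lapply(p$baseline, function(b) b + rnorm(2, 0, c(0.15, 0.05)))
    p$sigma_eps <- p$sigma_eps * exp(rnorm(1, 0, 0.1))
    p
  })
}

# dense-trapezoid brute-force subject log-likelihood (reference oracle)
brute_force_loglik <- function(subject, u, params, n_grid = 10000L) {
  ll <- 0
  if (nrow(subject$psa)) {
    m <- psa_mean(subject$psa$time, subject$age, params, u)
    r <- (log2(subject$psa$psa + 1) - m) / params$sigma_eps
    ll <- ll + sum(dt(r, 3, log = TRUE) - log(params$sigma_eps))
  }
  haz <- function(k, t) cause_specific_hazard(k, t, subject$age,
                                              subject$log_psa_density,
                                              params, u)
  Htrap <- function(k, t1) {
    if (t1 <= 0) return(0)
    tt <- seq(0, t1, length.out = n_grid)
    h <- haz(k, tt)
    sum((h[-1] + h[-n_grid]) / 2) * (t1 / (n_grid - 1))
  }
  ev <- if (subject$delta == 0) {
    -Htrap("PRG", subject$t_prg_minus) - Htrap("TRT", subject$t_upper)
  } else if (subject$delta == 2) {
    log(haz("TRT", subject$t_upper)) - Htrap("PRG", subject$t_prg_minus) -
      Htrap("TRT", subject$t_upper)
  } else {
    tt <- seq(0, subject$t_upper, length.out = n_grid)
    h <- haz("PRG", tt)
    Hc <- c(0, cumsum((h[-1] + h[-n_grid]) / 2 * diff(tt)))
    f <- h * exp(-Hc)
    inside <- tt >= subject$t_prg_minus
    ti <- tt[inside]; fi <- f[inside]
    log(sum((fi[-1] + fi[-length(fi)]) / 2 * diff(ti))) -
      Htrap("TRT", subject$t_upper)
  }
  ll + ev
}
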