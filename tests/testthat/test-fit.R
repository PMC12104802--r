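make_toy_cohort <- function(n = 10, seed = 21) {
  sc <- sim_config(n_train = n, n_test = 2, seed = seed)
  simulate_cohort(sc)$train
}

test_that("identical config and data give identical draws", {
  cohort <- make_toy_cohort(10)
  cfg <- mcmc_config(n_chains = 1, n_adapt = 40, n_burn = 20, n_iter = 60,
                     seed = 5)
  f1 <- icjm_fit(cohort, cfg, model = "psa", baseline = "weibull",
                 knots = test_knots)
  f2 <- icjm_fit(cohort, cfg, model = "psa", baseline = "weibull",
                 knots = test_knots)
  expect_identical(f1$draws$surv, f2$draws$surv)
  expect_identical(f1$draws$omega, f2$draws$omega)
  expect_identical(f1$draws$u, f2$draws$u)
})

test_that("single-block marginal matches a dense-grid posterior", {
  # two subjects, one PSA observation each at t = 0 and age 62, no follow-up:
  # the likelihood depends only on beta0, so its marginal posterior has a
  # 1-d closed grid form: N(0, 10^2) prior x t3 likelihood terms
  y_obs <- c(4.0, 6.5)
  sigma0 <- 0.4
  cohort <- lapply(1:2, function(i)
    icjm_subject(i, data.frame(time = 0, psa = y_obs[i]), NULL,
                 age = 62, log_psa_density = 0, delta = 0,
                 t_prg_minus = 0, t_upper = 0))
  fit <- suppressWarnings(icjm_fit(
    cohort, mcmc_config(n_chains = 1, n_adapt = 1000, n_burn = 500,
                        n_iter = 24000, thin = 12, seed = 9),
    model = "psa", baseline = "weibull", knots = test_knots,
    update = "bp", init = list(lsig = log(sigma0))))
  b0 <- fit$draws$beta_psa[, 1]
  grid <- seq(-3, 8, length.out = 4001)
  lp <- dnorm(grid, 0, 10, log = TRUE) +
    sapply(grid, function(b)
      sum(dt((log2(y_obs + 1) - b) / sigma0, 3, log = TRUE)))
  dens <- exp(lp - max(lp))
  cdf <- cumsum(dens) / sum(dens)
  ks <- max(abs(ecdf(b0)(grid) - cdf))
  expect_lt(ks, 0.05)
})

test_that("random effects concentrate with more data on a subject", {
  p <- default_params(two_marker = FALSE)
  set.seed(31)
  u_true <- icjm:::rmvn_chol(2, chol(p$omega))
  mk <- function(i, n_obs) {
    tt <- seq(0, 5, length.out = n_obs)
    m <- psa_mean(tt, 62, p, u_true[i, ])
    icjm_subject(i, data.frame(time = tt,
                               psa = pmax(2^(m + 0.25 * rt(n_obs, 3)) - 1, 0)),
                 NULL, 62, log(0.15), 0, 5, 5)
  }
  cohort <- list(mk(1, 2), mk(2, 50))
  fit <- suppressWarnings(icjm_fit(
    cohort, mcmc_config(n_chains = 1, n_adapt = 300, n_burn = 200,
                        n_iter = 1500, seed = 13),
    model = "psa", baseline = "weibull", knots = test_knots,
    update = "u",
    init = list(bp = p$beta_psa, lsig = log(p$sigma_eps),
                omega = p$omega)))
  sd_sparse <- sd(fit$draws$u[, 1, 1])
  sd_rich <- sd(fit$draws$u[, 2, 1])
  expect_lt(sd_rich, sd_sparse)
})

test_that("with no data the posterior reproduces the prior", {
  cohort <- lapply(1:2, function(i)
    icjm_subject(i, data.frame(time = numeric(), psa = numeric()), NULL,
                 age = 62, log_psa_density = 0, delta = 0,
                 t_prg_minus = 0, t_upper = 0))
  fit <- suppressWarnings(icjm_fit(
    cohort, mcmc_config(n_chains = 1, n_adapt = 500, n_burn = 200,
                        n_iter = 3000, thin = 2, seed = 17),
    model = "psa", baseline = "weibull", knots = test_knots))
  # coefficient priors are N(0, 10^2); posterior means near 0 on that scale
  expect_lt(max(abs(colMeans(fit$draws$surv))), 3)
  expect_lt(max(abs(colMeans(fit$draws$beta_psa))), 3)
  # every covariance draw positive definite, every scale draw positive
  q <- 4
  min_eig <- apply(fit$draws$omega, 1, function(v)
    min(eigen(matrix(v, q, q), symmetric = TRUE, only.values = TRUE)$values))
  expect_true(all(min_eig > 0))
  expect_true(all(fit$draws$sigma_eps > 0))
})

test_that("prior sampling respects the declared prior families", {
  template <- default_params(two_marker = FALSE)
  set.seed(23)
  pri <- sample_prior(1000, template, default_priors())
  eigs <- vapply(pri, function(p)
    min(eigen(p$omega, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_true(all(eigs > 0))
  expect_true(all(vapply(pri, function(p) p$sigma_eps, 0) > 0))
  # prior-predictive hazards on (0, 15] are strictly positive (moderate
  # coefficient scale keeps exp() inside double range)
  pri2 <- sample_prior(100, template, default_priors(coef_sd = 2))
  tt <- seq(0.1, 15, by = 0.5)
  hpos <- vapply(pri2, function(p)
    all(cause_specific_hazard("PRG", tt, 62, 0, p, numeric(4)) > 0), TRUE)
  expect_true(all(hpos))
})

test_that("two-marker model and B-spline baseline both sample", {
  sc <- sim_config(n_train = 40, n_test = 2, seed = 57)
  cohort <- simulate_cohort(sc)$train
  cfg <- mcmc_config(n_chains = 1, n_adapt = 60, n_burn = 30, n_iter = 80,
                     seed = 3)
  # PSA + core ratio: 7 random effects, core-ratio association in the hazard
  f2 <- icjm_fit(cohort, cfg, model = "psa-cr", baseline = "weibull",
                 knots = test_knots)
  expect_equal(dim(f2$draws$u)[3], 7L)
  expect_equal(ncol(f2$draws$surv), 8L)
  expect_true(all(is.finite(f2$draws$surv)))
  expect_true(all(is.finite(f2$draws$beta_cr)))
  # flexible B-spline baseline with roughness-penalty Gibbs updates
  fb <- icjm_fit(cohort, cfg, model = "psa", baseline = "bspline",
                 knots = test_knots)
  expect_equal(ncol(fb$draws$baseline), 18L)   # 9 coefficients per event
  expect_true(all(is.finite(fb$draws$baseline)))
  # baseline hazard evaluable from a materialized draw
  p <- as_params(fb, 5)
  h <- cause_specific_hazard("PRG", c(0.5, 3, 8), 62, -1.9, p, numeric(4))
  expect_true(all(is.finite(h) & h > 0))
})

test_that("fit warns on cohorts with too few events", {
  cohort <- make_toy_cohort(8, seed = 77)
  for (i in seq_along(cohort)) {
    cohort[[i]]$delta <- 0L   # force all-censored
    cohort[[i]]$t_prg_minus <- min(cohort[[i]]$t_prg_minus,
                                   cohort[[i]]$t_upper)
  }
  expect_warning(
    icjm_fit(cohort, mcmc_config(n_chains = 1, n_adapt = 20, n_burn = 10,
                                 n_iter = 20, seed = 2),
             model = "psa", baseline = "weibull", knots = test_knots),
    "fewer than 2")
})
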