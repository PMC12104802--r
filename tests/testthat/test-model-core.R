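test_that("psa_mean reduces to its components", {
  p <- const_hazard_params(0.1, 0.1)
  tt <- c(0, 0.7, 3, 9)
  expect_equal(psa_mean(tt, 70, p, numeric(4)), rep(0, 4))
  p$beta_psa[1] <- 1
  expect_equal(psa_mean(tt, 62, p, numeric(4)), rep(1, 4))
  # age centered at 62: age enters only through (age - 62)
  p$beta_psa[5] <- 0.02
  expect_equal(psa_mean(tt, 62, p, numeric(4)), rep(1, 4))
  expect_equal(psa_mean(tt, 67, p, numeric(4)), rep(1 + 0.1, 4))
})

test_that("psa_mean matches the truncated-power oracle", {
  anchors <- c(0.5, 2, 3, 7)
  M <- function(t) cbind(1, ns_basis(t, test_knots))
  A <- solve(tp_natural_basis(anchors, test_knots), M(anchors))
  set.seed(3)
  for (r in 1:5) {
    p <- const_hazard_params(0.1, 0.1)
    p$beta_psa <- rnorm(5)
    u <- rnorm(4, 0, 0.5)
    tt <- runif(20, -1, 12)
    oracle <- tp_natural_basis(tt, test_knots) %*% A %*%
      (p$beta_psa[1:4] + u) + p$beta_psa[5] * (65 - 62)
    expect_equal(psa_mean(tt, 65, p, u), drop(oracle), tolerance = 1e-9)
  }
})

test_that("psa_yearly_change handles constant, linear and early trajectories", {
  p <- const_hazard_params(0.1, 0.1)
  p$beta_psa[1] <- 2.5
  expect_equal(psa_yearly_change(c(0.2, 1, 5), 62, p, numeric(4)),
               rep(0, 3))
  # coefficients reproducing an exact line: change equals the slope
  # everywhere, including t < 1 where the lag is extrapolated
  tg <- seq(0, 11, by = 0.05)
  X <- cbind(1, ns_basis(tg, test_knots))
  b <- solve(crossprod(X), crossprod(X, 2 + 0.37 * tg))
  p$beta_psa <- c(b, 0)
  expect_equal(psa_yearly_change(c(0.1, 0.5, 1, 3, 9), 62, p, numeric(4)),
               rep(0.37, 5), tolerance = 1e-8)
  # t = 0.5: equals m(0.5) - m(-0.5) with the lag on the linear extension
  set.seed(4)
  p$beta_psa <- rnorm(5)
  u <- rnorm(4, 0, 0.3)
  expect_equal(psa_yearly_change(0.5, 64, p, u),
               psa_mean(0.5, 64, p, u) - psa_mean(-0.5, 64, p, u))
})

test_that("cr_mean is the quadratic logit trend", {
  p <- default_params(two_marker = TRUE)
  p$beta_cr <- c(0, 0, 0)
  expect_equal(cr_mean(c(0, 2, 5), p, numeric(7)), rep(0, 3))
  p$beta_cr <- c(qlogis(0.15), 0, 0)
  expect_equal(plogis(cr_mean(c(0, 3, 8), p, numeric(7))), rep(0.15, 3))
  set.seed(5)
  p$beta_cr <- rnorm(3, 0, 0.5)
  u <- c(numeric(4), rnorm(3, 0, 0.2))
  tt <- runif(20, 0, 10)
  expect_equal(cr_mean(tt, p, u),
               (p$beta_cr[1] + u[5]) + (p$beta_cr[2] + u[6]) * tt +
                 (p$beta_cr[3] + u[7]) * tt^2)
})

test_that("cause-specific hazard has the proportional-hazards structure", {
  p <- const_hazard_params(0.25, 0.08)
  tt <- c(0.4, 1, 6)
  expect_equal(cause_specific_hazard("PRG", tt, 62, 0, p, numeric(4)),
               rep(0.25, 3))
  expect_error(cause_specific_hazard("DTH", 1, 62, 0, p, numeric(4)),
               "unknown event")
  # +1 in log PSA density multiplies the hazard by exp(gamma)
  p$gamma <- list(PRG = 0.5, TRT = -0.2)
  for (k in c("PRG", "TRT")) {
    r <- cause_specific_hazard(k, tt, 62, -1, p, numeric(4)) /
      cause_specific_hazard(k, tt, 62, -2, p, numeric(4))
    expect_equal(log(r), rep(p$gamma[[k]], 3))
  }
  # one unit higher trajectory with alpha1 = log(1.14) scales by 1.14
  p2 <- const_hazard_params(0.25, 0.08)
  p2$alpha$PRG <- c(log(1.14), 0)
  h0 <- cause_specific_hazard("PRG", tt, 62, 0, p2, numeric(4))
  h1 <- cause_specific_hazard("PRG", tt, 62, 0, p2, c(1, 0, 0, 0))
  expect_equal(h1 / h0, rep(1.14, 3))
})

test_that("cumulative hazard matches closed forms and is additive", {
  p <- const_hazard_params(0.2, 0.1)
  expect_equal(cumulative_hazard("PRG", 0, 5, 62, 0, p, numeric(4)), 1.0)
  expect_identical(cumulative_hazard("PRG", 2, 2, 62, 0, p, numeric(4)), 0)
  expect_error(cumulative_hazard("PRG", 3, 2, 62, 0, p, numeric(4)), "t1")
  pw <- weibull_params(0.1, 1.5, 0.05, 0.8)
  expect_equal(cumulative_hazard("PRG", 0, 2, 62, 0, pw, numeric(4)),
               0.1 * 2^1.5, tolerance = 1e-8)
  # shape < 1: integrable singularity of the hazard at 0
  expect_equal(cumulative_hazard("TRT", 0, 3, 62, 0, pw, numeric(4)),
               0.05 * 3^0.8, tolerance = 1e-7)
  # additivity over random split points, with association effects active
  set.seed(6)
  pa <- weibull_params(0.08, 1.3, 0.04, 1, gamma = c(0.4, 0.2),
                       alpha1 = c(0.2, 0.1), alpha2 = c(1.5, 0.8),
                       beta_psa = c(2.5, 0.2, 0.5, 0.7, 0.01))
  u <- rnorm(4, 0, 0.3)
  for (r in 1:5) {
    ts <- sort(runif(3, 0, 10))
    H02 <- cumulative_hazard("PRG", ts[1], ts[3], 64, -1.8, pa, u)
    H01 <- cumulative_hazard("PRG", ts[1], ts[2], 64, -1.8, pa, u)
    H12 <- cumulative_hazard("PRG", ts[2], ts[3], 64, -1.8, pa, u)
    expect_equal(H02, H01 + H12, tolerance = 1e-8)
  }
})

test_that("event-coefficient swap swaps the two cause-specific hazards", {
  pa <- weibull_params(0.08, 1.3, 0.04, 1, gamma = c(0.4, 0.2),
                       alpha1 = c(0.2, 0.1), alpha2 = c(1.5, 0.8),
                       beta_psa = c(2.5, 0.2, 0.5, 0.7, 0.01))
  swapped <- pa
  swapped$gamma <- pa$gamma[c("TRT", "PRG")]
  names(swapped$gamma) <- c("PRG", "TRT")
  swapped$alpha <- setNames(pa$alpha[c("TRT", "PRG")], c("PRG", "TRT"))
  swapped$baseline <- setNames(pa$baseline[c("TRT", "PRG")], c("PRG", "TRT"))
  tt <- c(0.5, 2, 7)
  u <- c(0.2, -0.1, 0.05, 0)
  expect_equal(cause_specific_hazard("PRG", tt, 64, -1.8, swapped, u),
               cause_specific_hazard("TRT", tt, 64, -1.8, pa, u))
  expect_equal(cause_specific_hazard("TRT", tt, 64, -1.8, swapped, u),
               cause_specific_hazard("PRG", tt, 64, -1.8, pa, u))
})
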