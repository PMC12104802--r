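test_that("with no history the sampled effects follow the prior", {
  p <- default_params(two_marker = FALSE)
  draws <- rep(list(p), 400)
  set.seed(41)
  u <- sample_new_subject_effects(empty_context(0, 0), draws, n_steps = 40)
  # target reduces to MVN(0, Omega): mean near 0, spread near Omega diag
  se <- sqrt(diag(p$omega) / nrow(u))
  expect_true(all(abs(colMeans(u)) < 4 * se * sqrt(40)))  # correlated chains
  expect_equal(unname(apply(u, 2, sd)), unname(sqrt(diag(p$omega))),
               tolerance = 0.3)
})

test_that("Robbins-Monro adaptation reaches the target acceptance rate", {
  p <- default_params(two_marker = FALSE)
  draws <- rep(list(p), 300)
  ctx <- empty_context(2, 2)
  ctx$psa <- data.frame(time = c(0, 0.5, 1, 1.5, 2),
                        psa = c(4, 4.5, 5, 5.2, 6))
  set.seed(43)
  u <- sample_new_subject_effects(ctx, draws, n_steps = 120, target = 0.234)
  expect_lt(abs(attr(u, "accept") - 0.234), 0.05)
})

test_that("MH marginal matches a dense-grid posterior in a collapsed toy", {
  # effectively one random intercept: tiny variance on the other effects;
  # one observation; the 1-d target has a computable grid posterior
  p <- default_params(two_marker = FALSE)
  p$omega <- diag(c(0.6^2, 1e-10, 1e-10, 1e-10))
  p$beta_psa <- c(2.5, 0, 0, 0, 0)
  y <- 7
  ctx <- prediction_context(psa = data.frame(time = 0, psa = y),
                            age = 62, log_psa_density = 0, t_b = 0, t_v = 0)
  draws <- rep(list(p), 3000)
  set.seed(47)
  u <- sample_new_subject_effects(ctx, draws, n_steps = 40)
  grid <- seq(-2.5, 2.5, length.out = 2001)
  lp <- dnorm(grid, 0, 0.6, log = TRUE) +
    dt((log2(y + 1) - 2.5 - grid) / p$sigma_eps, 3, log = TRUE)
  dens <- exp(lp - max(lp))
  cdf <- cumsum(dens) / sum(dens)
  ks <- max(abs(ecdf(u[, 1])(grid) - cdf))
  expect_lt(ks, 0.05)
})

test_that("progression risk matches competing-exponential closed forms", {
  p <- const_hazard_params(0.3, 0.1)
  ctx <- empty_context(1, 1)
  expect_equal(progression_risk(1, ctx, p, numeric(4)), 0)
  p0 <- const_hazard_params(1e-14, 0.1)
  expect_lt(progression_risk(5, ctx, p0, numeric(4)), 1e-10)
  cf <- 0.3 / 0.4 * (1 - exp(-0.4 * 2))
  expect_equal(progression_risk(3, ctx, p, numeric(4), form = "entry"),
               cf, tolerance = 1e-8)
  expect_error(progression_risk(0.5, ctx, p, numeric(4)), "t_p")
})

test_that("risk formula variants agree on their overlapping domains", {
  pa <- weibull_params(0.12, 1.3, 0.05, 1, gamma = c(0.5, 0.2),
                       alpha1 = c(0.13, 0.4), alpha2 = c(1.5, 1),
                       beta_psa = c(2.58, 0.24, 0.65, 0.76, 0.01))
  u <- c(0.3, -0.2, 0.1, 0)
  # t_p = t_v: general and visit forms coincide (treatment factor cancels)
  ctx <- prediction_context(psa = data.frame(time = numeric(),
                                             psa = numeric()),
                            age = 64, log_psa_density = -1.8,
                            t_b = 1, t_v = 4)
  expect_equal(progression_risk(4, ctx, pa, u, form = "general"),
               progression_risk(4, ctx, pa, u, form = "visit"),
               tolerance = 1e-8)
  # t_b = t_v: general and overall-survival (entry) forms coincide
  ctx2 <- empty_context(1.5, 1.5, age = 64, lpd = -1.8)
  expect_equal(progression_risk(6, ctx2, pa, u, form = "general"),
               progression_risk(6, ctx2, pa, u, form = "entry"),
               tolerance = 1e-8)
})

test_that("conditioning on a later negative biopsy lowers the risk", {
  p <- const_hazard_params(0.3, 0.1)
  risks <- vapply(c(0.5, 1, 2, 3), function(tb)
    progression_risk(4, empty_context(tb, tb), p, numeric(4)), 0)
  expect_true(all(diff(risks) < 0))
  expect_equal(risks, 0.75 * (1 - exp(-0.4 * (4 - c(0.5, 1, 2, 3)))),
               tolerance = 1e-8)
})

test_that("risk curves are valid cumulative-incidence curves", {
  draws <- jittered_draws(25)
  ctx <- prediction_context(
    psa = data.frame(time = seq(0, 1, 0.25), psa = c(4, 5, 4.5, 5.5, 6)),
    age = 66, log_psa_density = -1.5, t_b = 0.5, t_v = 1)
  set.seed(53)
  for (type in c("visit", "general")) {
    crv <- risk_curve(ctx, draws, horizon = 10, type = type, n_steps = 15)
    expect_equal(unname(crv$risk[, 1]), rep(0, nrow(crv$risk)))
    expect_true(all(crv$risk >= 0 & crv$risk <= 1))
    expect_true(all(apply(crv$risk, 1, function(r) all(diff(r) >= -1e-12))))
    expect_equal(crv$mean, colMeans(crv$risk))
  }
  expect_error(risk_curve(ctx, list()), "no parameter draws")
})

test_that("curves collapse to the deterministic risk under a degenerate posterior", {
  p <- const_hazard_params(0.25, 0.1)
  ctx <- empty_context(1, 1)
  set.seed(59)
  crv <- risk_curve(ctx, rep(list(p), 8), grid = seq(1, 8, 0.25),
                    type = "general", n_steps = 3)
  tt <- c(2, 3.3, 5, 8)
  direct <- vapply(tt, function(t0)
    progression_risk(t0, ctx, p, numeric(4), form = "general"), 0)
  expect_equal(unname(risk_at(crv, tt)), direct, tolerance = 1e-7)
  expect_equal(max(apply(crv$risk, 2, sd)), 0, tolerance = 1e-12)
})

test_that("PRG and TRT cumulative incidences sum below overall mortality bound", {
  p <- const_hazard_params(0.3, 0.15)
  swapped <- p
  swapped$baseline <- list(PRG = p$baseline$TRT, TRT = p$baseline$PRG)
  ctx <- empty_context(0, 0)
  for (tp in c(2, 5, 10)) {
    r_prg <- progression_risk(tp, ctx, p, numeric(4), form = "entry")
    r_trt <- progression_risk(tp, ctx, swapped, numeric(4), form = "entry")
    bound <- 1 - exp(-(0.3 + 0.15) * tp)
    expect_equal(r_prg + r_trt, bound, tolerance = 1e-8)
    expect_lte(r_prg + r_trt, 1)
  }
})
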