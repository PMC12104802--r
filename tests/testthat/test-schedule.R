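# deterministic exponential risk curve (constant progression hazard h,
# no competing event) starting at t_b
exp_curve <- function(h, t_b = 0, horizon = 10, by = 0.25) {
  p <- const_hazard_params(h, 1e-14)
  set.seed(1)
  risk_curve(empty_context(t_b, t_b), list(p),
             grid = seq(t_b, horizon, by = by), type = "visit", n_steps = 2)
}

test_that("threshold limits produce the extreme schedules", {
  crv <- exp_curve(0.5)
  vg <- seq(0.5, 10, by = 0.5)
  s0 <- plan_biopsies(crv, 0, vg)
  expect_equal(s0$times, vg)             # biopsy at every visit
  s1 <- plan_biopsies(crv, 1, vg)
  expect_equal(s1$times, 10)             # only the horizon biopsy
  expect_error(plan_biopsies(crv, 1.2, vg), "phi")
})

test_that("exponential schedules are equally spaced and match a reset oracle", {
  h <- 0.5
  vg <- seq(0.5, 10, by = 0.5)
  for (phi in c(0.15, 0.3, 0.6)) {
    crv <- exp_curve(h)
    sch <- plan_biopsies(crv, phi, vg)
    # memorylessness: spacing is the smallest grid multiple with
    # 1 - exp(-h s) >= phi
    spacing <- 0.5 * ceiling(-log(1 - phi) / h / 0.5 - 1e-9)
    expected <- unique(c(seq(spacing, 10, by = spacing), 10))
    expect_equal(sch$times, expected)
    # explicit reset-and-resample oracle: rebuild the curve from scratch
    # after each scheduled biopsy
    t_b <- 0; oracle <- numeric(0)
    for (v in vg) {
      crv_o <- exp_curve(h, t_b = t_b)
      if (risk_at(crv_o, v) >= phi - 1e-12) {
        oracle <- c(oracle, v); t_b <- v
      }
    }
    if (!length(oracle) || oracle[length(oracle)] < 10)
      oracle <- c(oracle, 10)
    expect_equal(sch$times, oracle)
  }
})

test_that("expected number of biopsies follows the interval probabilities", {
  crv <- exp_curve(0.5)
  single <- structure(list(times = 4, phi = NA, t_b = 0, visit_grid = 4),
                      class = "icjm_schedule")
  expect_equal(expected_num_biopsies(single, crv), 1)
  two <- structure(list(times = c(1, 2), phi = NA, t_b = 0,
                        visit_grid = c(1, 2)), class = "icjm_schedule")
  cf <- (1 * (1 - exp(-0.5)) + 2 * (exp(-0.5) - exp(-1))) / (1 - exp(-1))
  expect_equal(expected_num_biopsies(two, crv), cf, tolerance = 1e-6)
  # equal interval probabilities -> 1.5 (uniform-ish via tiny hazard)
  crv_lin <- exp_curve(1e-6)
  two_eq <- structure(list(times = c(5, 10), phi = NA, t_b = 0,
                           visit_grid = c(5, 10)), class = "icjm_schedule")
  expect_equal(expected_num_biopsies(two_eq, crv_lin), 1.5,
               tolerance = 1e-4)
  # zero total risk -> flagged undefined
  crv0 <- exp_curve(1e-14)
  expect_warning(e <- expected_num_biopsies(two, crv0), "zero")
  expect_true(is.na(e))
})

test_that("expected delay matches truncated-exponential closed forms", {
  crv <- exp_curve(0.5)
  single2 <- structure(list(times = 2, phi = NA, t_b = 0, visit_grid = 2),
                       class = "icjm_schedule")
  e_t <- 1 / 0.5 - 2 * exp(-1) / (1 - exp(-1))
  expect_equal(expected_delay(single2, crv), 2 - e_t, tolerance = 1e-6)
  # uniform conditional density over one interval: delay (b - a) / 2
  crv_lin <- exp_curve(1e-6)
  ab <- structure(list(times = 7, phi = NA, t_b = 3, visit_grid = 7),
                  class = "icjm_schedule")
  crv_lin3 <- exp_curve(1e-6, t_b = 3)
  expect_equal(expected_delay(ab, crv_lin3), 2, tolerance = 1e-3)
})

test_that("optimal threshold minimizes the biopsy/delay distance", {
  crv <- exp_curve(0.5)
  vg <- seq(0.5, 10, by = 0.5)
  phis <- seq(0.1, 0.9, by = 0.1)
  opt <- optimal_threshold(crv, vg, phi_grid = phis, max_delay = Inf)
  # brute-force enumeration over the same candidates
  dist <- vapply(phis, function(phi) {
    s <- plan_biopsies(crv, phi, vg)
    sqrt((s$e_nb - 1)^2 + s$e_dd^2)
  }, 0)
  best <- max(phis[dist <= min(dist) + 1e-9])
  expect_equal(opt$phi, best)
  expect_equal(min(opt$table$distance), min(dist), tolerance = 1e-9)
  # lambda2 = 0 drives the choice toward one biopsy (phi = 1 region)
  opt2 <- optimal_threshold(crv, vg, phi_grid = phis, lambda = c(1, 0),
                            max_delay = Inf)
  expect_equal(opt2$phi, 0.9)
  expect_equal(opt2$schedule$e_nb, min(opt2$table$e_nb))
  # infeasible constraint falls back to minimal expected delay
  expect_warning(opt3 <- optimal_threshold(crv, vg, phi_grid = c(0.98, 0.99),
                                           max_delay = 0.01), "constraint")
  expect_equal(opt3$phi, 0.98)
})

test_that("a dominating candidate is always selected", {
  crv <- exp_curve(0.4)
  vg <- seq(0.5, 10, by = 0.5)
  opt <- optimal_threshold(crv, vg, phi_grid = seq(0.05, 0.95, 0.05),
                           max_delay = Inf)
  tab <- opt$table
  sel <- tab[tab$phi == opt$phi, ]
  dominated_by_other <- any(tab$e_nb < sel$e_nb - 1e-9 &
                              tab$e_dd < sel$e_dd - 1e-9)
  expect_false(dominated_by_other)
})

test_that("threshold monotonicity: fewer biopsies, longer delays", {
  # fixed non-trivial curve from jittered model draws
  draws <- jittered_draws(15)
  ctx <- prediction_context(
    psa = data.frame(time = seq(0, 1, 0.25), psa = c(5, 6, 6.5, 7, 8)),
    age = 66, log_psa_density = -1.2, t_b = 0, t_v = 1)
  set.seed(61)
  crv <- risk_curve(ctx, draws, grid = seq(0, 10, 0.125), type = "visit",
                    n_steps = 10)
  vg <- seq(1, 10, by = 0.5)
  phis <- seq(0.05, 0.95, by = 0.05)
  n_b <- e_dd <- numeric(length(phis))
  for (j in seq_along(phis)) {
    s <- plan_biopsies(crv, phis[j], vg)
    n_b[j] <- length(s$times); e_dd[j] <- s$e_dd
  }
  expect_true(all(diff(n_b) <= 0))
  expect_true(all(diff(e_dd) >= -1e-9))
})

test_that("fixed schedules reproduce the protocol definitions", {
  expect_equal(fixed_schedule("pass", 10)$times, c(1, 2, 4, 6, 8, 10))
  expect_equal(fixed_schedule("annual", 10)$times, 1:10)
  expect_equal(fixed_schedule("pass", 1)$times, 1)
  expect_equal(fixed_schedule("annual", 1)$times, 1)
  expect_equal(fixed_schedule("pass", 7)$times, c(1, 2, 4, 6, 7))
  expect_error(fixed_schedule("annual", 0), "horizon")
})

test_that("schedule evaluation follows the detection rules", {
  ann <- fixed_schedule("annual", 10)
  r <- evaluate_schedule(1.5, Inf, ann)
  expect_equal(r$nb, 2L); expect_equal(r$dd, 0.5)
  # treatment before progression: biopsies stop, no delay defined
  r2 <- evaluate_schedule(Inf, 1.5, ann)
  expect_equal(r2$nb, 1L); expect_true(is.na(r2$dd))
  r2b <- evaluate_schedule(3.9, 1.5, ann)
  expect_equal(r2b$nb, 1L)
  # progression after the horizon: all planned biopsies conducted
  r3 <- evaluate_schedule(11, Inf, ann)
  expect_equal(r3$nb, 10L); expect_true(is.na(r3$dd))
  # phi = 0 consistency: actual biopsies = visits up to the detecting one
  crv <- exp_curve(0.5)
  vg <- seq(0.5, 10, by = 0.5)
  s0 <- plan_biopsies(crv, 0, vg)
  r4 <- evaluate_schedule(2.3, Inf, s0)
  expect_equal(r4$nb, sum(vg < 2.3) + 1L)
  expect_equal(r4$dd, 2.5 - 2.3)
})
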