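#' Simulation configuration
#'
#' Describes the cohort-generating conditions: the generating parameter set,
#' cohort sizes, the observation process (PSA every 3 months, clinical
#' visits every 6 months, protocol biopsies at years 1 and 2 then
#' biennially, with a diagnostic biopsy at entry), a 10-year horizon, a
#' 5-year uniform accrual window for administrative censoring of training
#' subjects, and a multiplier on the treatment baseline hazard to tune the
#' fraction of early-treatment events (about 10% at the default).
#'
#' @param params generating [icjm_params()]; [default_params()] if NULL.
#' @param n_train,n_test training-set and test-set sizes.
#' @param psa_interval PSA measurement spacing (years).
#' @param visit_interval clinical-visit spacing (years).
#' @param horizon horizon time (years; multiple of `visit_interval`).
#' @param accrual uniform accrual window (years) for training censoring.
#' @param total_cores cores sampled per biopsy (12, the standard systematic
#'   biopsy).
#' @param trt_hazard_scale multiplier on the treatment baseline hazard.
#' @param age_mean,age_sd,lpd_mean,lpd_sd baseline covariate distributions
#'   (age normal; log PSA density normal).
#' @param seed integer seed.
#' @return a list of class `icjm_sim_config`.
#' @export
sim_config <- function(params = NULL, n_train = 300L, n_test = 200L,
                       psa_interval = 0.25, visit_interval = 0.5,
                       horizon = 10, accrual = 5, total_cores = 12L,
                       trt_hazard_scale = 1,
                       age_mean = 62, age_sd = 7,
                       lpd_mean = log(0.15), lpd_sd = 0.4, seed = 1L) {
  if (is.null(params)) params <- default_params()
  stopifnot(psa_interval > 0, visit_interval > 0, horizon > 0)
  if (abs(horizon / visit_interval - round(horizon / visit_interval)) > 1e-9)
    stop("horizon must be a multiple of visit_interval")
  structure(list(params = params, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), psa_interval = psa_interval,
                 visit_interval = visit_interval, horizon = horizon,
                 accrual = accrual, total_cores = as.integer(total_cores),
                 trt_hazard_scale = trt_hazard_scale,
                 age_mean = age_mean, age_sd = age_sd,
                 lpd_mean = lpd_mean, lpd_sd = lpd_sd,
                 seed = as.integer(seed)),
            class = "icjm_sim_config")
}

# protocol biopsy times (including the diagnostic biopsy at entry)
pass_biopsy_times <- function(horizon) {
  c(0, 1, 2, seq(4, max(horizon, 4), by = 2))[
    c(0, 1, 2, seq(4, max(horizon, 4), by = 2)) <= horizon]
}

scale_trt <- function(params, s) {
  if (s != 1) params$baseline$TRT[1L] <- params$baseline$TRT[1L] + log(s)
  params
}

#' Simulate latent event times for one subject
#'
#' The model's two latent times are conditionally independent given the
#' random effects: each is drawn by inverse-transform sampling of its own
#' cause-specific cumulative hazard, solving `H_k(0, T) = -log(U_k)` by
#' monotone (Hermite) interpolation of the quadrature-accumulated cumulative
#' hazard. Both latent times are returned — treatment may strike after a
#' latent (undetected) progression, which is exactly the situation the
#' interval-censored likelihood integrates over. The marginal law of the
#' first event and its type is the usual competing-risks one
#' (`P(type k | T) = h_k(T) / h_tot(T)`).
#'
#' @param u random-effects vector.
#' @param params generating [icjm_params()].
#' @param age,log_psa_density subject covariates.
#' @param seed optional integer seed.
#' @param t_max times beyond this bracket (years) are recorded as `Inf`.
#' @return list with latent `t_prg` and `t_trt` (years or `Inf`).
#' @export
simulate_event_times <- function(u, params, age = 62,
                                 log_psa_density = log(0.15), seed = NULL,
                                 t_max = 50) {
  if (!is.null(seed)) set.seed(seed)
  sim_event_times_multi(matrix(u, nrow = 1L), age, log_psa_density, params,
                        t_max = t_max)[1L, ]
}

# Vectorized latent event times for `n` subjects (rows of U). Returns a
# data.frame with t_prg, t_trt.
sim_event_times_multi <- function(U, ages, lpds, params, t_max = 50,
                                  chunk = 2000L) {
  n <- nrow(U)
  ages <- rep_len(ages, n); lpds <- rep_len(lpds, n)
  out <- data.frame(t_prg = rep(Inf, n), t_trt = rep(Inf, n))
  E <- matrix(stats::rexp(2L * n), n, 2L)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    out[idx, ] <- sim_event_chunk(U[idx, , drop = FALSE], ages[idx],
                                  lpds[idx], params, E[idx, , drop = FALSE],
                                  t_max)
  }
  out
}

sim_event_chunk <- function(U, ages, lpds, params, E, t_max) {
  ns <- nrow(U)
  grid <- seq(0, t_max, by = 0.25)
  G <- length(grid)
  nodes <- lapply(seq_len(G - 1L), function(g) gk_rescale(grid[g], grid[g + 1L]))
  tt <- unlist(lapply(nodes, `[[`, "t"))
  ww <- unlist(lapply(nodes, `[[`, "w"))
  seg <- rep(seq_len(G - 1L), each = 15L)
  lh <- sim_loghaz(c(tt, grid), U, ages, lpds, params)   # times x subjects x 2
  nT <- length(tt)
  out <- matrix(Inf, ns, 2L)
  for (k in 1:2) {
    hw <- ww * exp(lh[seq_len(nT), , k, drop = FALSE][, , 1, drop = TRUE])
    if (ns == 1L) hw <- matrix(hw, ncol = 1L)
    segsum <- rowsum(hw, seg)
    Hg <- rbind(0, apply(segsum, 2, cumsum))                     # G x ns
    hg <- exp(lh[nT + seq_len(G), , k, drop = FALSE][, , 1, drop = TRUE])
    if (ns == 1L) hg <- matrix(hg, ncol = 1L)
    for (i in seq_len(ns)) {
      if (Hg[G, i] < E[i, k]) next
      g <- findInterval(E[i, k], Hg[, i], rightmost.closed = TRUE)
      g <- min(max(g, 1L), G - 1L)
      f <- function(t) {
        hermite_interp(grid, t(Hg[, i, drop = FALSE]),
                       t(hg[, i, drop = FALSE]), t)[1L] - E[i, k]
      }
      out[i, k] <- stats::uniroot(f, c(grid[g], grid[g + 1L]),
                                  extendInt = "upX", tol = 1e-10)$root
    }
  }
  data.frame(t_prg = out[, 1L], t_trt = out[, 2L])
}

# log-hazards for both events at shared times (times x subjects x 2)
sim_loghaz <- function(t, U, ages, lpds, params) {
  B <- cbind(1, ns_basis(t, params$knots))
  Lg <- cbind(1, ns_basis(t - 1, params$knots))
  D <- baseline_design(t, params)
  coefs <- params$beta_psa[1:4] + t(U[, 1:4, drop = FALSE])    # 4 x ns
  agec <- (ages - params$age_center) * params$beta_psa[5L]
  two_cr <- length(params$alpha$PRG) >= 3L
  if (two_cr) ccr <- params$beta_cr + t(U[, 5:7, drop = FALSE])
  m <- sweep(B %*% coefs, 2, agec, "+")
  mlag <- sweep(Lg %*% coefs, 2, agec, "+")
  out <- array(0, c(length(t), nrow(U), 2L))
  for (k in 1:2) {
    kn <- c("PRG", "TRT")[k]
    a <- params$alpha[[kn]]
    lh <- a[1L] * m + a[2L] * (m - mlag)
    lh <- sweep(lh, 2, params$gamma[[kn]] * lpds, "+")
    lh <- lh + drop(D %*% params$baseline[[kn]])
    if (two_cr)
      lh <- lh + cbind(1, t, t^2) %*% ccr * a[3L]
    out[, , k] <- lh
  }
  out
}

#' Simulate a full training and test cohort
#'
#' Draws random effects from MVN(0, Omega), baseline covariates, latent
#' competing event times by inverse-transform sampling, and applies the
#' observation process: PSA with scaled-t(3) measurement error at regular
#' intervals, biopsy core counts at conducted biopsies, interval censoring
#' of progression by the protocol biopsy schedule, and administrative
#' censoring from a uniform accrual window. Test subjects receive an initial
#' negative biopsy at entry and are resampled until the configured quota of
#' progressing / non-progressing subjects is met.
#'
#' @param config an [sim_config()].
#' @return list with `train` (list of [icjm_subject()]), `truth_train`
#'   (data frame of latent times), `test` (list with `psa`, `age`,
#'   `log_psa_density`, `truth` per subject) and the `config`.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  params <- scale_trt(config$params, config$trt_hazard_scale)
  q <- n_random_effects(params)
  om_chol <- chol(params$omega)
  two_marker <- !is.null(params$beta_cr)

  n <- config$n_train
  U <- rmvn_chol(n, om_chol)
  ages <- stats::rnorm(n, config$age_mean, config$age_sd)
  lpds <- stats::rnorm(n, config$lpd_mean, config$lpd_sd)
  ev <- sim_event_times_multi(U, ages, lpds, params)
  cens <- config$horizon - stats::runif(n, 0, config$accrual)
  proto <- pass_biopsy_times(config$horizon)

  train <- vector("list", n)
  for (i in seq_len(n)) {
    obs <- observe_subject(i, U[i, ], ages[i], lpds[i], ev$t_prg[i],
                           ev$t_trt[i], cens[i], proto, params, config)
    train[[i]] <- obs
  }
  truth_train <- data.frame(id = seq_len(n), t_prg = ev$t_prg,
                            t_trt = ev$t_trt, censor = cens)

  # test set: fixed quota of progressing / non-progressing subjects
  n_test <- config$n_test
  quota_prg <- n_test %/% 2L
  quota_non <- n_test - quota_prg
  test <- vector("list", n_test)
  got_prg <- 0L; got_non <- 0L; tries <- 0L
  while (got_prg < quota_prg || got_non < quota_non) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("test-set quota unreachable: ", got_prg, "/", quota_prg,
           " progressing after ", tries, " batches")
    nb <- max(n_test, 64L)
    Ub <- rmvn_chol(nb, om_chol)
    ageb <- stats::rnorm(nb, config$age_mean, config$age_sd)
    lpdb <- stats::rnorm(nb, config$lpd_mean, config$lpd_sd)
    evb <- sim_event_times_multi(Ub, ageb, lpdb, params)
    progressed <- evb$t_prg <= config$horizon & evb$t_prg < evb$t_trt
    for (j in seq_len(nb)) {
      slot <- if (progressed[j] && got_prg < quota_prg) {
        got_prg <- got_prg + 1L; got_prg
      } else if (!progressed[j] && got_non < quota_non) {
        got_non <- got_non + 1L; quota_prg + got_non
      } else next
      psa_t <- seq(0, config$horizon, by = config$psa_interval)
      m <- psa_mean(psa_t, ageb[j], params, Ub[j, ])
      y <- m + params$sigma_eps * stats::rt(length(psa_t), 3)
      test[[slot]] <- list(
        id = slot, u = Ub[j, ], age = ageb[j], log_psa_density = lpdb[j],
        psa = data.frame(time = psa_t, psa = pmax(2^y - 1, 0)),
        truth = list(t_prg = evb$t_prg[j], t_trt = evb$t_trt[j]),
        progressed = progressed[j])
      if (got_prg >= quota_prg && got_non >= quota_non) break
    }
  }
  list(train = train, truth_train = truth_train, test = test,
       config = config)
}

# apply the observation process to one training subject
observe_subject <- function(id, u, age, lpd, t_prg, t_trt, cens, proto,
                            params, config) {
  bx <- proto
  det <- bx[bx >= t_prg & bx <= cens]
  det <- if (length(det)) det[1L] else Inf
  if (t_trt <= cens && t_trt < det) {
    delta <- 2L; t_upper <- t_trt
    t_minus <- max(bx[bx < t_trt - 1e-12], 0)
  } else if (is.finite(det)) {
    delta <- 1L; t_upper <- det
    t_minus <- max(bx[bx < t_prg - 1e-12], 0)
  } else {
    delta <- 0L; t_upper <- cens
    t_minus <- max(bx[bx <= cens], 0)
  }
  psa_t <- seq(0, t_upper, by = config$psa_interval)
  m <- psa_mean(psa_t, age, params, u)
  y <- m + params$sigma_eps * stats::rt(length(psa_t), 3)
  cores <- NULL
  if (!is.null(params$beta_cr)) {
    bx_done <- bx[bx <= t_upper - ifelse(delta == 2L, 1e-12, 0)]
    if (delta == 1L) bx_done <- bx_done[bx_done <= t_upper]
    p <- stats::plogis(cr_mean(bx_done, params, u))
    cores <- data.frame(time = bx_done,
                        pos_cores = stats::rbinom(length(bx_done),
                                                  config$total_cores, p),
                        total_cores = config$total_cores)
  }
  icjm_subject(id, data.frame(time = psa_t, psa = pmax(2^y - 1, 0)),
               cores, age, lpd, delta, t_minus, t_upper)
}
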