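#' MCMC configuration
#'
#' @param n_chains number of independent chains.
#' @param n_adapt adaptation iterations (proposal scales and covariances are
#'   tuned only during this phase).
#' @param n_burn additional burn-in iterations after adaptation.
#' @param n_iter post-burn-in iterations per chain.
#' @param thin thinning interval for stored draws.
#' @param seed integer seed; identical config + data give identical draws.
#' @param accept_target target acceptance rate for the multivariate
#'   random-walk blocks.
#' @return a list of class `icjm_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, n_adapt = 500L, n_burn = 500L,
                        n_iter = 1000L, thin = 1L, seed = 1L,
                        accept_target = 0.234) {
  stopifnot(n_chains >= 1, n_adapt >= 1, n_burn >= 1, n_iter >= 1, thin >= 1,
            accept_target > 0, accept_target < 1)
  structure(list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
                 n_burn = as.integer(n_burn), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), seed = as.integer(seed),
                 accept_target = accept_target),
            class = "icjm_mcmc_config")
}

rmvn_chol <- function(n, R) {
  # rows ~ N(0, t(R) %*% R) for an upper-triangular Cholesky factor R
  matrix(stats::rnorm(n * nrow(R)), n) %*% R
}

mvn_quadform <- function(u, R) {
  # u_i' Omega^{-1} u_i for each row of u, Omega = t(R) R
  v <- backsolve(R, t(u), transpose = TRUE)
  colSums(v^2)
}

#' Fit the interval-censored cause-specific joint model
#'
#' Bayesian estimation by Metropolis-within-Gibbs: adaptive Gaussian
#' random-walk blocks for the longitudinal fixed effects, the per-event
#' survival coefficients (covariate, association and baseline coefficients
#' jointly) and the log error scale; per-subject random-walk updates for the
#' random effects (proposals shaped by the current covariance); and
#' conjugate Gibbs draws for the random-effects covariance (inverse-Wishart)
#' and, for a B-spline baseline, the roughness-penalty precision. Proposal
#' scales follow a Robbins-Monro recursion toward the target acceptance rate
#' and block covariances are estimated adaptively, both only during the
#' adaptation phase.
#'
#' @param cohort list of [icjm_subject()] objects.
#' @param config an [mcmc_config()].
#' @param model `"psa"` for the PSA-only model (4 random effects) or
#'   `"psa-cr"` to add the binomial core-ratio submodel (7 random effects,
#'   core-ratio value included in both hazards).
#' @param baseline baseline hazard family, `"bspline"` (flexible default) or
#'   `"weibull"`.
#' @param knots PSA spline knots; computed from the data via
#'   [spline_knots()] when NULL.
#' @param priors an [default_priors()] object.
#' @param age_center centering constant for age.
#' @param update names of sampler blocks to update (default all); freezing
#'   blocks at their initial values is useful for sampler validation.
#' @param init optional named list overriding initial state components
#'   (`bp`, `bc`, `u`, `g2`, `amat`, `bco`, `lsig`, `omega`).
#' @param verbose print progress.
#' @return an object of class `icjm_fit` holding pooled posterior draws of
#'   all parameters and per-subject random effects, acceptance rates,
#'   split-Rhat and effective sample sizes for the survival coefficients.
#' @export
icjm_fit <- function(cohort, config = mcmc_config(),
                     model = c("psa", "psa-cr"),
                     baseline = c("bspline", "weibull"),
                     knots = NULL, priors = default_priors(),
                     age_center = 62,
                     update = c("bp", "bc", "surv1", "surv2", "lsig", "u",
                                "omega", "tau"),
                     init = NULL, verbose = FALSE) {
  model <- match.arg(model)
  baseline <- match.arg(baseline)
  two_marker <- model == "psa-cr"
  n <- length(cohort)
  delta <- vapply(cohort, function(s) s$delta, 0L)
  if (sum(delta == 1L) < 2L || sum(delta == 2L) < 2L)
    warning("fewer than 2 subjects for at least one event type; ",
            "survival coefficients may be poorly identified")

  if (is.null(knots))
    knots <- spline_knots(unlist(lapply(cohort, function(s) s$psa$time)),
                          vapply(cohort, function(s) s$t_upper, 0))
  t_up <- vapply(cohort, function(s) s$t_upper, 0)
  b_knots <- if (baseline == "bspline")
    baseline_bspline_knots(t_up, upper = max(t_up) * 1.001)
  nb <- if (baseline == "bspline") 9L else 2L
  q <- if (two_marker) 7L else 4L

  template <- icjm_params(
    beta_psa = numeric(5), beta_cr = if (two_marker) numeric(3),
    omega = diag(q), sigma_eps = 1,
    gamma = list(PRG = 0, TRT = 0),
    alpha = list(PRG = numeric(2 + two_marker), TRT = numeric(2 + two_marker)),
    baseline = list(PRG = numeric(nb), TRT = numeric(nb)),
    baseline_type = baseline, baseline_knots = b_knots,
    knots = knots, age_center = age_center)
  pre <- precompute_cohort(cohort, template)
  st0 <- init_state(pre, template, priors)
  for (nm in names(init)) st0[[nm]] <- init[[nm]]

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * (ch - 1L))
    chains[[ch]] <- run_chain(pre, template, st0, config, priors, update,
                              verbose, ch)
  }

  keep_names <- colnames(chains[[1L]]$surv)
  rhat <- vapply(keep_names, function(nm) {
    split_rhat(lapply(chains, function(cc) cc$surv[, nm]))
  }, 0)
  ess <- vapply(keep_names, function(nm) {
    sum(vapply(chains, function(cc) ess_basic(cc$surv[, nm]), 0))
  }, 0)

  pool <- function(field) do.call(rbind, lapply(chains, `[[`, field))
  u_all <- do.call(abind1, lapply(chains, `[[`, "u"))
  out <- list(
    draws = list(beta_psa = pool("beta_psa"),
                 beta_cr = if (two_marker) pool("beta_cr"),
                 surv = pool("surv"), baseline = pool("baseline"),
                 sigma_eps = do.call(c, lapply(chains, `[[`, "sigma_eps")),
                 omega = pool("omega"), u = u_all),
    chain = rep(seq_len(config$n_chains),
                each = nrow(chains[[1L]]$surv)),
    accept = lapply(chains, `[[`, "accept"),
    rhat = rhat, ess = ess,
    template = template, model = model, baseline = baseline,
    n_subjects = n, config = config)
  class(out) <- "icjm_fit"
  out
}

abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  out <- array(0, c(sum(vapply(arrs, function(a) dim(a)[1L], 0)), d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' @export
print.icjm_fit <- function(x, ...) {
  cat(sprintf("ICJM fit (%s model, %s baseline): %d subjects, %d draws\n",
              x$model, x$baseline, x$n_subjects, nrow(x$draws$surv)))
  cat("Survival coefficients (posterior mean [95% CI], Rhat):\n")
  s <- summary(x)
  print(round(s, 3))
  invisible(x)
}

#' Summarize survival coefficients of a fitted ICJM
#'
#' @param object an `icjm_fit`.
#' @param ... unused.
#' @return matrix with posterior mean, 95% credible bounds, Rhat and ESS per
#'   survival coefficient.
#' @export
summary.icjm_fit <- function(object, ...) {
  d <- object$draws$surv
  cbind(mean = colMeans(d),
        lower = apply(d, 2, stats::quantile, 0.025),
        upper = apply(d, 2, stats::quantile, 0.975),
        rhat = object$rhat, ess = object$ess)
}

#' Materialize one posterior draw as a parameter object
#'
#' @param fit an `icjm_fit`.
#' @param l draw index (row of the pooled draws).
#' @return an [icjm_params()] object.
#' @export
as_params <- function(fit, l) {
  d <- fit$draws
  p <- fit$template
  q <- n_random_effects(p)
  na <- 2L + (fit$model == "psa-cr")
  p$beta_psa <- d$beta_psa[l, ]
  if (!is.null(d$beta_cr)) p$beta_cr <- d$beta_cr[l, ]
  sv <- d$surv[l, ]
  p$gamma <- list(PRG = unname(sv[1L]), TRT = unname(sv[na + 2L]))
  p$alpha <- list(PRG = unname(sv[1L + seq_len(na)]),
                  TRT = unname(sv[na + 2L + seq_len(na)]))
  nb <- length(p$baseline$PRG)
  p$baseline <- list(PRG = unname(d$baseline[l, seq_len(nb)]),
                     TRT = unname(d$baseline[l, nb + seq_len(nb)]))
  p$sigma_eps <- d$sigma_eps[l]
  p$omega <- matrix(d$omega[l, ], q, q)
  p
}

# ---------------------------------------------------------------------------

init_state <- function(pre, template, priors) {
  n <- pre$n; q <- pre$q
  X <- cbind(pre$psa_Z, pre$agec[pre$psa_idx])
  bp <- drop(solve(crossprod(X) + diag(1e-6, 5), crossprod(X, pre$psa_y)))
  r <- pre$psa_y - drop(X %*% bp)
  sigma <- if (length(r) > 1L) max(stats::sd(r) / sqrt(3), 0.05) else 1
  # per-subject ridge estimates of the PSA random effects
  u <- matrix(0, n, q)
  prec0 <- diag(1 / c(0.4, 0.3, 0.3, 0.3)^2)
  for (i in seq_len(n)) {
    jj <- which(pre$psa_idx == i)
    if (!length(jj)) next
    Zi <- pre$psa_Z[jj, , drop = FALSE]
    u[i, 1:4] <- drop(solve(crossprod(Zi) / sigma^2 + prec0,
                            crossprod(Zi, r[jj]) / sigma^2))
  }
  bc <- NULL
  if (pre$two_marker) {
    ptot <- (sum(pre$cr_pos) + 0.5) / (sum(pre$cr_tot) + 1)
    bc <- c(stats::qlogis(ptot), 0, 0)
  }
  om <- diag(q)
  om[1:4, 1:4] <- stats::cov(u[, 1:4, drop = FALSE]) + diag(0.02, 4)
  if (q == 7L) om[5:7, 5:7] <- diag(c(0.5, 0.1, 0.02)^2)
  # crude person-years: role-0 node weights integrate t over both events
  t_up_sum <- max(sum(pre$node_w[pre$node_role == 0L]) / 2, 1)
  nb <- ncol(pre$node_D)
  rate <- function(k) {
    ev <- sum(pre$delta == k)
    log(max(ev, 0.5) / max(t_up_sum, 1))
  }
  bco <- matrix(0, nb, 2)
  bco[1L, ] <- c(rate(1L), rate(2L))
  if (nb > 2L) bco[] <- rep(c(rate(1L), rate(2L)), each = nb)
  list(bp = bp, bc = bc, u = u, g2 = c(0, 0), amat = matrix(0, 2, 3),
       bco = bco, lsig = log(sigma), omega = om, tau = c(1, 1))
}

run_chain <- function(pre, template, st, config, priors,
                      update = c("bp", "bc", "surv1", "surv2", "lsig", "u",
                                 "omega", "tau"),
                      verbose = FALSE, chain_id = 1L) {
  n <- pre$n; q <- pre$q
  two_marker <- pre$two_marker
  na <- 2L + two_marker          # association coefficients per event
  nb <- ncol(pre$node_D)
  bspline <- template$baseline_type == "bspline"
  K2 <- if (bspline) crossprod(diff(diag(nb), differences = 2L))
  n_adapt <- config$n_adapt
  n_total <- n_adapt + config$n_burn + config$n_iter
  n_keep <- config$n_iter %/% config$thin
  target <- config$accept_target

  eval_ll <- function(st, what) {
    ll <- cohort_loglik(pre, st$bp, st$bc, st$u, st$g2, st$amat,
                        st$bco, exp(st$lsig), what)
    if (any(!is.finite(ll$event)) || any(!is.finite(ll$psa)))
      ll$event[!is.finite(ll$event)] <- -Inf
    ll
  }
  cur <- eval_ll(st, c(TRUE, TRUE))
  if (!all(is.finite(cur$event + cur$psa + cur$cr))) {
    st$u[] <- 0
    cur <- eval_ll(st, c(TRUE, TRUE))
    if (!all(is.finite(cur$event + cur$psa + cur$cr)))
      stop("non-finite likelihood at initial values")
  }

  # MH blocks: parameter getters/setters over the flat state
  blocks <- list(
    bp = list(get = function(st) st$bp,
              set = function(st, v) { st$bp <- v; st },
              what = c(TRUE, TRUE),
              lp = function(v) lprior_normal(v, priors$coef_sd)),
    surv1 = list(get = function(st) c(st$g2[1L], st$amat[1L, seq_len(na)],
                                      st$bco[, 1L]),
                 set = function(st, v) {
                   st$g2[1L] <- v[1L]; st$amat[1L, seq_len(na)] <- v[1L + seq_len(na)]
                   st$bco[, 1L] <- v[-seq_len(1L + na)]; st
                 },
                 what = c(FALSE, TRUE),
                 lp = function(v) {
                   b <- v[-seq_len(1L + na)]
                   lprior_normal(v, priors$coef_sd) -
                     if (bspline) 0.5 * st$tau[1L] *
                       drop(crossprod(b, K2 %*% b)) else 0
                 }),
    surv2 = list(get = function(st) c(st$g2[2L], st$amat[2L, seq_len(na)],
                                      st$bco[, 2L]),
                 set = function(st, v) {
                   st$g2[2L] <- v[1L]; st$amat[2L, seq_len(na)] <- v[1L + seq_len(na)]
                   st$bco[, 2L] <- v[-seq_len(1L + na)]; st
                 },
                 what = c(FALSE, TRUE),
                 lp = function(v) {
                   b <- v[-seq_len(1L + na)]
                   lprior_normal(v, priors$coef_sd) -
                     if (bspline) 0.5 * st$tau[2L] *
                       drop(crossprod(b, K2 %*% b)) else 0
                 }),
    lsig = list(get = function(st) st$lsig,
                set = function(st, v) { st$lsig <- v; st },
                what = c(TRUE, FALSE),
                lp = function(v) lprior_sigma(v, priors$sigma_scale)))
  if (two_marker)
    blocks$bc <- list(get = function(st) st$bc,
                      set = function(st, v) { st$bc <- v; st },
                      what = c(TRUE, TRUE),
                      lp = function(v) lprior_normal(v, priors$coef_sd))
  blocks <- blocks[intersect(names(blocks), update)]

  dims <- vapply(blocks, function(b) length(b$get(st)), 0L)
  ls <- log(2.38 / sqrt(dims)) - 1       # initial log proposal scales
  prop_chol <- lapply(dims, function(d) diag(0.1, d))
  hist_mat <- lapply(dims, function(d) matrix(0, n_adapt, d))
  acc_cnt <- stats::setNames(numeric(length(blocks)), names(blocks))
  ls_u <- log(0.5); acc_u <- 0
  S0 <- diag(priors$omega_scale, q)

  keep <- list(beta_psa = matrix(0, n_keep, 5),
               beta_cr = if (two_marker) matrix(0, n_keep, 3),
               surv = matrix(0, n_keep, 2L * (1L + na)),
               baseline = matrix(0, n_keep, 2L * nb),
               sigma_eps = numeric(n_keep),
               omega = matrix(0, n_keep, q * q),
               u = array(0, c(n_keep, n, q)))
  surv_names <- c(t(outer(c("PRG", "TRT"),
                          c("gamma", "alpha1", "alpha2",
                            if (two_marker) "alpha_cr"),
                          paste, sep = "_")))
  colnames(keep$surv) <- surv_names
  kk <- 0L

  lsum <- function(ll) sum(ll$psa) + sum(ll$cr) + sum(ll$event)
  om_chol <- chol(st$omega)

  for (it in seq_len(n_total)) {
    adapting <- it <= n_adapt
    rm_step <- 3 / sqrt(it)

    # --- MH coefficient blocks ---
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      v <- b$get(st)
      vp <- v + drop(rmvn_chol(1, prop_chol[[bi]])) * exp(ls[bi])
      stp <- b$set(st, vp)
      llp <- eval_ll(stp, b$what)
      if (!b$what[1L]) { llp$psa <- cur$psa; llp$cr <- cur$cr }
      if (!b$what[2L]) llp$event <- cur$event
      lr <- lsum(llp) + b$lp(vp) - lsum(cur) - b$lp(v)
      apr <- min(1, exp(lr))
      if (is.finite(lr) && stats::runif(1) < apr) {
        st <- stp; cur <- llp
        if (!adapting) acc_cnt[bi] <- acc_cnt[bi] + 1
      }
      if (adapting) {
        ls[bi] <- ls[bi] + rm_step * ((if (is.finite(apr)) apr else 0) - target)
        hist_mat[[bi]][it, ] <- b$get(st)
        if (it >= 100L && it %% 25L == 0L) {
          cv <- stats::cov(hist_mat[[bi]][seq_len(it), , drop = FALSE])
          cv <- cv + diag(1e-8 + 1e-6 * mean(diag(cv)), dims[bi])
          prop_chol[[bi]] <- chol(cv)
        }
      }
    }

    # --- per-subject random effects ---
    if ("u" %in% update) {
    up <- st$u + rmvn_chol(n, om_chol) * exp(ls_u)
    stp <- st; stp$u <- up
    llp <- eval_ll(stp, c(TRUE, TRUE))
    qf_cur <- mvn_quadform(st$u, om_chol)
    qf_prop <- mvn_quadform(up, om_chol)
    lr_i <- (llp$psa + llp$cr + llp$event - 0.5 * qf_prop) -
      (cur$psa + cur$cr + cur$event - 0.5 * qf_cur)
    acc_i <- is.finite(lr_i) & stats::runif(n) < exp(lr_i)
    if (any(acc_i)) {
      st$u[acc_i, ] <- up[acc_i, , drop = FALSE]
      cur$psa[acc_i] <- llp$psa[acc_i]
      cur$cr[acc_i] <- llp$cr[acc_i]
      cur$event[acc_i] <- llp$event[acc_i]
    }
    a_mean <- mean(pmin(1, exp(pmax(pmin(lr_i, 0), -50))))
    if (adapting) ls_u <- ls_u + rm_step * (a_mean - target)
    else acc_u <- acc_u + mean(acc_i)
    }

    # --- Gibbs: random-effects covariance ---
    if ("omega" %in% update) {
      Sn <- S0 + crossprod(st$u)
      W <- stats::rWishart(1, q + priors$omega_df + n, solve(Sn))[, , 1]
      st$omega <- chol2inv(chol(W))
      st$omega <- (st$omega + t(st$omega)) / 2
      om_chol <- chol(st$omega)
    }

    # --- Gibbs: roughness penalty precision (B-spline baseline) ---
    if (bspline && "tau" %in% update) {
      for (k in 1:2) {
        qf <- drop(crossprod(st$bco[, k], K2 %*% st$bco[, k]))
        st$tau[k] <- stats::rgamma(1, priors$rw2_a + (nb - 2) / 2,
                                   priors$rw2_b + qf / 2)
      }
    }

    post <- it - n_adapt - config$n_burn
    if (post > 0L && post %% config$thin == 0L) {
      kk <- kk + 1L
      keep$beta_psa[kk, ] <- st$bp
      if (two_marker) keep$beta_cr[kk, ] <- st$bc
      keep$surv[kk, ] <- c(st$g2[1L], st$amat[1L, seq_len(na)],
                           st$g2[2L], st$amat[2L, seq_len(na)])
      keep$baseline[kk, ] <- c(st$bco[, 1L], st$bco[, 2L])
      keep$sigma_eps[kk] <- exp(st$lsig)
      keep$omega[kk, ] <- st$omega
      keep$u[kk, , ] <- st$u
    }
    if (verbose && it %% 500L == 0L)
      message(sprintf("chain %d: iteration %d/%d", chain_id, it, n_total))
  }

  keep$accept <- c(acc_cnt / (n_total - n_adapt),
                   u = acc_u / (n_total - n_adapt))
  keep
}

# split-Rhat over a list of per-chain draw vectors
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); nn <- length(halves[[1L]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars); B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size via the initial positive sequence of autocorrelations
ess_basic <- function(x) {
  nn <- length(x)
  if (stats::var(x) == 0) return(0)
  ac <- stats::acf(x, lag.max = min(nn - 1L, 200L), plot = FALSE)$acf[-1L]
  s <- 0
  for (j in seq_along(ac)) {
    if (ac[j] < 0.05) break
    s <- s + ac[j]
  }
  nn / (1 + 2 * s)
}
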