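#' Prediction context for a new subject
#'
#' Gathers everything known about a subject at the moment a risk prediction
#' is made: the biomarker history up to `t_y`, the baseline covariates, the
#' time `t_b` of the last (negative) biopsy and the current visit time `t_v`.
#'
#' @param psa data frame with columns `time`, `psa` (history up to `t_y`).
#' @param cores optional data frame with `time`, `pos_cores`, `total_cores`.
#' @param age age at entry (years).
#' @param log_psa_density log baseline PSA density.
#' @param t_b time of the most recent negative biopsy (years).
#' @param t_v current clinical visit time, `t_v >= t_b`.
#' @param t_y time of the latest biomarker measurement (defaults to the last
#'   observation time; must not exceed `t_v`).
#' @return an object of class `icjm_context`.
#' @export
prediction_context <- function(psa, cores = NULL, age, log_psa_density,
                               t_b, t_v = t_b, t_y = NULL) {
  psa <- as.data.frame(psa)
  if (is.null(t_y))
    t_y <- max(c(0, psa$time, if (!is.null(cores)) cores$time))
  if (t_b > t_v + 1e-12) stop("t_b must not exceed t_v")
  if (t_y > t_v + 1e-9) stop("biomarker observations cannot postdate t_v")
  keep <- psa$time <= t_y + 1e-9
  psa <- psa[keep, , drop = FALSE]
  if (!is.null(cores)) {
    cores <- as.data.frame(cores)
    cores <- cores[cores$time <= t_y + 1e-9, , drop = FALSE]
    if (!nrow(cores)) cores <- NULL
  }
  structure(list(psa = psa, cores = cores, age = age,
                 log_psa_density = log_psa_density,
                 t_b = t_b, t_v = t_v, t_y = t_y),
            class = "icjm_context")
}

#' Thin posterior draws into a list of parameter objects
#'
#' @param fit an [icjm_fit()] object.
#' @param n_draws number of approximately equally spaced draws to keep.
#' @return list of [icjm_params()] objects.
#' @export
thin_draws <- function(fit, n_draws = 500L) {
  nt <- nrow(fit$draws$surv)
  idx <- unique(round(seq(1L, nt, length.out = min(n_draws, nt))))
  lapply(idx, function(l) as_params(fit, l))
}

# Stack a list of icjm_params into draw-indexed arrays for vectorized
# evaluation across draws.
stack_params <- function(draws) {
  L <- length(draws)
  q <- n_random_effects(draws[[1L]])
  nb <- length(draws[[1L]]$baseline$PRG)
  na <- length(draws[[1L]]$alpha$PRG)
  g <- function(f) vapply(draws, f, 0)
  list(L = L, q = q, na = na,
       b13 = vapply(draws, function(p) p$beta_psa[1:4], numeric(4)),  # 4 x L
       b4 = g(function(p) p$beta_psa[5L]),
       bcr = if (!is.null(draws[[1L]]$beta_cr))
         vapply(draws, function(p) p$beta_cr, numeric(3)),
       sigma = g(function(p) p$sigma_eps),
       gam = rbind(PRG = g(function(p) p$gamma$PRG),
                   TRT = g(function(p) p$gamma$TRT)),
       a_prg = vapply(draws, function(p) p$alpha$PRG, numeric(na)),
       a_trt = vapply(draws, function(p) p$alpha$TRT, numeric(na)),
       bco_prg = vapply(draws, function(p) p$baseline$PRG, numeric(nb)),
       bco_trt = vapply(draws, function(p) p$baseline$TRT, numeric(nb)),
       om_chol = lapply(draws, function(p) chol(p$omega)),
       template = draws[[1L]])
}

# log-hazard matrix (length(t) x L) for all draws at times t, given
# per-draw random effects U (L x q)
loghaz_draws <- function(k, t, sp, U, context) {
  p0 <- sp$template
  B <- cbind(1, ns_basis(t, p0$knots))
  Lg <- cbind(1, ns_basis(t - 1, p0$knots))
  D <- baseline_design(t, p0)
  coefs <- sp$b13 + t(U[, 1:4, drop = FALSE])          # 4 x L
  m <- B %*% coefs
  mlag <- Lg %*% coefs
  agec_term <- (context$age - p0$age_center) * sp$b4   # length L
  m <- sweep(m, 2, agec_term, "+")
  mlag <- sweep(mlag, 2, agec_term, "+")
  a <- if (k == "PRG") sp$a_prg else sp$a_trt
  bco <- if (k == "PRG") sp$bco_prg else sp$bco_trt
  lh <- D %*% bco + sweep(m, 2, a[1L, ], "*") +
    sweep(m - mlag, 2, a[2L, ], "*")
  lh <- sweep(lh, 2, sp$gam[k, ] * context$log_psa_density, "+")
  if (nrow(a) >= 3L) {
    mcr <- cbind(1, t, t^2) %*% (sp$bcr + t(U[, 5:7, drop = FALSE]))
    lh <- lh + sweep(mcr, 2, a[3L, ], "*")
  }
  lh
}

# Cumulative hazards H_k(t0, t1) for all draws: composite GK with
# ceil((t1-t0)/panel) panels; returns length-L vector.
cumhaz_draws <- function(k, t0, t1, sp, U, context, panel = 2) {
  if (t1 <= t0) return(numeric(sp$L))
  brk <- seq(t0, t1, length.out = 1L + max(1L, ceiling((t1 - t0) / panel)))
  tt <- ww <- numeric(0)
  for (j in seq_len(length(brk) - 1L)) {
    gk <- gk_rescale(brk[j], brk[j + 1L])
    tt <- c(tt, gk$t); ww <- c(ww, gk$w)
  }
  colSums(ww * exp(loghaz_draws(k, tt, sp, U, context)))
}

# Build a fast evaluator of the random-effects log target (MVN prior +
# longitudinal likelihood + survival-to-(t_b[, t_v]) factor) for all draws
# at once; all design matrices and draw-static terms are precomputed so each
# Metropolis step costs a few dense matrix products.
make_ctx_target <- function(sp, context, condition_trt) {
  p0 <- sp$template
  L <- sp$L
  omi <- lapply(sp$om_chol, chol2inv)
  ldet <- -vapply(sp$om_chol, function(R) sum(log(diag(R))), 0)
  n_psa <- nrow(context$psa)
  if (n_psa) {
    Z <- cbind(1, ns_basis(context$psa$time, p0$knots))
    y <- log2(context$psa$psa + 1)
    m0 <- Z %*% sp$b13 +
      rep((context$age - p0$age_center) * sp$b4, each = n_psa)
    lsig_term <- -n_psa * log(sp$sigma)
  }
  has_cr <- !is.null(context$cores) && !is.null(sp$bcr)
  if (has_cr) {
    tc <- context$cores$time
    Zc <- cbind(1, tc, tc^2)
    eta0 <- Zc %*% sp$bcr
  }
  haz_block <- function(k, t1) {
    brk <- seq(0, t1, length.out = 1L + max(1L, ceiling(t1 / 2)))
    tt <- ww <- numeric(0)
    for (j in seq_len(length(brk) - 1L)) {
      gk <- gk_rescale(brk[j], brk[j + 1L])
      tt <- c(tt, gk$t); ww <- c(ww, gk$w)
    }
    B <- cbind(1, ns_basis(tt, p0$knots))
    Lg <- cbind(1, ns_basis(tt - 1, p0$knots))
    D <- baseline_design(tt, p0)
    a <- if (k == "PRG") sp$a_prg else sp$a_trt
    bco <- if (k == "PRG") sp$bco_prg else sp$bco_trt
    nnod <- length(tt)
    # draw-static part of the log-hazard at the nodes
    stat <- D %*% bco +
      rep(sp$gam[k, ] * context$log_psa_density, each = nnod) +
      (B %*% sp$b13) * rep(a[1L, ], each = nnod) +
      ((B - Lg) %*% sp$b13) * rep(a[2L, ], each = nnod) +
      rep((context$age - p0$age_center) * sp$b4 * a[1L, ], each = nnod)
    if (nrow(a) >= 3L)
      stat <- stat + (cbind(1, tt, tt^2) %*% sp$bcr) * rep(a[3L, ], each = nnod)
    list(w = ww, B = B, BL = B - Lg, Zc = cbind(1, tt, tt^2), a = a,
         stat = stat)
  }
  hb_prg <- if (context$t_b > 0) haz_block("PRG", context$t_b)
  hb_trt <- if (condition_trt && context$t_v > 0)
    haz_block("TRT", context$t_v)
  cum_block <- function(hb, U) {
    u4 <- t(U[, 1:4, drop = FALSE])
    lh <- hb$stat + (hb$B %*% u4) * rep(hb$a[1L, ], each = length(hb$w)) +
      (hb$BL %*% u4) * rep(hb$a[2L, ], each = length(hb$w))
    if (nrow(hb$a) >= 3L)
      lh <- lh + (hb$Zc[, 1:3] %*% t(U[, 5:7, drop = FALSE])) *
        rep(hb$a[3L, ], each = length(hb$w))
    colSums(hb$w * exp(lh))
  }
  function(U) {
    lt <- ldet
    for (l in seq_len(L))
      lt[l] <- lt[l] - 0.5 * drop(U[l, ] %*% omi[[l]] %*% U[l, ])
    if (n_psa) {
      rs <- (y - m0 - Z %*% t(U[, 1:4, drop = FALSE])) /
        rep(sp$sigma, each = n_psa)
      lt <- lt + colSums(-2 * log1p(rs^2 / 3)) + lsig_term
    }
    if (has_cr) {
      eta <- eta0 + Zc %*% t(U[, 5:7, drop = FALSE])
      lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
      lt <- lt + colSums(context$cores$pos_cores * eta -
                           context$cores$total_cores * lse)
    }
    if (!is.null(hb_prg)) lt <- lt - cum_block(hb_prg, U)
    if (!is.null(hb_trt)) lt <- lt - cum_block(hb_trt, U)
    lt
  }
}

ctx_log_target <- function(U, sp, context, condition_trt) {
  make_ctx_target(sp, context, condition_trt)(U)
}

#' Sample a new subject's random effects given their history
#'
#' Draws one random-effects vector per posterior parameter draw from
#' `p(u | T_PRG > t_b [, T_TRT > t_v], biomarker history, theta)` by a
#' Gaussian random-walk Metropolis-Hastings chain per draw (all chains
#' advance in lock-step, vectorized across draws), with the proposal scale
#' tuned by a Robbins-Monro recursion toward a target acceptance rate. With
#' `condition_trt = TRUE` the target also conditions on being treatment-free
#' until `t_v`; with `FALSE` only on being progression-free until `t_b`, the
#' cheaper form used during schedule generation.
#'
#' @param context a [prediction_context()].
#' @param draws list of [icjm_params()] posterior draws (see [thin_draws()]),
#'   or an [icjm_fit()] (then `n_draws` are thinned from it).
#' @param n_steps Metropolis-Hastings steps per chain.
#' @param target target acceptance rate (0.234, the standard multivariate
#'   random-walk optimum).
#' @param condition_trt condition on treatment-free survival until `t_v`.
#' @param n_draws number of parameter draws when `draws` is a fit.
#' @return matrix (draws x random effects) with attributes `accept`
#'   (realized post-adaptation acceptance rate) and `scale`.
#' @export
sample_new_subject_effects <- function(context, draws, n_steps = 25L,
                                       target = 0.234, condition_trt = TRUE,
                                       n_draws = 500L) {
  if (inherits(draws, "icjm_fit")) draws <- thin_draws(draws, n_draws)
  sp <- stack_params(draws)
  L <- sp$L; q <- sp$q
  # warm start: penalized least squares under the average parameter draw
  U <- matrix(0, L, q)
  if (nrow(context$psa)) {
    Z <- cbind(1, ns_basis(context$psa$time, sp$template$knots))
    sig2 <- mean(sp$sigma)^2
    omega_bar <- Reduce(`+`, lapply(sp$om_chol, crossprod)) / L
    b13_bar <- rowMeans(sp$b13)
    r <- log2(context$psa$psa + 1) - Z %*% b13_bar -
      (context$age - sp$template$age_center) * mean(sp$b4)
    prec <- crossprod(Z) / sig2 + solve(omega_bar)[1:4, 1:4]
    u0 <- drop(solve(prec, crossprod(Z, r) / sig2))
    U[, 1:4] <- matrix(u0, L, 4, byrow = TRUE)
  }
  ltarget <- make_ctx_target(sp, context, condition_trt)
  cur <- ltarget(U)
  if (any(!is.finite(cur))) {
    U[] <- 0  # re-center at the prior mode
    cur <- ltarget(U)
  }
  ls <- log(2.38 / sqrt(q))
  n_adapt <- max(10L, ceiling(n_steps * 0.6))
  acc_sum <- 0; acc_n <- 0L
  for (s in seq_len(n_steps)) {
    Z0 <- matrix(stats::rnorm(L * q), L, q)
    Up <- U
    for (l in seq_len(L))
      Up[l, ] <- U[l, ] + exp(ls) * drop(Z0[l, ] %*% sp$om_chol[[l]])
    prop <- ltarget(Up)
    lr <- prop - cur
    apr <- pmin(1, exp(pmin(lr, 0)))
    acc <- is.finite(lr) & stats::runif(L) < exp(lr)
    U[acc, ] <- Up[acc, , drop = FALSE]
    cur[acc] <- prop[acc]
    if (s <= n_adapt) {
      ls <- ls + 2 / s^0.6 * (mean(apr, na.rm = TRUE) - target)
    } else {
      acc_sum <- acc_sum + mean(acc); acc_n <- acc_n + 1L
    }
  }
  structure(U, accept = if (acc_n) acc_sum / acc_n else NA_real_,
            scale = exp(ls))
}

#' Progression-specific cumulative risk for one parameter draw
#'
#' The conditional probability that progression occurs by `t_p` and before
#' treatment, given progression-free survival to `t_b` and treatment-free
#' survival to `t_v`:
#' \deqn{\int_{t_b}^{t_p} h_{PRG}(v) \exp[-H_{PRG}(v) -
#'   H_{TRT}\{\max(v, t_v)\}] dv \; / \;
#'   \exp\{-H_{PRG}(t_b) - H_{TRT}(t_v)\}.}
#' `form = "general"` evaluates this directly; `"visit"` uses the simplified
#' expression valid when `t_p = t_v` (the treatment factor cancels, leaving
#' only the progression hazard) and is also the planning form for future
#' visits, where the patient is assumed treatment-free through each visit;
#' `"entry"` uses the overall-survival form valid when `t_b = t_v`. The
#' default picks the simplification automatically.
#'
#' @param t_p prediction time, `t_p >= t_b`.
#' @param context a [prediction_context()].
#' @param params one [icjm_params()] draw.
#' @param u random-effects vector for this subject and draw.
#' @param form risk formula variant; see Details.
#' @param tol quadrature tolerance.
#' @return risk in `[0, 1]`.
#' @export
progression_risk <- function(t_p, context, params, u,
                             form = c("auto", "general", "visit", "entry"),
                             tol = 1e-10) {
  form <- match.arg(form)
  t_b <- context$t_b; t_v <- context$t_v
  if (t_p < t_b) stop("t_p must be >= t_b")
  if (t_p == t_b) return(0)
  if (form == "auto")
    form <- if (t_p <= t_v) "visit" else if (t_b == t_v) "entry" else "general"
  if (form == "visit" && t_p > t_v && t_b < t_v)
    warning("'visit' form with t_p > t_v assumes the subject stays ",
            "treatment-free through t_p (planning assumption)")
  if (form == "entry" && abs(t_b - t_v) > 1e-9)
    stop("'entry' form requires t_b = t_v")
  haz <- function(k, t) cause_specific_hazard(k, t, context$age,
                                              context$log_psa_density,
                                              params, u)
  cum <- function(k, a, b) cumulative_hazard(k, a, b, context$age,
                                             context$log_psa_density,
                                             params, u, tol = tol)
  Hp <- function(t) vapply(t, function(x) cum("PRG", t_b, x), 0)
  num <- switch(form,
    general = gk_integrate(function(v)
      haz("PRG", v) * exp(-Hp(v) -
        vapply(v, function(x) cum("TRT", t_v, max(x, t_v)), 0)),
      t_b, t_p, tol = tol),
    visit = gk_integrate(function(v) haz("PRG", v) * exp(-Hp(v)),
                         t_b, t_p, tol = tol),
    entry = gk_integrate(function(v)
      haz("PRG", v) * exp(-Hp(v) - vapply(v, function(x)
        cum("TRT", t_b, x), 0)), t_b, t_p, tol = tol))
  min(max(num, 0), 1)
}

#' Monte-Carlo progression-risk curve for a new subject
#'
#' Averages the per-draw progression-specific cumulative risk over posterior
#' parameter draws and matched random-effects draws (one `u` per `theta`),
#' on a time grid starting at the last negative biopsy. `type = "visit"`
#' (the scheduling form) uses only the progression hazard, so each draw's
#' curve is `1 - exp[-H_PRG(t_b, t)]`; `type = "general"` additionally
#' discounts by the treatment hazard beyond the current visit.
#'
#' Per-draw cumulative hazards are accumulated by the 15-point
#' Gauss-Kronrod rule per grid segment; between grid points the curve is
#' evaluated from a cubic Hermite interpolant of the cumulative hazard
#' (whose derivative, the hazard itself, is stored exactly at the grid).
#'
#' @param context a [prediction_context()].
#' @param draws list of [icjm_params()] or an [icjm_fit()].
#' @param grid increasing prediction times; defaults to visit-spacing / 4
#'   steps from `t_b` to `horizon`.
#' @param horizon latest prediction time (years).
#' @param u optional matrix of random-effects draws (rows matched to
#'   `draws`); sampled via [sample_new_subject_effects()] when missing.
#' @param type `"visit"` or `"general"`.
#' @param visit_spacing grid resolution is `visit_spacing / 4`.
#' @param n_draws,n_steps passed to the random-effects sampler.
#' @param level credible-band level.
#' @return an object of class `icjm_risk` with the grid, per-draw risks,
#'   and the posterior mean and credible band.
#' @export
risk_curve <- function(context, draws, grid = NULL, horizon = 10, u = NULL,
                       type = c("visit", "general"), visit_spacing = 0.5,
                       n_draws = 500L, n_steps = 25L, level = 0.95) {
  type <- match.arg(type)
  if (inherits(draws, "icjm_fit")) draws <- thin_draws(draws, n_draws)
  if (!length(draws)) stop("no parameter draws supplied")
  t_b <- context$t_b
  if (is.null(grid))
    grid <- seq(t_b, max(horizon, t_b), by = visit_spacing / 4)
  grid <- sort(unique(c(t_b, grid)))
  if (any(grid < t_b)) stop("grid times must be >= t_b")
  if (is.null(u))
    u <- sample_new_subject_effects(context, draws, n_steps = n_steps,
                                    condition_trt = (type == "general"))
  sp <- stack_params(draws)
  L <- sp$L; G <- length(grid)

  # per-draw H_PRG(t_b, grid) and hazard values at the grid; all quadrature
  # nodes are evaluated in a single basis construction
  nseg <- G - 1L
  gk_t <- gk_w <- numeric(0)
  for (g in seq_len(nseg)) {
    gk <- gk_rescale(grid[g], grid[g + 1L])
    gk_t <- c(gk_t, gk$t); gk_w <- c(gk_w, gk$w)
  }
  nN <- length(gk_t)
  seg_id <- rep(seq_len(nseg), each = 15L)
  accum <- function(k) {
    lh_all <- exp(loghaz_draws(k, c(gk_t, grid), sp, u, context))
    segsum <- rowsum(gk_w * lh_all[seq_len(nN), , drop = FALSE], seg_id)
    H <- t(rbind(0, apply(segsum, 2, cumsum)))          # L x G
    list(H = H, h = t(lh_all[nN + seq_len(G), , drop = FALSE]),
         lh_nodes = lh_all[seq_len(nN), , drop = FALSE])
  }
  ap <- accum("PRG")
  Hp <- ap$H; hp <- ap$h
  if (type == "general") {
    at <- accum("TRT")
    Ht <- at$H; ht <- at$h
  }
  if (type == "visit") {
    risk <- 1 - exp(-Hp)
  } else {
    # numerator integrand h_PRG exp(-H_PRG(t_b,v) - H_TRT(t_v, max(v,t_v)));
    # the treatment discount starts accruing at t_v
    risk <- matrix(0, L, G)
    Htv <- apply_htv(Ht, grid, context$t_v)
    Hmid <- t(hermite_interp(grid, Hp, hp, gk_t))                   # nN x L
    Htmid <- t(hermite_interp(grid, Ht, ht, pmax(gk_t, context$t_v)))
    Htmid <- Htmid - rep(Htv, each = nN)
    fint <- gk_w * ap$lh_nodes * exp(-Hmid - Htmid)
    inc <- rowsum(fint, seg_id)                                     # nseg x L
    risk[, -1L] <- t(apply(inc, 2, cumsum))
    # integrand at the grid points = exact derivative of the risk curve,
    # stored for Hermite evaluation between grid points
    Htg <- Ht
    Htg[, grid <= context$t_v] <- 0
    Htg[, grid > context$t_v] <- Htg[, grid > context$t_v, drop = FALSE] -
      Htv
    fgrid <- hp * exp(-Hp - Htg)
  }
  al <- (1 - level) / 2
  structure(list(grid = grid, t_b = t_b, t_v = context$t_v, type = type,
                 risk = risk, mean = colMeans(risk),
                 lower = apply(risk, 2, stats::quantile, al),
                 upper = apply(risk, 2, stats::quantile, 1 - al),
                 H = Hp, h = hp,
                 Ht = if (type == "general") Ht,
                 ht = if (type == "general") ht,
                 f = if (type == "general") fgrid,
                 u = u, level = level),
            class = "icjm_risk")
}

# H(t_b, t_v) per draw from the grid interpolant
apply_htv <- function(H, grid, t_v) {
  if (t_v <= grid[1L]) return(numeric(nrow(H)))
  drop(hermite_interp(grid, H, NULL, t_v))
}

# Cubic Hermite interpolation of per-draw cumulative hazards: `grid` the
# knots, `H` (L x G) values, `h` (L x G) exact derivatives (hazards); when
# `h` is NULL, falls back to monotone linear-in-segment slopes. Returns a
# (L x length(t)) matrix.
hermite_interp <- function(grid, H, h, t) {
  G <- length(grid)
  k <- pmin(pmax(findInterval(t, grid), 1L), G - 1L)
  d <- grid[k + 1L] - grid[k]
  s <- (t - grid[k]) / d
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  A <- t(H[, k, drop = FALSE]); B <- t(H[, k + 1L, drop = FALSE]) # T x L
  if (is.null(h)) {
    mk <- mk1 <- (B - A) / d
  } else {
    mk <- t(h[, k, drop = FALSE]); mk1 <- t(h[, k + 1L, drop = FALSE])
  }
  t(h00 * A + h01 * B + (d * h10) * mk + (d * h11) * mk1)
}

#' Evaluate a risk curve at arbitrary times
#'
#' Per-draw risks at times `t` from the curve's stored cumulative-hazard
#' interpolant; exact at grid points.
#'
#' @param curve an `icjm_risk` object.
#' @param t numeric vector of times within the curve's grid range.
#' @param draw_level return the per-draw matrix instead of the mean.
#' @return numeric vector (posterior-mean risk) or draws x times matrix.
#' @export
risk_at <- function(curve, t, draw_level = FALSE) {
  if (any(t < curve$t_b - 1e-9) || any(t > max(curve$grid) + 1e-9))
    stop("times outside the curve's grid range")
  t <- pmin(pmax(t, curve$t_b), max(curve$grid))
  if (curve$type == "visit") {
    Hm <- hermite_interp(curve$grid, curve$H, curve$h, t)
    r <- 1 - exp(-Hm)
  } else {
    # general curves: cubic Hermite on the per-draw risks, whose exact
    # derivative (the numerator integrand) is stored at the grid
    r <- hermite_interp(curve$grid, curve$risk, curve$f, t)
  }
  if (draw_level) unname(r) else unname(colMeans(r))
}

#' @export
print.icjm_risk <- function(x, ...) {
  cat(sprintf(
    "Progression-risk curve (%s form): %d draws, t_b = %.2f, grid up to %.2f\n",
    x$type, nrow(x$risk), x$t_b, max(x$grid)))
  cat(sprintf("  risk at horizon: %.3f [%.3f, %.3f]\n",
              x$mean[length(x$mean)], x$lower[length(x$lower)],
              x$upper[length(x$upper)]))
  invisible(x)
}
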