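# Precompute every data-dependent design quantity the cohort likelihood
# needs, so MCMC iterations reduce to dense linear algebra over fixed
# matrices. Quadrature node layout ("role" codes):
#   0  cumulative-hazard node: contributes -w * h(t) to the event loglik
#   1  outer node of the delta = 1 interval integral (needs h(t) and the
#      inner cumulative hazard of its group)
#   2  inner node: accumulates w * h(t) into its outer group's cumulative
#      hazard H_PRG(0, s_outer)
#   3  log-hazard point: contributes log h(t) (delta = 2 treatment density)
precompute_cohort <- function(cohort, params) {
  n <- length(cohort)
  q <- n_random_effects(params)
  two_marker <- !is.null(params$beta_cr)

  psa_t <- lapply(cohort, function(s) s$psa$time)
  n_psa <- lengths(psa_t)
  psa_idx <- rep.int(seq_len(n), n_psa)
  psa_time <- unlist(psa_t, use.names = FALSE)
  psa_y <- unlist(lapply(cohort, function(s) log2(s$psa$psa + 1)),
                  use.names = FALSE)
  agec <- vapply(cohort, function(s) s$age - params$age_center, 0)
  wcov <- vapply(cohort, function(s) s$log_psa_density, 0)
  delta <- vapply(cohort, function(s) s$delta, 0L)
  psa_Z <- cbind(1, ns_basis(psa_time, params$knots))

  if (two_marker) {
    cr_n <- vapply(cohort, function(s) if (is.null(s$cores)) 0L
                   else nrow(s$cores), 0L)
    cr_idx <- rep.int(seq_len(n), cr_n)
    cr_time <- unlist(lapply(cohort, function(s) s$cores$time),
                      use.names = FALSE)
    cr_pos <- unlist(lapply(cohort, function(s) s$cores$pos_cores),
                     use.names = FALSE)
    cr_tot <- unlist(lapply(cohort, function(s) s$cores$total_cores),
                     use.names = FALSE)
    if (is.null(cr_time)) cr_time <- numeric()
    cr_Z <- cbind(1, cr_time, cr_time^2)
    cr_lch <- lchoose(cr_tot, cr_pos)
  } else {
    cr_idx <- integer(); cr_pos <- numeric(); cr_tot <- numeric()
    cr_Z <- matrix(0, 0, 3); cr_lch <- numeric()
  }

  # -- quadrature nodes ------------------------------------------------
  idx <- integer(); event <- integer(); role <- integer(); grp <- integer()
  wgt <- numeric(); tim <- numeric()
  g_next <- 0L
  add <- function(i, ev, ro, gr, w, t) {
    idx <<- c(idx, rep.int(i, length(t)))
    event <<- c(event, rep.int(ev, length(t)))
    role <<- c(role, rep.int(ro, length(t)))
    grp <<- c(grp, rep.int(gr, length(t)))
    wgt <<- c(wgt, w); tim <<- c(tim, t)
  }
  for (i in seq_len(n)) {
    s <- cohort[[i]]
    if (s$delta != 1L && s$t_prg_minus > 0) {
      gk <- gk_rescale(0, s$t_prg_minus)
      add(i, 0L, 0L, -1L, gk$w, gk$t)
    }
    if (s$t_upper > 0) {
      gk <- gk_rescale(0, s$t_upper)
      add(i, 1L, 0L, -1L, gk$w, gk$t)
    }
    if (s$delta == 1L) {
      out <- gk_rescale(s$t_prg_minus, s$t_upper)
      for (j in seq_along(out$t)) {
        add(i, 0L, 1L, g_next, out$w[j], out$t[j])
        inn <- gk_rescale(0, out$t[j])
        add(i, 0L, 2L, g_next, inn$w, inn$t)
        g_next <- g_next + 1L
      }
    } else if (s$delta == 2L) {
      add(i, 1L, 3L, -1L, 1, s$t_upper)
    }
  }
  node_B <- cbind(1, ns_basis(tim, params$knots))
  node_L <- cbind(1, ns_basis(tim - 1, params$knots))
  node_D <- baseline_design(tim, params)

  list(n = n, q = q, two_marker = two_marker,
       psa_idx = as.integer(psa_idx), psa_y = psa_y, psa_Z = psa_Z,
       cr_idx = as.integer(cr_idx), cr_pos = as.numeric(cr_pos),
       cr_tot = as.numeric(cr_tot), cr_Z = cr_Z, cr_lch = cr_lch,
       agec = agec, wcov = wcov, delta = as.integer(delta),
       node_idx = as.integer(idx), node_event = as.integer(event),
       node_role = as.integer(role), node_grp = as.integer(grp),
       node_w = wgt, node_t = tim, node_t2 = tim^2,
       node_B = node_B, node_L = node_L, node_D = node_D,
       n_groups = g_next)
}

# Compiled cohort log-likelihood over a precomputed design. Returns the
# per-subject longitudinal (PSA, core-ratio) and event log-likelihood
# vectors. `theta` is the flat state used by the sampler.
cohort_loglik <- function(pre, beta_psa, beta_cr, u, gamma2, alpha_mat,
                          bcoef, sigma, what = c(TRUE, TRUE)) {
  icjm_loglik_cpp(pre, beta_psa,
                  if (is.null(beta_cr)) numeric() else beta_cr,
                  u, gamma2, alpha_mat, bcoef, sigma,
                  what[1L], what[2L])
}

# Assemble the sampler-facing pieces of an icjm_params object.
params_to_state <- function(params) {
  alpha_mat <- matrix(0, 2, 3)
  for (j in 1:2) {
    a <- params$alpha[[c("PRG", "TRT")[j]]]
    alpha_mat[j, seq_along(a)] <- a
  }
  list(beta_psa = params$beta_psa, beta_cr = params$beta_cr,
       gamma2 = c(params$gamma$PRG, params$gamma$TRT),
       alpha_mat = alpha_mat,
       bcoef = cbind(params$baseline$PRG, params$baseline$TRT),
       sigma = params$sigma_eps, omega = params$omega)
}
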