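# 15-point Gauss-Kronrod rule on [-1, 1] (QUADPACK abscissae/weights).
gk15 <- local({
  x <- c(0.991455371120813, 0.949107912342759, 0.864864423359769,
         0.741531185599394, 0.586087235467691, 0.405845151377397,
         0.207784955007898, 0)
  w <- c(0.022935322010529, 0.063092092629979, 0.104790010322250,
         0.140653259715525, 0.169004726639267, 0.190350578064785,
         0.204432940075298, 0.209482141084728)
  list(nodes = c(-x[1:7], x[8:1]), weights = c(w[1:7], w[8:1]))
})

# weights of the embedded 7-point Gauss rule (at nodes 2, 4, ..., 14)
g7_weights <- c(0.129484966168870, 0.279705391489277, 0.381830050505119,
                0.417959183673469, 0.381830050505119, 0.279705391489277,
                0.129484966168870)

# Adaptive composite Gauss-Kronrod integration: bisect panels until the
# embedded Gauss-7/Kronrod-15 error estimate meets `tol`. `f` must be
# vectorized.
gk_integrate <- function(f, a, b, tol = 1e-10, max_depth = 20L) {
  panel <- function(a, b, depth) {
    gk <- gk_rescale(a, b)
    fv <- f(gk$t)
    k15 <- sum(gk$w * fv)
    g7 <- (b - a) / 2 * sum(g7_weights * fv[c(2, 4, 6, 8, 10, 12, 14)])
    err <- (200 * abs(k15 - g7))^1.5
    if (depth >= max_depth || err <= max(tol, tol * abs(k15)))
      return(k15)
    mid <- (a + b) / 2
    panel(a, mid, depth + 1L) + panel(mid, b, depth + 1L)
  }
  if (b <= a) return(0)
  panel(a, b, 0L)
}

# Nodes/weights of the 15-point rule rescaled to (a, b); vectors of length 15.
gk_rescale <- function(a, b) {
  h <- (b - a) / 2
  list(t = (a + b) / 2 + h * gk15$nodes, w = h * gk15$weights)
}

# Baseline log-hazard design d(t): Weibull -> (1, log t); B-spline -> cubic
# B-spline basis clamped to its knot range (constant log-hazard beyond it).
baseline_design <- function(t, params) {
  if (params$baseline_type == "weibull") {
    cbind(1, log(pmax(t, 1e-12)))
  } else {
    kn <- params$baseline_knots
    tc <- pmin(pmax(t, kn[4L] + 1e-10), kn[length(kn) - 3L] - 1e-10)
    splines::splineDesign(kn, tc, ord = 4L)
  }
}

# Full knot vector for a 9-column cubic B-spline baseline on [0, upper],
# interior knots at quantiles of the observed event/censoring times.
baseline_bspline_knots <- function(event_times, upper = max(event_times),
                                   df = 9L) {
  n_int <- df - 4L
  interior <- stats::quantile(event_times[event_times > 0],
                              probs = seq_len(n_int) / (n_int + 1))
  sort(c(rep(0, 4L), pmin(pmax(interior, 1e-3), upper - 1e-3), rep(upper, 4L)))
}

#' Cause-specific hazard of progression or treatment
#'
#' Proportional-hazards form
#' `h_k(t) = h0_k(t) exp(gamma_k w + a1 m(t) + a2 (m(t) - m(t-1)) [+ a3 mcr(t)])`
#' where `m` is the expected log2(PSA+1) trajectory, `m(t) - m(t-1)` its
#' yearly change (extrapolated for `t < 1`), and `mcr` the logit-scale
#' expected core ratio (two-marker model only).
#'
#' @param k event type, `"PRG"` (progression) or `"TRT"` (early treatment).
#' @param t numeric vector of positive times (years).
#' @param age subject age at entry.
#' @param log_psa_density subject log baseline PSA density.
#' @param params an [icjm_params()] object.
#' @param u random-effects vector.
#' @return numeric vector of hazards (strictly positive).
#' @export
cause_specific_hazard <- function(k, t, age, log_psa_density, params,
                                  u = numeric(nrow(params$omega))) {
  if (!k %in% c("PRG", "TRT")) stop("unknown event type: ", k)
  a <- params$alpha[[k]]
  lh <- drop(baseline_design(t, params) %*% params$baseline[[k]]) +
    params$gamma[[k]] * log_psa_density +
    a[1L] * psa_mean(t, age, params, u) +
    a[2L] * psa_yearly_change(t, age, params, u)
  if (length(a) >= 3L) lh <- lh + a[3L] * cr_mean(t, params, u)
  exp(lh)
}

#' Cumulative cause-specific hazard by Gauss-Kronrod quadrature
#'
#' `H_k(t0, t1) = int_{t0}^{t1} h_k(v) dv`, computed with the 15-point
#' Gauss-Kronrod rule on the rescaled interval, bisecting panels adaptively
#' (via the embedded 7-point Gauss error estimate) until the requested
#' tolerance is met.
#'
#' @inheritParams cause_specific_hazard
#' @param t0,t1 integration limits in years, `0 <= t0 <= t1`.
#' @param tol absolute/relative quadrature tolerance.
#' @export
cumulative_hazard <- function(k, t0, t1, age, log_psa_density, params,
                              u = numeric(nrow(params$omega)), tol = 1e-10) {
  if (t1 < t0) stop("t1 must be >= t0")
  if (t1 == t0) return(0)
  gk_integrate(function(t) cause_specific_hazard(k, t, age, log_psa_density,
                                                 params, u),
               t0, t1, tol = tol)
}
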