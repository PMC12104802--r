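#' Natural cubic spline basis for the PSA time trend
#'
#' Evaluates the 3-column natural cubic spline basis \eqn{C^{(1..3)}(t)} used
#' for the time effect in the PSA trajectory model. The basis is twice
#' continuously differentiable between the boundary knots and exactly linear
#' outside them, so evaluation at times below the lower boundary knot (needed
#' for the one-year-lagged PSA value at \eqn{t < 1}) is a linear extrapolation
#' of the fitted trajectory.
#'
#' @param t numeric vector of times (years); values outside the boundary knots
#'   are allowed and extrapolated linearly.
#' @param knots list with components `interior` (2 interior knots) and
#'   `boundary` (2 boundary knots), as produced by [spline_knots()].
#' @return numeric matrix with `length(t)` rows and 3 columns.
#' @export
ns_basis <- function(t, knots) {
  check_knots(knots)
  if (!length(t)) return(matrix(0, 0L, 3L))
  # splines::ns with 2 interior knots gives the 3-df natural basis; it is
  # linear beyond the boundary knots by construction.
  unclass(splines::ns(t, knots = knots$interior,
                      Boundary.knots = knots$boundary))[, , drop = FALSE]
}

check_knots <- function(knots) {
  if (!is.list(knots) || is.null(knots$interior) || is.null(knots$boundary))
    stop("`knots` must be a list with `interior` and `boundary` components")
  all_k <- c(knots$boundary[1L], knots$interior, knots$boundary[2L])
  if (anyNA(all_k) || any(diff(all_k) <= 0))
    stop("spline knots must be strictly increasing, with interior knots ",
         "inside the boundary knots")
  invisible(knots)
}

#' Choose spline knots from observed follow-up times
#'
#' Interior knots are placed at the 33.3% and 66.7% quantiles of the pooled
#' PSA measurement times and event/censoring times; the boundary knots at 0
#' and the 99th percentile, following the usual practice of tying the knot
#' locations to the observed time distribution.
#'
#' @param psa_times numeric vector of PSA measurement times (years).
#' @param event_times numeric vector of observed event/censoring times.
#' @return a knot list suitable for [ns_basis()].
#' @export
spline_knots <- function(psa_times, event_times = numeric()) {
  tt <- c(psa_times, event_times)
  tt <- tt[is.finite(tt) & tt >= 0]
  if (length(tt) < 4L) stop("too few time points to place spline knots")
  interior <- unname(stats::quantile(tt, c(1 / 3, 2 / 3)))
  upper <- unname(stats::quantile(tt, 0.99))
  if (interior[1L] <= 0) interior[1L] <- upper / 3
  if (diff(interior) <= 0 || interior[2L] >= upper)
    stop("degenerate time distribution: cannot place interior knots")
  list(interior = interior, boundary = c(0, upper))
}
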