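#' Assemble one subject's observed data
#'
#' One record per subject on active surveillance: longitudinal PSA and biopsy
#' core-count observations, baseline covariates, and the event summary
#' consisting of the censoring indicator `delta` and the observed time pair.
#' `delta = 0` means right-censored (last negative biopsy at `t_prg_minus`,
#' treatment-free until `t_upper`, the censoring time); `delta = 1` means
#' progression detected by a biopsy, with the true progression time interval
#' censored in `(t_prg_minus, t_upper]`; `delta = 2` means early treatment
#' started at `t_upper`, with the last negative biopsy at `t_prg_minus`.
#'
#' @param id subject identifier.
#' @param psa data frame with columns `time` (years) and `psa` (ng/ml).
#' @param cores data frame with columns `time`, `pos_cores`, `total_cores`,
#'   or NULL when no biopsy core counts are recorded.
#' @param age age at entry (years).
#' @param log_psa_density log of baseline PSA density (time-fixed covariate).
#' @param delta censoring indicator in {0, 1, 2}.
#' @param t_prg_minus time of the last progression-free biopsy (years).
#' @param t_upper censoring time (`delta = 0`), detection-biopsy time
#'   (`delta = 1`) or treatment time (`delta = 2`).
#' @return an object of class `icjm_subject`.
#' @export
icjm_subject <- function(id, psa, cores = NULL, age, log_psa_density,
                         delta, t_prg_minus, t_upper) {
  psa <- as.data.frame(psa)
  stopifnot(all(c("time", "psa") %in% names(psa)))
  if (!is.null(cores) && nrow(as.data.frame(cores))) {
    cores <- as.data.frame(cores)
    stopifnot(all(c("time", "pos_cores", "total_cores") %in% names(cores)))
  } else cores <- NULL
  if (!delta %in% 0:2) stop("delta must be 0, 1 or 2")
  if (t_prg_minus < 0 || t_upper < 0) stop("event times must be >= 0")
  if (t_prg_minus > t_upper + 1e-12)
    stop("t_prg_minus must not exceed t_upper")
  if (delta == 1 && t_prg_minus >= t_upper)
    stop("delta = 1 requires a nonempty censoring interval ",
         "(t_prg_minus < t_upper)")
  if (nrow(psa) && any(psa$time > t_upper + 1e-9))
    stop("PSA observations after t_upper")
  if (nrow(psa) && (any(psa$time < 0) || any(psa$psa < 0)))
    stop("PSA times and values must be >= 0")
  if (!is.null(cores)) {
    if (any(cores$time > t_upper + 1e-9))
      stop("core observations after t_upper")
    if (any(cores$total_cores <= 0) ||
        any(cores$pos_cores < 0) ||
        any(cores$pos_cores > cores$total_cores))
      stop("core counts must satisfy 0 <= pos_cores <= total_cores")
  }
  structure(list(id = id, psa = psa, cores = cores, age = age,
                 log_psa_density = log_psa_density, delta = as.integer(delta),
                 t_prg_minus = t_prg_minus, t_upper = t_upper),
            class = "icjm_subject")
}

#' @export
print.icjm_subject <- function(x, ...) {
  cat(sprintf(
    "Subject %s: %d PSA obs, %d biopsy core records, delta = %d, T = (%.2f, %.2f]\n",
    x$id, nrow(x$psa), if (is.null(x$cores)) 0L else nrow(x$cores),
    x$delta, x$t_prg_minus, x$t_upper))
  invisible(x)
}
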