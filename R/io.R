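#' Read a cohort from long-format CSV files
#'
#' `psa.csv` must have columns `id,time,psa`; `cores.csv` (optional)
#' `id,time,pos_cores,total_cores`; `events.csv`
#' `id,delta,t_prg_minus,t_upper,age,log_psa_density`. Rows violating the
#' subject invariants are rejected with their file and line number (header
#' is line 1). IDs must be consistent across files: every id in the
#' longitudinal files must appear in the event table.
#'
#' @param psa_path,events_path,cores_path file paths (`cores_path` optional).
#' @return list of [icjm_subject()] objects.
#' @export
read_cohort <- function(psa_path, events_path, cores_path = NULL) {
  psa <- read_checked(psa_path, c("id", "time", "psa"))
  events <- read_checked(events_path, c("id", "delta", "t_prg_minus",
                                        "t_upper", "age", "log_psa_density"))
  cores <- if (!is.null(cores_path))
    read_checked(cores_path, c("id", "time", "pos_cores", "total_cores"))
  if (anyDuplicated(events$id))
    stop("duplicate ids in ", events_path)
  bad <- !psa$id %in% events$id
  if (any(bad))
    stop(psa_path, " line ", which(bad)[1L] + 1L,
         ": id not present in the event table")
  if (!is.null(cores)) {
    bad <- !cores$id %in% events$id
    if (any(bad))
      stop(cores_path, " line ", which(bad)[1L] + 1L,
           ": id not present in the event table")
    badc <- cores$pos_cores > cores$total_cores | cores$pos_cores < 0 |
      cores$total_cores <= 0
    if (any(badc))
      stop(cores_path, " line ", which(badc)[1L] + 1L,
           ": core counts must satisfy 0 <= pos_cores <= total_cores")
  }
  if (any(!events$delta %in% 0:2))
    stop(events_path, " line ", which(!events$delta %in% 0:2)[1L] + 1L,
         ": delta must be 0, 1 or 2")
  cohort <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    cohort[[i]] <- tryCatch(
      icjm_subject(e$id,
                   psa[psa$id == e$id, c("time", "psa"), drop = FALSE],
                   if (!is.null(cores))
                     cores[cores$id == e$id,
                           c("time", "pos_cores", "total_cores"),
                           drop = FALSE],
                   e$age, e$log_psa_density, e$delta, e$t_prg_minus,
                   e$t_upper),
      error = function(err)
        stop(events_path, " line ", i + 1L, " (id ", e$id, "): ",
             conditionMessage(err), call. = FALSE))
  }
  cohort
}

read_checked <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  missing <- setdiff(cols, names(d))
  if (length(missing))
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  for (cc in setdiff(cols, "id")) {
    if (!is.numeric(d[[cc]]))
      stop(path, " line ",
           which(is.na(suppressWarnings(as.numeric(d[[cc]]))))[1L] + 1L,
           ": non-numeric value in column ", cc)
  }
  d
}

#' Write a cohort to long-format CSV files
#'
#' Inverse of [read_cohort()]; writes `psa.csv`, `events.csv` and, when any
#' subject has core records, `cores.csv` into `dir`.
#'
#' @param cohort list of [icjm_subject()] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  psa <- do.call(rbind, lapply(cohort, function(s)
    if (nrow(s$psa)) data.frame(id = s$id, time = s$psa$time,
                                psa = s$psa$psa)))
  events <- do.call(rbind, lapply(cohort, function(s)
    data.frame(id = s$id, delta = s$delta, t_prg_minus = s$t_prg_minus,
               t_upper = s$t_upper, age = s$age,
               log_psa_density = s$log_psa_density)))
  paths <- c(psa = file.path(dir, "psa.csv"),
             events = file.path(dir, "events.csv"))
  utils::write.csv(psa, paths["psa"], row.names = FALSE)
  utils::write.csv(events, paths["events"], row.names = FALSE)
  cores <- do.call(rbind, lapply(cohort, function(s)
    if (!is.null(s$cores) && nrow(s$cores))
      data.frame(id = s$id, time = s$cores$time,
                 pos_cores = s$cores$pos_cores,
                 total_cores = s$cores$total_cores)))
  if (!is.null(cores)) {
    paths <- c(paths, cores = file.path(dir, "cores.csv"))
    utils::write.csv(cores, paths["cores"], row.names = FALSE)
  }
  invisible(paths)
}

run_config_schema <- c("knots_interior", "knots_boundary",
                       "model", "baseline", "n_chains", "n_adapt", "n_burn",
                       "n_iter", "thin", "seed", "accept_target",
                       "n_train", "n_test", "psa_interval", "visit_interval",
                       "horizon", "accrual", "total_cores",
                       "trt_hazard_scale", "age_mean", "age_sd", "lpd_mean",
                       "lpd_sd", "t_plan", "max_delay", "n_theta",
                       "n_replicates", "phi")

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected so that typos never silently fall back to
#' defaults.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  unknown <- setdiff(names(cfg), run_config_schema)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

# manifest describing a run, sufficient to reproduce the outputs
write_manifest <- function(out_path, config, seed) {
  manifest <- list(
    package = "icjm",
    version = as.character(utils::packageVersion("icjm")),
    seed = seed,
    config = config,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paste0(out_path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
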