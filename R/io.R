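#' Load and validate a run configuration
#'
#' A run configuration is a YAML file with (all optional except `profile`):
#' \preformatted{
#' profile: miapaca2            # builtin name, or a nested profile mapping
#' use_normal_counterpart: no
#' egf_conc: 0
#' horizon: 96
#' n0: 1000
#' drugs:                       # builtin names or full drug definitions
#'   - palbociclib
#'   - {name: drugX, mechanism: s_phase_kill, ec50: 10, hill_n: 2, emax: 1}
#' schedule:
#'   - {drug: palbociclib, concentration: 30, t_start: 0, t_end: 48}
#' }
#' Validation errors name the offending key path.  Unknown top-level keys
#' produce a warning, not an error.
#'
#' @param path Path to a YAML config file.
#' @return List with `profile` ([cell_line_profile()]), `drugs` (named list
#'   of [drug_model()]), `schedule` ([exposure_schedule()]), `egf_conc`,
#'   `horizon`, `n0`, and the raw parsed config as `raw`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("profile", "use_normal_counterpart", "egf_conc", "horizon",
             "n0", "drugs", "schedule")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  if (is.null(raw$profile)) stop("config error at 'profile': required",
                                 call. = FALSE)
  profile <- if (is.character(raw$profile)) {
    builtin_profile(raw$profile)
  } else {
    x <- raw$profile
    if (!is.null(x$phase_duration_split)) {
      x$phase_duration_split <- unlist(x$phase_duration_split)
    }
    tryCatch(do.call(cell_line_profile,
                     x[names(x) %in% names(formals(cell_line_profile))]),
             error = function(e) stop("config error at 'profile': ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (isTRUE(raw$use_normal_counterpart)) {
    profile <- normalized_counterpart(profile)
  }
  drugs <- list()
  for (i in seq_along(raw$drugs)) {
    dr <- raw$drugs[[i]]
    drugs[[length(drugs) + 1]] <- if (is.character(dr)) builtin_drug(dr)
    else tryCatch(do.call(drug_model,
                          dr[names(dr) %in% names(formals(drug_model))]),
                  error = function(e) stop(
                    sprintf("config error at 'drugs[%d]': %s", i,
                            conditionMessage(e)), call. = FALSE))
  }
  names(drugs) <- vapply(drugs, `[[`, character(1), "name")
  schedule <- if (is.null(raw$schedule)) exposure_schedule() else {
    seg <- do.call(rbind, lapply(seq_along(raw$schedule), function(i) {
      s <- raw$schedule[[i]]
      for (f in c("drug", "concentration", "t_start", "t_end")) {
        if (is.null(s[[f]])) stop(sprintf(
          "config error at 'schedule[%d].%s': required", i, f),
          call. = FALSE)
      }
      if (s$concentration < 0) stop(sprintf(
        "config error at 'schedule[%d].concentration': must be >= 0", i),
        call. = FALSE)
      data.frame(drug = s$drug, concentration = s$concentration,
                 t_start = s$t_start, t_end = s$t_end)
    }))
    missing_drugs <- setdiff(unique(seg$drug), names(drugs))
    if (length(missing_drugs) > 0) {
      stop("config error at 'schedule': no drug definition for ",
           paste(missing_drugs, collapse = ", "), call. = FALSE)
    }
    tryCatch(exposure_schedule(seg),
             error = function(e) stop("config error at 'schedule': ",
                                      conditionMessage(e), call. = FALSE))
  }
  num_or <- function(key, default) {
    v <- raw[[key]]
    if (is.null(v)) return(default)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(sprintf("config error at '%s': must be a finite number", key),
           call. = FALSE)
    }
    v
  }
  list(profile = profile, drugs = drugs, schedule = schedule,
       egf_conc = num_or("egf_conc", 0), horizon = num_or("horizon", 96),
       n0 = num_or("n0", 1000), raw = raw)
}

#' Write a run configuration
#' @param config A list as returned by [load_config()] (or with the same
#'   `profile`, `drugs`, `schedule`, `egf_conc`, `horizon`, `n0` elements).
#' @param path Output YAML path.
#' @return `path` invisibly.
#' @export
write_config <- function(config, path) {
  prof <- unclass(config$profile)
  prof$phase_duration_split <- as.list(config$profile$phase_duration_split)
  out <- list(
    profile = prof,
    egf_conc = config$egf_conc, horizon = config$horizon, n0 = config$n0,
    drugs = lapply(unname(config$drugs), unclass),
    schedule = lapply(seq_len(nrow(config$schedule$segments)), function(i)
      as.list(config$schedule$segments[i, ]))
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a simulation result to a directory
#'
#' Emits a deterministic file set: `timeseries.csv` (time plus the 63
#' compartment columns, cumulative dead, births, total live),
#' `phases.csv` (long phase fractions), `metrics.json` (headline metrics)
#' and `manifest.json` listing the produced files with their MD5 checksums.
#' All numbers are written at full precision.
#'
#' @param result A `simulation_result` (or a `scenario_result`, whose tables
#'   are written as CSVs named after their list entries).
#' @param dir Output directory (created if needed).
#' @param metrics Optional named list of extra metrics for `metrics.json`.
#' @return Invisibly, the manifest (data frame of file names and checksums).
#' @export
write_result <- function(result, dir, metrics = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  files <- character(0)
  wcsv <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                     f, row.names = FALSE, quote = FALSE)
    files <<- c(files, name)
  }
  if (inherits(result, "simulation_result")) {
    wcsv(result$timeseries, "timeseries.csv")
    wcsv(result$phases, "phases.csv")
    ts <- result$timeseries
    metrics <- c(metrics, list(
      final_total_live = ts$total_live[nrow(ts)],
      final_cumulative_dead = ts$cumulative_dead[nrow(ts)]))
    td <- tryCatch(doubling_time(result), error = function(e) NULL)
    if (!is.null(td)) metrics$doubling_time_h <- td
  } else if (inherits(result, "scenario_result")) {
    for (nm in names(result)) {
      if (is.data.frame(result[[nm]])) wcsv(result[[nm]],
                                            paste0(nm, ".csv"))
    }
    metrics <- c(metrics, result$metrics)
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  mf <- file.path(dir, "metrics.json")
  jsonlite::write_json(metrics, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, "metrics.json")
  manifest <- data.frame(
    file = files,
    md5 = vapply(files, function(f)
      unname(tools::md5sum(file.path(dir, f))), character(1)),
    row.names = NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
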