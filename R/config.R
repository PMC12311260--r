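#' Default pipeline configuration
#'
#' One nested list holds every tunable of the pipeline: the declared local
#' timezone, QA thresholds for chamber fluxes, deadband policy, meteorology
#' gap policy, GWP set, integration-period normalization, spline settings and
#' seeds. Field loggers record timezone-naive local time; the timezone is
#' declared once here and applied to every timestamp read.
#'
#' @param ... named overrides, e.g. `flux_config(gwp = "AR4")`. Nested lists
#'   are merged one level deep.
#' @return a list of class `fenflux_config`.
#' @export
flux_config <- function(...) {
  cfg <- list(
    tz = "Etc/GMT-1",
    latitude = 48.4,     # deg N, southern-German fen belt
    longitude = 11.7,    # deg E
    qa = list(
      r2_min_co2 = 0.9,
      r2_min_trace = 0.75,
      near_zero_co2 = 0.1,    # umol m-2 s-1
      near_zero_trace = 30,   # ug m-2 h-1
      range_max_co2 = 150,    # |flux| beyond this is physically implausible
      range_max_trace = 2e5
    ),
    deadband_frac = 0.10,
    deadband_min_s = 10,
    max_gap_hours = 24,       # meteorology gaps longer than this are an error
    gwp = "AR5",
    period_normalize = TRUE,  # scale off-365/366-d windows to a 365.25-d year
    flux_model = "linear",    # "linear" or "exponential"
    spline = list(k = 10, lambda_grid = 10^seq(-4, 6, length.out = 31),
                  site_ridge = c(0.1, 1, 10)),
    ch4_shift = 5,            # kg CH4 ha-1 yr-1 added before log-link fitting
    tweedie_p = 1.5,
    n_boot = 200,
    seed = 1L
  )
  modify_config(cfg, list(...))
}

modify_config <- function(cfg, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  class(cfg) <- "fenflux_config"
  cfg
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML; unspecified keys fall back to
#' [flux_config()] defaults.
#'
#' @param path file path.
#' @rdname config_io
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  modify_config(flux_config(), over)
}

#' @param config a `fenflux_config` list.
#' @rdname config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# --- run log -----------------------------------------------------------------
# Every pipeline stage reports record counts and QA tallies to a shared,
# machine-readable log (JSON lines when backed by a file).

#' Create a pipeline run log
#'
#' @param path optional file; when given, entries are appended as JSON lines.
#' @return an environment of class `fenflux_log`.
#' @export
new_run_log <- function(path = NULL) {
  log <- new.env(parent = emptyenv())
  log$entries <- list()
  log$path <- path
  class(log) <- "fenflux_log"
  log
}

#' Append a stage record to a run log
#'
#' @param log a `fenflux_log` (or `NULL`, a no-op).
#' @param stage stage name.
#' @param ... named counts/tallies.
#' @export
log_stage <- function(log, stage, ...) {
  if (is.null(log)) return(invisible(NULL))
  entry <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             list(...))
  log$entries[[length(log$entries) + 1L]] <- entry
  if (!is.null(log$path)) {
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        file = log$path, append = TRUE, sep = "")
  }
  invisible(entry)
}
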