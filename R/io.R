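# Site dataset: reading, validation and writing of the plain-CSV interchange
# tables. CSV dialect is fixed: comma separator, "." decimal, ISO-8601
# timestamps in the single timezone declared in the config.

GENERA <- c("Carex", "Phalaris", "Phragmites", "Typha")
INTENSITIES <- c("one_cut", "two_cut_fertilized")
GASES <- c("CO2", "CH4", "N2O")
CHAMBER_TYPES <- c("opaque", "transparent")

TS_FMT <- "%Y-%m-%d %H:%M:%S"

parse_ts <- function(x, tz, file) {
  out <- as.POSIXct(x, tz = tz, format = TS_FMT)
  # dates without a time component are accepted for event tables
  bad <- is.na(out)
  out[bad] <- as.POSIXct(x[bad], tz = tz, format = "%Y-%m-%d")
  if (anyNA(out)) {
    row <- which(is.na(out))[1]
    stop(sprintf("%s: unparseable timestamp '%s' at data row %d",
                 file, x[row], row))
  }
  out
}

need_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s",
                 file, paste(miss, collapse = ", ")))
  }
}

read_csv_ <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a site dataset from a directory of CSV tables
#'
#' Expects `met.csv`, `wt.csv`, `closures.csv`, `events.csv` and `meta.csv`
#' with documented headers (see the package vignette). All tables are
#' schema-validated with row-level diagnostics and cross-linked: every closure
#' and water-table record must resolve to a replicate/treatment declared in
#' `meta.csv`.
#'
#' @param dir directory containing the tables.
#' @param config a [flux_config()] list (declares the timezone).
#' @param log optional [new_run_log()].
#' @return a list of class `site_dataset` with elements `met`, `wt`,
#'   `closures`, `events`, `meta`.
#' @export
read_site_dataset <- function(dir, config = flux_config(), log = NULL) {
  tz <- config$tz
  f <- function(name) file.path(dir, name)

  meta <- read_csv_(f("meta.csv"))
  need_cols(meta, c("site_id", "treatment_id", "replicate_id", "plant_genus",
                    "management_intensity", "stand_age"), "meta.csv")
  bad <- which(!meta$plant_genus %in% GENERA)
  if (length(bad)) stop(sprintf("meta.csv: unknown plant_genus '%s' at data row %d",
                                meta$plant_genus[bad[1]], bad[1]))
  bad <- which(!meta$management_intensity %in% INTENSITIES)
  if (length(bad)) stop(sprintf("meta.csv: unknown management_intensity '%s' at data row %d",
                                meta$management_intensity[bad[1]], bad[1]))
  if (any(meta$stand_age < 1)) stop("meta.csv: stand_age must be >= 1")

  met <- read_csv_(f("met.csv"))
  need_cols(met, c("timestamp", "tair", "par", "pressure"), "met.csv")
  met$timestamp <- parse_ts(met$timestamp, tz, "met.csv")
  validate_met(met)

  wt <- read_csv_(f("wt.csv"))
  need_cols(wt, c("treatment_id", "timestamp", "wt"), "wt.csv")
  wt$timestamp <- parse_ts(wt$timestamp, tz, "wt.csv")
  if (any(wt$wt < -2 | wt$wt > 1)) {
    stop(sprintf("wt.csv: water table outside [-2, 1] m at data row %d",
                 which(wt$wt < -2 | wt$wt > 1)[1]))
  }
  bad <- which(!wt$treatment_id %in% meta$treatment_id)
  if (length(bad)) stop(sprintf("wt.csv: unknown treatment '%s' at data row %d",
                                wt$treatment_id[bad[1]], bad[1]))

  closures <- read_csv_(f("closures.csv"))
  need_cols(closures, c("closure_id", "replicate_id", "gas", "chamber_type",
                        "start", "elapsed_s", "conc", "tair", "pressure",
                        "par", "area_m2", "volume_m3"), "closures.csv")
  closures$start <- parse_ts(closures$start, tz, "closures.csv")
  bad <- which(!closures$gas %in% GASES)
  if (length(bad)) stop(sprintf("closures.csv: unknown gas '%s' at data row %d",
                                closures$gas[bad[1]], bad[1]))
  bad <- which(!closures$chamber_type %in% CHAMBER_TYPES)
  if (length(bad)) stop(sprintf("closures.csv: unknown chamber_type at data row %d", bad[1]))
  bad <- which(!closures$replicate_id %in% meta$replicate_id)
  if (length(bad)) stop(sprintf("closures.csv: unknown replicate '%s' at data row %d",
                                closures$replicate_id[bad[1]], bad[1]))
  if (any(closures$area_m2 <= 0) || any(closures$volume_m3 <= 0)) {
    stop("closures.csv: chamber area and volume must be > 0")
  }

  events <- read_csv_(f("events.csv"))
  need_cols(events, c("treatment_id", "date", "kind", "dm_yield",
                      "corg_fraction", "c_applied", "n_applied"), "events.csv")
  if (nrow(events)) {
    events$date <- parse_ts(events$date, tz, "events.csv")
    bad <- which(!events$kind %in% c("harvest", "fertilization"))
    if (length(bad)) stop(sprintf("events.csv: unknown event kind at data row %d", bad[1]))
    h <- events$kind == "harvest"
    if (any(h & (is.na(events$corg_fraction) | events$corg_fraction <= 0 |
                   events$corg_fraction >= 1))) {
      stop("events.csv: harvest rows need corg_fraction in (0, 1)")
    }
    bad <- which(!events$treatment_id %in% meta$treatment_id)
    if (length(bad)) stop(sprintf("events.csv: unknown treatment '%s' at data row %d",
                                  events$treatment_id[bad[1]], bad[1]))
  }

  ds <- structure(list(met = met, wt = wt, closures = closures,
                       events = events, meta = meta),
                  class = "site_dataset")
  log_stage(log, "read_site_dataset",
            n_met = nrow(met), n_wt = nrow(wt),
            n_closure_rows = nrow(closures), n_events = nrow(events),
            n_replicates = nrow(meta))
  ds
}

#' Write a site dataset to a directory of CSV tables
#'
#' Inverse of [read_site_dataset()]; `write` then `read` round-trips the
#' dataset.
#'
#' @param ds a `site_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_site_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wts <- function(df, col) {
    df[[col]] <- format(df[[col]], TS_FMT)
    df
  }
  utils::write.csv(wts(ds$met[c("timestamp", "tair", "par", "pressure")], "timestamp"),
                   file.path(dir, "met.csv"), row.names = FALSE)
  utils::write.csv(wts(ds$wt, "timestamp"), file.path(dir, "wt.csv"), row.names = FALSE)
  utils::write.csv(wts(ds$closures, "start"), file.path(dir, "closures.csv"),
                   row.names = FALSE)
  ev <- ds$events
  if (nrow(ev)) ev <- wts(ev, "date")
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(ds$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.site_dataset <- function(x, ...) {
  cat("<site_dataset>\n")
  cat(sprintf("  replicates: %d (%d treatments, %d sites)\n",
              nrow(x$meta), length(unique(x$meta$treatment_id)),
              length(unique(x$meta$site_id))))
  cat(sprintf("  met: %d steps, %s .. %s\n", nrow(x$met),
              format(min(x$met$timestamp)), format(max(x$met$timestamp))))
  cat(sprintf("  closures: %d (%d samples); events: %d\n",
              length(unique(x$closures$closure_id)), nrow(x$closures),
              nrow(x$events)))
  invisible(x)
}
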