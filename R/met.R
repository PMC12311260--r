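# Meteorology series handling: validation, solar geometry, resampling,
# night-time PAR imputation.

#' Validate a meteorology series
#'
#' A meteorology series is a data.frame with columns `timestamp` (POSIXct),
#' `tair` (deg C), `par` (umol m-2 s-1) and `pressure` (Pa) at a step of at
#' most 0.5 h. Timestamps must be strictly increasing, PAR nonnegative and
#' pressure positive.
#'
#' @param met data.frame as above.
#' @return the validated data.frame, invisibly classed `met_series`.
#' @export
validate_met <- function(met) {
  need <- c("timestamp", "tair", "par", "pressure")
  miss <- setdiff(need, names(met))
  if (length(miss)) stop("met series missing column(s): ", paste(miss, collapse = ", "))
  if (!inherits(met$timestamp, "POSIXct")) stop("met$timestamp must be POSIXct")
  dt <- diff(as.numeric(met$timestamp))
  if (any(dt <= 0)) stop("met timestamps must be strictly increasing")
  if (any(dt > 1800 + 1e-6)) stop("met step exceeds 0.5 h")
  if (any(met$par < 0, na.rm = TRUE)) stop("par must be >= 0")
  if (any(met$pressure <= 0, na.rm = TRUE)) stop("pressure must be > 0")
  class(met) <- c("met_series", "data.frame")
  invisible(met)
}

#' Solar elevation angle
#'
#' Simple solar-geometry rule (declination + hour angle, local solar time from
#' longitude) sufficient to decide day vs. night and to shape a clear-sky PAR
#' envelope. No equation-of-time or refraction correction.
#'
#' @param time POSIXct (timezone-naive local time as declared in the config).
#' @param lat,lon site coordinates in degrees.
#' @return elevation above the horizon in degrees.
#' @export
solar_elevation <- function(time, lat, lon) {
  doy <- as.integer(format(time, "%j"))
  hour <- as.integer(format(time, "%H")) + as.integer(format(time, "%M")) / 60
  # timezone offset of the declared local time, in hours east of UTC
  off <- as.numeric(format(time[1], "%z"))
  off <- (off %/% 100) + (off %% 100) / 60
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365.25) * pi / 180
  solar_hour <- hour + (lon / 15 - off)
  ha <- (solar_hour - 12) * 15 * pi / 180
  latr <- lat * pi / 180
  sin_el <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  asin(pmin(1, pmax(-1, sin_el))) * 180 / pi
}

#' Impute night-time PAR
#'
#' Missing PAR is set to 0 only when the sun is below the horizon; daytime
#' gaps are left as gaps for the resampling policy to handle.
#'
#' @param met met series.
#' @param lat,lon site coordinates (degrees).
#' @export
impute_night_par <- function(met, lat, lon) {
  idx <- is.na(met$par) & solar_elevation(met$timestamp, lat, lon) < 0
  met$par[idx] <- 0
  met
}

#' Resample a meteorology series to a coarser step
#'
#' Values are averaged per target interval (time-weighted means; for a regular
#' native grid this is the plain interval mean). Gaps no longer than
#' `max_gap_s` are linearly interpolated first; longer gaps stop the pipeline
#' unless `allow_long_gaps` keeps them as NA-flagged intervals.
#'
#' @param met met series.
#' @param step_s target step in seconds; must be >= the native step.
#' @param max_gap_s longest interpolatable gap, seconds.
#' @param allow_long_gaps if TRUE, intervals inside longer gaps stay NA and
#'   are flagged in the `gap` column; if FALSE (default) a long gap is an error.
#' @return a met series on the coarser grid with a logical `gap` column.
#' @export
resample_met <- function(met, step_s, max_gap_s = 24 * 3600,
                         allow_long_gaps = FALSE) {
  validate_met(met)
  tnum <- as.numeric(met$timestamp)
  native <- min(diff(tnum))
  if (step_s < native - 1e-6) stop("target step must be >= native step")

  fill <- function(v) {
    if (!anyNA(v)) return(list(v = v, long = rep(FALSE, length(v))))
    ok <- !is.na(v)
    vi <- stats::approx(tnum[ok], v[ok], xout = tnum, rule = 2)$y
    # identify runs of NA whose time extent exceeds max_gap_s
    long <- rep(FALSE, length(v))
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      lo <- max(1L, starts[i] - 1L); hi <- min(length(v), ends[i] + 1L)
      if (tnum[hi] - tnum[lo] > max_gap_s) long[starts[i]:ends[i]] <- TRUE
    }
    if (any(long) && !allow_long_gaps) {
      stop(sprintf("meteorology gap of %.1f h exceeds maximum of %.1f h",
                   (max(tnum[long]) - min(tnum[long])) / 3600, max_gap_s / 3600))
    }
    vi[long] <- NA_real_
    list(v = vi, long = long)
  }

  cols <- lapply(met[c("tair", "par", "pressure")], fill)
  grid <- floor((tnum - tnum[1]) / step_s)
  agg <- function(v) as.numeric(tapply(v, grid, mean))
  out <- data.frame(
    timestamp = as.POSIXct(tnum[1] + unique(grid) * step_s,
                           origin = "1970-01-01", tz = attr(met$timestamp, "tzone")),
    tair = agg(cols$tair$v),
    par = agg(cols$par$v),
    pressure = agg(cols$pressure$v)
  )
  out$gap <- as.logical(tapply(cols$tair$long | cols$par$long | cols$pressure$long,
                               grid, any))
  class(out) <- c("met_series", "data.frame")
  out
}

#' Time-weighted mean of an irregular series
#'
#' Trapezoidal time-weighted average, used e.g. for the mean annual water
#' table from logger series.
#'
#' @param timestamp POSIXct.
#' @param value numeric.
#' @export
time_weighted_mean <- function(timestamp, value) {
  t <- as.numeric(timestamp)
  if (length(t) == 1) return(value)
  w <- diff(t)
  sum((value[-1] + value[-length(value)]) / 2 * w) / sum(w)
}
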