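# Synthetic fen-site generator. Produces a complete, schema-valid site
# dataset (meteorology, water tables, chamber closures, management events,
# metadata) from a known ground truth, so every downstream stage can be
# validated against exact integrals. RNG: R's default Mersenne-Twister via
# set.seed(); all draws are derived from the single `seed` argument, so a
# fixed seed reproduces the dataset bit-for-bit across platforms.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

ar1 <- function(n, sd, phi) {
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  stats::filter(e, phi, method = "recursive")
}

season01 <- function(doy, peak = 200) {
  0.5 + 0.5 * cos(2 * pi * (doy - peak) / 365.25)
}

#' Ground-truth parameters for the synthetic site
#'
#' Default truth of the generator: four treatments (one per plant genus,
#' three replicates each) spanning mean annual water tables from -0.22 m to
#' 0.00 m — the moderately rewetted to flooded span of temperate fen
#' paludiculture trials. Respiration follows a Lloyd-Taylor model with a
#' seasonal base rate, photosynthesis a rectangular hyperbola with a seasonal
#' capacity, CH4 a log-linear water-table/biomass response with a summer
#' peak, and N2O a water-table-curvature baseline plus decaying fertilization
#' pulses.
#'
#' @param treatments optional replacement treatment table; see the default
#'   for the required columns.
#' @param noise list of measurement-noise settings: `co2_ppm`, `ch4_ppb`,
#'   `n2o_ppb` (additive Gaussian concentration noise), `rep_sd` (lognormal
#'   sd of replicate spatial heterogeneity), `flux_lognorm_sd` (optional
#'   flux-proportional lognormal noise for trace gases, reproducing their
#'   positive skew).
#' @param seed recorded into the output metadata.
#' @return list of class `truth_params`.
#' @export
truth_params <- function(treatments = NULL, noise = NULL, seed = 1L) {
  if (is.null(treatments)) {
    treatments <- data.frame(
      site_id = "SYN",
      treatment_id = c("carex_wet", "phalaris_wet", "phragmites_mid", "typha_mid"),
      plant_genus = c("Carex", "Phalaris", "Phragmites", "Typha"),
      management_intensity = c("one_cut", "two_cut_fertilized", "one_cut", "one_cut"),
      stand_age = c(3L, 4L, 4L, 2L),
      wt_mean = c(-0.03, 0.00, -0.13, -0.22),
      rref_max = c(4.5, 5.5, 4.0, 4.8),     # umol m-2 s-1 at 283.15 K, summer
      e0 = c(250, 280, 230, 260),           # K
      gpmax_max = c(45, 50, 48, 36),        # umol m-2 s-1, summer
      alpha = c(0.045, 0.050, 0.042, 0.040),
      ch4_c0 = 7.6,                         # log ug m-2 h-1 at wt = 0, no biomass
      ch4_wt = 12.0,                        # per m (positive: CH4 rises with WT)
      ch4_bio = 0.04,                       # per t DM ha-1 yr-1
      ch4_amp = 1.1,                        # seasonal log-amplitude
      n2o_base = 2.0,                       # ug m-2 h-1
      n2o_curv = 350,                       # ug m-2 h-1 per m^2 of WT depth
      n2o_pulse = 800,                      # ug m-2 h-1 at a fertilization peak
      n2o_tau_d = 10                        # pulse e-folding time, days
    )
  }
  if (is.null(noise)) {
    noise <- list(co2_ppm = 0.3, ch4_ppb = 5, n2o_ppb = 0.4,
                  rep_sd = 0.05, flux_lognorm_sd = 0)
  }
  structure(list(treatments = treatments, noise = noise, seed = seed),
            class = "truth_params")
}

#' Campaign and closure schedule
#'
#' Three-weekly full-day CO2 campaigns and seven-day trace-gas intervals.
#' Closure durations default to 3 min with 13 samples for CO2 and 60 min
#' with 4 samples for CH4/N2O, matching common practice for manual chamber
#' systems; all are configurable.
#'
#' @param ... named overrides.
#' @export
campaign_schedule <- function(...) {
  sch <- list(co2_start_doy = 10, co2_every_days = 21,
              co2_hours = c(2, 5, 8, 10, 12, 14, 16, 19, 22),
              co2_duration_s = 180, co2_n = 13,
              trace_start_doy = 5, trace_every_days = 7, trace_hour = 12,
              trace_duration_s = 3600, trace_n = 4,
              area_m2 = 0.5625, height_m = 0.5)
  over <- list(...)
  sch[names(over)] <- over
  sch
}

#' Generate synthetic half-hourly meteorology
#'
#' Air temperature is an annual + diurnal sinusoid plus AR(1) noise around a
#' 9 degC annual mean (the temperate-fen climate normal); PAR is a
#' solar-geometry clear-sky envelope scaled by day-persistent cloudiness;
#' pressure is a constant lowland value with slow AR(1) wobble.
#'
#' @param year calendar year.
#' @param seed RNG seed.
#' @param config a [flux_config()] (timezone, coordinates).
#' @return a `met_series` data.frame.
#' @export
generate_met <- function(year = 2021, seed = 1L, config = flux_config()) {
  tz <- config$tz
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = tz)
  t1 <- as.POSIXct(sprintf("%d-12-31 23:30:00", year), tz = tz)
  ts <- seq(t0, t1, by = 1800)
  doy <- as.integer(format(ts, "%j"))
  hour <- as.integer(format(ts, "%H")) + as.integer(format(ts, "%M")) / 60
  with_seed(seed, {
    tair <- 9 + 9 * cos(2 * pi * (doy - 205) / 365.25) +
      4 * cos(2 * pi * (hour - 14) / 24) +
      as.numeric(ar1(length(ts), sd = 1.5, phi = 0.95))
    elev <- solar_elevation(ts, config$latitude, config$longitude)
    envelope <- 2200 * pmax(0, sin(pmax(elev, 0) * pi / 180))
    ndays <- max(doy)
    cloud_day <- 0.25 + 0.75 * stats::plogis(as.numeric(ar1(ndays, 1.2, 0.7)))
    par <- envelope * cloud_day[doy]
    pressure <- 95800 + as.numeric(ar1(length(ts), 150, 0.99))
    met <- data.frame(timestamp = ts, tair = tair, par = par, pressure = pressure)
    validate_met(met)
    met
  })
}

#' Generate a water-table logger series for one treatment
#'
#' Mean-preserving: a mild seasonal cycle plus slow AR(1) wander, re-centred
#' so the time-weighted annual mean equals `wt_mean` exactly.
#'
#' @param wt_mean target mean annual water table, m (negative below surface).
#' @param year calendar year.
#' @param seed RNG seed.
#' @param config a [flux_config()].
#' @export
generate_wt <- function(wt_mean, year = 2021, seed = 1L, config = flux_config()) {
  tz <- config$tz
  ts <- seq(as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = tz),
            as.POSIXct(sprintf("%d-12-31 23:30:00", year), tz = tz), by = 1800)
  doy <- as.integer(format(ts, "%j"))
  with_seed(seed, {
    wt <- wt_mean + 0.03 * cos(2 * pi * (doy - 60) / 365.25) +
      as.numeric(ar1(length(ts), 0.02, 0.999))
    wt <- wt - (time_weighted_mean(ts, wt) - wt_mean)
    data.frame(timestamp = ts, wt = pmin(1, pmax(-2, wt)))
  })
}

# Seasonal trajectories of the truth parameters
truth_trajectories <- function(tr, doy) {
  list(rref = tr$rref_max * pmax(0.25, season01(doy, 205)),
       e0 = rep(tr$e0, length(doy)),
       gpmax = tr$gpmax_max * pmax(0.02, exp(-((doy - 200) / 95)^2)),
       alpha = rep(tr$alpha, length(doy)))
}

#' True per-timestep fluxes for one treatment
#'
#' Evaluates the generative flux models on the meteorology and water-table
#' series: `nee = reco + gpp` holds at every step, GPP <= 0, Reco >= 0
#' (atmospheric sign convention), CH4 (ug m-2 h-1) is strictly increasing in
#' WT, and N2O (ug m-2 h-1) carries decaying post-fertilization pulses.
#'
#' @param tr one row of the truth treatment table.
#' @param met met series.
#' @param wt water-table series on the met grid.
#' @param events management events for the treatment (for N2O pulses and the
#'   CH4 biomass term).
#' @return data.frame `timestamp`, `reco`, `gpp`, `nee` (umol m-2 s-1),
#'   `ch4`, `n2o` (ug m-2 h-1).
#' @export
generate_true_fluxes <- function(tr, met, wt, events = NULL) {
  doy <- as.integer(format(met$timestamp, "%j")) +
    as.integer(format(met$timestamp, "%H")) / 24
  tj <- truth_trajectories(tr, doy)
  reco <- lloyd_taylor(met$tair, tj$rref, tj$e0)
  gpp <- rect_hyperbola(met$par, tj$alpha, tj$gpmax)
  bio <- if (!is.null(events) && nrow(events)) {
    sum(events$dm_yield[events$kind == "harvest"], na.rm = TRUE)
  } else 0
  ch4 <- exp(tr$ch4_c0 + tr$ch4_wt * wt$wt + tr$ch4_bio * bio +
               tr$ch4_amp * cos(2 * pi * (doy - 220) / 365.25))
  n2o <- tr$n2o_base + tr$n2o_curv * wt$wt^2
  if (!is.null(events) && nrow(events)) {
    for (i in which(events$kind == "fertilization")) {
      dt_d <- as.numeric(difftime(met$timestamp, events$date[i], units = "days"))
      n2o <- n2o + ifelse(dt_d >= 0, tr$n2o_pulse * exp(-dt_d / tr$n2o_tau_d), 0)
    }
  }
  data.frame(timestamp = met$timestamp, reco = reco, gpp = gpp,
             nee = reco + gpp, ch4 = ch4, n2o = n2o)
}

#' Generate management events for one treatment
#'
#' One-cut regimes get a single winter harvest (December); two-cut fertilized
#' regimes add an early-summer harvest and a spring digestate application
#' with 92-143 kg N ha-1. Dry-matter yields are drawn within the observed
#' paludiculture span (1.6-15.0 t DM ha-1 yr-1, wetter regimes yielding
#' more), Corg fractions within 44.9%-48.3% of DM. Digestate C is derived
#' from N at a C:N ratio of 5 (typical of liquid biogas digestate).
#'
#' @param tr one row of the truth treatment table.
#' @param year calendar year.
#' @param seed RNG seed.
#' @param config a [flux_config()].
#' @return a management-event data.frame (events.csv schema).
#' @export
generate_management <- function(tr, year = 2021, seed = 1L, config = flux_config()) {
  tz <- config$tz
  regime <- tr$management_intensity
  with_seed(seed, {
    wetness <- (tr$wt_mean + 0.3) / 0.34  # 0 dry .. ~1 flooded over the span
    lo <- 1.6 + 6 * max(0, min(1, wetness))
    total_yield <- stats::runif(1, lo, min(lo + 5, 15))
    corg <- function() stats::runif(1, 0.449, 0.483)
    dec <- as.POSIXct(sprintf("%d-12-15", year), tz = tz)
    if (regime == "one_cut") {
      ev <- data.frame(treatment_id = tr$treatment_id, date = dec,
                       kind = "harvest", dm_yield = total_yield,
                       corg_fraction = corg(), c_applied = NA_real_,
                       n_applied = NA_real_)
    } else {
      n_app <- stats::runif(1, 92, 143)
      ev <- data.frame(
        treatment_id = tr$treatment_id,
        date = c(as.POSIXct(sprintf("%d-04-20", year), tz = tz),
                 as.POSIXct(sprintf("%d-07-05", year), tz = tz), dec),
        kind = c("fertilization", "harvest", "harvest"),
        dm_yield = c(NA, 0.45 * total_yield, 0.55 * total_yield),
        corg_fraction = c(NA, corg(), corg()),
        c_applied = c(n_app * 5 / 1000, NA, NA),
        n_applied = c(n_app, NA, NA))
    }
    ev
  })
}

#' Generate chamber closures for one replicate
#'
#' Each closure's concentration trace is a linear ramp whose slope encodes the
#' true areal flux through the ideal-gas relation for the chamber geometry,
#' plus additive Gaussian concentration noise. Opaque chambers see Reco (and
#' the trace gases), transparent chambers see NEE.
#'
#' @keywords internal
generate_closures_rep <- function(rep_id, tr, true_flux, met, sch, noise,
                                  rep_factor, year, seed, config) {
  tz <- config$tz
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = tz)
  idx_of <- function(times) {
    i <- round(as.numeric(difftime(times, t0, units = "secs")) / 1800) + 1L
    pmin(pmax(i, 1L), nrow(met))
  }
  base_conc <- c(CO2 = 415, CH4 = 1900, N2O = 333)  # ambient mole fractions
  vol <- sch$area_m2 * sch$height_m

  co2_days <- seq(sch$co2_start_doy, 365, by = sch$co2_every_days)
  co2_starts <- t0 + (rep(co2_days, each = length(sch$co2_hours)) - 1) * 86400 +
    sch$co2_hours * 3600
  trace_days <- seq(sch$trace_start_doy, 365, by = sch$trace_every_days)
  trace_starts <- t0 + (trace_days - 1) * 86400 + sch$trace_hour * 3600

  with_seed(seed, {
    mk <- function(start, gas, type, flux_true, dur, n, conc_sd) {
      i <- idx_of(start)
      t_k <- met$tair[i] + 273.15
      col <- met$pressure[i] * sch$height_m / (R_GAS * t_k)
      slope <- if (gas == "CO2") flux_true / col else
        flux_true / (1e-9 * col * MOLAR_MASS[[gas]] * 1e6 * 3600)
      el <- seq(0, dur, length.out = n)
      conc <- base_conc[[gas]] + slope * el + stats::rnorm(n, 0, conc_sd)
      data.frame(replicate_id = rep_id, gas = gas, chamber_type = type,
                 start = start, elapsed_s = el, conc = conc,
                 tair = met$tair[i], pressure = met$pressure[i],
                 par = if (type == "opaque") 0 else met$par[i],
                 area_m2 = sch$area_m2, volume_m3 = vol)
    }
    out <- vector("list", 0)
    for (s in seq_along(co2_starts)) {
      st <- co2_starts[s]; i <- idx_of(st)
      reco_t <- true_flux$reco[i] * rep_factor
      nee_t <- (true_flux$reco[i] + true_flux$gpp[i]) * rep_factor
      out[[length(out) + 1]] <- mk(st, "CO2", "opaque", reco_t,
                                   sch$co2_duration_s, sch$co2_n, noise$co2_ppm)
      out[[length(out) + 1]] <- mk(st, "CO2", "transparent", nee_t,
                                   sch$co2_duration_s, sch$co2_n, noise$co2_ppm)
    }
    for (s in seq_along(trace_starts)) {
      st <- trace_starts[s]; i <- idx_of(st)
      ln <- function(x) if (noise$flux_lognorm_sd > 0)
        x * stats::rlnorm(1, -noise$flux_lognorm_sd^2 / 2, noise$flux_lognorm_sd)
      else x
      out[[length(out) + 1]] <- mk(st, "CH4", "opaque",
                                   ln(true_flux$ch4[i] * rep_factor),
                                   sch$trace_duration_s, sch$trace_n, noise$ch4_ppb)
      out[[length(out) + 1]] <- mk(st, "N2O", "opaque",
                                   ln(true_flux$n2o[i] * rep_factor),
                                   sch$trace_duration_s, sch$trace_n, noise$n2o_ppb)
    }
    do.call(rbind, out)
  })
}

#' Generate a complete synthetic site with known ground truth
#'
#' @param config a [flux_config()].
#' @param seed master seed; every internal draw derives from it.
#' @param truth a [truth_params()].
#' @param schedule a [campaign_schedule()].
#' @param year calendar year to simulate.
#' @param keep_series if TRUE, the per-treatment true flux series are kept in
#'   `truth$true_series` (for recovery tests against the exact truth).
#' @return list with `dataset` (a schema-valid `site_dataset`) and `truth`
#'   (the `truth_params` plus `true_annual`, the exact annual integrals per
#'   replicate: Reco/GPP/NEE in t CO2 ha-1 yr-1, CH4 and N2O in kg ha-1
#'   yr-1, and the replicate heterogeneity factors).
#' @export
generate_site <- function(config = flux_config(), seed = 1L,
                          truth = truth_params(seed = seed),
                          schedule = campaign_schedule(), year = 2021,
                          keep_series = FALSE) {
  trs <- truth$treatments
  met <- generate_met(year, seed, config)
  noise <- truth$noise

  meta <- do.call(rbind, lapply(seq_len(nrow(trs)), function(i) {
    data.frame(site_id = trs$site_id[i], treatment_id = trs$treatment_id[i],
               replicate_id = paste0(trs$treatment_id[i], "_r", 1:3),
               plant_genus = trs$plant_genus[i],
               management_intensity = trs$management_intensity[i],
               stand_age = trs$stand_age[i])
  }))

  wt_list <- list(); events_list <- list(); closure_list <- list()
  true_rows <- list(); series_list <- list(); rep_factor_list <- list()
  for (i in seq_len(nrow(trs))) {
    tr <- trs[i, ]
    wt <- generate_wt(tr$wt_mean, year, seed + 100 + i, config)
    wt_list[[i]] <- cbind(treatment_id = tr$treatment_id, wt)
    ev <- generate_management(tr, year, seed + 200 + i, config)
    events_list[[i]] <- ev
    tf <- generate_true_fluxes(tr, met, wt, ev)
    if (keep_series) series_list[[tr$treatment_id]] <- tf
    rep_factors <- with_seed(seed + 300 + i,
                             exp(stats::rnorm(3, -noise$rep_sd^2 / 2, noise$rep_sd)))
    reps <- paste0(tr$treatment_id, "_r", 1:3)
    for (r in 1:3) {
      closure_list[[length(closure_list) + 1]] <-
        generate_closures_rep(reps[r], tr, tf, met, schedule, noise,
                              rep_factors[r], year, seed + 1000 + 10 * i + r,
                              config)
      w <- c(diff(as.numeric(met$timestamp)))
      w <- c(w, w[length(w)])
      tmean <- function(v) sum(v * w) / sum(w)
      true_rows[[length(true_rows) + 1]] <- data.frame(
        treatment_id = tr$treatment_id, replicate_id = reps[r],
        rep_factor = rep_factors[r],
        reco = co2_umol_to_t_ha_yr(tmean(tf$reco)) * rep_factors[r],
        gpp = co2_umol_to_t_ha_yr(tmean(tf$gpp)) * rep_factors[r],
        nee = co2_umol_to_t_ha_yr(tmean(tf$nee)) * rep_factors[r],
        ch4_kg = trace_ug_to_kg_ha_yr(tmean(tf$ch4)) * rep_factors[r],
        n2o_kg = trace_ug_to_kg_ha_yr(tmean(tf$n2o)) * rep_factors[r],
        wt_mean = tr$wt_mean)
    }
  }

  closures <- do.call(rbind, closure_list)
  closures$closure_id <- paste(closures$replicate_id, closures$gas,
                               closures$chamber_type,
                               format(closures$start, "%Y%m%d%H%M"), sep = "_")
  ds <- structure(list(met = met, wt = do.call(rbind, wt_list),
                       closures = closures,
                       events = do.call(rbind, events_list), meta = meta),
                  class = "site_dataset")
  truth$true_annual <- do.call(rbind, true_rows)
  if (keep_series) truth$true_series <- series_list
  truth$seed <- seed
  truth$year <- year
  list(dataset = ds, truth = truth)
}
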