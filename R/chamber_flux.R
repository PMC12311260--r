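# Closed-chamber flux computation. The areal flux follows from the rate of
# change of the dry-air mole fraction and the molar column of air enclosed
# per unit soil area: F = dX/dt * p * (V/A) / (R * T).

#' Compute an areal gas flux from one chamber closure
#'
#' Ordinary least squares on the concentration-time series after discarding a
#' deadband (the first `deadband_frac` of elapsed time, at least
#' `deadband_min_s`, where pressure-equilibration artifacts live). The slope
#' is converted through the ideal-gas molar column `p*(V/A)/(R*T)`:
#' CO2 fluxes are returned in umol m-2 s-1, CH4 and N2O in ug m-2 h-1
#' (via molar masses 16.04 and 44.01 g mol-1). An exponential saturation
#' model (initial-slope estimate) is available behind `flux_model =
#' "exponential"` in the config.
#'
#' @param elapsed_s seconds since closure, strictly increasing, >= 4 points.
#' @param conc dry-air mole fraction: umol mol-1 for CO2, nmol mol-1 for
#'   CH4/N2O.
#' @param gas `"CO2"`, `"CH4"` or `"N2O"`.
#' @param tair_c chamber-internal air temperature, deg C.
#' @param pressure_pa air pressure, Pa.
#' @param area_m2,volume_m3 chamber basal area and headspace volume.
#' @param config a [flux_config()].
#' @return list with `flux`, `se`, `r2`, `n_points`, `qa` (initially
#'   `"pending"`; see [apply_qa()]).
#' @export
compute_flux <- function(elapsed_s, conc, gas, tair_c, pressure_pa,
                         area_m2, volume_m3, config = flux_config()) {
  gas <- match.arg(gas, GASES)
  if (length(elapsed_s) < 4) stop("closure needs >= 4 concentration points")
  if (any(diff(elapsed_s) <= 0)) stop("elapsed times must be strictly increasing")
  t_k <- tair_c + 273.15
  if (t_k <= 0 || pressure_pa <= 0 || area_m2 <= 0 || volume_m3 <= 0) {
    stop("temperature (K), pressure, area and volume must all be positive")
  }

  dead <- max(config$deadband_frac * max(elapsed_s), config$deadband_min_s)
  keep <- elapsed_s >= dead
  if (sum(keep) < 3) stop("fewer than 3 usable points after deadband")
  tt <- elapsed_s[keep]
  cc <- conc[keep]

  if (identical(config$flux_model, "exponential") && stats::sd(cc) > 0) {
    # C(t) = Cs + (C0 - Cs) exp(-k t); report the initial slope k (Cs - C0)
    fit <- try(minpack.lm::nlsLM(
      cc ~ cs + (c0 - cs) * exp(-k * (tt - tt[1])),
      start = list(cs = cc[length(cc)] + (cc[length(cc)] - cc[1]),
                   c0 = cc[1], k = 1 / diff(range(tt))),
      lower = c(-Inf, -Inf, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- stats::coef(fit)
      slope <- cf[["k"]] * (cf[["cs"]] - cf[["c0"]])
      g <- c(cs = cf[["k"]], c0 = -cf[["k"]], k = cf[["cs"]] - cf[["c0"]])
      se_slope <- sqrt(drop(t(g) %*% stats::vcov(fit) %*% g))
      r2 <- 1 - sum(stats::resid(fit)^2) / sum((cc - mean(cc))^2)
      return(finish_flux(slope, se_slope, r2, sum(keep), gas, t_k,
                         pressure_pa, volume_m3 / area_m2))
    } # fall through to linear on failure
  }

  fit <- stats::lm(cc ~ tt)
  slope <- stats::coef(fit)[["tt"]]
  sm <- suppressWarnings(summary(fit))  # zero-noise closures fit perfectly
  se_slope <- sm$coefficients["tt", "Std. Error"]
  sst <- sum((cc - mean(cc))^2)
  r2 <- if (sst > 0) sm$r.squared else 0
  finish_flux(slope, se_slope, r2, sum(keep), gas, t_k, pressure_pa,
              volume_m3 / area_m2)
}

finish_flux <- function(slope, se_slope, r2, n, gas, t_k, p_pa, height_m) {
  col <- p_pa * height_m / (R_GAS * t_k)  # mol air per m2 ground
  if (gas == "CO2") {
    k <- col                                   # umol/mol/s -> umol m-2 s-1
  } else {
    k <- 1e-9 * col * MOLAR_MASS[[gas]] * 1e6 * 3600  # nmol/mol/s -> ug m-2 h-1
  }
  list(flux = slope * k, se = abs(se_slope * k), r2 = r2,
       n_points = n, qa = "pending")
}

#' Compute fluxes for every closure in a dataset
#'
#' @param closures long-format closure table (see [read_site_dataset()]).
#' @param config a [flux_config()].
#' @param log optional run log.
#' @return a `fluxes` data.frame, one row per closure, with the flux estimate,
#'   its standard error, regression r2, QA flag and closure metadata. Units:
#'   umol m-2 s-1 (CO2), ug m-2 h-1 (CH4/N2O).
#' @export
compute_fluxes <- function(closures, config = flux_config(), log = NULL) {
  ids <- unique(closures$closure_id)
  rows <- lapply(ids, function(id) {
    cl <- closures[closures$closure_id == id, ]
    cl <- cl[order(cl$elapsed_s), ]
    est <- compute_flux(cl$elapsed_s, cl$conc, cl$gas[1], cl$tair[1],
                        cl$pressure[1], cl$area_m2[1], cl$volume_m3[1], config)
    data.frame(closure_id = id, replicate_id = cl$replicate_id[1],
               gas = cl$gas[1], chamber_type = cl$chamber_type[1],
               start = cl$start[1], tair = cl$tair[1], par = cl$par[1],
               flux = est$flux, se = est$se, r2 = est$r2,
               n_points = est$n_points, qa = est$qa)
  })
  fluxes <- do.call(rbind, rows)
  fluxes <- apply_qa(fluxes, config)
  log_stage(log, "compute_fluxes", n_closures = nrow(fluxes),
            n_accepted = sum(fluxes$qa %in% c("accepted", "accepted_near_zero")),
            n_rejected_r2 = sum(fluxes$qa == "rejected_r2"),
            n_rejected_range = sum(fluxes$qa == "rejected_range"))
  fluxes
}

#' Quality control for flux estimates
#'
#' A flux is `accepted` when its regression r2 reaches the gas-specific
#' minimum; fluxes inside the near-zero band are exempt from the r2 rule
#' (`accepted_near_zero` — with no concentration change there is nothing for
#' the regression to explain). Physically implausible magnitudes are
#' `rejected_range`, the rest `rejected_r2`. Rejected rows are retained (for
#' tallies) but excluded downstream.
#'
#' @param fluxes data.frame from [compute_fluxes()] (needs `flux`, `r2`, `gas`).
#' @param config a [flux_config()]; thresholds live in `config$qa`. Setting
#'   `r2_min_* = 0` disables the r2 rule.
#' @return `fluxes` with the `qa` column set.
#' @export
apply_qa <- function(fluxes, config = flux_config()) {
  qa <- config$qa
  co2 <- fluxes$gas == "CO2"
  r2min <- ifelse(co2, qa$r2_min_co2, qa$r2_min_trace)
  band <- ifelse(co2, qa$near_zero_co2, qa$near_zero_trace)
  rmax <- ifelse(co2, qa$range_max_co2, qa$range_max_trace)
  r2 <- ifelse(is.na(fluxes$r2), 0, fluxes$r2)
  flag <- ifelse(abs(fluxes$flux) > rmax, "rejected_range",
          ifelse(r2 >= r2min, "accepted",
          ifelse(abs(fluxes$flux) <= band, "accepted_near_zero", "rejected_r2")))
  fluxes$qa <- flag
  fluxes
}

#' Accepted fluxes only
#' @param fluxes a fluxes data.frame.
#' @export
accepted_fluxes <- function(fluxes) {
  fluxes[fluxes$qa %in% c("accepted", "accepted_near_zero"), , drop = FALSE]
}
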