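# Physical constants and unit conversions used throughout the pipeline.
# Sign convention everywhere: atmospheric — emission to the atmosphere is
# positive, ecosystem uptake negative.

# universal gas constant, J mol-1 K-1
R_GAS <- 8.314462618

# molar masses, g mol-1
MOLAR_MASS <- c(CO2 = 44.01, CH4 = 16.04, N2O = 44.01)

# mass ratios for element accounting; exact, round-trips are identities
C_PER_CO2 <- 12 / 44
C_PER_CH4 <- 12 / 16
N_PER_N2O <- 28 / 44

# CO2-equivalents per t C for import/export terms. The inventory convention
# uses the printed factor 3.66 rather than 44/12 = 3.667; budgets are only
# reproducible against inventory tables with the literal factor.
C_TO_CO2E <- 3.66

# Gregorian year used for period normalization
SECONDS_PER_YEAR <- 365.25 * 86400
HOURS_PER_YEAR <- 365.25 * 24

#' Global warming potential sets
#'
#' GWP100 weights for CH4 and N2O under the IPCC Fifth (AR5) and Fourth (AR4)
#' Assessment Reports. AR5 (28, 265) matches current German inventory
#' reporting; AR4 (25, 298) allows comparison with older national emission
#' factors.
#'
#' @param name `"AR5"` or `"AR4"`.
#' @return A list with elements `name`, `gwp_ch4`, `gwp_n2o`.
#' @examples
#' gwp_set("AR5")$gwp_ch4  # 28
#' @export
gwp_set <- function(name = c("AR5", "AR4")) {
  name <- match.arg(name)
  if (name == "AR5") {
    list(name = "AR5", gwp_ch4 = 28, gwp_n2o = 265)
  } else {
    list(name = "AR4", gwp_ch4 = 25, gwp_n2o = 298)
  }
}

#' Convert a mean CO2 flux to an annual balance
#'
#' A sustained flux of 1 umol CO2 m-2 s-1 over a 365.25-day year amounts to
#' about 13.89 t CO2 ha-1 yr-1; this helper is the unit bridge between
#' chamber-scale fluxes and annual budgets.
#'
#' @param mean_flux_umol mean flux in umol m-2 s-1.
#' @return annual balance in t CO2 ha-1 yr-1.
#' @export
co2_umol_to_t_ha_yr <- function(mean_flux_umol) {
  # umol m-2 s-1 -> g m-2 yr-1 -> t ha-1 yr-1 (x 1e4 m2/ha / 1e6 g/t)
  mean_flux_umol * 1e-6 * MOLAR_MASS[["CO2"]] * SECONDS_PER_YEAR * 1e-2
}

#' Convert a mean trace-gas flux to an annual balance
#'
#' @param mean_flux_ug mean flux in ug m-2 h-1.
#' @return annual balance in kg ha-1 yr-1.
#' @export
trace_ug_to_kg_ha_yr <- function(mean_flux_ug) {
  # ug m-2 h-1 -> kg m-2 yr-1 -> kg ha-1 yr-1
  mean_flux_ug * 1e-9 * HOURS_PER_YEAR * 1e4
}
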