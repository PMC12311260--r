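# Water-table classification, IPCC off-site defaults, emission-factor
# aggregation and mitigation-scenario arithmetic.

# IPCC / national inventory off-site defaults
DOC_DEFAULT <- c(rewetted = 0.24, drained = 0.31)  # t C ha-1 yr-1
DITCH_CH4_EF <- 527     # kg CH4 ha-1 yr-1 on the ditch area
DITCH_FRACTION <- 0.013 # national default ditch area fraction

#' Classify a balance by mean annual water table
#'
#' `rewetted` for mean annual WT >= -0.10 m (boundary inclusive),
#' `moderately_rewetted` for -0.30 < WT < -0.10 m, `excluded` for WT <=
#' -0.30 m (too deeply drained for a paludiculture emission factor).
#'
#' @param mean_wt mean annual water table, m (negative below surface);
#'   vectorized.
#' @return character vector over `{rewetted, moderately_rewetted, excluded}`.
#' @export
classify_wt <- function(mean_wt) {
  stopifnot(all(is.finite(mean_wt)))
  ifelse(mean_wt >= -0.10, "rewetted",
         ifelse(mean_wt > -0.30, "moderately_rewetted", "excluded"))
}

#' Add IPCC off-site defaults to onsite components
#'
#' Builds the "organic" reporting columns: DOC export is added to the onsite
#' CO2-C (0.24 t C ha-1 yr-1 for rewetted, 0.31 otherwise); ditch CH4 is
#' blended by area weighting `(1 - f) * land + f * 527` with the national
#' ditch fraction f = 0.013 for moderately rewetted classes and not applied
#' to rewetted ones; direct N2O-N passes through unchanged.
#'
#' @param co2_c_onsite t C ha-1 yr-1.
#' @param ch4_land kg CH4 ha-1 yr-1.
#' @param n2o_n_direct kg N2O-N ha-1 yr-1.
#' @param wt_class `"rewetted"` or `"moderately_rewetted"`.
#' @return list `co2_c_organic`, `ch4_organic`, `n2o_n_organic`.
#' @export
add_offsite_defaults <- function(co2_c_onsite, ch4_land, n2o_n_direct,
                                 wt_class) {
  wt_class <- match.arg(wt_class, c("rewetted", "moderately_rewetted"))
  if (wt_class == "rewetted") {
    list(co2_c_organic = co2_c_onsite + DOC_DEFAULT[["rewetted"]],
         ch4_organic = ch4_land,
         n2o_n_organic = n2o_n_direct)
  } else {
    list(co2_c_organic = co2_c_onsite + DOC_DEFAULT[["drained"]],
         ch4_organic = (1 - DITCH_FRACTION) * ch4_land +
           DITCH_FRACTION * DITCH_CH4_EF,
         n2o_n_organic = n2o_n_direct)
  }
}

#' Recompute a GHG balance from organic reporting components
#'
#' `3.66 * CO2-C_organic + gwp_ch4 * CH4_organic + gwp_n2o * (N2O-N x 44/28)`
#' with the gas columns in kg converted to t.
#'
#' @param co2_c_organic t C ha-1 yr-1.
#' @param ch4_organic kg CH4 ha-1 yr-1.
#' @param n2o_n_organic kg N2O-N ha-1 yr-1.
#' @param gwp a [gwp_set()].
#' @return t CO2e ha-1 yr-1.
#' @export
ghg_from_components <- function(co2_c_organic, ch4_organic, n2o_n_organic,
                                gwp = gwp_set("AR5")) {
  C_TO_CO2E * co2_c_organic + gwp$gwp_ch4 * ch4_organic / 1000 +
    gwp$gwp_n2o * (n2o_n_organic / N_PER_N2O) / 1000
}

#' Aggregate emission factors for one water-table class
#'
#' Arithmetic means of the budget components over all balances in the class,
#' with 95th-percentile brackets (empirical 2.5th-97.5th percentiles of the
#' per-balance distribution). The onsite CO2-C column is `NEE-C - C_import +
#' C_export` (the NECB without its small CH4-C term); the GHG columns are
#' means of the per-balance GHG values, never recomputed from rounded
#' component means.
#' Off-site defaults produce the organic columns via
#' [add_offsite_defaults()].
#'
#' @param budgets annual-budget table ([assemble_budget()] rows).
#' @param wt_class class to aggregate (`"rewetted"` or
#'   `"moderately_rewetted"`); budgets are classified from their `wt_mean`.
#' @return one-row data.frame of class means, brackets and `n`.
#' @export
aggregate_ef <- function(budgets, wt_class) {
  wt_class <- match.arg(wt_class, c("rewetted", "moderately_rewetted"))
  cls <- classify_wt(budgets$wt_mean)
  b <- budgets[cls == wt_class, , drop = FALSE]
  if (!nrow(b)) stop("no balances in class ", wt_class)
  # onsite CO2-C: NEE-C - C_import + C_export (NECB without the CH4-C term)
  co2_c_onsite <- b$necb - b$ch4_c
  # per-balance organic components and GHG values with ditch/DOC add-ons
  org <- add_offsite_defaults(co2_c_onsite, b$ch4_kg, b$n2o_kg * N_PER_N2O,
                              wt_class)
  doc <- DOC_DEFAULT[[if (wt_class == "rewetted") "rewetted" else "drained"]]
  ghg5 <- b$ghg_ar5 + C_TO_CO2E * doc +
    gwp_set("AR5")$gwp_ch4 * (org$ch4_organic - b$ch4_kg) / 1000
  ghg4 <- b$ghg_ar4 + C_TO_CO2E * doc +
    gwp_set("AR4")$gwp_ch4 * (org$ch4_organic - b$ch4_kg) / 1000
  q <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  qc <- function(v) {
    x <- q(v)
    stats::setNames(list(x[1], x[2]), c("lo", "hi"))
  }
  n2o_n <- b$n2o_kg * N_PER_N2O
  out <- data.frame(
    wt_class = wt_class, n = nrow(b),
    co2_c_onsite = mean(co2_c_onsite),
    co2_c_onsite_lo = q(co2_c_onsite)[1], co2_c_onsite_hi = q(co2_c_onsite)[2],
    ch4_land = mean(b$ch4_kg),
    ch4_land_lo = q(b$ch4_kg)[1], ch4_land_hi = q(b$ch4_kg)[2],
    n2o_n_direct = mean(n2o_n),
    n2o_n_direct_lo = q(n2o_n)[1], n2o_n_direct_hi = q(n2o_n)[2],
    co2_c_organic = mean(org$co2_c_organic),
    ch4_organic = mean(org$ch4_organic),
    n2o_n_organic = mean(org$n2o_n_organic),
    ghg_ar4 = mean(ghg4), ghg_ar5 = mean(ghg5),
    ghg_ar5_lo = q(ghg5)[1], ghg_ar5_hi = q(ghg5)[2])
  out
}

#' Build the full emission-factor table from a budget table
#'
#' One row per water-table class present in the budgets; class counts
#' (including excluded balances) partition the input.
#'
#' @param budgets annual-budget table.
#' @param log optional run log.
#' @return data.frame of class `ef_table` with an `excluded_n` attribute.
#' @export
ef_table <- function(budgets, log = NULL) {
  cls <- classify_wt(budgets$wt_mean)
  out <- do.call(rbind, lapply(intersect(c("rewetted", "moderately_rewetted"),
                                         unique(cls)),
                               function(k) aggregate_ef(budgets, k)))
  attr(out, "excluded_n") <- sum(cls == "excluded")
  log_stage(log, "ef_table", n_balances = nrow(budgets),
            n_rewetted = sum(cls == "rewetted"),
            n_moderately_rewetted = sum(cls == "moderately_rewetted"),
            n_excluded = sum(cls == "excluded"))
  class(out) <- c("ef_table", "data.frame")
  out
}

#' Reference emission factors for German organic-soil land-use categories
#'
#' Inventory emission factors (means) for drained cropland, drained
#' grassland and rewetted organic soils, plus the proposed preliminary fen
#' paludiculture factors, as used for mitigation arithmetic. Values are the
#' published inventory/reporting numbers (Tiemeyer et al. 2020 national EFs;
#' paludiculture rows from the field dataset this pipeline reimplements);
#' GHG columns in t CO2e ha-1 yr-1, components in t C and kg.
#'
#' @return data.frame with one row per land-use category.
#' @export
reference_efs <- function() {
  data.frame(
    category = c("cropland", "grassland", "rewetted_organic_soils",
                 "paludiculture_rewetted", "paludiculture_moderately_rewetted"),
    co2_c_onsite = c(9.2, 8.3, -0.4, -5.5, -0.74),
    ch4_land = c(5.5, 11.2, 279, 270.5, 29.9),
    n2o_n_direct = c(11.1, 4.6, 0.1, 0.2, 1.5),
    co2_c_organic = c(9.5, 8.0, -0.4, -5.3, -0.4),
    ch4_organic = c(20.6, 21.7, 279.0, 270.5, 36.4),
    n2o_n_organic = c(11.1, 4.2, 0.1, 0.2, 1.5),
    ghg_ar4 = c(40.4, 31.7, 5.5, -12.8, -0.1),
    ghg_ar5 = c(39.9, 31.6, 6.4, -12.0, -0.1),
    source = c(rep("national inventory (Tiemeyer et al. 2020)", 3),
               rep("preliminary fen paludiculture EF", 2)))
}

#' Mitigation potential of a land-use conversion
#'
#' Difference between the paludiculture EF and the reference land-use EF
#' under the same GWP set; negative deltas are net mitigation, also reported
#' as a positive savings magnitude.
#'
#' @param ef_palu,ef_reference t CO2e ha-1 yr-1.
#' @param gwp_palu,gwp_reference GWP-set names; must match.
#' @return list `delta` (ef_palu - ef_reference) and `savings` (=-delta).
#' @export
mitigation_potential <- function(ef_palu, ef_reference,
                                 gwp_palu = "AR5", gwp_reference = "AR5") {
  if (!identical(gwp_palu, gwp_reference)) {
    stop("GWP sets differ between the two emission factors")
  }
  delta <- ef_palu - ef_reference
  list(delta = delta, savings = -delta)
}

#' Scale a per-hectare mitigation delta to an area scenario
#'
#' @param delta_per_ha t CO2e ha-1 yr-1 (negative = mitigation).
#' @param area_ha affected area, ha (>= 0).
#' @return list of class `mitigation_scenario`: `delta_per_ha`, `area_ha`,
#'   `total_mt` (|delta| x area x 1e-6, Mt CO2e yr-1) and `total_mt_rounded`
#'   (one decimal, for reporting).
#' @export
scale_scenario <- function(delta_per_ha, area_ha) {
  stopifnot(area_ha >= 0)
  total <- abs(delta_per_ha) * area_ha * 1e-6
  structure(list(delta_per_ha = delta_per_ha, area_ha = area_ha,
                 total_mt = total, total_mt_rounded = round(total, 1)),
            class = "mitigation_scenario")
}
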