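# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Zero-noise synthetic year, processed end to end (the truth-integral oracle).
zero_noise_run <- function() {
  if (is.null(.fixtures$zn)) {
    tp <- truth_params()
    tp$noise <- list(co2_ppm = 0, ch4_ppb = 0, n2o_ppb = 0, rep_sd = 0,
                     flux_lognorm_sd = 0)
    site <- generate_site(seed = 3, truth = tp, keep_series = TRUE)
    res <- process_site(site$dataset, scope = "replicate")
    .fixtures$zn <- list(site = site, res = res,
                         truth = site$truth$true_annual)
  }
  .fixtures$zn
}

# Synthetic annual-balance table for the response models: log-linear CH4,
# sqrt-quadratic N2O, known coefficients.
response_data <- function(seed, n = 105, ch4_wt_slope = 10, ch4_bio = 0.05) {
  set.seed(seed)
  d <- data.frame(
    wt_mean = stats::runif(n, -0.3, 0.04),
    plant_genus = sample(c("Carex", "Phalaris", "Phragmites", "Typha"), n, TRUE),
    management_intensity = sample(c("one_cut", "two_cut_fertilized"), n, TRUE),
    stand_age = sample(1:5, n, TRUE),
    biomass_yield = stats::runif(n, 2, 14),
    site_id = sample(c("A", "B", "C"), n, TRUE))
  eta <- log(30) + ch4_wt_slope * d$wt_mean + ch4_bio * d$biomass_yield +
    c(Carex = 0, Phalaris = 0.5, Phragmites = -0.3, Typha = 0.7)[d$plant_genus]
  d$ch4_kg <- exp(eta) * stats::rlnorm(n, -0.35^2 / 2, 0.35)
  d$n2o_kg <- (pmax(0.3 - 3 * d$wt_mean, 0.05) + 0.5 * (d$stand_age == 1))^2 +
    stats::rnorm(n, 0, 0.4)
  d
}

# 50-seed CH4 WT-slope recovery (shared by module and acceptance tests).
ch4_slope_recovery <- function() {
  if (is.null(.fixtures$ch4rec)) {
    cfg <- flux_config(ch4_shift = 0)
    res <- vapply(1:50, function(s) {
      f <- fit_ch4_model(response_data(s), cfg)
      i <- which(names(f$fit$coef) == "wt")
      c(f$fit$coef[[i]], f$fit$se[i])
    }, numeric(2))
    .fixtures$ch4rec <- list(est = res[1, ], se = res[2, ], truth = 10)
  }
  .fixtures$ch4rec
}

# 100-seed Lloyd-Taylor / rectangular-hyperbola recovery under realistic noise.
param_recovery <- function() {
  if (is.null(.fixtures$prec)) {
    out <- t(vapply(1:100, function(s) {
      set.seed(s)
      tair <- stats::runif(9, 5, 25)
      reco_true <- lloyd_taylor(tair, 2, 300)
      rf <- fit_reco(tair, reco_true + stats::rnorm(9, 0, 0.3))
      par <- stats::runif(9, 50, 1500)
      t2 <- stats::runif(9, 10, 22)
      nee <- lloyd_taylor(t2, rf$rref, rf$e0) + rect_hyperbola(par, 0.05, 20) +
        stats::rnorm(9, 0, 0.5)
      gf <- fit_gpp(par, nee, t2, rf)
      abs(c(rf$rref - 2, rf$e0 - 300, gf$gpmax - 20, gf$alpha - 0.05)) /
        c(2, 300, 20, 0.05)
    }, numeric(4)))
    colnames(out) <- c("rref", "e0", "gpmax", "alpha")
    .fixtures$prec <- out
  }
  .fixtures$prec
}

# U-shaped GHG response with known optimum and a linear NECB with known
# zero crossing, for the spline oracle tests.
spline_data <- function(seed = 7, n = 120, noise_sd = 1.0) {
  set.seed(seed)
  d <- data.frame(
    wt_mean = stats::runif(n, -0.3, 0.04),
    plant_genus = sample(c("Carex", "Phalaris"), n, TRUE),
    management_intensity = "one_cut",
    site_id = sample(c("A", "B"), n, TRUE))
  d$ghg_ar5 <- 200 * (d$wt_mean + 0.07)^2 - 10 +
    2 * (d$plant_genus == "Phalaris") + stats::rnorm(n, 0, noise_sd)
  d$necb <- -40 * (d$wt_mean + 0.15) + 4 * (d$plant_genus == "Phalaris") +
    stats::rnorm(n, 0, 0.3)
  d
}

# Minimal valid input directory written by hand (schema fixtures).
write_mini_dir <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("site_id,treatment_id,replicate_id,plant_genus,management_intensity,stand_age",
               "S1,t1,t1_r1,Carex,one_cut,3"),
             file.path(dir, "meta.csv"))
  writeLines(c("timestamp,tair,par,pressure",
               "2021-01-01 00:00:00,5,0,96000",
               "2021-01-01 00:30:00,5.2,0,96000",
               "2021-01-01 01:00:00,5.1,0,96000"),
             file.path(dir, "met.csv"))
  writeLines(c("treatment_id,timestamp,wt",
               "t1,2021-01-01 00:00:00,-0.05",
               "t1,2021-01-01 00:30:00,-0.06"),
             file.path(dir, "wt.csv"))
  writeLines(c("closure_id,replicate_id,gas,chamber_type,start,elapsed_s,conc,tair,pressure,par,area_m2,volume_m3",
               "c1,t1_r1,CO2,opaque,2021-01-01 00:00:00,0,415,5,96000,0,0.5625,0.28125",
               "c1,t1_r1,CO2,opaque,2021-01-01 00:00:00,30,416,5,96000,0,0.5625,0.28125",
               "c1,t1_r1,CO2,opaque,2021-01-01 00:00:00,60,417,5,96000,0,0.5625,0.28125",
               "c1,t1_r1,CO2,opaque,2021-01-01 00:00:00,90,418,5,96000,0,0.5625,0.28125"),
             file.path(dir, "closures.csv"))
  writeLines(c("treatment_id,date,kind,dm_yield,corg_fraction,c_applied,n_applied",
               "t1,2021-12-15,harvest,8.0,0.47,,"),
             file.path(dir, "events.csv"))
  dir
}
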