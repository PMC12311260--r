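test_that("noiseless campaigns recover Lloyd-Taylor parameters exactly", {
  tair <- seq(5, 25, length.out = 12)
  y <- lloyd_taylor(tair, 2, 300)
  fit <- fit_reco(tair, y)
  expect_equal(fit$rref, 2, tolerance = 1e-6)
  expect_equal(fit$e0, 300, tolerance = 1e-6)
  expect_equal(fit$metrics$nse, 1, tolerance = 1e-9)
})

test_that("temperature-independent respiration collapses to its mean", {
  tair <- seq(5, 25, length.out = 10)
  fit <- fit_reco(tair, rep(3, 10))
  expect_lt(fit$e0, 1e-4)
  expect_equal(fit$rref, 3, tolerance = 1e-6)
})

test_that("under-determined respiration campaigns are refused", {
  expect_error(fit_reco(c(5, 20), c(1, 2)), ">= 3")
  expect_error(fit_reco(c(10, 10.5, 11), c(1, 2, 3)), "spread")
})

test_that("noiseless light-response campaigns recover their parameters", {
  tair <- seq(8, 20, length.out = 10)
  rf <- fit_reco(tair, lloyd_taylor(tair, 2, 300))
  par <- seq(100, 1500, length.out = 10)
  nee <- lloyd_taylor(tair, 2, 300) + rect_hyperbola(par, 0.05, 20)
  gf <- fit_gpp(par, nee, tair, rf)
  expect_equal(gf$gpmax, 20, tolerance = 1e-6)
  expect_equal(gf$alpha, 0.05, tolerance = 1e-6)

  # the model predicts exactly zero GPP in darkness
  expect_equal(rect_hyperbola(0, gf$alpha, gf$gpmax), 0)

  # NEE identical to the respiration prediction -> no photosynthesis signal
  gf0 <- fit_gpp(par, lloyd_taylor(tair, 2, 300), tair, rf)
  expect_equal(gf0$gpmax, 0)
  expect_error(fit_gpp(c(0, 0, 0), c(1, 1, 1), c(10, 10, 10), rf), "PAR > 0")
})

test_that("parameter recovery stays under 10% median error with noise", {
  err <- param_recovery()  # 100 seeded campaigns, realistic noise
  med <- apply(err, 2, stats::median)
  expect_lt(med[["rref"]], 0.10)
  expect_lt(med[["e0"]], 0.10)
  expect_lt(med[["gpmax"]], 0.10)
  expect_lt(med[["alpha"]], 0.10)
})

test_that("campaign parameters interpolate linearly with constant tails", {
  tz <- "Etc/GMT-1"
  params <- data.frame(
    campaign_id = c("a", "b"), scope_id = "t",
    date = as.POSIXct(c("2021-03-01", "2021-05-01"), tz = tz),
    rref = c(1, 3), e0 = c(200, 300), gpmax = c(10, 20), alpha = c(0.02, 0.04))
  mid <- as.POSIXct("2021-04-01", tz = tz) - 0.5 * 86400 + 0.5 * 86400
  q <- interpolate_params(params, as.POSIXct("2021-04-01", tz = tz))
  expect_equal(q$rref, 2, tolerance = 0.02)  # near the midpoint of 61 days
  before <- interpolate_params(params, as.POSIXct("2021-01-01", tz = tz))
  expect_equal(before$rref, 1)
  after <- interpolate_params(params, as.POSIXct("2021-12-01", tz = tz))
  expect_equal(after$rref, 3)
  expect_warning(interpolate_params(params[1, ], mid), "single campaign")
})

test_that("a sustained unit flux integrates to the canonical annual balance", {
  tz <- "Etc/GMT-1"
  ts <- seq(as.POSIXct("2021-01-01", tz = tz),
            as.POSIXct("2021-12-31 23:30:00", tz = tz), by = 1800)
  met <- data.frame(timestamp = ts, tair = 10, par = 0, pressure = 96000)
  params <- data.frame(campaign_id = c("a", "b"), scope_id = "t",
                       date = range(ts), rref = 1, e0 = 0, gpmax = 0, alpha = 0)
  ann <- reconstruct_annual(params, met)
  # 1 umol m-2 s-1 for a 365.25-d year = 44.01e-6 * 3.15576e7 / 100 t/ha
  expect_equal(ann$reco, 13.888, tolerance = 1e-3)
  expect_equal(ann$reco, co2_umol_to_t_ha_yr(1), tolerance = 1e-6)
  expect_equal(ann$gpp, 0)
  expect_equal(ann$nee, ann$reco)

  params0 <- params; params0$rref <- 0
  ann0 <- reconstruct_annual(params0, met)
  expect_equal(abs(ann0$reco) + abs(ann0$gpp) + abs(ann0$nee), 0)
})

test_that("additivity NEE = Reco + GPP holds per step and annually", {
  run <- zero_noise_run()
  params <- campaign_params(run$res$fits)
  p1 <- params[params$scope_id == params$scope_id[1], ]
  met <- run$site$dataset$met
  ser <- reconstruct_series(p1, met)
  expect_equal(ser$nee, ser$reco + ser$gpp, tolerance = 1e-12)
  ann <- reconstruct_annual(p1, met)
  expect_equal(ann$nee, ann$reco + ann$gpp, tolerance = 1e-10)
  # monotonicity of the response surfaces
  expect_true(all(diff(lloyd_taylor(seq(0, 30, 1), 2, 300)) > 0))
  expect_true(all(diff(abs(rect_hyperbola(seq(0, 2000, 50), 0.05, 20))) > 0))
})

test_that("reconstruction error shrinks with campaign frequency", {
  tz <- "Etc/GMT-1"
  met <- generate_met(2021, 21)
  doy <- as.integer(format(met$timestamp, "%j"))
  # smooth truth trajectories sampled exactly at the campaign dates
  rref_t <- 2 + 1.5 * sin(2 * pi * (doy - 120) / 365.25)
  gpmax_t <- 25 * exp(-((doy - 200) / 90)^2)
  true_reco <- lloyd_taylor(met$tair, rref_t, 250)
  true_gpp <- rect_hyperbola(met$par, 0.04, gpmax_t)
  truth_nee <- co2_umol_to_t_ha_yr(mean(true_reco + true_gpp))
  err <- sapply(c(6, 12, 24), function(n_camp) {
    d <- round(seq(5, 360, length.out = n_camp))
    dates <- as.POSIXct(sprintf("2021-%03d 12:00:00", d), format = "%Y-%j %H:%M:%S", tz = tz)
    params <- data.frame(campaign_id = as.character(d), scope_id = "t",
                         date = dates,
                         rref = 2 + 1.5 * sin(2 * pi * (d - 120) / 365.25),
                         e0 = 250, gpmax = 25 * exp(-((d - 200) / 90)^2),
                         alpha = 0.04)
    ann <- reconstruct_annual(params, met)
    abs(ann$nee - truth_nee)
  })
  expect_true(all(diff(err) < 0))
})

test_that("evaluation metrics match their hand-computed values", {
  perfect <- evaluate_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$nse, 1)
  expect_equal(perfect$pbias, 0)
  expect_equal(perfect$rmse, 0)
  expect_true(perfect$satisfactory)

  m <- evaluate_fit(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$nse, 0)
  expect_equal(m$pbias, 0)
  expect_equal(m$rmse, 0.8164966, tolerance = 1e-6)
  expect_false(m$satisfactory)

  zv <- evaluate_fit(c(2, 2), c(1, 3))
  expect_true(is.na(zv$nse))
  expect_true(zv$zero_variance)
})

test_that("bootstrap uncertainty is seeded, zero for exact fits, noise-monotone", {
  tz <- "Etc/GMT-1"
  met <- generate_met(2021, 31)
  mk_fits <- function(noise_sd, seed) {
    set.seed(seed)
    days <- c(60, 180, 300)
    fits <- lapply(days, function(d) {
      tair <- stats::runif(9, 5, 25)
      y <- lloyd_taylor(tair, 2.5, 280) + stats::rnorm(9, 0, noise_sd)
      rf <- fit_reco(tair, y)
      par <- stats::runif(9, 100, 1500)
      nee <- lloyd_taylor(tair, rf$rref, rf$e0) +
        rect_hyperbola(par, 0.05, 18) + stats::rnorm(9, 0, noise_sd)
      gf <- fit_gpp(par, nee, tair, rf)
      list(campaign_id = paste0("c", d), scope_id = "t",
           date = as.POSIXct(sprintf("2021-%03d", d), format = "%Y-%j", tz = tz),
           reco = rf, gpp = gf)
    })
    names(fits) <- paste0("c", days)
    class(fits) <- "campaign_fits"
    fits
  }
  f0 <- mk_fits(0, 1)
  u0 <- uncertainty_annual(f0, met, n_boot = 50, seed = 5)
  expect_lt(u0$nee, 1e-4)

  fs <- mk_fits(0.3, 2)
  us1 <- uncertainty_annual(fs, met, n_boot = 50, seed = 5)
  us2 <- uncertainty_annual(fs, met, n_boot = 50, seed = 5)
  expect_identical(us1$nee, us2$nee)  # deterministic under a fixed seed

  fb <- mk_fits(1.5, 2)
  ub <- uncertainty_annual(fb, met, n_boot = 50, seed = 5)
  expect_lt(us1$nee, ub$nee)  # less closure noise, tighter interval
})
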