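test_that("the CH4 model recovers a known log-linear WT slope", {
  rec <- ch4_slope_recovery()  # 50 seeded datasets, truth slope 10 per m
  expect_lt(abs(stats::median(rec$est) - rec$truth),
            2 * stats::median(rec$se))
  expect_gte(mean(abs(rec$est - rec$truth) <= 2 * rec$se), 0.90)
})

test_that("a null biomass effect is not declared significant", {
  cfg <- flux_config(ch4_shift = 0)
  hits <- vapply(1:50, function(s) {
    d <- response_data(s + 500, ch4_bio = 0)
    f <- fit_ch4_model(d, cfg)
    i <- which(names(f$fit$coef) == "bio")
    abs(f$fit$coef[[i]]) <= 2 * f$fit$se[i]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("CH4 predictions collapse toward zero under deep water tables", {
  cfg <- flux_config(ch4_shift = 0)
  d <- response_data(3)
  f <- fit_ch4_model(d, cfg)
  nd <- function(w) data.frame(wt_mean = w, plant_genus = "Carex",
                               biomass_yield = 8)
  deep <- predict(f, nd(-0.25))
  wet <- predict(f, nd(0))
  expect_lt(deep / wet, 0.1)
  # link monotonicity: positive WT coefficient means strictly rising CH4
  grid <- predict(f, nd(seq(-0.3, 0.04, length.out = 50)))
  expect_true(all(diff(grid) > 0))
})

test_that("the CH4 shift is reversed on prediction", {
  d <- response_data(4)
  cfg0 <- flux_config(ch4_shift = 0)
  cfg5 <- flux_config(ch4_shift = 5)
  f5 <- fit_ch4_model(d, cfg5)
  nd <- data.frame(wt_mean = -0.05, plant_genus = "Carex", biomass_yield = 8)
  # prediction is on the original (unshifted) response scale
  p5 <- predict(f5, nd)
  expect_gt(p5, 0)
  expect_lt(abs(p5 - predict(fit_ch4_model(d, cfg0), nd)) / p5, 0.25)
  expect_error(fit_ch4_model(d[1:10, ], cfg0), ">= 20")
})

test_that("the N2O model recovers curvature and stand-age structure", {
  neg <- vapply(1:50, function(s) {
    f <- suppressWarnings(fit_n2o_model(response_data(s + 900)))
    f$fit$coef[["wt"]] < 0  # declining emissions toward the surface
  }, logical(1))
  expect_gte(mean(neg), 0.95)

  d <- response_data(12)
  f <- fit_n2o_model(d)
  i <- which(names(f$fit$coef) == "age1")
  expect_gt(f$fit$coef[[i]], 2 * f$fit$se[i])  # first-year stands elevated

  z <- response_data(13); z$n2o_kg <- 0
  fz <- fit_n2o_model(z)
  expect_equal(predict(fz, data.frame(wt_mean = c(-0.2, 0),
                                      plant_genus = "Carex", stand_age = 2)),
               c(0, 0))
})

test_that("the penalized spline tracks a smooth truth below the noise floor", {
  d <- spline_data(seed = 7, noise_sd = 1.0)
  fit <- fit_balance_spline(d, "ghg_ar5")
  truth <- 200 * (d$wt_mean + 0.07)^2 - 10 + 2 * (d$plant_genus == "Phalaris")
  pred <- predict(fit, data.frame(wt_mean = d$wt_mean,
                                  plant_genus = d$plant_genus,
                                  management_intensity = d$management_intensity))
  expect_lt(sqrt(mean((pred - truth)^2)), 1.0)
  expect_lte(fit$edf_spline, flux_config()$spline$k - 1)
})

test_that("the penalty limit degenerates to a linear WT trend", {
  d <- spline_data(seed = 8)
  f_inf <- fit_balance_spline(d, "ghg_ar5", lambda = 1e10, include_site = FALSE)
  expect_lt(f_inf$edf_spline, 1.05)

  # zero-noise linear truth: GCV picks an (almost) linear smooth
  d$necb <- -40 * (d$wt_mean + 0.15)
  f_lin <- fit_balance_spline(d, "necb", include_site = FALSE)
  expect_lt(f_lin$edf_spline, 2)
})

test_that("lambda = 0 without site offsets reproduces OLS on the basis", {
  d <- spline_data(seed = 9)
  f0 <- fit_balance_spline(d, "necb", lambda = 0, include_site = FALSE)
  sm <- mgcv::smoothCon(mgcv::s(wt, bs = "cr", k = 10),
                        data = data.frame(wt = d$wt_mean),
                        absorb.cons = TRUE)[[1]]
  X <- cbind(stats::model.matrix(~ plant_genus, d), sm$X)
  ols <- stats::lm.fit(X, d$necb)
  expect_equal(unname(f0$coef), unname(ols$coefficients), tolerance = 1e-8)
})

test_that("spline predictions are invariant to affine WT rescaling", {
  d <- spline_data(seed = 10)
  f1 <- fit_balance_spline(d, "ghg_ar5", lambda = 0, include_site = FALSE)
  d2 <- d; d2$wt_mean <- 2 * d$wt_mean + 0.1
  f2 <- fit_balance_spline(d2, "ghg_ar5", lambda = 0, include_site = FALSE)
  w <- seq(-0.25, 0, length.out = 20)
  p1 <- predict(f1, data.frame(wt_mean = w, plant_genus = "Carex"))
  p2 <- predict(f2, data.frame(wt_mean = 2 * w + 0.1, plant_genus = "Carex"))
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("the GHG optimum is recovered within the grid tolerance", {
  d <- spline_data(seed = 7)
  fit <- fit_balance_spline(d, "ghg_ar5")
  opt <- find_optimum(fit, n_boot = 30, seed = 2)
  expect_false(opt$boundary)
  expect_lt(abs(opt$wt_opt - (-0.07)), 0.02)
  expect_true(opt$ci[1] <= opt$wt_opt && opt$wt_opt <= opt$ci[2])

  # monotone truth: the minimum sits on the range boundary and is flagged
  d$ghg_ar5 <- 50 * d$wt_mean + stats::rnorm(nrow(d), 0, 0.5)
  fmono <- fit_balance_spline(d, "ghg_ar5")
  expect_true(find_optimum(fmono, n_boot = 0)$boundary)
})

test_that("the NECB sink threshold is recovered and flagged correctly", {
  d <- spline_data(seed = 7)
  fit <- fit_balance_spline(d, "necb")
  thr <- find_threshold(fit, genus = "Carex")
  expect_true(thr$defined)
  expect_lt(abs(thr$wt_zero - (-0.15)), 0.02)

  # genus offset shifts the crossing: -40 (wt + 0.15) + 4 = 0 at wt = -0.05
  thr_p <- find_threshold(fit, genus = "Phalaris")
  expect_true(thr_p$defined)
  expect_lt(abs(thr_p$wt_zero - (-0.05)), 0.02)

  # all-negative NECB: no crossing, undefined with the all-sink flag
  d$necb <- d$necb - 30
  fneg <- fit_balance_spline(d, "necb")
  thr_n <- find_threshold(fneg)
  expect_false(thr_n$defined)
  expect_true(thr_n$all_sink)
})

test_that("the spline fit agrees with an independent GAM on the same data", {
  d <- spline_data(seed = 11)
  fit <- fit_balance_spline(d, "ghg_ar5", include_site = FALSE)
  gam <- mgcv::gam(ghg_ar5 ~ s(wt_mean, bs = "cr", k = 10) + plant_genus,
                   data = d)
  w <- seq(-0.28, 0.02, length.out = 25)
  p1 <- predict(fit, data.frame(wt_mean = w, plant_genus = "Carex"))
  p2 <- as.numeric(predict(gam, data.frame(wt_mean = w, plant_genus = "Carex")))
  expect_lt(max(abs(p1 - p2)), 0.5)  # same curve up to smoothing differences
})
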