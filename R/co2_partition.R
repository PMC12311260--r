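# Campaign-based CO2 partitioning: ecosystem respiration (Reco) is fitted
# against air temperature with the Lloyd-Taylor exponential, gross primary
# production (GPP) against PAR with a rectangular hyperbola; campaign
# parameters are interpolated through time and driven with continuous
# meteorology to reconstruct and integrate annual Reco/GPP/NEE.

LT_TREF <- 283.15  # K, reference temperature
LT_T0 <- 227.13    # K, temperature offset

#' Lloyd-Taylor respiration model
#'
#' `Reco(T) = rref * exp(e0 * (1/(tref - t0) - 1/(T_K - t0)))` with the
#' conventional constants tref = 283.15 K and t0 = 227.13 K.
#'
#' @param tair_c air temperature, deg C.
#' @param rref respiration at the reference temperature, umol m-2 s-1.
#' @param e0 temperature sensitivity, K.
#' @return Reco in umol m-2 s-1 (>= 0).
#' @export
lloyd_taylor <- function(tair_c, rref, e0) {
  t_k <- tair_c + 273.15
  rref * exp(e0 * (1 / (LT_TREF - LT_T0) - 1 / (t_k - LT_T0)))
}

#' Rectangular-hyperbola light response
#'
#' `GPP(PAR) = -(alpha * PAR * gpmax) / (alpha * PAR + gpmax)`; 0 at PAR = 0
#' and saturating at `-gpmax`. Returned with the atmospheric sign convention
#' (uptake negative).
#'
#' @param par photosynthetic photon flux density, umol m-2 s-1.
#' @param alpha initial light-use efficiency, umol CO2 per umol photons.
#' @param gpmax light-saturated gross photosynthesis, umol m-2 s-1 (>= 0).
#' @export
rect_hyperbola <- function(par, alpha, gpmax) {
  den <- alpha * par + gpmax
  ifelse(den > 0, -(alpha * par * gpmax) / den, 0)
}

#' Fit the Lloyd-Taylor model to one campaign's Reco observations
#'
#' Bounded Levenberg-Marquardt nonlinear least squares with multi-start on
#' failure (rref >= 0, 0 <= e0 <= 1000). Requires at least 3 accepted
#' opaque-chamber observations spanning >= 3 K of air temperature.
#'
#' @param tair_c observation air temperatures, deg C.
#' @param reco_obs observed Reco fluxes, umol m-2 s-1.
#' @return list of class `reco_fit`: `rref`, `e0`, `vcov`, `fitted`,
#'   `metrics` (see [evaluate_fit()]), `convergence`.
#' @export
fit_reco <- function(tair_c, reco_obs) {
  if (length(reco_obs) < 3) stop("Reco fit needs >= 3 observations")
  if (diff(range(tair_c)) < 3) stop("Reco fit needs >= 3 K air-temperature spread")
  df <- data.frame(t = tair_c, y = reco_obs)
  starts <- lapply(c(150, 50, 400), function(e0) {
    list(rref = max(mean(reco_obs) / mean(exp(e0 * (1 / (LT_TREF - LT_T0) -
           1 / (tair_c + 273.15 - LT_T0)))), 1e-6), e0 = e0)
  })
  fit <- NULL
  for (st in starts) {
    f <- try(minpack.lm::nlsLM(y ~ lloyd_taylor(t, rref, e0), data = df,
                               start = st, lower = c(0, 0), upper = c(Inf, 1000),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 300, ftol = 1e-10, ptol = 1e-10)),
             silent = TRUE)
    if (!inherits(f, "try-error")) { fit <- f; break }
  }
  if (is.null(fit)) stop("Reco fit did not converge")
  cf <- stats::coef(fit)
  vc <- try(stats::vcov(fit), silent = TRUE)
  if (inherits(vc, "try-error") || anyNA(vc)) vc <- matrix(0, 2, 2)
  pred <- lloyd_taylor(tair_c, cf[["rref"]], cf[["e0"]])
  structure(list(rref = cf[["rref"]], e0 = cf[["e0"]], vcov = vc,
                 fitted = pred, metrics = evaluate_fit(reco_obs, pred),
                 convergence = TRUE, n = length(reco_obs)),
            class = "reco_fit")
}

#' Fit the light-response model to one campaign's NEE observations
#'
#' GPP observations are derived as `NEE_obs - Reco(T_obs)` using the
#' campaign's respiration fit, then `GPP(PAR)` is fitted by bounded nonlinear
#' least squares. Internally `gpmax` and `alpha` are nonnegative; the sign is
#' applied at reconstruction.
#'
#' @param par_obs PAR at the transparent-chamber closures, umol m-2 s-1.
#' @param nee_obs observed NEE fluxes, umol m-2 s-1.
#' @param tair_c air temperatures paired with `nee_obs`.
#' @param reco a `reco_fit`.
#' @return list of class `gpp_fit`: `gpmax`, `alpha`, `vcov`, `metrics`.
#' @export
fit_gpp <- function(par_obs, nee_obs, tair_c, reco) {
  if (all(par_obs <= 0)) stop("GPP fit needs observations with PAR > 0")
  if (length(nee_obs) < 3) stop("GPP fit needs >= 3 observations")
  gpp_obs <- nee_obs - lloyd_taylor(tair_c, reco$rref, reco$e0)
  y <- -gpp_obs  # fit on the positive scale
  if (max(abs(y)) < 1e-8) {
    fit <- list(gpmax = 0, alpha = 0, vcov = matrix(0, 2, 2),
                metrics = evaluate_fit(gpp_obs, rep(0, length(gpp_obs))),
                n = length(y))
    class(fit) <- "gpp_fit"
    return(fit)
  }
  df <- data.frame(q = par_obs, y = y)
  starts <- list(list(gpmax = max(max(y), 0.1), alpha = 0.03),
                 list(gpmax = max(2 * max(y), 0.1), alpha = 0.01),
                 list(gpmax = max(max(y), 0.1), alpha = 0.1))
  fit <- NULL
  for (st in starts) {
    f <- try(minpack.lm::nlsLM(y ~ (alpha * q * gpmax) / (alpha * q + gpmax),
                               data = df, start = st,
                               lower = c(1e-9, 1e-9), upper = c(500, 5),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 300, ftol = 1e-10, ptol = 1e-10)),
             silent = TRUE)
    if (!inherits(f, "try-error")) { fit <- f; break }
  }
  if (is.null(fit)) stop("GPP fit did not converge")
  cf <- stats::coef(fit)
  vc <- try(stats::vcov(fit), silent = TRUE)
  if (inherits(vc, "try-error") || anyNA(vc)) vc <- matrix(0, 2, 2)
  pred <- rect_hyperbola(par_obs, cf[["alpha"]], cf[["gpmax"]])
  structure(list(gpmax = cf[["gpmax"]], alpha = cf[["alpha"]], vcov = vc,
                 metrics = evaluate_fit(gpp_obs, pred), n = length(y)),
            class = "gpp_fit")
}

#' Fit campaign models across a flux table
#'
#' Accepted CO2 fluxes are grouped into full-day campaigns (by calendar date)
#' per treatment (pooled replicates; pass `scope = "replicate"` for
#' high-frequency automated data that supports per-replicate fits). Opaque
#' closures are Reco observations, transparent closures NEE observations.
#'
#' @param fluxes fluxes table from [compute_fluxes()].
#' @param meta replicate metadata (site/treatment/replicate keys).
#' @param scope `"treatment"` or `"replicate"`.
#' @param log optional run log.
#' @return list of class `campaign_fits`: one element per campaign x scope
#'   with `campaign_id`, `scope_id`, `date`, `reco`, `gpp`.
#' @export
fit_campaigns <- function(fluxes, meta, scope = c("treatment", "replicate"),
                          log = NULL) {
  scope <- match.arg(scope)
  flx <- accepted_fluxes(fluxes[fluxes$gas == "CO2", ])
  key <- if (scope == "treatment") {
    meta$treatment_id[match(flx$replicate_id, meta$replicate_id)]
  } else flx$replicate_id
  flx$scope_id <- key
  flx$day <- as.Date(flx$start, tz = attr(flx$start, "tzone"))
  groups <- split(flx, list(flx$scope_id, flx$day), drop = TRUE)
  fits <- list()
  n_failed <- 0L
  for (g in groups) {
    op <- g[g$chamber_type == "opaque", ]
    tr <- g[g$chamber_type == "transparent" & g$par > 0, ]
    res <- try({
      reco <- fit_reco(op$tair, op$flux)
      gpp <- fit_gpp(tr$par, tr$flux, tr$tair, reco)
      list(campaign_id = sprintf("%s_%s", g$scope_id[1], format(g$day[1])),
           scope_id = g$scope_id[1], date = mean(g$start),
           reco = reco, gpp = gpp)
    }, silent = TRUE)
    if (inherits(res, "try-error")) n_failed <- n_failed + 1L else {
      fits[[res$campaign_id]] <- res
    }
  }
  log_stage(log, "fit_campaigns", n_campaigns = length(fits),
            n_failed = n_failed, scope = scope)
  structure(fits, class = "campaign_fits")
}

#' Campaign parameter table
#'
#' Flat view of a `campaign_fits` object (the shape of a campaign-parameter
#' repository table): one row per campaign with dates, rref, e0, gpmax,
#' alpha and fit diagnostics.
#'
#' @param fits a `campaign_fits`.
#' @export
campaign_params <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(campaign_id = f$campaign_id, scope_id = f$scope_id,
               date = f$date, rref = f$reco$rref, e0 = f$reco$e0,
               gpmax = f$gpp$gpmax, alpha = f$gpp$alpha,
               nse_reco = f$reco$metrics$nse, nse_gpp = f$gpp$metrics$nse,
               rmse_reco = f$reco$metrics$rmse, rmse_gpp = f$gpp$metrics$rmse,
               n_reco = f$reco$n, n_gpp = f$gpp$n, row.names = NULL)
  }))
}

#' Interpolate campaign parameters onto a timestamp grid
#'
#' Piecewise-linear interpolation of each parameter between campaign
#' midpoints on the parameter scale, with constant extrapolation before the
#' first and after the last campaign. Parameter bounds (nonnegativity) are
#' preserved by linearity. A single campaign yields a constant model with a
#' warning.
#'
#' @param params campaign parameter table ([campaign_params()]) for one scope.
#' @param times POSIXct grid.
#' @return data.frame with `rref`, `e0`, `gpmax`, `alpha` per time.
#' @export
interpolate_params <- function(params, times) {
  params <- params[order(params$date), ]
  if (nrow(params) == 1) {
    warning("single campaign: using a constant parameter model")
    return(data.frame(rref = rep(params$rref, length(times)),
                      e0 = params$e0, gpmax = params$gpmax, alpha = params$alpha))
  }
  x <- as.numeric(params$date)
  xo <- as.numeric(times)
  ip <- function(v) stats::approx(x, v, xout = xo, rule = 2)$y
  data.frame(rref = ip(params$rref), e0 = ip(params$e0),
             gpmax = ip(params$gpmax), alpha = ip(params$alpha))
}

#' Reconstruct continuous Reco/GPP/NEE from campaign fits and meteorology
#'
#' @param params campaign parameter table for one scope.
#' @param met met series covering the period at <= 0.5 h.
#' @return data.frame `timestamp`, `reco`, `gpp`, `nee` in umol m-2 s-1,
#'   satisfying `nee = reco + gpp` at every step.
#' @export
reconstruct_series <- function(params, met) {
  p <- interpolate_params(params, met$timestamp)
  reco <- lloyd_taylor(met$tair, p$rref, p$e0)
  gpp <- rect_hyperbola(met$par, p$alpha, p$gpmax)
  data.frame(timestamp = met$timestamp, reco = reco, gpp = gpp,
             nee = reco + gpp)
}

#' Integrate an annual CO2 balance
#'
#' Per-step fluxes are time-weighted, summed over the measurement window and
#' converted to t CO2 ha-1 yr-1. Windows deviating from a full year are
#' normalized to a 365.25-day year when `config$period_normalize` is TRUE.
#'
#' @param params campaign parameter table for one scope.
#' @param met met series.
#' @param period POSIXct length-2 start/end; default the met range.
#' @param config a [flux_config()].
#' @return list of class `annual_co2`: `reco`, `gpp`, `nee` (t CO2 ha-1
#'   yr-1), `period`, `seconds`.
#' @export
reconstruct_annual <- function(params, met, period = range(met$timestamp),
                               config = flux_config()) {
  sel <- met$timestamp >= period[1] & met$timestamp <= period[2]
  met <- met[sel, ]
  if (!is.null(met$gap) && any(met$gap)) stop("met series has unfilled gaps in period")
  ser <- reconstruct_series(params, met)
  tnum <- as.numeric(met$timestamp)
  w <- diff(tnum)
  w <- c(w, w[length(w)])  # last step weighted like its predecessor
  total_s <- sum(w)
  int <- function(v) sum(v * w) / total_s  # time-weighted mean, umol m-2 s-1
  scale <- if (isTRUE(config$period_normalize)) 1 else total_s / SECONDS_PER_YEAR
  out <- list(reco = co2_umol_to_t_ha_yr(int(ser$reco)) * scale,
              gpp = co2_umol_to_t_ha_yr(int(ser$gpp)) * scale,
              period = period, seconds = total_s)
  out$nee <- out$reco + out$gpp
  class(out) <- "annual_co2"
  out
}

#' Model evaluation metrics
#'
#' Nash-Sutcliffe efficiency `NSE = 1 - sum((o-p)^2)/sum((o-mean(o))^2)`,
#' percent bias `PBIAS = 100 * sum(o-p)/sum(o)` and root-mean-square error.
#' NSE > 0.5 is conventionally classed a satisfactory simulation.
#'
#' @param observed,predicted paired nonempty flux vectors.
#' @return list `nse`, `pbias`, `rmse`, `satisfactory`; NSE is NA (flagged
#'   via `zero_variance`) when the observations have no variance.
#' @export
evaluate_fit <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) > 0)
  err <- observed - predicted
  sst <- sum((observed - mean(observed))^2)
  nse <- if (sst > 0) 1 - sum(err^2) / sst else NA_real_
  pbias <- if (sum(observed) != 0) 100 * sum(err) / sum(observed) else 0
  list(nse = nse, pbias = pbias, rmse = sqrt(mean(err^2)),
       satisfactory = isTRUE(nse > 0.5), zero_variance = sst == 0)
}

#' Bootstrap uncertainty of an annual CO2 balance
#'
#' Parametric bootstrap over the campaign parameter covariances: each draw
#' samples (rref, e0) and (gpmax, alpha) per campaign from their estimated
#' Gaussian sampling distributions (clipped to parameter bounds), the annual
#' balance is re-integrated, and the 95% half-width is half the distance
#' between the 2.5th and 97.5th percentiles. Singular covariances degrade to
#' point parameters for that campaign.
#'
#' @param fits a `campaign_fits` for one scope.
#' @param met met series.
#' @param period integration window.
#' @param n_boot bootstrap draws.
#' @param seed RNG seed (local, does not disturb the global RNG stream).
#' @param config a [flux_config()].
#' @return list with half-widths `reco`, `gpp`, `nee` (t CO2 ha-1 yr-1) and
#'   the bootstrap draws in `draws`.
#' @export
uncertainty_annual <- function(fits, met, period = range(met$timestamp),
                               n_boot = 200, seed = 1L, config = flux_config()) {
  base <- campaign_params(fits)
  draws <- matrix(NA_real_, n_boot, 3, dimnames = list(NULL, c("reco", "gpp", "nee")))
  rng <- local({ set.seed(seed); lapply(seq_len(n_boot), function(i) {
    lapply(fits, function(f) {
      th_r <- draw_params(c(f$reco$rref, f$reco$e0), f$reco$vcov,
                          lower = c(0, 0), upper = c(Inf, 1000))
      th_g <- draw_params(c(f$gpp$gpmax, f$gpp$alpha), f$gpp$vcov,
                          lower = c(0, 0), upper = c(500, 5))
      c(th_r, th_g)
    })
  })})
  for (i in seq_len(n_boot)) {
    pb <- base
    th <- rng[[i]]
    for (j in seq_along(fits)) {
      pb$rref[j] <- th[[j]][1]; pb$e0[j] <- th[[j]][2]
      pb$gpmax[j] <- th[[j]][3]; pb$alpha[j] <- th[[j]][4]
    }
    ann <- reconstruct_annual(pb, met, period, config)
    draws[i, ] <- c(ann$reco, ann$gpp, ann$nee)
  }
  hw <- apply(draws, 2, function(v) diff(stats::quantile(v, c(0.025, 0.975))) / 2)
  list(reco = hw[["reco"]], gpp = hw[["gpp"]], nee = hw[["nee"]], draws = draws)
}

draw_params <- function(mu, vc, lower, upper) {
  ok <- all(is.finite(vc)) && all(diag(vc) > 0) &&
    !inherits(try(chol(vc), silent = TRUE), "try-error")
  th <- if (ok) MASS::mvrnorm(1, mu, vc) else mu
  pmin(pmax(th, lower), upper)
}
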