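# Nonlinear water-table response models for annual balances.
#
# CH4: log-link GLM with Tweedie-type variance (V(mu) = mu^p), genus and
#   biomass fixed effects. N2O: Gaussian with square-root link, genus and
#   stand-age effects. NECB / GHG balance: penalized cubic-regression-spline
#   smooth of WT with genus and management fixed effects. In all three, the
#   site grouping enters as ridge-penalized dummy offsets sharing one
#   penalty — a fixed-effect approximation of a random intercept that keeps
#   the shrinkage behaviour without mixed-model machinery.

fac <- function(x, levels) factor(x, levels = levels)

site_design <- function(site_id) {
  s <- factor(site_id)
  Z <- stats::model.matrix(~ 0 + s)
  colnames(Z) <- paste0("site_", levels(s))
  Z
}

# Penalized iteratively reweighted least squares.
# links: "identity", "log", "sqrt"; variance V(mu) = mu^var_power (0 = const).
pglm_irls <- function(y, X, penalty_diag, link = "log", var_power = 0,
                      max_iter = 100, tol = 1e-10) {
  n <- length(y)
  linkfun <- switch(link, identity = function(m) m, log = log, sqrt = sqrt)
  linkinv <- switch(link, identity = function(e) e, log = exp,
                    sqrt = function(e) e^2)
  mu_eta <- switch(link, identity = function(e) rep(1, length(e)),
                   log = function(e) exp(e), sqrt = function(e) 2 * e)
  mu0 <- switch(link, identity = y,
                log = pmax(y, max(mean(abs(y)) * 0.01, 1e-3)),
                sqrt = pmax(y, max(mean(abs(y)) * 0.01, 1e-3)))
  eta <- linkfun(mu0)
  P <- diag(penalty_diag, ncol(X))
  beta <- rep(0, ncol(X))
  truncated <- FALSE
  for (it in seq_len(max_iter)) {
    if (link == "sqrt") {
      bad <- eta < 1e-6
      if (any(bad)) { eta[bad] <- 1e-6; truncated <- TRUE }
    }
    mu <- linkinv(eta)
    me <- mu_eta(eta)
    V <- if (var_power == 0) rep(1, n) else pmax(mu, 1e-12)^var_power
    z <- eta + (y - mu) / me
    w <- me^2 / V
    XtW <- t(X * w)
    A <- XtW %*% X + P
    b_new <- try(solve(A, XtW %*% z), silent = TRUE)
    if (inherits(b_new, "try-error")) stop("IRLS failed: singular system (separation?)")
    b_new <- drop(b_new)
    if (max(abs(b_new - beta)) < tol * (1 + max(abs(beta)))) { beta <- b_new; break }
    beta <- b_new
    eta <- drop(X %*% beta)
    if (it == max_iter) warning("IRLS reached max_iter without convergence")
  }
  if (truncated) warning("sqrt-link linear predictor truncated at zero")
  eta <- drop(X %*% beta)
  if (link == "sqrt") eta <- pmax(eta, 0)
  mu <- linkinv(eta)
  me <- mu_eta(pmax(eta, if (link == "sqrt") 1e-6 else -Inf))
  V <- if (var_power == 0) rep(1, n) else pmax(mu, 1e-12)^var_power
  w <- me^2 / V
  XtW <- t(X * w)
  A <- XtW %*% X + P
  Ainv <- solve(A)
  H <- Ainv %*% (XtW %*% X)
  edf <- sum(diag(H))
  phi <- sum((y - mu)^2 / V) / max(n - edf, 1)
  Vb <- phi * Ainv
  list(coef = stats::setNames(beta, colnames(X)),
       se = sqrt(pmax(diag(Vb), 0)), vcov = Vb, fitted = mu, edf = edf,
       dispersion = phi,
       pseudo_r2 = 1 - sum((y - mu)^2) / sum((y - mean(y))^2))
}

#' Fit the annual CH4 water-table response model
#'
#' `CH4 ~ WT + plant genus + biomass yield` with a log link and Tweedie-type
#' variance `V(mu) = mu^p` (default p = 1.5; optionally profiled over a grid
#' by extended quasi-likelihood), fitted by penalized IRLS with
#' ridge-penalized site offsets. Because annual CH4 balances can be slightly
#' negative, a documented shift constant is added before fitting and removed
#' on prediction.
#'
#' @param data data.frame with `ch4_kg` (kg CH4 ha-1 yr-1), `wt_mean` (m),
#'   `plant_genus`, `biomass_yield` (t DM ha-1 yr-1), `site_id`.
#' @param config a [flux_config()] (`ch4_shift`, `tweedie_p`).
#' @param site_ridge ridge penalty on the site offsets.
#' @param profile_p if TRUE, profile the variance power over
#'   `seq(1.1, 1.9, 0.1)`.
#' @return list of class `wt_glm` with the coefficient table, link, variance
#'   power, site offsets and pseudo-R2.
#' @export
fit_ch4_model <- function(data, config = flux_config(), site_ridge = 1,
                          profile_p = FALSE) {
  if (nrow(data) < 20) stop("CH4 model needs >= 20 rows")
  shift <- config$ch4_shift
  y <- data$ch4_kg + shift
  if (any(y <= 0)) stop("ch4_kg + shift must be positive; raise config$ch4_shift")
  g <- fac(data$plant_genus, GENERA)
  g <- droplevels(g)
  if (any(table(g) == 0)) g <- droplevels(g)
  Xf <- stats::model.matrix(~ g + wt + bio,
                            data.frame(g = g, wt = data$wt_mean,
                                       bio = data$biomass_yield))
  Z <- site_design(data$site_id)
  X <- cbind(Xf, Z)
  pen <- c(rep(0, ncol(Xf)), rep(site_ridge, ncol(Z)))
  fit_p <- function(p) pglm_irls(y, X, pen, link = "log", var_power = p)
  p_use <- config$tweedie_p
  if (profile_p) {
    grid <- seq(1.1, 1.9, by = 0.1)
    eql <- sapply(grid, function(p) {
      f <- fit_p(p)
      V <- pmax(f$fitted, 1e-12)^p
      -0.5 * sum((y - f$fitted)^2 / (f$dispersion * V) +
                   log(2 * pi * f$dispersion * V))
    })
    p_use <- grid[which.max(eql)]
  }
  f <- fit_p(p_use)
  structure(list(fit = f, link = "log", var_power = p_use, shift = shift,
                 genus_levels = levels(g), fixed_cols = colnames(Xf),
                 site_cols = colnames(Z), response = "ch4_kg",
                 coef_table = data.frame(term = names(f$coef),
                                         estimate = f$coef, se = f$se,
                                         row.names = NULL)),
            class = "wt_glm")
}

#' Fit the annual N2O water-table response model
#'
#' `N2O ~ WT + plant genus + first-year-stand indicator` as a Gaussian GLM
#' with a square-root link (the squared linear predictor gives the
#' approximately quadratic decline of N2O with rising water table), site as
#' ridge-penalized offsets. Negative fitted link values are truncated at
#' zero with a warning.
#'
#' @param data data.frame with `n2o_kg` (kg N2O ha-1 yr-1), `wt_mean`,
#'   `plant_genus`, `stand_age`, `site_id`.
#' @param site_ridge ridge penalty on the site offsets.
#' @return a `wt_glm`.
#' @export
fit_n2o_model <- function(data, site_ridge = 1) {
  if (nrow(data) < 20) stop("N2O model needs >= 20 rows")
  y <- data$n2o_kg
  if (all(y == 0)) {
    return(structure(list(fit = list(coef = c(`(Intercept)` = 0), fitted = y * 0,
                                     pseudo_r2 = NA_real_, edf = 1),
                          link = "sqrt", intercept_only = TRUE,
                          response = "n2o_kg"),
                     class = "wt_glm"))
  }
  g <- droplevels(fac(data$plant_genus, GENERA))
  Xf <- stats::model.matrix(~ g + wt + age1,
                            data.frame(g = g, wt = data$wt_mean,
                                       age1 = as.numeric(data$stand_age == 1)))
  Z <- site_design(data$site_id)
  X <- cbind(Xf, Z)
  pen <- c(rep(0, ncol(Xf)), rep(site_ridge, ncol(Z)))
  f <- pglm_irls(y, X, pen, link = "sqrt", var_power = 0)
  structure(list(fit = f, link = "sqrt", shift = 0, genus_levels = levels(g),
                 fixed_cols = colnames(Xf), site_cols = colnames(Z),
                 response = "n2o_kg",
                 coef_table = data.frame(term = names(f$coef),
                                         estimate = f$coef, se = f$se,
                                         row.names = NULL)),
            class = "wt_glm")
}

#' Predict from a water-table GLM
#'
#' Site offsets are set to zero (population-level prediction); the CH4 shift
#' is reversed.
#'
#' @param object a `wt_glm`.
#' @param newdata data.frame with the model's covariates.
#' @param ... unused.
#' @export
predict.wt_glm <- function(object, newdata, ...) {
  if (isTRUE(object$intercept_only)) return(rep(0, nrow(newdata)))
  g <- fac(newdata$plant_genus, object$genus_levels)
  df <- data.frame(g = g, wt = newdata$wt_mean)
  df$bio <- if ("bio" %in% colnames0(object$fixed_cols)) newdata$biomass_yield else NULL
  if (object$response == "ch4_kg") {
    df$bio <- newdata$biomass_yield
    Xf <- stats::model.matrix(~ g + wt + bio, df)
  } else {
    df$age1 <- as.numeric(newdata$stand_age == 1)
    Xf <- stats::model.matrix(~ g + wt + age1, df)
  }
  eta <- drop(Xf %*% object$fit$coef[object$fixed_cols])
  mu <- switch(object$link, log = exp(eta), sqrt = pmax(eta, 0)^2, eta)
  mu - (if (!is.null(object$shift)) object$shift else 0)
}

colnames0 <- function(x) if (is.null(x)) character() else x

# ---------------------------------------------------------------------------
# Penalized cubic-regression-spline fit for NECB / GHG balance vs WT.

#' Fit a penalized spline water-table response for an annual balance
#'
#' Penalized least squares on a cubic regression spline basis in mean annual
#' WT (k knots at WT quantiles, basis and curvature penalty from
#' `mgcv::smoothCon`), plus genus and management fixed effects and
#' ridge-penalized site offsets. The smoothing parameter is chosen by
#' generalized cross-validation `GCV = n RSS / (n - edf)^2` over a log-spaced
#' grid, jointly with a coarse grid for the shared site ridge.
#'
#' @param data data.frame with the response column, `wt_mean`, `plant_genus`,
#'   `management_intensity`, `site_id`.
#' @param response `"necb"` or `"ghg_ar5"` / `"ghg_ar4"` (any numeric column).
#' @param config a [flux_config()]; `config$spline` holds `k`, `lambda_grid`
#'   and `site_ridge`.
#' @param lambda optional fixed smoothing parameter (skips GCV); `lambda = 0`
#'   with `include_site = FALSE` reproduces ordinary least squares on the
#'   spline basis.
#' @param include_site include ridge-penalized site offsets (default TRUE).
#' @return list of class `wt_spline`: coefficients, `edf` (total),
#'   `edf_spline`, `lambda`, `site_ridge`, `gcv`, `r2_adj`, plus the basis
#'   object for prediction.
#' @export
fit_balance_spline <- function(data, response = "necb",
                               config = flux_config(), lambda = NULL,
                               include_site = TRUE) {
  y <- data[[response]]
  if (is.null(y)) stop("response column not found: ", response)
  if (nrow(data) < 30) stop("spline fit needs >= 30 rows")
  if (diff(range(data$wt_mean)) < 0.2) stop("spline fit needs >= 0.2 m WT span")
  k <- config$spline$k
  g <- droplevels(fac(data$plant_genus, GENERA))
  m <- droplevels(fac(data$management_intensity, INTENSITIES))
  fdf <- data.frame(g = g, m = m)
  fixed_form <- if (nlevels(m) > 1) ~ g + m else ~ g
  Xf <- stats::model.matrix(fixed_form, fdf)
  sm <- mgcv::smoothCon(mgcv::s(wt, bs = "cr", k = k),
                        data = data.frame(wt = data$wt_mean),
                        absorb.cons = TRUE)[[1]]
  Xs <- sm$X
  S <- sm$S[[1]]
  Z <- if (include_site) site_design(data$site_id) else
    matrix(0, nrow(data), 0)
  X <- cbind(Xf, Xs, Z)
  idx_f <- seq_len(ncol(Xf))
  idx_s <- ncol(Xf) + seq_len(ncol(Xs))
  idx_z <- ncol(Xf) + ncol(Xs) + seq_len(ncol(Z))
  n <- length(y)

  solve_pls <- function(lam, lam_z) {
    P <- matrix(0, ncol(X), ncol(X))
    P[idx_s, idx_s] <- lam * S
    if (length(idx_z)) P[idx_z, idx_z] <- diag(lam_z, length(idx_z))
    A <- crossprod(X) + P
    cb <- try(chol(A), silent = TRUE)
    if (inherits(cb, "try-error")) return(NULL)  # rank deficient at this lambda
    beta <- backsolve(cb, forwardsolve(t(cb), crossprod(X, y)))
    H <- chol2inv(cb) %*% crossprod(X)
    fitted <- drop(X %*% beta)
    edf <- sum(diag(H))
    rss <- sum((y - fitted)^2)
    list(beta = drop(beta), fitted = fitted, edf = edf,
         edf_spline = sum(diag(H)[idx_s]),
         gcv = n * rss / (n - edf)^2, rss = rss)
  }

  lam_z_grid <- if (length(idx_z)) config$spline$site_ridge else 0
  if (is.null(lambda)) {
    best <- NULL
    # with interpolating fits (RSS at machine zero, e.g. noiseless data) GCV
    # is pure round-off; such ties break toward the smoother fit
    tol0 <- 1e-10 * n * stats::var(y)
    for (lz in lam_z_grid) for (lam in sort(config$spline$lambda_grid)) {
      s <- solve_pls(lam, lz)
      if (is.null(s)) next
      take <- if (is.null(best)) TRUE
      else if (s$rss < tol0 && best$rss < tol0) s$edf < best$edf - 1e-8
      else s$gcv < best$gcv * (1 + 1e-7)
      if (take) { best <- s; best$lambda <- lam; best$site_ridge <- lz }
    }
    if (is.null(best)) stop("spline fit failed: rank-deficient design")
  } else {
    lz <- if (length(idx_z)) config$spline$site_ridge[1] else 0
    best <- solve_pls(lambda, lz)
    if (is.null(best)) stop("spline fit failed: rank-deficient design")
    best$lambda <- lambda; best$site_ridge <- lz
  }

  r2_adj <- 1 - (best$rss / (n - best$edf)) / stats::var(y)
  structure(list(coef = best$beta, sm = sm, fixed_form = fixed_form,
                 genus_levels = levels(g), mgmt_levels = levels(m),
                 idx_f = idx_f, idx_s = idx_s, idx_z = idx_z,
                 lambda = best$lambda, site_ridge = best$site_ridge,
                 edf = best$edf, edf_spline = best$edf_spline,
                 gcv = best$gcv, r2_adj = r2_adj, fitted = best$fitted,
                 response = response, y = y,
                 wt_range = range(data$wt_mean), data = data),
            class = "wt_spline")
}

#' Predict from a fitted balance spline
#'
#' Site offsets are zero; genus/management default to the reference levels
#' (Carex, one_cut) unless supplied in `newdata`.
#'
#' @param object a `wt_spline`.
#' @param newdata data.frame with `wt_mean` and optionally `plant_genus`,
#'   `management_intensity`.
#' @param ... unused.
#' @export
predict.wt_spline <- function(object, newdata, ...) {
  ng <- if (!is.null(newdata$plant_genus)) newdata$plant_genus else
    object$genus_levels[1]
  nm <- if (!is.null(newdata$management_intensity)) newdata$management_intensity
  else object$mgmt_levels[1]
  fdf <- data.frame(g = fac(ng, object$genus_levels),
                    m = fac(nm, object$mgmt_levels))
  Xf <- stats::model.matrix(object$fixed_form, fdf)
  Xs <- mgcv::PredictMat(object$sm, data.frame(wt = newdata$wt_mean))
  eta_f <- drop(Xf %*% object$coef[object$idx_f])
  eta_s <- drop(Xs %*% object$coef[object$idx_s])
  eta_f + eta_s
}

#' Water-table optimum of a fitted balance spline
#'
#' The WT minimizing the predicted balance over a dense grid within the
#' observed range, at reference covariate levels (genus Carex, one_cut
#' management, site offset zero). A minimum on the range boundary is
#' flagged. The bootstrap interval refits on resampled rows with the
#' smoothing parameter held at its fitted value.
#'
#' @param fit a `wt_spline` (typically for the GHG balance).
#' @param genus,management covariate levels for the prediction.
#' @param n_grid grid resolution.
#' @param n_boot bootstrap resamples (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @param config a [flux_config()].
#' @return list of class `wt_optimum`: `wt_opt` (m), `value`, `boundary`,
#'   `ci` (2.5/97.5 percentiles or NULL).
#' @export
find_optimum <- function(fit, genus = "Carex", management = "one_cut",
                         n_grid = 500, n_boot = 100, seed = 1L,
                         config = flux_config()) {
  grid <- seq(fit$wt_range[1], fit$wt_range[2], length.out = n_grid)
  pred <- predict(fit, data.frame(wt_mean = grid, plant_genus = genus,
                                  management_intensity = management))
  i <- which.min(pred)
  boundary <- i == 1 || i == n_grid
  ci <- NULL
  if (n_boot > 0) {
    opts <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(fit$data), replace = TRUE)
      bf <- try(fit_balance_spline(fit$data[idx, ], fit$response, config,
                                   lambda = fit$lambda,
                                   include_site = length(fit$idx_z) > 0),
                silent = TRUE)
      if (inherits(bf, "try-error")) return(NA_real_)
      p <- predict(bf, data.frame(wt_mean = grid, plant_genus = genus,
                                  management_intensity = management))
      grid[which.min(p)]
    }, numeric(1)))
    ci <- stats::quantile(opts, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  structure(list(wt_opt = grid[i], value = pred[i], boundary = boundary,
                 ci = ci), class = "wt_optimum")
}

#' Carbon-sink water-table threshold of a fitted NECB spline
#'
#' The driest (most negative) WT at which the predicted NECB crosses into
#' sink territory (<= 0), found by grid scan from the wet end and refined by
#' bisection. Per-genus (or per-management) thresholds come from
#' genus-specific predictions. No crossing in the observed range — all
#' source or all sink — yields an undefined threshold with a flag.
#'
#' @param fit a `wt_spline` fitted to NECB.
#' @param genus,management covariate levels.
#' @param n_grid grid resolution.
#' @return list of class `wt_threshold`: `wt_zero` (m or NA), `defined`,
#'   `all_sink`, `all_source`.
#' @export
find_threshold <- function(fit, genus = "Carex", management = "one_cut",
                           n_grid = 500) {
  grid <- seq(fit$wt_range[1], fit$wt_range[2], length.out = n_grid)
  f <- function(w) predict(fit, data.frame(wt_mean = w, plant_genus = genus,
                                           management_intensity = management))
  pred <- f(grid)
  if (all(pred <= 0)) {
    return(structure(list(wt_zero = NA_real_, defined = FALSE,
                          all_sink = TRUE, all_source = FALSE),
                     class = "wt_threshold"))
  }
  if (all(pred > 0)) {
    return(structure(list(wt_zero = NA_real_, defined = FALSE,
                          all_sink = FALSE, all_source = TRUE),
                     class = "wt_threshold"))
  }
  # scan from the wet end down to the last wt still in sink territory
  sink <- pred <= 0
  j <- length(grid)
  while (j >= 1 && sink[j]) j <- j - 1
  if (j == length(grid)) {
    # wet end itself is a source: no sink region bordering the wet end
    return(structure(list(wt_zero = NA_real_, defined = FALSE,
                          all_sink = FALSE, all_source = FALSE),
                     class = "wt_threshold"))
  }
  root <- stats::uniroot(f, lower = grid[j], upper = grid[j + 1],
                         tol = 1e-6)$root
  structure(list(wt_zero = root, defined = TRUE, all_sink = FALSE,
                 all_source = FALSE), class = "wt_threshold")
}
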