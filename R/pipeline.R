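# Pipeline stages tying the modules together. Each stage reads/writes plain
# CSV so the steps can be run separately (or through the thin command-line
# dispatcher in inst/cli/fenflux.R: simulate, fluxes, co2model, budget, ef,
# wtresponse, report).

#' Assemble annual budgets for every replicate of a dataset
#'
#' Runs the flux, campaign-fit, reconstruction, trace-gas integration and
#' budget stages over a site dataset. CO2 campaign models are fitted per
#' treatment (pooled replicates, the manual-chamber design) or per replicate
#' (high-frequency automated design); trace gases are always integrated per
#' replicate.
#'
#' @param ds a `site_dataset`.
#' @param config a [flux_config()].
#' @param scope `"replicate"` or `"treatment"` for the CO2 campaign fits.
#' @param n_boot bootstrap draws for CO2 uncertainty (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @param log optional run log.
#' @return list with `fluxes`, `fits`, `budgets` (annual-budget table).
#' @export
process_site <- function(ds, config = flux_config(), scope = "replicate",
                         n_boot = 0, seed = 1L, log = NULL) {
  fluxes <- compute_fluxes(ds$closures, config, log)
  fits <- fit_campaigns(fluxes, ds$meta, scope, log)
  period <- range(ds$met$timestamp)
  params_all <- campaign_params(fits)
  acc <- accepted_fluxes(fluxes)

  rows <- list()
  for (i in seq_len(nrow(ds$meta))) {
    mr <- ds$meta[i, ]
    scope_id <- if (scope == "treatment") mr$treatment_id else mr$replicate_id
    params <- params_all[params_all$scope_id == scope_id, ]
    if (nrow(params) == 0) {
      log_stage(log, "budget_skip", replicate = mr$replicate_id)
      next
    }
    co2 <- reconstruct_annual(params, ds$met, period, config)
    unc <- if (n_boot > 0) {
      sub <- fits[vapply(fits, function(f) f$scope_id == scope_id, logical(1))]
      uncertainty_annual(sub, ds$met, period, n_boot = n_boot,
                         seed = seed + i, config = config)
    } else NULL
    ch4f <- acc[acc$gas == "CH4" & acc$replicate_id == mr$replicate_id, ]
    n2of <- acc[acc$gas == "N2O" & acc$replicate_id == mr$replicate_id, ]
    ch4 <- integrate_trace_gas(ch4f$start, ch4f$flux, period,
                               normalize = config$period_normalize)
    n2o <- integrate_trace_gas(n2of$start, n2of$flux, period,
                               normalize = config$period_normalize)
    ev <- ds$events[ds$events$treatment_id == mr$treatment_id, , drop = FALSE]
    wt <- ds$wt[ds$wt$treatment_id == mr$treatment_id, ]
    rows[[length(rows) + 1]] <- assemble_budget(mr, co2, ch4, n2o, ev, wt, unc)
  }
  budgets <- do.call(rbind, rows)
  log_stage(log, "process_site", n_budgets = nrow(budgets))
  list(fluxes = fluxes, fits = fits, budgets = budgets)
}

#' @rdname pipeline_stages
#' @param outdir,indir stage directories.
#' @param seed master seed for the generator.
#' @param config a [flux_config()].
#' @export
run_simulate <- function(outdir, config = flux_config(), seed = 1L) {
  site <- generate_site(config, seed)
  write_site_dataset(site$dataset, outdir)
  tr <- site$truth
  jsonlite::write_json(list(seed = tr$seed, year = tr$year,
                            treatments = tr$treatments, noise = tr$noise,
                            true_annual = tr$true_annual),
                       file.path(outdir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(outdir)
}

#' Pipeline stages
#'
#' Thin stage wrappers used by the command-line dispatcher. Each reads the
#' input directory, runs the corresponding module and writes its output CSV.
#'
#' @name pipeline_stages
#' @param scope CO2 campaign-fit scope.
#' @param log optional run log.
#' @return the output directory, invisibly.
#' @export
run_fluxes <- function(indir, outdir = indir, config = flux_config(),
                       log = NULL) {
  ds <- read_site_dataset(indir, config, log)
  fluxes <- compute_fluxes(ds$closures, config, log)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- fluxes
  out$start <- format(out$start, TS_FMT)
  utils::write.csv(out, file.path(outdir, "fluxes.csv"), row.names = FALSE)
  invisible(outdir)
}

#' @rdname pipeline_stages
#' @export
run_co2model <- function(indir, outdir = indir, config = flux_config(),
                         scope = "replicate", log = NULL) {
  ds <- read_site_dataset(indir, config, log)
  fluxes <- compute_fluxes(ds$closures, config, log)
  fits <- fit_campaigns(fluxes, ds$meta, scope, log)
  params <- campaign_params(fits)
  params$date <- format(params$date, TS_FMT)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(params, file.path(outdir, "campaign_params.csv"),
                   row.names = FALSE)
  invisible(outdir)
}

#' @rdname pipeline_stages
#' @param n_boot CO2 bootstrap draws.
#' @param seed bootstrap seed.
#' @export
run_budget <- function(indir, outdir = indir, config = flux_config(),
                       scope = "replicate", n_boot = 0, seed = 1L,
                       log = NULL) {
  ds <- read_site_dataset(indir, config, log)
  res <- process_site(ds, config, scope, n_boot, seed, log)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$budgets, file.path(outdir, "annual_budgets.csv"),
                   row.names = FALSE)
  invisible(outdir)
}

#' @rdname pipeline_stages
#' @export
run_ef <- function(indir, outdir = indir, config = flux_config(), log = NULL) {
  budgets <- utils::read.csv(file.path(indir, "annual_budgets.csv"))
  ef <- ef_table(budgets, log)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ef, file.path(outdir, "ef_table.csv"), row.names = FALSE)
  invisible(outdir)
}

#' @rdname pipeline_stages
#' @export
run_wtresponse <- function(indir, outdir = indir, config = flux_config(),
                           log = NULL) {
  budgets <- utils::read.csv(file.path(indir, "annual_budgets.csv"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  grid <- seq(min(budgets$wt_mean), max(budgets$wt_mean), length.out = 100)
  out <- data.frame(wt = grid)
  report <- list()
  if (nrow(budgets) >= 30 && diff(range(budgets$wt_mean)) >= 0.2) {
    for (resp in c("necb", "ghg_ar5")) {
      fit <- fit_balance_spline(budgets, resp, config)
      out[[paste0(resp, "_pred")]] <-
        predict(fit, data.frame(wt_mean = grid))
      report[[paste0(resp, "_edf")]] <- fit$edf_spline
    }
    ghg_fit <- fit_balance_spline(budgets, "ghg_ar5", config)
    opt <- find_optimum(ghg_fit, n_boot = 0, config = config)
    necb_fit <- fit_balance_spline(budgets, "necb", config)
    thr <- find_threshold(necb_fit)
    report$wt_optimum <- opt$wt_opt
    report$wt_optimum_boundary <- opt$boundary
    report$necb_threshold <- thr$wt_zero
  } else {
    warning("too few balances or too little WT span for spline fits")
  }
  if (nrow(budgets) >= 20) {
    ch4 <- fit_ch4_model(budgets, config)
    n2o <- fit_n2o_model(budgets)
    report$ch4_wt_slope <- unname(ch4$fit$coef[["wt"]])
    report$n2o_wt_coef <- unname(n2o$fit$coef[["wt"]])
  }
  utils::write.csv(out, file.path(outdir, "wt_response.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(outdir, "wt_response_report.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(outdir)
}

#' @rdname pipeline_stages
#' @export
run_report <- function(indir, outdir = indir, log = NULL) {
  budgets <- utils::read.csv(file.path(indir, "annual_budgets.csv"))
  ef_path <- file.path(indir, "ef_table.csv")
  lines <- c(
    "fenflux pipeline report",
    sprintf("balances: %d (NEE %.1f to %.1f t CO2 ha-1 yr-1)",
            nrow(budgets), min(budgets$nee), max(budgets$nee)),
    sprintf("NECB %.2f to %.2f t C ha-1 yr-1; GHG (AR5) %.1f to %.1f t CO2e",
            min(budgets$necb), max(budgets$necb),
            min(budgets$ghg_ar5), max(budgets$ghg_ar5)))
  if (file.exists(ef_path)) {
    ef <- utils::read.csv(ef_path)
    lines <- c(lines, apply(ef, 1, function(r) {
      sprintf("EF %s (n=%s): GHG AR5 %.1f t CO2e ha-1 yr-1",
              r[["wt_class"]], r[["n"]], as.numeric(r[["ghg_ar5"]]))
    }))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(outdir)
}
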