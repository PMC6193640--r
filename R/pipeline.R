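# End-to-end orchestration: simulate -> fit-spatial -> fit-trend ->
# forecast -> media, with a single config document, per-stage outputs,
# and a hashed manifest.

#' Default pipeline configuration ("paper-regime" preset)
#'
#' Returns the full configuration document driving [run_pipeline()]:
#' either simulation from the default truth or user-supplied input paths,
#' stage toggles, seeds, MCMC settings, bin width and forecast horizons.
#' Override any element via `...` (nested lists are merged).
#'
#' @param ... overrides, e.g. `seed = 7`, `mcmc = list(n_iter = 4000)`.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    preset = "paper-regime",
    inputs = NULL,  # or list(incidents=, states=, adjacency=, media=)
    stages = list(simulate = TRUE, fit_spatial = TRUE, fit_trend = TRUE,
                  forecast = TRUE, media = TRUE),
    seed = 20180522L,
    mcmc = list(n_chains = 2L, n_iter = 8000L, thin = 4L),
    bin_width_years = 2L,
    forecast_horizons = c(1, 2, 3, 6, 9, 12),
    forecast_rates = NULL,  # NULL: use interarrival MLE + trend prediction
    outdir = "massincidence-run",
    force = FALSE)
  override <- list(...)
  cfg <- modifyList(cfg, override)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a `run_config` (defaults filled in for absent fields).
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!isTRUE(cfg$stages$simulate) && is.null(cfg$inputs) &&
      (isTRUE(cfg$stages$fit_spatial) || isTRUE(cfg$stages$fit_trend) ||
       isTRUE(cfg$stages$media))) {
    stop("fitting stages need either the simulate stage or input paths")
  }
  if (!is.null(cfg$inputs)) {
    need <- c("incidents", "states", "adjacency", "media")
    missing <- setdiff(need, names(cfg$inputs))
    if (length(missing)) {
      stop("inputs lack: ", paste(missing, collapse = ", "))
    }
  }
  invisible(cfg)
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing every output
#' under `config$outdir` and returning a manifest with an md5 hash per
#' file. Logging (versions, seed, per-stage wall time) goes to standard
#' error; results only ever go to files. A failed stage aborts downstream
#' stages, writes the partial manifest, and re-raises the error.
#'
#' @param config a `run_config` (see [pipeline_config()]), or a path to a
#'   YAML/JSON config document.
#' @return invisibly, the manifest (also written to `manifest.json`):
#'   file names, md5 hashes, seed, and per-stage timings.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[massincidence] ", sprintf(...))
  log_msg("run: seed %d, outdir %s, package %s", config$seed, outdir,
          as.character(utils::packageVersion("massincidence")))
  files <- character(0)
  timings <- list()
  stage <- function(name, enabled, fn) {
    if (!isTRUE(enabled)) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- fn()
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    log_msg("stage %s done in %.2fs", name, timings[[name]])
    res
  }
  out_path <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p) && !isTRUE(config$force)) {
      stop("output exists (use force = TRUE): ", p)
    }
    files <<- c(files, p)
    p
  }

  incidents <- panel <- intervals <- NULL
  on.exit({
    manifest <- list(
      preset = config$preset, seed = config$seed,
      files = if (length(files))
        data.frame(file = basename(files),
                   md5 = unname(tools::md5sum(files)),
                   row.names = NULL) else list(),
      timings = timings,
      complete = FALSE)
    mp <- file.path(outdir, "manifest.json")
    write_atomic(function(p) jsonlite::write_json(
      manifest, p, auto_unbox = TRUE, digits = NA, dataframe = "rows"), mp)
  })

  # --- inputs: simulate or read -------------------------------------------
  stage("simulate", config$stages$simulate, function() {
    truth <- sim_truth(seed = config$seed)
    study <- simulate_study(truth)
    for (f in c("incidents.csv", "states.csv", "adjacency.txt",
                "media.csv", "truth.json")) out_path(f)
    write_study(study, outdir)
    incidents <<- study$incidents
    panel <<- study$panel
    intervals <<- study$intervals
  })
  if (is.null(incidents) && !is.null(config$inputs)) {
    incidents <- read_incidents(config$inputs$incidents)
    panel <- read_state_panel(config$inputs$states,
                              config$inputs$adjacency,
                              incidents = incidents)
    media <- read_media(config$inputs$media)
    intervals <- build_intervals(incidents, media$article_count,
                                 media$search_interest)
  }

  # --- spatial ZIP-CAR fit -------------------------------------------------
  stage("fit_spatial", config$stages$fit_spatial, function() {
    m <- config$mcmc
    fit <- fit_zip_car_mcmc(panel, n_chains = m$n_chains,
                            n_iter = m$n_iter, thin = m$thin,
                            seed = config$seed)
    summ <- summarize_posterior(fit)
    names(summ) <- c("Parameter", "Mean", "SD", "2.5%", "Median", "97.5%")
    write_atomic(function(p) write.csv(summ, p, row.names = FALSE),
                 out_path("spatial_summary.csv"))
    diag <- list(dic = fit$dic, accept = as.list(fit$accept),
                 max_rhat = max(fit$rhat), converged = fit$converged,
                 kendall_permissiveness = kendall_permissiveness(panel),
                 settings = fit$settings)
    write_atomic(function(p) jsonlite::write_json(
      diag, p, auto_unbox = TRUE, digits = NA),
      out_path("spatial_diagnostics.json"))
    if (!fit$converged) stop("spatial MCMC did not converge")
  })

  # --- trend fit ------------------------------------------------------------
  trend <- stage("fit_trend", config$stages$fit_trend, function() {
    binned <- bin_counts(incidents, config$bin_width_years)
    fit <- fit_trend(binned)
    annual <- fit_trend(bin_counts(incidents, 1L))
    cmp <- if (config$bin_width_years == 2L) compare_aic(annual, fit)
           else compare_aic(fit, annual)
    res <- list(coefficients = as.list(fit$coefficients),
                aic = fit$aic,
                pearson_dispersion = fit$pearson_dispersion,
                slope_p_value = fit$slope_p_value,
                aic_comparison = cmp,
                interarrival = interarrival_mle(incidents))
    write_atomic(function(p) jsonlite::write_json(
      res, p, auto_unbox = TRUE, digits = NA), out_path("trend.json"))
    fit
  })

  # --- forecast --------------------------------------------------------------
  stage("forecast", config$stages$forecast, function() {
    rates <- config$forecast_rates
    if (is.null(rates)) {
      if (is.null(trend)) stop("forecast needs rates or the trend stage")
      binned <- bin_counts(incidents, config$bin_width_years)
      off <- max(binned$year_offset) + config$bin_width_years + 1
      rates <- c(constant = interarrival_mle(incidents)$rate_monthly,
                 regression = predict_monthly_rate(trend, off))
    }
    if (is.null(names(rates))) names(rates) <- paste0("rate", seq_along(rates))
    tabs <- lapply(rates, risk_table, horizons = config$forecast_horizons)
    out <- data.frame(months = config$forecast_horizons)
    for (nm in names(tabs)) {
      out[[sprintf("p_%s_%.3f", nm, attr(tabs[[nm]], "monthly_rate"))]] <-
        tabs[[nm]]$probability_3dp
    }
    write_atomic(function(p) write.csv(out, p, row.names = FALSE),
                 out_path("forecast.csv"))
  })

  # --- media contagion -------------------------------------------------------
  stage("media", config$stages$media, function() {
    fit <- media_analysis(intervals)
    sp <- as.data.frame(fit$spearman$rho)
    sp <- cbind(variable = rownames(fit$spearman$rho), sp)
    write_atomic(function(p) write.csv(sp, p, row.names = FALSE),
                 out_path("spearman.csv"))
    write_atomic(function(p) jsonlite::write_json(
      fit$ridge[c("coefficients_std", "coefficients", "intercept",
                  "penalty", "edf", "p_value")],
      p, auto_unbox = TRUE, digits = NA), out_path("ridge.json"))
    write_atomic(function(p) jsonlite::write_json(
      list(coefficients = as.list(fit$poisson$coefficients),
           p_value = as.list(fit$poisson$p_value),
           dispersion = fit$poisson$dispersion,
           floored = fit$poisson$floored),
      p, auto_unbox = TRUE, digits = NA), out_path("poisson.json"))
    sens <- sensitivity_remove(intervals, character(0))
    write_atomic(function(p) jsonlite::write_json(
      list(comparison = sens$comparison, n_removed = sens$n_removed),
      p, auto_unbox = TRUE, digits = NA, dataframe = "rows"),
      out_path("sensitivity.json"))
  })

  on.exit()  # replace the partial-manifest handler with the final write
  manifest <- list(
    preset = config$preset, seed = config$seed,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       row.names = NULL),
    timings = timings,
    complete = TRUE)
  write_atomic(function(p) jsonlite::write_json(
    manifest, p, auto_unbox = TRUE, digits = NA, dataframe = "rows"),
    file.path(outdir, "manifest.json"))
  log_msg("pipeline complete: %d output file(s)", length(files))
  invisible(manifest)
}
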