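#' Validate a pipeline configuration
#'
#' @param config list (or YAML file path) with elements:
#'   \code{stages} (character subset of "simulate", "fit_qens", "infer",
#'   "growth"), \code{out_dir}, \code{seed}, \code{map} (power-law preset
#'   or exponent), \code{growth_mode}, plus stage-specific blocks
#'   (\code{simulate}: truth parameters; \code{fit}: arguments of
#'   [fit_config()]; \code{spectra_dir} when simulate is off).
#' @return the validated config (invisibly errors listing all violations).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  problems <- character(0)
  if (is.null(config$out_dir)) problems <- c(problems, "out_dir is missing")
  stages <- config$stages %||% c("simulate", "fit_qens", "infer", "growth")
  bad <- setdiff(stages, c("simulate", "fit_qens", "infer", "growth"))
  if (length(bad)) problems <- c(problems, paste("unknown stages:",
                                                 paste(bad, collapse = ", ")))
  if (!("simulate" %in% stages)) {
    if (is.null(config$spectra_dir))
      problems <- c(problems, "spectra_dir required when simulate is off")
    else if (!dir.exists(config$spectra_dir) ||
             length(list.files(config$spectra_dir, pattern = "\\.csv$")) == 0)
      problems <- c(problems,
                    paste("spectra_dir has no spectrum files:",
                          config$spectra_dir))
  }
  if (length(problems))
    stop("validation error:\n  - ", paste(problems, collapse = "\n  - "))
  config$stages <- stages
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

#' Run the full inference pipeline
#'
#' Orchestrates spectra -> dynamics series -> stability curve -> growth
#' fit with plain-file handoff (CSV/JSON) between stages and a manifest
#' carrying parameters and output checksums, so a run is reproducible
#' from its config plus seed and any stage can be rerun in isolation.
#' A failing stage halts downstream stages; the partial report is still
#' written.
#'
#' @param config see [validate_pipeline_config()].
#' @return the run report (list), invisibly; written as
#'   \code{report.json} in \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config[setdiff(names(config), "out_dir")],
                 stages = list(), outputs = character(0))
  seed <- config$seed
  ok <- TRUE

  sim <- config$simulate %||% list()
  truth_curve <- gen_stability_curve(
    midpoint = sim$midpoint %||% 330, steepness = sim$steepness %||% 0.25,
    plateau = sim$plateau %||% 1.0,
    T_grid = seq(sim$T_min %||% 280, sim$T_max %||% 362,
                 length.out = sim$n_temperatures %||% 24),
    map = power_law_map(config$map %||% "a99SB-disp"))
  resolution <- resolution_model(fwhm = sim$resolution_fwhm %||% 0.75)

  spectra <- NULL
  if ("simulate" %in% config$stages && ok) {
    res <- try({
      spec_dir <- file.path(out_dir, "spectra")
      dir.create(spec_dir, showWarnings = FALSE)
      tsm <- two_state_model(sim$c_f %||% 7.9, sim$m_f %||% -0.02,
                             sim$c_u %||% 3.7, sim$m_u %||% -0.01)
      spectra <- lapply(seq_len(nrow(truth_curve)), function(i) {
        Ti <- truth_curve$T[i]
        e <- endmember_D(tsm, Ti)
        D_G <- (1 - truth_curve$a_u[i]) * e$D_f + truth_curve$a_u[i] * e$D_u
        sp <- gen_qens_spectrum(
          spectrum_params(intensity = 1, D_G = D_G, tau_G = 0.05,
                          D_L = sim$D_L %||% 30, tau_L = sim$tau_L %||% 180,
                          r_L = sim$r_L %||% 2, p_L = sim$p_L %||% 0.4),
          resolution, T = Ti, noise_rel = sim$noise_rel %||% 0.02,
          seed = seed + i)
        write_spectrum_csv(sp, file.path(spec_dir, sprintf("T%07.2fK.csv", Ti)))
        sp
      })
      spec_dir
    }, silent = TRUE)
    report <- record_stage(report, "simulate", res); ok <- report$ok
  } else if (!("simulate" %in% config$stages)) {
    files <- list.files(config$spectra_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    spectra <- lapply(files, read_spectrum_csv)
  }

  series <- NULL
  if ("fit_qens" %in% config$stages && ok) {
    res <- try({
      cfg <- do.call(fit_config, config$fit %||% list())
      series <- fit_temperature_series(spectra, resolution, cfg)
      f <- file.path(out_dir, "series.csv")
      write_series_csv(series, f)
      f
    }, silent = TRUE)
    report <- record_stage(report, "fit_qens", res); ok <- report$ok
  }

  curve <- NULL
  if ("infer" %in% config$stages && ok) {
    res <- try({
      map <- power_law_map(config$map %||% "a99SB-disp")
      ts_fit <- fit_two_state(series,
                              au_shape = config$au_shape %||% "power_logistic",
                              map = map)
      curve <- stability_curve(series, ts_fit$model, map)
      f <- file.path(out_dir, "stability.csv")
      utils::write.csv(as.data.frame(curve), f, row.names = FALSE)
      f
    }, silent = TRUE)
    report <- record_stage(report, "infer", res); ok <- report$ok
  }

  if ("growth" %in% config$stages && ok) {
    res <- try({
      mode <- config$growth_mode %||% "constant_g0"
      gcfg <- config$growth %||% list()
      # synthetic growth data come from the simulation truth, never from
      # the inferred curve, so the growth fit genuinely propagates the
      # stability-inference error instead of testing against itself
      gdata <- if (!is.null(gcfg$data_file)) utils::read.csv(gcfg$data_file)
        else gen_growth_data(
          growth_params(gcfg$g0 %||% 1e6, gcfg$deltaH %||% 45,
                        gcfg$Gamma %||% 86, mode),
          truth_curve,
          D_G_series = if (mode != "constant_g0") series else NULL,
          noise_rel = gcfg$noise_rel %||% 0.03,
          T_range = c(gcfg$T_min %||% (min(truth_curve$T) + 1),
                      gcfg$T_max %||% 326),
          seed = seed + 1000L)
      gfit <- fit_growth(gdata, curve %||% truth_curve,
                         D_G_series = if (mode != "constant_g0") series,
                         mode = mode, seed = seed)
      f <- file.path(out_dir, "growth_params.json")
      jsonlite::write_json(list(g0 = gfit$params$g0,
                                deltaH = gfit$params$deltaH,
                                Gamma = gfit$params$Gamma,
                                Gamma_rounded = gfit$Gamma_rounded,
                                mode = mode, redchi2 = gfit$redchi2),
                           f, auto_unbox = TRUE, digits = NA)
      f
    }, silent = TRUE)
    report <- record_stage(report, "growth", res); ok <- report$ok
  }

  outs <- unlist(lapply(report$stages, `[[`, "output"))
  outs <- outs[!is.na(outs) & file.exists(outs)]
  outs <- unlist(lapply(outs, function(p)
    if (dir.exists(p)) list.files(p, full.names = TRUE) else p))
  report$checksums <- as.list(tools::md5sum(outs))
  report$ok <- NULL
  report$completed <- ok
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

record_stage <- function(report, name, res) {
  if (inherits(res, "try-error")) {
    report$stages[[name]] <- list(status = "error",
                                  message = as.character(res),
                                  output = NA_character_)
    report$ok <- FALSE
  } else {
    report$stages[[name]] <- list(status = "ok", output = res)
    report$ok <- TRUE
  }
  report
}
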