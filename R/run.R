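#' Default run configuration
#'
#' Plain nested list describing a complete simulated experiment:
#' condition grid, staircase parameters, population (listener) model,
#' and experiment size. The `"paper"` preset is the study design: 3
#' carriers x 6 bandwidths, 9 listeners, 3 repetitions, bandwidth slope
#' -0.20 log10 units per ERB.
#'
#' @param preset `"paper"` (the default is identical; the name exists
#'   so configs are self-describing).
#' @return a named list, serializable to YAML.
#' @export
default_run_config <- function(preset = "paper") {
  stopifnot(preset == "paper")
  list(grid = list(center_freqs_hz = c(4000, 8000, 12000),
                   bandwidths_erb = seq(0.5, 3, by = 0.5)),
       staircase = list(initial_itd_us = 2500,
                        step_factor_initial = 2,
                        step_factor_final = sqrt(2),
                        switch_after_reversals = 2,
                        stop_reversals = 10,
                        threshold_reversals = 6,
                        itd_cap_us = 3000),
       population = list(intercept_log10us = log10(300) + 0.20,
                         slope_per_erb = -0.20,
                         listener_sd = 0.15,
                         track_sd = 0.08,
                         beta = 0.8,
                         lapse = 0.02),
       experiment = list(n_listeners = 9, reps = 3))
}

#' Write / read a run configuration as YAML
#'
#' Round-trip safe: `read_run_config(write_run_config(cfg, f))` returns
#' a configuration equal to `cfg`.
#'
#' @param config configuration list (see [default_run_config()]).
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (blk in c("grid", "staircase", "population", "experiment"))
    if (is.null(cfg[[blk]])) stop("config is missing block: ", blk)
  cfg
}

config_objects <- function(config) {
  p <- config$population
  list(grid = condition_grid(config$grid$center_freqs_hz,
                             config$grid$bandwidths_erb),
       staircase = do.call(staircase_config, config$staircase),
       population = population_model(
         intercept_log10us = p$intercept_log10us,
         slope_per_erb = p$slope_per_erb,
         listener_sd = p$listener_sd,
         track_sd = p$track_sd,
         beta = p$beta, lapse = p$lapse))
}

#' Run the complete simulated experiment and analysis
#'
#' Chains the whole pipeline: sample listeners from the population
#' model, run all adaptive staircases, aggregate the threshold table,
#' fit the bandwidth slopes (ERB and log-ERB predictors), run the
#' repeated-measures ANOVA and the post hoc comparisons, and write
#' everything to tidy CSVs plus a JSON manifest recording seed, config
#' hash and package version. Byte-identical outputs for identical
#' (config, seed).
#'
#' @param config configuration list (default [default_run_config()]).
#' @param seed master integer seed.
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return invisibly, a list with all in-memory results (`staircases`,
#'   `thresholds`, `fits`, `anova`, `posthoc`, `manifest`).
#' @export
run_all <- function(config = default_run_config(), seed, out_dir,
                    force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory is not empty; use force = TRUE to overwrite")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- config_objects(config)
  raw <- run_experiment(obj$population,
                        n_listeners = config$experiment$n_listeners,
                        config = obj$staircase, grid = obj$grid,
                        reps = config$experiment$reps, seed = seed)
  tab <- aggregate_thresholds(raw)
  f_erb <- fit_slope(tab, "erb")
  f_log <- fit_slope(tab, "log_erb")
  fits <- tibble::tibble(
    predictor = c(f_erb$predictor, f_log$predictor),
    slope = c(f_erb$slope, f_log$slope),
    ci95_lo = c(f_erb$ci95_lo, f_log$ci95_lo),
    ci95_hi = c(f_erb$ci95_hi, f_log$ci95_hi),
    r_squared = c(f_erb$r_squared, f_log$r_squared))
  aov_res <- rm_anova(tab)
  ph <- posthoc_bandwidth(tab)

  utils::write.csv(raw, file.path(out_dir, "staircases.csv"),
                   row.names = FALSE)
  utils::write.csv(tab, file.path(out_dir, "thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(fits, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(aov_res, file.path(out_dir, "anova.csv"),
                   row.names = FALSE)
  utils::write.csv(ph, file.path(out_dir, "posthoc.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   n_staircases = nrow(raw),
                   package_version =
                     as.character(utils::packageVersion("itdsim")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(staircases = raw, thresholds = tab, fits = fits,
                 anova = aov_res, posthoc = ph, manifest = manifest))
}

#' Synthesize one condition's stimulus and write it as WAV
#'
#' File is named `cf<Hz>_bw<ERB>_itd<us>.wav` in the output directory.
#'
#' @param spec a [pulse_train_spec].
#' @param out_dir output directory (created if needed).
#' @return the file path, invisibly.
#' @export
write_stimulus_wav <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- make_pulse_train(spec)
  path <- file.path(out_dir,
                    sprintf("cf%d_bw%g_itd%g.wav",
                            as.integer(spec$center_freq_hz),
                            spec$bandwidth_erb, spec$itd_us))
  write_wav(w, path)
  invisible(path)
}
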