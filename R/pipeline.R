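#' Run a configured analysis pipeline
#'
#' Executes a sequence of named stages (simulate, analyze, kinetics,
#' binding, enrichment, distfit, flowcalc) against a shared output
#' directory and writes a manifest recording the package version, seed,
#' per-stage parameters, output files and their checksums, so any run can
#' be reproduced bit-identically from the manifest alone.
#'
#' The configuration is a list (or a YAML file path) with a `stages`
#' element; each stage is a list with `name`, `type` and type-specific
#' parameters:
#'
#' * `simulate`: `total_conc_um`, `dilute_conc_um`, `droplet_count`, plus
#'   optional [simulation_config()] fields.  Writes the trace and its
#'   ground truth.  Requires the pipeline seed.
#' * `analyze`: `trace_file` or `from_stage` (a simulate stage name),
#'   `calibration` (list with `concentrations_um`, `baselines_fu`),
#'   `expected_total_conc_um`, optional `threshold_fu`, `median_window`.
#' * `kinetics`: `trace_file` or `from_stage`, optional ALS parameters.
#' * `binding`: `titration_file` (CSV with `analyte_um, rh_nm`),
#'   `stoichiometry_n`.
#' * `enrichment`: `trace_a_file`/`trace_b_file` or `from_stage_a`/`_b`,
#'   with per-trace baseline levels.
#' * `distfit`: `from_stage` (an analyze stage), `brightness_cv`, `mode`.
#' * `flowcalc`: optional [capillary_system()] fields.
#'
#' @param config A list or path to a YAML file.
#' @param seed Integer seed; mandatory whenever any stage is stochastic.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of per-stage results; the manifest is written
#'   to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = tempfile("capflow_run_")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0) {
    abort("Pipeline config must contain a non-empty `stages` list.",
          class = "capflowr_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  valid <- c("simulate", "analyze", "kinetics", "binding", "enrichment",
             "distfit", "flowcalc")
  results <- list()
  manifest <- list(package = "capflowr",
                   version = as.character(utils::packageVersion("capflowr")),
                   seed = seed, stages = list())
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    name <- st$name %||% sprintf("stage%02d", k)
    type <- st$type
    if (is.null(type) || !type %in% valid) {
      abort(sprintf("Unknown pipeline stage type `%s`; valid: %s.",
                    type %||% "<missing>", paste(valid, collapse = ", ")),
            class = "capflowr_config_error")
    }
    res <- switch(type,
      simulate = stage_simulate(st, seed, k, out_dir, name),
      analyze = stage_analyze(st, results),
      kinetics = stage_kinetics(st, results),
      binding = stage_binding(st),
      enrichment = stage_enrichment(st, results),
      distfit = stage_distfit(st, results),
      flowcalc = stage_flowcalc(st)
    )
    out_file <- file.path(out_dir, paste0(name, ".json"))
    write_results(res$report, out_file)
    results[[name]] <- res
    manifest$stages[[name]] <- list(
      type = type,
      params = st[setdiff(names(st), c("name", "type"))],
      output = basename(out_file),
      md5 = unname(tools::md5sum(out_file))
    )
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE,
                              null = "null"), manifest_path)
  invisible(results)
}

stage_simulate <- function(st, seed, k, out_dir, name) {
  if (is.null(seed)) {
    abort("Stage `simulate` is stochastic: an explicit pipeline seed is required.",
          class = "capflowr_config_error")
  }
  gt <- synthetic_ground_truth(
    total_conc_um = st$total_conc_um,
    dilute_conc_um = st$dilute_conc_um,
    droplet_count = st$droplet_count %||% 0,
    volume_meanlog = st$volume_meanlog %||% 0,
    volume_sdlog = st$volume_sdlog %||% 0.5,
    seed = (seed + 1009L * k) %% .Machine$integer.max
  )
  cfg_args <- st[intersect(names(st),
                           c("noise_sd_fu", "saturation_ceiling_fu",
                             "sampling_rate_hz", "duration_s", "fu_per_um",
                             "intercept_fu", "brightness_fu_per_vol",
                             "radial_pdf_mode", "front_mode", "plug_flow"))]
  cfg <- do.call(simulation_config, c(list(ground_truth = gt), cfg_args))
  sim <- simulate_trace(cfg)
  trace_path <- file.path(out_dir, paste0(name, "_trace.csv"))
  write_trace(sim$trace, trace_path)
  list(sim = sim, config = cfg,
       report = list(
         stage = "simulate", trace_file = basename(trace_path),
         ground_truth = unclass(gt)[c("total_conc_um", "dilute_conc_um",
                                      "droplet_count", "seed")],
         baseline_fu = sim$baseline_fu,
         n_events = nrow(sim$events)))
}

resolve_trace <- function(st, results, file_key = "trace_file",
                          stage_key = "from_stage") {
  if (!is.null(st[[stage_key]])) {
    res <- results[[st[[stage_key]]]]
    if (is.null(res) || is.null(res$sim)) {
      abort(sprintf("Stage `%s` not found or is not a simulate stage.",
                    st[[stage_key]]),
            class = "capflowr_config_error")
    }
    res$sim$trace
  } else if (!is.null(st[[file_key]])) {
    read_trace(st[[file_key]], channel = st$channel %||% "alexa488")
  } else {
    abort(sprintf("Stage needs `%s` or `%s`.", file_key, stage_key),
          class = "capflowr_config_error")
  }
}

stage_analyze <- function(st, results) {
  trace <- resolve_trace(st, results)
  cal <- fit_standard_curve(st$calibration$concentrations_um,
                            st$calibration$baselines_fu)
  bl <- extract_baseline(trace, cal, st$expected_total_conc_um,
                         median_window = st$median_window %||% 31,
                         quantile_p = st$quantile_p %||% 0.05)
  pk <- detect_peaks(trace, bl, threshold_fu = st$threshold_fu %||% 0.2,
                     saturation_ceiling_fu = st$saturation_ceiling_fu %||% 50)
  list(baseline = bl, peaks = pk,
       report = list(stage = "analyze",
                     baseline_fu = bl$baseline_fu,
                     dilute_conc_um = bl$dilute_conc_um,
                     n_peaks = nrow(pk)))
}

stage_kinetics <- function(st, results) {
  trace <- resolve_trace(st, results)
  bl <- als_baseline(trace,
                     asymmetry_p = st$asymmetry_p %||% 0.001,
                     smoothness_log10 = st$smoothness_log10 %||% 4,
                     iterations = st$iterations %||% 20)
  pk <- detect_kinetic_peaks(trace, bl, rel_threshold = st$rel_threshold %||% 0.01)
  onset <- onset_and_rate(pk, window = st$window %||% 10,
                          fit_start_s = st$fit_start_s %||% 0,
                          fit_end_s = st$fit_end_s %||% 120)
  list(baseline = bl, peaks = pk, onset = onset,
       report = list(stage = "kinetics", lag_time_s = onset$lag_time_s,
                     rate_fu_per_min = onset$rate_fu_per_min,
                     n_peaks = onset$n_peaks))
}

stage_binding <- function(st) {
  tit <- readr::read_csv(st$titration_file, show_col_types = FALSE,
                         progress = FALSE)
  fit <- fit_binding(tit, stoichiometry_n = st$stoichiometry_n,
                     fix_unbound = st$fix_unbound)
  list(fit = fit,
       report = list(stage = "binding",
                     stoichiometry_n = fit$model$stoichiometry_n,
                     kd_um = fit$model$kd_um, kd_se_um = fit$kd_se_um,
                     rh_unbound_nm = fit$model$rh_unbound_nm,
                     rh_bound_nm = fit$model$rh_bound_nm, rss = fit$rss))
}

stage_enrichment <- function(st, results) {
  tr_a <- resolve_trace(st, results, "trace_a_file", "from_stage_a")
  tr_b <- resolve_trace(st, results, "trace_b_file", "from_stage_b")
  base_a <- st$baseline_a %||% results[[st$from_stage_a]]$sim$baseline_fu
  base_b <- st$baseline_b %||% results[[st$from_stage_b]]$sim$baseline_fu
  enr <- relative_enrichment(tr_a, tr_b, base_a, base_b,
                             rel_threshold = st$rel_threshold %||% 0.005)
  list(enrichment = enr,
       report = c(list(stage = "enrichment"), as.list(enr)))
}

stage_distfit <- function(st, results) {
  peaks <- results[[st$from_stage]]$peaks
  if (is.null(peaks)) {
    abort(sprintf("Stage `%s` has no peak table.", st$from_stage),
          class = "capflowr_config_error")
  }
  stats <- intensity_stats(peaks)
  list(stats = stats,
       report = c(list(stage = "distfit"), as.list(stats)))
}

stage_flowcalc <- function(st) {
  sys_args <- st[intersect(names(st),
                           c("length_m", "inner_diameter_m", "turn_radius_m",
                             "pressure_mbar", "viscosity_pa_s",
                             "density_kg_m3", "detection_window_m",
                             "temperature_k"))]
  sys <- do.call(capillary_system, sys_args)
  fs <- flow_summary(sys, mode = st$mode %||% "physical")
  list(flow = fs, report = c(list(stage = "flowcalc"), as.list(fs)))
}
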