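#' Experiment configuration
#'
#' Bundles everything needed for a full in-silico repeatability study:
#' the profiles, per-cohort sample count and variability, thermal and
#' grid settings, rendering, and the statistical comparison parameters.
#'
#' @param profiles A named list of [ablation_profile()] objects; defaults
#'   to the ten bundled study profiles.
#' @param n Samples per profile cohort (default 6).
#' @param seed Master seed.
#' @param params A [thermal_params()].
#' @param grid A [simulation_grid()].
#' @param render A [render_params()].
#' @param efficiency_range,diffusivity_jitter,threshold_jitter Cohort
#'   variability, see [cohort_spec()].
#' @param margin,alpha Noninferiority margin (mm) and significance level.
#' @param output_dir Optional directory for CSV/JSON/PNG outputs.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(profiles = study_profiles(), n = 6, seed = 1L,
                              params = thermal_params(),
                              grid = simulation_grid(),
                              render = render_params(),
                              efficiency_range = c(0.85, 0.90),
                              diffusivity_jitter = 0.03, threshold_jitter = 2,
                              margin = 1.0, alpha = 0.05,
                              output_dir = NULL) {
  if (length(profiles) == 0)
    stop_ablashape("no profiles supplied", "validation_error")
  for (p in profiles) check_profile(p)
  structure(list(profiles = profiles, n = as.integer(n), seed = as.integer(seed),
                 params = params, grid = grid, render = render,
                 efficiency_range = efficiency_range,
                 diffusivity_jitter = diffusivity_jitter,
                 threshold_jitter = threshold_jitter,
                 margin = margin, alpha = alpha, output_dir = output_dir),
            class = "experiment_config")
}

#' Run the full in-silico repeatability study
#'
#' For every profile: discretize, simulate a seeded cohort with
#' inter-sample variability, render cross-section images, segment them
#' with the colour-based approach (the ground-truth masks are never used
#' downstream), measure widths at the 5 mm points plus head/tail lengths,
#' and compute per-point repeatability.  Then compare configurable versus
#' standard repeatability with the Mann-Whitney noninferiority test and
#' regress repeatability on probe speed.  Deterministic for a fixed seed.
#'
#' @param config An [experiment_config()].
#' @param progress Print per-profile progress to stderr.
#' @return An object of class `study_report`: `widths` (per sample and
#'   point), `samples` (per-sample head/tail/volume/sphericity),
#'   `repeatability` (per point), `summaries` (per-point median/IQR),
#'   `noninferiority`, `regression`, `config_seed`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  if (!inherits(config, "experiment_config"))
    stop_ablashape("expected an `experiment_config`", "validation_error")
  priors <- color_model(config$render$fg_hsv, config$render$bg_hsv)
  widths <- list(); samples <- list(); repeats <- list(); summaries <- list()
  for (k in seq_along(config$profiles)) {
    prof <- config$profiles[[k]]
    if (progress) message(sprintf("[%d/%d] %s", k, length(config$profiles), prof$name))
    spec <- cohort_spec(prof, config$n,
                        efficiency_range = config$efficiency_range,
                        diffusivity_jitter = config$diffusivity_jitter,
                        threshold_jitter = config$threshold_jitter,
                        render = config$render,
                        seed = derive_seed(config$seed, k, 0L),
                        params = config$params, grid = config$grid)
    cohort <- generate_cohort(spec)
    measured <- lapply(cohort, function(img) {
      m <- segment_image(img, priors)
      measure_sample(m, img$meta, sample_id = img$sample_id,
                     shape_label = prof$shape_label)
    })
    widths[[k]] <- do.call(rbind, lapply(measured, function(s)
      data.frame(sample_id = s$sample_id, profile = prof$name,
                 shape_label = prof$shape_label,
                 z_mm = s$points$z_mm, width_mm = s$points$width_mm)))
    samples[[k]] <- do.call(rbind, lapply(measured, function(s)
      data.frame(sample_id = s$sample_id, profile = prof$name,
                 shape_label = prof$shape_label,
                 head_mm = s$head, tail_mm = s$tail,
                 volume_mm3 = s$volume, sphericity = s$sphericity)))
    repeats[[k]] <- cohort_repeatability(measured, prof)
    summ <- summarize_cohort(measured)
    summ$profile <- prof$name
    summaries[[k]] <- summ
  }
  widths <- do.call(rbind, widths)
  samples <- do.call(rbind, samples)
  repeats <- do.call(rbind, repeats)
  summaries <- do.call(rbind, summaries)
  conf_vals <- repeats$repeatability_mm[repeats$group == "configurable"]
  std_vals <- repeats$repeatability_mm[repeats$group == "standard"]
  noninf <- if (length(conf_vals) && length(std_vals))
    mann_whitney_noninferiority(conf_vals, std_vals,
                                margin = config$margin, alpha = config$alpha)
  else NULL
  reg <- if (length(unique(repeats$speed_mm_s)) >= 2)
    speed_regression(repeats$repeatability_mm, repeats$speed_mm_s)
  else NULL
  report <- structure(list(widths = widths, samples = samples,
                           repeatability = repeats, summaries = summaries,
                           noninferiority = noninf, regression = reg,
                           config_seed = config$seed),
                      class = "study_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d profiles, %d samples, %d repeatability points\n",
              length(unique(x$widths$profile)),
              length(unique(x$samples$sample_id)),
              nrow(x$repeatability)))
  med <- tapply(x$repeatability$repeatability_mm, x$repeatability$group, median)
  for (g in names(med)) cat(sprintf("  median repeatability (%s): %.2f mm\n", g, med[[g]]))
  if (!is.null(x$noninferiority)) print(x$noninferiority)
  invisible(x)
}

#' Write a study report to disk
#'
#' CSV tables (`widths.csv`, `samples.csv`, `repeatability.csv`,
#' `summaries.csv`) and a JSON report (`report.json`) with the
#' noninferiority and regression results.  Re-running with the same
#' config and seed overwrites identically.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$widths, file.path(dir, "widths.csv"), row.names = FALSE)
  write.csv(report$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  write.csv(report$repeatability, file.path(dir, "repeatability.csv"),
            row.names = FALSE)
  write.csv(report$summaries, file.path(dir, "summaries.csv"), row.names = FALSE)
  ni <- report$noninferiority
  reg <- report$regression
  jsonlite::write_json(list(
    seed = report$config_seed,
    noninferiority = if (!is.null(ni)) ni[c("p_value", "delta", "ci_upper",
                                            "margin", "alpha", "n_conf", "n_std")],
    regression = if (!is.null(reg)) reg[c("slope", "ci", "r_squared", "p_value")],
    median_repeatability_mm = as.list(tapply(report$repeatability$repeatability_mm,
                                             report$repeatability$group, median))),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Synthetic generator power log
#'
#' The physical workflow captures the generator's output power every 30 s.
#' This reproduces such a log for a schedule: the planned power sampled at
#' the capture interval, scaled by the generator output factor.
#'
#' @param schedule A `probe_schedule`.
#' @param profile The matching [ablation_profile()].
#' @param capture_interval Sampling interval in seconds (default 30).
#' @param efficiency Generator output factor applied to the planned power.
#' @return A data frame with columns `time_s`, `power_w`.
#' @export
power_log <- function(schedule, profile, capture_interval = 30, efficiency = 1) {
  if (!inherits(schedule, "probe_schedule"))
    stop_ablashape("expected a `probe_schedule`", "validation_error")
  total <- schedule$total_time
  times <- if (total <= 0) 0 else seq(0, total, by = capture_interval)
  if (total > 0 && times[length(times)] < total - 1e-9)
    times <- c(times, total)
  data.frame(time_s = times,
             power_w = profile_power(profile, times) * efficiency)
}
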