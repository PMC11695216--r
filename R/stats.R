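#' Repeatability at one measurement point
#'
#' The study's repeatability metric: the median of the absolute pairwise
#' differences in width across replicate samples at a measurement point.
#' This is an Sn-type robust scale statistic (pairwise-difference based):
#' translation invariant, scale equivariant, resistant to outliers and
#' valid for asymmetric distributions.
#'
#' @param widths Numeric vector of widths (mm) across samples (>= 2).
#' @return Repeatability in mm (>= 0).
#' @examples
#' repeatability_at_point(c(1, 2, 4))  # pairwise diffs 1, 3, 2 -> 2
#' @export
repeatability_at_point <- function(widths) {
  if (!is.numeric(widths) || length(widths) < 2)
    stop_ablashape("need at least 2 widths", "validation_error")
  d <- abs(outer(widths, widths, "-"))
  median(d[upper.tri(d)])
}

#' Mann-Whitney noninferiority test of repeatability
#'
#' One-sided test of H0: the configurable group's repeatability exceeds
#' the standard group's by at least the margin, against H1: it does not
#' (noninferiority).  Implemented as the standard location-shift
#' construction: a Mann-Whitney U test of `conf - margin` vs `std` with
#' alternative "less".  The effect `delta` is the Hodges-Lehmann estimate
#' of the median difference `conf - std`, and `ci_upper` the one-sided
#' upper confidence bound obtained by test inversion.  The exact U
#' distribution is used when both groups have at most 12 observations and
#' no ties are present; otherwise the normal approximation with tie
#' correction.
#'
#' @param conf Repeatability values (mm) of the configurable group.
#' @param std Repeatability values (mm) of the standard group.
#' @param margin Noninferiority margin in mm (default 1.0).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `noninferiority_result`: `p_value`, `delta`,
#'   `ci_upper`, `margin`, `alpha`, `n_conf`, `n_std`, `statistic`.
#' @export
mann_whitney_noninferiority <- function(conf, std, margin = 1.0, alpha = 0.05) {
  if (length(conf) == 0 || length(std) == 0)
    stop_ablashape("both groups must be nonempty", "validation_error")
  if (margin < 0) stop_ablashape("`margin` must be >= 0", "validation_error")
  use_exact <- length(conf) <= 12 && length(std) <= 12 &&
    !any(duplicated(c(conf - margin, std)))
  test <- suppressWarnings(
    wilcox.test(conf - margin, std, alternative = "less", exact = use_exact,
                correct = TRUE))
  diffs <- as.vector(outer(conf, std, "-"))
  delta <- median(diffs)                    # Hodges-Lehmann estimate
  ci_upper <- if (max(diffs) - min(diffs) < .Machine$double.eps^0.5) {
    delta                                   # degenerate: all differences equal
  } else {
    est <- suppressWarnings(
      wilcox.test(conf, std, alternative = "less", conf.int = TRUE,
                  conf.level = 1 - alpha, exact = use_exact))
    unname(est$conf.int[2])
  }
  structure(list(p_value = unname(test$p.value),
                 delta = delta,
                 ci_upper = ci_upper,
                 margin = margin, alpha = alpha,
                 n_conf = length(conf), n_std = length(std),
                 statistic = unname(test$statistic)),
            class = "noninferiority_result")
}

#' @export
print.noninferiority_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney noninferiority (margin %.2f mm, alpha %.2f)\n",
              x$margin, x$alpha))
  cat(sprintf("  n = %d (configurable) vs %d (standard)\n", x$n_conf, x$n_std))
  cat(sprintf("  p = %.3g, delta = %.2f mm, one-sided %d%% CI <= %.2f mm\n",
              x$p_value, x$delta, round(100 * (1 - x$alpha)), x$ci_upper))
  cat(if (x$p_value < x$alpha) "  -> noninferior\n" else "  -> not shown noninferior\n")
  invisible(x)
}

#' Simulation-based noninferiority sample-size search
#'
#' Reproduces the study's power analysis: ablation widths are assumed
#' normal in both groups with the pooled standard deviations measured in
#' pilot data; datapoints are generated with a common arbitrary mean, the
#' standard group holding `ratio` times the configurable group's size, and
#' the Mann-Whitney noninferiority test applied.  The search returns the
#' smallest `(n_std, n_conf)` whose Monte-Carlo rejection probability
#' reaches `power_target`.  Common random numbers across candidate sizes
#' make the estimated power non-decreasing in `n_conf` for a fixed seed.
#'
#' @param sd_std Width standard deviation of the standard group (mm);
#'   pilot value 0.5.
#' @param sd_conf Width standard deviation of the configurable group
#'   (mm); feasibility-study value 1.1.
#' @param margin Noninferiority margin in mm (default 1.0).
#' @param ratio Standard : configurable generation ratio (default 0.5).
#' @param alpha Significance level.
#' @param power_target Required rejection probability; default
#'   `1 - 1/reps`, the Monte-Carlo surrogate for "always significant".
#' @param reps Monte-Carlo replicates per candidate size (>= 100).
#' @param seed Integer seed.
#' @param n_start,n_step,n_max Search grid over the configurable group
#'   size.
#' @return A list `n_std`, `n_conf`, `power`, `reps`.
#' @export
sample_size_search <- function(sd_std = 0.5, sd_conf = 1.1, margin = 1.0,
                               ratio = 0.5, alpha = 0.05,
                               power_target = NULL, reps = 500, seed = 1L,
                               n_start = 4L, n_step = 2L, n_max = 200L) {
  if (sd_std <= 0 || sd_conf <= 0)
    stop_ablashape("standard deviations must be positive", "validation_error")
  if (ratio <= 0 || ratio > 1)
    stop_ablashape("`ratio` must be in (0, 1]", "validation_error")
  if (reps < 100) stop_ablashape("`reps` must be >= 100", "validation_error")
  power_target <- power_target %||% (1 - 1 / reps)
  set.seed(as.integer(seed))
  n_conf_max <- n_max
  n_std_max <- max(2L, ceiling(ratio * n_conf_max))
  conf_draws <- matrix(rnorm(n_conf_max * reps, 0, sd_conf), n_conf_max, reps)
  std_draws <- matrix(rnorm(n_std_max * reps, 0, sd_std), n_std_max, reps)
  estimate_power <- function(n_conf, n_std) {
    rej <- vapply(seq_len(reps), function(r) {
      p <- suppressWarnings(
        wilcox.test(conf_draws[seq_len(n_conf), r] - margin,
                    std_draws[seq_len(n_std), r],
                    alternative = "less", exact = FALSE))$p.value
      p < alpha
    }, logical(1))
    mean(rej)
  }
  for (n_conf in seq(n_start, n_max, by = n_step)) {
    n_std <- max(2L, round(ratio * n_conf))
    pw <- estimate_power(n_conf, n_std)
    if (pw >= power_target)
      return(list(n_std = n_std, n_conf = n_conf, power = pw, reps = reps))
  }
  stop_ablashape("power target not reached within the search bounds",
                 "search_limit_error")
}

#' Regression of repeatability on probe speed
#'
#' Ordinary least squares of the per-point repeatability values on the
#' commanded probe speed at each point, with a two-sided 95 % confidence
#' interval for the slope and the coefficient of determination.
#'
#' @param values Repeatability values in mm.
#' @param speeds Probe speeds in mm/s (same length, not all equal).
#' @return A list `slope`, `ci` (length 2), `r_squared`, `p_value`,
#'   `intercept`, `fit` (the `lm` object).
#' @export
speed_regression <- function(values, speeds) {
  if (length(values) != length(speeds) || length(values) < 3)
    stop_ablashape("need >= 3 paired observations", "validation_error")
  if (length(unique(speeds)) < 2)
    stop_ablashape("speeds are constant: degenerate design", "degenerate_design_error")
  fit <- lm(values ~ speeds)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       ci = unname(confint(fit, "speeds", level = 0.95)[1, ]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       intercept = unname(coef(fit)[1]),
       fit = fit)
}

#' Per-point repeatability of a measured cohort
#'
#' @param samples A list of `width_profile_sample` objects for one shape
#'   cohort (same measurement grid).
#' @param profile The cohort's [ablation_profile()] (for speeds and
#'   grouping).
#' @return A data frame with one row per measurement point: `profile`,
#'   `shape_label`, `group`, `z_mm`, `speed_mm_s`, `repeatability_mm`,
#'   `n`.
#' @export
cohort_repeatability <- function(samples, profile) {
  zs <- samples[[1]]$points$z_mm
  w <- vapply(samples, function(s) s$points$width_mm, numeric(length(zs)))
  w <- matrix(w, nrow = length(zs))
  data.frame(profile = profile$name,
             shape_label = profile$shape_label,
             group = if (profile$shape_label == "OVAL") "standard" else "configurable",
             z_mm = zs,
             speed_mm_s = speed_at_point(profile, zs),
             repeatability_mm = apply(w, 1, repeatability_at_point),
             n = length(samples))
}
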