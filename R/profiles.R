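#' Ablation interval
#'
#' One interval of an ablation profile: the generator runs at `power` watts
#' for `duration` seconds while the probe is retracted by `distance`
#' millimetres along its axis.  A `distance` of zero is a static (dwell)
#' interval.
#'
#' @param power Generator power setting in watts (> 0).
#' @param duration Interval duration in seconds (> 0).
#' @param distance Axial retraction during the interval in mm (>= 0).
#' @return An object of class `ablation_interval`.
#' @examples
#' ablation_interval(60, 600, 50)
#' @export
ablation_interval <- function(power, duration, distance) {
  if (!is.numeric(power) || length(power) != 1L || !is.finite(power) || power <= 0)
    stop_ablashape("`power` must be a single positive number (watts)", "validation_error")
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) || duration <= 0)
    stop_ablashape("`duration` must be a single positive number (seconds)", "validation_error")
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance) || distance < 0)
    stop_ablashape("`distance` must be a single non-negative number (mm)", "validation_error")
  structure(list(power = power, duration = duration, distance = distance),
            class = "ablation_interval")
}

#' Ablation profile
#'
#' A named treatment program: an ordered series of (power, duration,
#' distance) intervals executed while the probe is withdrawn along its
#' trajectory.  The shape label records the target ablation geometry.
#'
#' @param name Profile name, e.g. `"HOUR-60W-600s"`.
#' @param shape_label One of `"OVAL"`, `"LONG"`, `"HOUR"`, `"TEAR"`, `"PEAR"`.
#' @param intervals A list of [ablation_interval()] objects (at least one).
#' @return An object of class `ablation_profile`.
#' @export
ablation_profile <- function(name, shape_label, intervals) {
  labels <- c("OVAL", "LONG", "HOUR", "TEAR", "PEAR")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_ablashape("`name` must be a non-empty string", "validation_error")
  if (!shape_label %in% labels)
    stop_ablashape(sprintf("`shape_label` must be one of %s",
                           paste(labels, collapse = ", ")), "validation_error")
  if (!is.list(intervals) || length(intervals) == 0L)
    stop_ablashape("`intervals` must be a non-empty list", "validation_error")
  if (inherits(intervals, "ablation_interval")) intervals <- list(intervals)
  ok <- vapply(intervals, inherits, logical(1), "ablation_interval")
  if (!all(ok))
    stop_ablashape("every element of `intervals` must be an ablation_interval",
                   "validation_error")
  structure(list(name = name, shape_label = shape_label, intervals = intervals),
            class = "ablation_profile")
}

#' @export
print.ablation_profile <- function(x, ...) {
  cat(sprintf("<ablation_profile> %s [%s]\n", x$name, x$shape_label))
  for (iv in x$intervals)
    cat(sprintf("  %g W  %g s  %g mm\n", iv$power, iv$duration, iv$distance))
  cat(sprintf("  total: %g s, %g mm, %.3f kJ\n",
              total_duration(x), total_distance(x), total_energy(x)))
  invisible(x)
}

#' Total duration and retraction distance of a profile
#'
#' @param profile An [ablation_profile()].
#' @return Duration in seconds / distance in mm.
#' @export
total_duration <- function(profile) {
  check_profile(profile)
  sum(vapply(profile$intervals, `[[`, numeric(1), "duration"))
}

#' @rdname total_duration
#' @export
total_distance <- function(profile) {
  check_profile(profile)
  sum(vapply(profile$intervals, `[[`, numeric(1), "distance"))
}

check_profile <- function(profile) {
  if (!inherits(profile, "ablation_profile"))
    stop_ablashape("expected an `ablation_profile`", "validation_error")
  if (length(profile$intervals) == 0L)
    stop_ablashape("profile has no intervals", "validation_error")
  invisible(profile)
}

#' Delivered energy of an ablation profile
#'
#' Sums power times duration over all intervals and converts joules to
#' kilojoules.  This is the planned (setting) energy; generator efficiency
#' is applied downstream by the thermal simulator.
#'
#' @param profile An [ablation_profile()].
#' @return Energy in kilojoules.
#' @examples
#' p <- ablation_profile("OVAL-60W-120s", "OVAL", list(ablation_interval(60, 120, 0)))
#' total_energy(p)  # 7.2
#' @export
total_energy <- function(profile) {
  check_profile(profile)
  sum(vapply(profile$intervals,
             function(iv) iv$power * iv$duration, numeric(1))) / 1000
}

#' Commanded probe speed of an interval
#'
#' @param interval An [ablation_interval()].
#' @return Speed in mm/s; 0 for a static interval.
#' @export
interval_speed <- function(interval) {
  if (!inherits(interval, "ablation_interval"))
    stop_ablashape("expected an `ablation_interval`", "validation_error")
  if (interval$duration <= 0)
    stop_ablashape("interval duration must be positive", "validation_error")
  interval$distance / interval$duration
}

#' Discretize an ablation profile into an executable probe schedule
#'
#' Robot platforms typically cannot track continuous linear speeds below
#' about 1 mm/s.  Moving intervals whose commanded speed falls below
#' `speed_threshold` are therefore discretized into alternating short
#' retraction steps (`step` mm in `move_time` s) and waiting periods, such
#' that the mean speed of every segment equals the commanded speed.  Static
#' intervals become a single dwell and intervals at or above the threshold
#' a single constant-speed move.  Total time and total distance are
#' conserved exactly.
#'
#' When the remaining distance of an interval is not a multiple of `step`,
#' a shorter final step is emitted with the move and dwell times scaled
#' proportionally.  Within each segment the probe moves first and then
#' dwells.
#'
#' @param profile An [ablation_profile()].
#' @param step Retraction step in mm for discretized intervals.
#' @param move_time Duration in seconds of each retraction step.
#' @param speed_threshold Speed in mm/s below which discretization applies.
#' @return An object of class `probe_schedule`: piecewise-linear waypoints
#'   `(time, position)` with position measured in mm of retraction from the
#'   trajectory start (the deepest probe position).
#' @export
discretize <- function(profile, step = 2, move_time = 2, speed_threshold = 1) {
  check_profile(profile)
  if (!is.numeric(step) || step <= 0)
    stop_ablashape("`step` must be positive", "validation_error")
  if (!is.numeric(move_time) || move_time <= 0)
    stop_ablashape("`move_time` must be positive", "validation_error")
  t <- 0; p <- 0
  times <- 0; poss <- 0
  add <- function(tt, pp) { times[length(times) + 1L] <<- tt; poss[length(poss) + 1L] <<- pp }
  for (iv in profile$intervals) {
    v <- iv$distance / iv$duration
    if (iv$distance == 0) {
      add(t + iv$duration, p)                       # dwell
    } else if (v >= speed_threshold) {
      add(t + iv$duration, p + iv$distance)         # continuous move
    } else {
      # alternating move/dwell segments with exact mean-speed conservation
      remaining <- iv$distance
      t0 <- t; p0 <- p
      while (remaining > 1e-12) {
        d <- min(step, remaining)
        frac <- d / step
        seg_time <- d / v
        mt <- min(move_time * frac, seg_time)
        add(t0 + mt, p0 + d)
        if (seg_time - mt > 1e-12) add(t0 + seg_time, p0 + d)
        t0 <- t0 + seg_time; p0 <- p0 + d
        remaining <- remaining - d
      }
      # pin the interval endpoint to remove floating-point drift
      times[length(times)] <- t + iv$duration
      poss[length(poss)] <- p + iv$distance
    }
    t <- t + iv$duration
    p <- p + iv$distance
  }
  # drop duplicated consecutive times (merged dwells)
  keep <- c(TRUE, diff(times) > 1e-12)
  structure(list(time = times[keep], position = poss[keep],
                 step = step, move_time = move_time,
                 speed_threshold = speed_threshold,
                 total_time = t, total_distance = p),
            class = "probe_schedule")
}

#' @export
print.probe_schedule <- function(x, ...) {
  cat(sprintf("<probe_schedule> %d waypoints, %g s, %g mm\n",
              length(x$time), x$total_time, x$total_distance))
  invisible(x)
}

#' Axial probe position at a given time
#'
#' Linear interpolation between schedule waypoints.  Position is mm of
#' retraction from the trajectory start.
#'
#' @param schedule A `probe_schedule` from [discretize()].
#' @param t Time(s) in seconds, within `[0, total_time]`.
#' @return Axial position(s) in mm, non-decreasing in `t`.
#' @export
probe_position <- function(schedule, t) {
  if (!inherits(schedule, "probe_schedule"))
    stop_ablashape("expected a `probe_schedule`", "validation_error")
  if (any(t < -1e-9 | t > schedule$total_time + 1e-9))
    stop_ablashape("`t` outside [0, total_time]", "range_error")
  approx(schedule$time, schedule$position, xout = pmin(pmax(t, 0), schedule$total_time),
         method = "linear", rule = 2)$y
}

#' Planned generator power at a given time
#'
#' Piecewise-constant power over the profile's intervals; right-continuous,
#' with the final instant taking the last interval's power.
#'
#' @param profile An [ablation_profile()].
#' @param t Time(s) in seconds.
#' @return Power in watts (0 outside `[0, total_duration]`).
#' @export
profile_power <- function(profile, t) {
  check_profile(profile)
  ends <- cumsum(vapply(profile$intervals, `[[`, numeric(1), "duration"))
  pw <- vapply(profile$intervals, `[[`, numeric(1), "power")
  vapply(t, function(ti) {
    if (ti < 0 || ti > ends[length(ends)]) return(0)
    idx <- which(ti < ends)
    if (length(idx) == 0L) idx <- length(ends)
    pw[idx[1L]]
  }, numeric(1))
}

#' Read and write ablation profile files
#'
#' Profiles are stored as YAML with keys `name`, `shape_label` and
#' `intervals`, each interval holding `power_w`, `duration_s`,
#' `distance_mm`.
#'
#' @param path File path.
#' @return [read_profile()] returns an [ablation_profile()];
#'   [write_profile()] returns `path` invisibly.
#' @export
read_profile <- function(path) {
  y <- yaml::read_yaml(path)
  ivs <- lapply(y$intervals, function(iv)
    ablation_interval(iv$power_w, iv$duration_s, iv$distance_mm))
  ablation_profile(y$name, y$shape_label, ivs)
}

#' @rdname read_profile
#' @param profile An [ablation_profile()].
#' @export
write_profile <- function(profile, path) {
  check_profile(profile)
  y <- list(name = profile$name, shape_label = profile$shape_label,
            intervals = lapply(profile$intervals, function(iv)
              list(power_w = iv$power, duration_s = iv$duration,
                   distance_mm = iv$distance)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The ten study ablation profiles
#'
#' Loads the bundled profile definitions: six standard single-position
#' profiles (OVAL, 60/100 W for 120/240/360 s) and four configurable
#' profiles (LONG, HOUR, TEAR, PEAR; 60 W, 600 s total).
#'
#' @return A named list of [ablation_profile()] objects.
#' @export
study_profiles <- function() {
  dir <- system.file("extdata", "profiles", package = "ablashape")
  files <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  profs <- lapply(files, read_profile)
  names(profs) <- vapply(profs, `[[`, character(1), "name")
  # stable study order: standard first, then configurable
  ord <- order(match(vapply(profs, `[[`, character(1), "shape_label"),
                     c("OVAL", "LONG", "HOUR", "TEAR", "PEAR")),
               names(profs))
  profs[ord]
}

#' Commanded probe speed at an axial position
#'
#' Returns the commanded speed of the profile interval active while the
#' probe (feed zone) passes position `z` along the trajectory.  Positions
#' shared by several intervals (dwell locations) take the minimum speed,
#' since the slowest interval dominates local heat delivery.
#'
#' @param profile An [ablation_profile()].
#' @param z Axial position(s) in mm from the trajectory start.
#' @return Speed(s) in mm/s.
#' @export
speed_at_point <- function(profile, z) {
  check_profile(profile)
  d <- vapply(profile$intervals, `[[`, numeric(1), "distance")
  dur <- vapply(profile$intervals, `[[`, numeric(1), "duration")
  ends <- cumsum(d)
  starts <- c(0, head(ends, -1))
  sp <- d / dur
  vapply(z, function(zi) {
    if (zi < -1e-9 || zi > ends[length(ends)] + 1e-9)
      stop_ablashape("`z` outside trajectory", "range_error")
    hit <- which(starts - 1e-9 <= zi & zi <= ends + 1e-9)
    min(sp[hit])
  }, numeric(1))
}
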