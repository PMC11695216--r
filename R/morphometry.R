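#' Axial measurement points along a trajectory
#'
#' Measurement points are placed every `step` mm from the trajectory start
#' (the deepest probe position), at multiples of `step` not exceeding the
#' trajectory length; the endpoint is included only when the length is
#' divisible by the step.  A zero-length trajectory (standard static
#' profile) has the single point 0.
#'
#' @param trajectory_length Trajectory length in mm (>= 0).
#' @param step Measurement step in mm (default 5).
#' @return Numeric vector of z positions in mm.
#' @examples
#' measurement_points(50)  # 0, 5, ..., 50
#' measurement_points(0)   # 0
#' @export
measurement_points <- function(trajectory_length, step = 5) {
  if (!is.numeric(trajectory_length) || trajectory_length < 0)
    stop_ablashape("`trajectory_length` must be non-negative", "validation_error")
  if (step <= 0) stop_ablashape("`step` must be positive", "validation_error")
  seq(0, by = step, length.out = floor(trajectory_length / step + 1e-9) + 1)
}

row_for_z <- function(meta, z) {
  row <- round(meta$start_row - z / meta$scale)
  as.integer(row)
}

axis_cols <- function(meta) {
  unique(c(floor(meta$axis_col), ceiling(meta$axis_col)))
}

# width (mm) of the foreground run crossing the probe axis in one mask row
row_width <- function(row_vals, cols, scale) {
  if (!any(row_vals)) return(0)
  r <- rle(row_vals)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    if (any(cols >= starts[k] & cols <= ends[k]))
      return(r$lengths[k] * scale)
  }
  0
}

#' Ablation width at an axial position
#'
#' Width of the foreground run that crosses the probe axis at trajectory
#' depth `z`, measured perpendicular to the axis.  Returns 0 when no
#' foreground touches the axis at that row.
#'
#' @param mask Logical cross-section raster (rows axial, columns lateral).
#' @param meta Image metadata (`scale`, `axis_col`, `start_row`), as
#'   produced by [mask_image()] or carried by a rendered image.
#' @param z Axial position in mm from the trajectory start.
#' @return Width in mm.
#' @export
width_at <- function(mask, meta, z) {
  row <- row_for_z(meta, z)
  if (row < 1L || row > nrow(mask))
    stop_ablashape("`z` maps outside the raster", "range_error")
  row_width(mask[row, ], axis_cols(meta), meta$scale)
}

#' Head and tail lengths beyond the planned trajectory
#'
#' Lengths are measured along the probe axis line (the long axis of the
#' cut): `tail` is how far the ablation extends beyond the trajectory
#' start (distal, below the initial source position) and `head` how far
#' beyond the trajectory end (proximal, above the final retracted
#' position).  Both are >= 0.
#'
#' @param mask Logical cross-section raster.
#' @param meta Image metadata.
#' @param trajectory_length Trajectory length in mm.
#' @return Named numeric vector `c(head = , tail = )` in mm.
#' @export
head_tail <- function(mask, meta, trajectory_length) {
  cols <- axis_cols(meta)
  on_axis <- rowSums(mask[, cols, drop = FALSE]) > 0
  if (!any(on_axis)) stop_ablashape("empty mask", "measurement_error")
  rows <- which(on_axis)
  zp <- (meta$start_row - rows) * meta$scale
  c(head = max(0, max(zp) - trajectory_length), tail = max(0, -min(zp)))
}

#' Per-row width profile of a cross-section mask
#'
#' Axis-crossing widths for every raster row, in trajectory coordinates.
#' This is the full-resolution profile used for revolved volume and
#' surface integration.
#'
#' @param mask Logical cross-section raster.
#' @param meta Image metadata.
#' @return A data frame with columns `z_mm` (decreasing row order) and
#'   `width_mm`.
#' @export
width_profile <- function(mask, meta) {
  cols <- axis_cols(meta)
  widths <- apply(mask, 1, row_width, cols = cols, scale = meta$scale)
  zp <- (meta$start_row - seq_len(nrow(mask))) * meta$scale
  keep <- widths > 0
  data.frame(z_mm = rev(zp[keep]), width_mm = rev(widths[keep]))
}

resample_profile <- function(profile_fn, ds = 0.5) {
  if (is.data.frame(profile_fn)) {
    z <- profile_fn$z_mm; w <- profile_fn$width_mm
    if (length(z) < 2) return(list(z = z, w = w))
    zz <- seq(min(z), max(z), by = ds)
    if (zz[length(zz)] < max(z)) zz <- c(zz, max(z))
    ww <- approx(z, w, xout = zz, rule = 2)$y
    list(z = zz, w = pmax(ww, 0))
  } else {
    stop_ablashape("supply a data.frame(z_mm, width_mm)", "validation_error")
  }
}

#' Volume of the revolved cross-section
#'
#' Disc integration `V = integral of pi (w(z)/2)^2 dz` over the full axial
#' support of the width profile (head + trajectory + tail), by the
#' trapezoid rule at <= `ds` mm sampling.
#'
#' @param profile A data frame with columns `z_mm`, `width_mm` (e.g. from
#'   [width_profile()]).
#' @param ds Sampling step in mm (default 0.5).
#' @return Volume in mm^3.
#' @export
revolve_volume <- function(profile, ds = 0.5) {
  if (is.data.frame(profile) && nrow(profile) == 0) return(0)
  s <- resample_profile(profile, ds)
  if (length(s$z) < 2) return(0)
  pracma::trapz(s$z, pi * (s$w / 2)^2)
}

#' Surface area of the revolved cross-section
#'
#' Lateral surface of the solid of revolution,
#' `A = integral of 2 pi rho sqrt(1 + rho'^2) dz` with `rho = w/2` and the
#' slope taken by central differences, plus end discs where the profile
#' does not close.
#'
#' @inheritParams revolve_volume
#' @return Surface area in mm^2.
#' @export
revolve_surface <- function(profile, ds = 0.5) {
  s <- resample_profile(profile, ds)
  n <- length(s$z)
  if (n < 2) return(0)
  rho <- s$w / 2
  drho <- pracma::gradient(rho, s$z)
  lat <- pracma::trapz(s$z, 2 * pi * rho * sqrt(1 + drho^2))
  lat + pi * rho[1]^2 + pi * rho[n]^2
}

#' Wadell sphericity of a solid
#'
#' `psi = pi^(1/3) (6 V)^(2/3) / A`: the ratio of the surface area of a
#' sphere of the same volume to the actual surface area.  1 for a sphere,
#' smaller for elongated solids.
#'
#' @param volume Volume in mm^3 (> 0).
#' @param surface Surface area in mm^2 (> 0).
#' @return Sphericity index in (0, 1].
#' @export
sphericity <- function(volume, surface) {
  if (!is.numeric(volume) || !is.numeric(surface) || volume <= 0 || surface <= 0)
    stop_ablashape("`volume` and `surface` must be positive", "validation_error")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface
}

#' Measure one cross-section sample
#'
#' Widths at the 5 mm measurement points, head/tail lengths, revolved
#' volume, surface and sphericity of a segmented (or ground-truth) mask.
#'
#' @param mask Logical cross-section raster.
#' @param meta Image metadata (must carry `trajectory_length`).
#' @param sample_id Optional identifier stored with the measurements.
#' @param shape_label Optional shape label.
#' @param step Measurement step in mm.
#' @return A list of class `width_profile_sample`: `points` (data frame
#'   `z_mm`, `width_mm`), `head`, `tail`, `volume`, `surface`,
#'   `sphericity`, `length_total`, `sample_id`, `shape_label`.
#' @export
measure_sample <- function(mask, meta, sample_id = NA_character_,
                           shape_label = NA_character_, step = 5) {
  L <- meta$trajectory_length %||% 0
  zs <- measurement_points(L, step)
  widths <- vapply(zs, function(z) width_at(mask, meta, z), numeric(1))
  ht <- head_tail(mask, meta, L)
  wp <- width_profile(mask, meta)
  vol <- revolve_volume(wp)
  surf <- revolve_surface(wp)
  structure(list(points = data.frame(z_mm = zs, width_mm = widths),
                 head = unname(ht["head"]), tail = unname(ht["tail"]),
                 volume = vol, surface = surf,
                 sphericity = if (vol > 0 && surf > 0) sphericity(vol, surf) else NA_real_,
                 length_total = L + sum(ht),
                 sample_id = sample_id, shape_label = shape_label),
            class = "width_profile_sample")
}

#' Per-point median and IQR across a cohort
#'
#' Aligns replicate samples by measurement point and summarizes the width
#' distribution at each point, as medians and interquartile ranges.
#'
#' @param samples A list of `width_profile_sample` objects (>= 2), all
#'   measured on the same z grid.
#' @return A data frame with columns `z_mm`, `median_mm`, `iqr_mm`, `n`.
#' @export
summarize_cohort <- function(samples) {
  if (length(samples) < 2)
    stop_ablashape("need at least 2 samples", "validation_error")
  zs <- lapply(samples, function(s) s$points$z_mm)
  if (!all(vapply(zs, function(z) isTRUE(all.equal(z, zs[[1]])), logical(1))))
    stop_ablashape("samples measured on different z grids", "alignment_error")
  w <- vapply(samples, function(s) s$points$width_mm, numeric(length(zs[[1]])))
  w <- matrix(w, nrow = length(zs[[1]]))
  data.frame(z_mm = zs[[1]],
             median_mm = apply(w, 1, median),
             iqr_mm = apply(w, 1, IQR),
             n = length(samples))
}
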