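#' Thermal parameters of the tissue-mimicking phantom and ablation probe
#'
#' Defaults describe a water-rich polyacrylamide gel tempered in a 37 degC
#' bath, with an irreversible thermochromic transition at 60 degC, and a
#' microwave probe whose emission (feed) zone sits 18 mm from the tip.
#' Generator output is modelled as a fraction `efficiency` of the planned
#' power; recorded device output typically runs at 85-90 % of the setting,
#' so the default is the midpoint 0.875.
#'
#' Only part of the generator output actually heats the gel: reflection
#' losses and heat carried away by the probe coolant dissipate the rest.
#' `absorbed_fraction` is that coupling factor; its default is calibrated
#' so the 60 W standard profiles produce ablation widths in the 20-30 mm
#' range.  Deposited power is `absorbed_fraction * efficiency * planned`.
#'
#' @param diffusivity Thermal diffusivity alpha in mm^2/s.  Default 0.143
#'   (water-like gel).
#' @param volumetric_heat_capacity rho*c in J/(mm^3 K).  Default 0.00418.
#' @param efficiency Generator output as a fraction of the planned power.
#' @param source_sigma Gaussian spread (mm) of the volumetric heat source.
#' @param feed_zone_offset Distance (mm) from probe tip to the source
#'   centre.  Default 18.
#' @param cooling_sink Probe-coolant line sink in W per mm of shaft above
#'   the feed zone (>= 0; 0 disables shaft cooling).  During simulation
#'   the extraction is capped so shaft cells never drop below
#'   `coolant_temp`.
#' @param coolant_temp Probe coolant temperature in degC (coolant is
#'   stored at 0-5 degC).
#' @param shaft_standoff Distance in mm above the source centre at which
#'   the cooled shaft begins (the emitting section itself is not cooled).
#' @param absorbed_fraction Fraction of generator output that couples into
#'   the medium as heat.
#' @param ambient_temp Bath / initial temperature in degC.
#' @param threshold_temp Irreversible coagulation threshold in degC.
#' @return An object of class `thermal_params`.
#' @export
thermal_params <- function(diffusivity = 0.143,
                           volumetric_heat_capacity = 0.00418,
                           efficiency = 0.875,
                           absorbed_fraction = 0.3,
                           source_sigma = 3,
                           feed_zone_offset = 18,
                           cooling_sink = 0.5,
                           coolant_temp = 5,
                           shaft_standoff = 2,
                           ambient_temp = 37,
                           threshold_temp = 60) {
  if (diffusivity <= 0) stop_ablashape("`diffusivity` must be > 0", "validation_error")
  if (volumetric_heat_capacity <= 0)
    stop_ablashape("`volumetric_heat_capacity` must be > 0", "validation_error")
  if (efficiency <= 0 || efficiency > 1)
    stop_ablashape("`efficiency` must be in (0, 1]", "validation_error")
  if (source_sigma <= 0) stop_ablashape("`source_sigma` must be > 0", "validation_error")
  if (cooling_sink < 0) stop_ablashape("`cooling_sink` must be >= 0", "validation_error")
  if (absorbed_fraction <= 0 || absorbed_fraction > 1)
    stop_ablashape("`absorbed_fraction` must be in (0, 1]", "validation_error")
  if (threshold_temp <= ambient_temp)
    stop_ablashape("`threshold_temp` must exceed `ambient_temp`", "validation_error")
  structure(list(diffusivity = diffusivity,
                 volumetric_heat_capacity = volumetric_heat_capacity,
                 efficiency = efficiency,
                 absorbed_fraction = absorbed_fraction,
                 source_sigma = source_sigma,
                 feed_zone_offset = feed_zone_offset,
                 cooling_sink = cooling_sink,
                 coolant_temp = coolant_temp,
                 shaft_standoff = shaft_standoff,
                 ambient_temp = ambient_temp,
                 threshold_temp = threshold_temp),
            class = "thermal_params")
}

#' Axisymmetric simulation grid
#'
#' Finite-volume grid in cylindrical (r, z) coordinates with cell centres
#' at `(i - 1/2) dr` and `(j - 1/2) dz`.  Extents default to the phantom
#' container (54 mm diameter, 90 mm height): radial 27 mm, axial 90 mm.
#' The outermost cell ring (r = radial extent and both axial ends) is held
#' at the ambient bath temperature.
#'
#' If `dt` is `NULL` it is set at simulation time to 0.9 times the explicit
#' stability limit `1 / (2 alpha (1/dr^2 + 1/dz^2))`.
#'
#' @param radial_extent,axial_extent Domain size in mm.
#' @param dr,dz Cell size in mm.
#' @param dt Time step in s, or `NULL` for automatic.
#' @return An object of class `simulation_grid`.
#' @export
simulation_grid <- function(radial_extent = 27, axial_extent = 90,
                            dr = 0.5, dz = 0.5, dt = NULL) {
  if (radial_extent <= 0 || axial_extent <= 0 || dr <= 0 || dz <= 0)
    stop_ablashape("grid extents and spacings must be positive", "validation_error")
  nr <- round(radial_extent / dr)
  nz <- round(axial_extent / dz)
  if (abs(nr * dr - radial_extent) > 1e-9 || abs(nz * dz - axial_extent) > 1e-9)
    stop_ablashape("extents must be integer multiples of dr/dz", "validation_error")
  structure(list(radial_extent = radial_extent, axial_extent = axial_extent,
                 dr = dr, dz = dz, dt = dt, nr = as.integer(nr), nz = as.integer(nz),
                 r = (seq_len(nr) - 0.5) * dr, z = (seq_len(nz) - 0.5) * dz),
            class = "simulation_grid")
}

#' Explicit stability limit for the grid
#'
#' @param params A [thermal_params()].
#' @param grid A [simulation_grid()].
#' @return Maximum stable time step in seconds.
#' @export
dt_stability_limit <- function(params, grid) {
  1 / (2 * params$diffusivity * (1 / grid$dr^2 + 1 / grid$dz^2))
}

resolve_dt <- function(params, grid) {
  lim <- dt_stability_limit(params, grid)
  if (is.null(grid$dt)) return(0.9 * lim)
  if (grid$dt > lim + 1e-12)
    stop_ablashape(sprintf("dt = %g exceeds stability limit %g", grid$dt, lim),
                   "configuration_error")
  grid$dt
}

#' Cell volumes of the axisymmetric grid
#'
#' Annular cell volumes `2 pi r dr dz` (exact for cell-centred radii), as
#' an `nr x nz` matrix in mm^3.  Useful for energy book-keeping.
#'
#' @param grid A [simulation_grid()].
#' @return Matrix of cell volumes.
#' @export
cell_volumes <- function(grid) {
  matrix(2 * pi * grid$r * grid$dr * grid$dz, nrow = grid$nr, ncol = grid$nz)
}

#' Volumetric heat deposition field of the probe
#'
#' An isotropic Gaussian source (spread `source_sigma`) centred on the
#' probe axis at `feed_zone_offset` mm above the tip, discretely normalized
#' so that the deposited power integrates to
#' `absorbed_fraction * efficiency * power` over the grid.  An optional
#' uniform line sink along the shaft above the feed zone models
#' probe-coolant heat removal (nominal, uncapped, form; the simulator
#' additionally caps extraction at the coolant temperature).
#'
#' @param probe_tip_z Axial tip position in mm (grid z coordinate).
#' @param power Planned generator power in W.
#' @param params A [thermal_params()].
#' @param grid A [simulation_grid()].
#' @return An `nr x nz` matrix of deposition density in W/mm^3.
#' @export
source_field <- function(probe_tip_z, power, params, grid) {
  z_src <- probe_tip_z + params$feed_zone_offset
  if (z_src < 0 || z_src > grid$axial_extent)
    stop_ablashape("source centre outside the grid", "range_error")
  q <- matrix(0, grid$nr, grid$nz)
  if (power > 0) {
    s2 <- params$source_sigma^2
    fr <- exp(-grid$r^2 / (2 * s2))
    fz <- exp(-(grid$z - z_src)^2 / (2 * s2))
    tot <- sum(fr * 2 * pi * grid$r * grid$dr) * sum(fz * grid$dz)
    q <- outer(fr, fz) * (params$absorbed_fraction * params$efficiency * power / tot)
  }
  if (params$cooling_sink > 0) {
    shaft <- grid$z > z_src + params$shaft_standoff
    rows <- which(grid$r < 1)                      # probe shaft footprint
    if (any(shaft) && length(rows)) {
      v <- 2 * pi * grid$r[rows] * grid$dr * grid$dz
      q[rows, shaft] <- q[rows, shaft] - params$cooling_sink * grid$dz / sum(v)
    }
  }
  q
}

#' One explicit finite-volume heat-conduction step
#'
#' Advances the temperature field by `dt` under
#' `dT/dt = alpha laplacian(T) + q / (rho c)` in cylindrical (r, z)
#' coordinates with axis symmetry at r = 0 (zero flux through the axis
#' face) and the outer boundary cells held at the ambient temperature
#' (water bath).  Interior fluxes cancel pairwise, so thermal energy is
#' conserved exactly away from the boundary.
#'
#' @param T_field `nr x nz` temperature matrix in degC.
#' @param q Deposition field in W/mm^3 (matrix of the same shape, or 0).
#' @param params A [thermal_params()].
#' @param grid A [simulation_grid()].
#' @param dt Time step in s (defaults to the grid's resolved step).
#' @return The updated temperature matrix.
#' @export
heat_step <- function(T_field, q, params, grid, dt = NULL) {
  dt <- dt %||% resolve_dt(params, grid)
  lim <- dt_stability_limit(params, grid)
  if (dt > lim + 1e-12)
    stop_ablashape("unstable time step", "configuration_error")
  st <- step_setup(params, grid)
  advance(T_field, q, dt, st)
}

# Precompute flux coefficients; reused across many steps of a simulation.
step_setup <- function(params, grid) {
  nr <- grid$nr; nz <- grid$nz
  r <- grid$r; dr <- grid$dr; dz <- grid$dz
  r_plus <- r + dr / 2
  r_minus <- r - dr / 2
  cp <- r_plus / (r * dr^2)     # coefficient of (T[i+1] - T[i])
  cm <- r_minus / (r * dr^2)    # coefficient of (T[i-1] - T[i]); cm[1] = 0
  cm[1] <- 0
  cp[nr] <- 0                   # outer ring is a fixed boundary cell
  list(nr = nr, nz = nz, cp = cp, cm = cm, inv_dz2 = 1 / dz^2,
       alpha = params$diffusivity, rc = params$volumetric_heat_capacity,
       amb = params$ambient_temp)
}

advance <- function(T_field, q, dt, st) {
  nr <- st$nr; nz <- st$nz
  up <- T_field[c(2:nr, nr), , drop = FALSE]
  down <- T_field[c(1, 1:(nr - 1)), , drop = FALSE]
  lap_r <- st$cp * (up - T_field) + st$cm * (down - T_field)
  left <- T_field[, c(1, 1:(nz - 1)), drop = FALSE]
  right <- T_field[, c(2:nz, nz), drop = FALSE]
  lap_z <- (left + right - 2 * T_field) * st$inv_dz2
  lap_z[, 1] <- 0; lap_z[, nz] <- 0
  Tn <- T_field + dt * st$alpha * (lap_r + lap_z)
  if (!identical(q, 0)) Tn <- Tn + q * (dt / st$rc)
  Tn[nr, ] <- st$amb
  Tn[, 1] <- st$amb
  Tn[, nz] <- st$amb
  Tn
}

#' Simulate an ablation and record the maximum-temperature field
#'
#' Steps the heat equation over the whole probe schedule, moving the
#' volumetric source with the probe (feed-zone centre at
#' `src_start_z + probe_position(t)`) and modulating power according to
#' `power_fun(t)`.  Because the thermochromic phantom records the maximum
#' temperature irreversibly, the per-cell running maximum is the quantity
#' of interest; the final temperature field is returned as well.
#'
#' @param schedule A `probe_schedule` from [discretize()].
#' @param power_fun Function of time (s) returning planned power (W); for
#'   a profile use `function(t) profile_power(profile, t)`.
#' @param params A [thermal_params()].
#' @param grid A [simulation_grid()].
#' @param src_start_z Initial axial position (mm, grid coordinate) of the
#'   source centre, i.e. of the feed zone at the trajectory start.  `NULL`
#'   centres the source path in the axial extent.
#' @return An object of class `max_temperature_field` with elements
#'   `values` (running maximum, degC), `final` (temperature at the last
#'   step), `grid`, `params`, `src_start_z` and `trajectory_length`.
#' @export
simulate_ablation <- function(schedule, power_fun, params = thermal_params(),
                              grid = simulation_grid(), src_start_z = NULL) {
  if (!inherits(schedule, "probe_schedule"))
    stop_ablashape("expected a `probe_schedule`", "validation_error")
  if (schedule$total_time <= 0)
    stop_ablashape("schedule duration must be positive", "validation_error")
  D <- schedule$total_distance
  src0 <- src_start_z %||% ((grid$axial_extent - D) / 2)
  margin <- 2 * grid$dz
  if (src0 < margin || src0 + D > grid$axial_extent - margin)
    stop_ablashape("probe trajectory exits the grid", "range_error")
  dt <- resolve_dt(params, grid)
  st <- step_setup(params, grid)
  s2 <- params$source_sigma^2
  fr <- exp(-grid$r^2 / (2 * s2))
  sum_fr <- sum(fr * 2 * pi * grid$r * grid$dr)
  shaft_rows <- which(grid$r < 1)                  # probe shaft footprint
  v_shaft <- sum(2 * pi * grid$r[shaft_rows] * grid$dr * grid$dz)
  Tcur <- matrix(params$ambient_temp, grid$nr, grid$nz)
  Tmax <- Tcur
  t <- 0
  total <- schedule$total_time
  while (t < total - 1e-9) {
    h <- min(dt, total - t)
    tm <- t + h / 2
    pw <- power_fun(tm)
    z_src <- src0 + probe_position(schedule, tm)
    if (pw > 0) {
      fz <- exp(-(grid$z - z_src)^2 / (2 * s2))
      tot <- sum_fr * sum(fz * grid$dz)
      q <- outer(fr, fz) * (params$absorbed_fraction * params$efficiency * pw / tot)
    } else {
      q <- 0
    }
    Tcur <- advance(Tcur, q, h, st)
    if (params$cooling_sink > 0) {
      # coolant-limited shaft extraction: remove up to cooling_sink W/mm,
      # never pulling the gel below the coolant temperature
      shaft <- grid$z > z_src + params$shaft_standoff
      if (any(shaft)) {
        dT_max <- params$cooling_sink * grid$dz * h /
          (params$volumetric_heat_capacity * v_shaft)
        block <- Tcur[shaft_rows, shaft, drop = FALSE]
        block <- block - pmin(pmax(block - params$coolant_temp, 0), dT_max)
        Tcur[shaft_rows, shaft] <- block
      }
    }
    Tmax <- pmax(Tmax, Tcur)
    t <- t + h
  }
  structure(list(values = Tmax, final = Tcur, grid = grid, params = params,
                 src_start_z = src0, trajectory_length = D, dt = dt),
            class = "max_temperature_field")
}

#' @export
print.max_temperature_field <- function(x, ...) {
  cat(sprintf("<max_temperature_field> %d x %d cells, peak %.1f degC\n",
              nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

#' Threshold a maximum-temperature field into an ablation mask
#'
#' A cell is ablated if its maximum temperature reached the coagulation
#' threshold.  The result lives on the (r, z) half-plane; use
#' [mask_image()] to mirror it into a full 2D cross-section.
#'
#' @param maxfield A `max_temperature_field` from [simulate_ablation()].
#' @param threshold Threshold temperature in degC; defaults to the
#'   simulation's `threshold_temp` (60).
#' @return Logical `nr x nz` matrix.
#' @export
ablation_mask <- function(maxfield, threshold = NULL) {
  if (!inherits(maxfield, "max_temperature_field"))
    stop_ablashape("expected a `max_temperature_field`", "validation_error")
  threshold <- threshold %||% maxfield$params$threshold_temp
  maxfield$values >= threshold
}

#' Mirror an (r, z) mask into a full cross-section raster with metadata
#'
#' Builds the 2D cross-section a cut sample would show: rows run along the
#' probe axis (row 1 at the top of the container, the probe entry side),
#' columns laterally, with the probe axis midway between the two central
#' columns.  The metadata carries the mm-per-pixel scale, the (possibly
#' fractional) axis column and start row, and the trajectory length, so
#' downstream morphometry needs no registration.  Trajectory coordinate:
#' `z_mm = (start_row - row) * scale`, zero at the initial feed-zone
#' position and increasing toward the entry.
#'
#' @param mask Logical `nr x nz` matrix (or a `max_temperature_field`, which
#'   is thresholded first).
#' @param grid The [simulation_grid()] the mask lives on (`dr` must equal `dz`).
#' @param src_start_z Initial source-centre z (mm); taken from the field if
#'   one is supplied.
#' @param trajectory_length Trajectory length in mm; likewise.
#' @return A list with elements `mask` (logical, `nz x 2 nr`) and `meta`
#'   (list `scale`, `axis_col`, `start_row`, `trajectory_length`,
#'   `width_mm`, `height_mm`).
#' @export
mask_image <- function(mask, grid = NULL, src_start_z = NULL,
                       trajectory_length = NULL) {
  if (inherits(mask, "max_temperature_field")) {
    grid <- mask$grid
    src_start_z <- src_start_z %||% mask$src_start_z
    trajectory_length <- trajectory_length %||% mask$trajectory_length
    mask <- ablation_mask(mask)
  }
  if (is.null(grid) || is.null(src_start_z))
    stop_ablashape("`grid` and `src_start_z` are required", "validation_error")
  if (abs(grid$dr - grid$dz) > 1e-12)
    stop_ablashape("mask_image requires dr == dz", "validation_error")
  nr <- grid$nr; nz <- grid$nz
  # rows: z = axial_extent -> 0 (top to bottom); cols: -R -> R
  half <- t(mask)[nz:1, , drop = FALSE]           # nz x nr, row 1 = top
  full <- cbind(half[, nr:1, drop = FALSE], half)
  meta <- list(scale = grid$dz,
               axis_col = nr + 0.5,
               start_row = (grid$axial_extent - src_start_z) / grid$dz + 0.5,
               trajectory_length = trajectory_length %||% 0,
               width_mm = 2 * grid$radial_extent,
               height_mm = grid$axial_extent)
  list(mask = full, meta = meta)
}

#' Calibrate the absorbed-power fraction to a target ablation width
#'
#' One-dimensional search on `absorbed_fraction` so that a reference
#' static profile reaches a user-supplied width target; ablation width
#' grows monotonically with deposited power, so bisection on the simulated
#' width converges.  Intended for matching the simulator to a specific
#' ablation device and phantom.
#'
#' @param profile Reference [ablation_profile()] (typically a static OVAL).
#' @param target_width_mm Desired maximum ablation width in mm.
#' @param params Base [thermal_params()]; all fields except
#'   `absorbed_fraction` are kept.
#' @param grid A [simulation_grid()].
#' @param range Absorbed-fraction search interval.
#' @param tol Width tolerance in mm.
#' @return A [thermal_params()] with calibrated `absorbed_fraction`.
#' @export
calibrate_absorption <- function(profile, target_width_mm,
                                 params = thermal_params(),
                                 grid = simulation_grid(),
                                 range = c(0.1, 1), tol = 0.5) {
  width_for <- function(eff) {
    p <- params; p$absorbed_fraction <- eff
    fld <- simulate_ablation(discretize(profile), function(t) profile_power(profile, t),
                             p, grid)
    mi <- mask_image(fld)
    wp <- width_profile(mi$mask, mi$meta)
    if (nrow(wp) == 0) 0 else max(wp$width_mm)
  }
  lo <- range[1]; hi <- range[2]
  w_lo <- width_for(lo); w_hi <- width_for(hi)
  if (target_width_mm < w_lo || target_width_mm > w_hi)
    stop_ablashape("target width outside achievable range", "search_limit_error")
  for (i in 1:20) {
    mid <- (lo + hi) / 2
    w <- width_for(mid)
    if (abs(w - target_width_mm) < tol) { lo <- hi <- mid; break }
    if (w < target_width_mm) lo <- mid else hi <- mid
  }
  out <- params
  out$absorbed_fraction <- (lo + hi) / 2
  out
}
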