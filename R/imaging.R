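#' Rendering parameters for synthetic cross-section photographs
#'
#' The thermochromic phantom turns from off-white to magenta where the
#' coagulation threshold was exceeded, with no sharp colour cut-off: the
#' transition is a 1-2 mm gradient.  The renderer maps the signed distance
#' to the ablation boundary onto a linear blend between the two colours
#' over `gradient_width` mm (in HSV, hue along the shortest arc) and adds
#' per-channel Gaussian noise.
#'
#' Hue is expressed on \code{[0, 1)} (i.e. degrees / 360).
#'
#' @param scale Rendered mm per pixel.
#' @param fg_hsv Foreground (ablated, magenta) HSV triple.
#' @param bg_hsv Background (non-ablated, off-white) HSV triple.
#' @param gradient_width Width in mm of the colour gradient at the
#'   boundary (default 1.5, the middle of the 1-2 mm uncertainty band).
#' @param noise_sd Per-channel RGB noise standard deviation (0-1 scale).
#' @param artifact_spec Optional list of contour perturbations applied
#'   before rendering; see [perturb_contour()].
#' @return An object of class `render_params`.
#' @export
render_params <- function(scale = 0.25,
                          fg_hsv = c(300 / 360, 0.70, 0.80),
                          bg_hsv = c(40 / 360, 0.06, 0.95),
                          gradient_width = 1.5,
                          noise_sd = 0.02,
                          artifact_spec = NULL) {
  if (scale <= 0) stop_ablashape("`scale` must be positive", "validation_error")
  if (gradient_width < 0)
    stop_ablashape("`gradient_width` must be >= 0", "validation_error")
  if (isTRUE(all.equal(fg_hsv, bg_hsv)))
    stop_ablashape("foreground and background colours must differ", "validation_error")
  structure(list(scale = scale, fg_hsv = fg_hsv, bg_hsv = bg_hsv,
                 gradient_width = gradient_width, noise_sd = noise_sd,
                 artifact_spec = artifact_spec),
            class = "render_params")
}

# blend two HSV colours along the shortest hue arc; alpha = 1 -> fg
hsv_blend <- function(alpha, fg, bg) {
  dh <- ((fg[1] - bg[1] + 0.5) %% 1) - 0.5
  h <- (bg[1] + alpha * dh) %% 1
  s <- bg[2] + alpha * (fg[2] - bg[2])
  v <- bg[3] + alpha * (fg[3] - bg[3])
  rgbcol <- col2rgb(hsv(h, pmin(pmax(s, 0), 1), pmin(pmax(v, 0), 1))) / 255
  rgbcol
}

signed_distance_px <- function(mask) {
  storage.mode(mask) <- "integer"
  inside <- EBImage::distmap(mask)
  outside <- EBImage::distmap(1L - mask)
  inside - outside
}

upsample_meta <- function(meta, new_scale) {
  list(scale = new_scale,
       axis_col = meta$width_mm / 2 / new_scale + 0.5,
       start_row = (meta$height_mm - (meta$height_mm -
                     (meta$start_row - 0.5) * meta$scale)) / new_scale + 0.5,
       trajectory_length = meta$trajectory_length,
       width_mm = meta$width_mm, height_mm = meta$height_mm)
}

upsample_mask <- function(mask, meta, new_scale) {
  H <- round(meta$height_mm / new_scale)
  W <- round(meta$width_mm / new_scale)
  rows <- pmin(pmax(ceiling((seq_len(H) - 0.5) * new_scale / meta$scale), 1), nrow(mask))
  cols <- pmin(pmax(ceiling((seq_len(W) - 0.5) * new_scale / meta$scale), 1), ncol(mask))
  mask[rows, cols, drop = FALSE]
}

#' Render an ablation mask into a photograph-like cross-section image
#'
#' The binary mask (in mm coordinates, carried by its metadata) is
#' resampled to the rendering scale; the signed distance to the ablation
#' boundary is mapped onto a linear foreground/background colour blend
#' over the gradient width, and seeded Gaussian noise is added per RGB
#' channel.  The ground-truth mask at rendering resolution is attached.
#' Rendering is deterministic per seed.
#'
#' @param mask Logical cross-section raster (e.g. `mask_image(...)$mask`).
#' @param meta Its metadata (`scale`, `axis_col`, `start_row`, ...).
#' @param params A [render_params()].
#' @param seed Integer seed for the rendering noise.
#' @return An object of class `cross_section_image`: `pixels`
#'   (H x W x 3 array, RGB in 0-1), `scale`, `meta`, `truth_mask`.
#' @export
render_cross_section <- function(mask, meta, params = render_params(), seed = 1L) {
  gw <- params$gradient_width
  if (gw > min(meta$height_mm, meta$width_mm))
    stop_ablashape("gradient wider than the image", "validation_error")
  m2 <- upsample_mask(mask, meta, params$scale)
  meta2 <- upsample_meta(meta, params$scale)
  sd_mm <- signed_distance_px(m2) * params$scale
  alpha <- if (gw > 0) pmin(pmax(0.5 + sd_mm / gw, 0), 1) else (sd_mm > 0) * 1
  rgbcol <- hsv_blend(as.vector(alpha), params$fg_hsv, params$bg_hsv)
  H <- nrow(m2); W <- ncol(m2)
  px <- array(0, c(H, W, 3))
  px[, , 1] <- rgbcol[1, ]; px[, , 2] <- rgbcol[2, ]; px[, , 3] <- rgbcol[3, ]
  if (params$noise_sd > 0) {
    set.seed(as.integer(seed))
    px <- px + rnorm(length(px), 0, params$noise_sd)
    px <- pmin(pmax(px, 0), 1)
  }
  structure(list(pixels = px, scale = params$scale, meta = meta2,
                 truth_mask = m2 > 0),
            class = "cross_section_image")
}

#' @export
print.cross_section_image <- function(x, ...) {
  cat(sprintf("<cross_section_image> %d x %d px, %.3g mm/px\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$scale))
  invisible(x)
}

#' Perturb an ablation contour with shape artifacts
#'
#' Adds the two artifact families seen on real cut samples: lateral
#' extrusions (local outward bumps on one side of the contour, e.g. from
#' inhomogeneous gel) and proximal indents (an inward notch at the head,
#' from probe-shaft cooling).  An empty specification returns the mask
#' unchanged.
#'
#' Each element of `artifact_spec` is a list with `type`
#' (`"extrusion"` or `"indent"`), `z_mm` (axial location for extrusions,
#' trajectory coordinate), `amplitude_mm`, `width_mm`, and for extrusions
#' an optional `side` (`"left"`/`"right"`, default seeded at random).
#'
#' @param mask Logical cross-section raster.
#' @param meta Its metadata.
#' @param artifact_spec List of artifact descriptions (possibly empty).
#' @param seed Integer seed (used only for unspecified extrusion sides).
#' @return The perturbed logical mask.
#' @export
perturb_contour <- function(mask, meta, artifact_spec, seed = 1L) {
  if (is.null(artifact_spec) || length(artifact_spec) == 0) return(mask)
  set.seed(as.integer(seed))
  sc <- meta$scale
  cols <- axis_cols(meta)
  for (a in artifact_spec) {
    amp <- a$amplitude_mm %||% 0
    if (amp < 0) stop_ablashape("artifact amplitude must be >= 0", "validation_error")
    w <- a$width_mm %||% 3
    if (identical(a$type, "extrusion")) {
      side <- a$side %||% sample(c("left", "right"), 1)
      rows <- seq_len(nrow(mask))
      zp <- (meta$start_row - rows) * sc
      sel <- which(abs(zp - a$z_mm) <= 2 * w)
      for (i in sel) {
        rv <- mask[i, ]
        if (!any(rv)) next
        r <- rle(rv); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
        hit <- which(r$values & starts <= max(cols) & ends >= min(cols))
        if (!length(hit)) next
        bump <- round(amp * exp(-((zp[i] - a$z_mm) / w)^2 / 2) / sc)
        if (bump < 1) next
        if (side == "right") {
          e <- ends[hit[1]]
          mask[i, seq(e, min(ncol(mask), e + bump))] <- TRUE
        } else {
          s <- starts[hit[1]]
          mask[i, seq(max(1, s - bump), s)] <- TRUE
        }
      }
    } else if (identical(a$type, "indent")) {
      on_axis <- which(rowSums(mask[, cols, drop = FALSE]) > 0)
      if (!length(on_axis)) next
      top <- min(on_axis)             # head end (row 1 = proximal)
      depth_px <- max(1, round(amp / sc))
      half_w <- max(1, round(w / 2 / sc))
      for (d in 0:(depth_px - 1)) {
        i <- top + d
        if (i > nrow(mask)) break
        hw <- max(0, round(half_w * (1 - d / depth_px)))
        cc <- seq(max(1, floor(meta$axis_col) - hw),
                  min(ncol(mask), ceiling(meta$axis_col) + hw))
        mask[i, cc] <- FALSE
      }
    } else {
      stop_ablashape("unknown artifact type", "validation_error")
    }
  }
  mask
}

#' Cohort specification for the synthetic-data generator
#'
#' Describes a cohort of replicate ablation samples for one profile.
#' Inter-sample variability emulates what is seen on the physical system:
#' generator output drawn uniformly from `efficiency_range` (recorded
#' device output runs at 85-90 % of the planned power) and Gaussian
#' relative jitter on the thermal diffusivity standing in for gel
#' inhomogeneity.
#'
#' @param profile An [ablation_profile()].
#' @param n Number of samples (>= 2).
#' @param efficiency_range Uniform range for the generator output factor.
#' @param diffusivity_jitter Relative standard deviation of the
#'   per-sample diffusivity (default 0.03).
#' @param threshold_jitter Standard deviation in degC of the per-sample
#'   coagulation threshold (default 2): thermochromic inks switch over
#'   a tolerance band of a couple of degrees rather than at a sharp
#'   temperature, and the band centre varies from batch to batch.
#' @param render A [render_params()].
#' @param seed Integer master seed for the cohort.
#' @param params Base [thermal_params()].
#' @param grid A [simulation_grid()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(profile, n, efficiency_range = c(0.85, 0.90),
                        diffusivity_jitter = 0.03, threshold_jitter = 2,
                        render = render_params(), seed = 1L,
                        params = thermal_params(), grid = simulation_grid()) {
  check_profile(profile)
  if (n < 2) stop_ablashape("`n` must be >= 2", "validation_error")
  if (any(efficiency_range <= 0) || any(efficiency_range > 1) ||
      efficiency_range[1] > efficiency_range[2])
    stop_ablashape("`efficiency_range` must be within (0, 1] and ordered",
                   "validation_error")
  if (threshold_jitter < 0)
    stop_ablashape("`threshold_jitter` must be >= 0", "validation_error")
  structure(list(profile = profile, n = as.integer(n),
                 efficiency_range = efficiency_range,
                 diffusivity_jitter = diffusivity_jitter,
                 threshold_jitter = threshold_jitter,
                 render = render, seed = as.integer(seed),
                 params = params, grid = grid),
            class = "cohort_spec")
}

#' Generate a seeded cohort of synthetic cross-section images
#'
#' Runs `n` simulate-and-render passes for the cohort's profile.  Each
#' sample gets a seed derived from the cohort seed, its own generator
#' output factor (uniform in `efficiency_range`) and its own thermal
#' diffusivity (relative Gaussian jitter), so replicate shapes differ the
#' way physical samples do.  Fully reproducible for a fixed cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `cross_section_image` objects of length `spec$n`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop_ablashape("expected a `cohort_spec`", "validation_error")
  schedule <- discretize(spec$profile)
  pw <- function(t) profile_power(spec$profile, t)
  lapply(seq_len(spec$n), function(i) {
    s_i <- derive_seed(spec$seed, 0L, i)
    set.seed(s_i)
    eff <- runif(1, spec$efficiency_range[1], spec$efficiency_range[2])
    jit <- rnorm(1, 0, spec$diffusivity_jitter)
    thr <- rnorm(1, 0, spec$threshold_jitter)
    p <- spec$params
    p$efficiency <- eff
    p$diffusivity <- max(1e-3, p$diffusivity * (1 + jit))
    p$threshold_temp <- max(p$ambient_temp + 1, p$threshold_temp + thr)
    fld <- simulate_ablation(schedule, pw, p, spec$grid)
    mi <- mask_image(fld)
    m <- perturb_contour(mi$mask, mi$meta, spec$render$artifact_spec,
                         seed = derive_seed(s_i, 1L, i))
    img <- render_cross_section(m, mi$meta, spec$render,
                                seed = derive_seed(s_i, 2L, i))
    img$sample_id <- sprintf("%s-%02d", spec$profile$name, i)
    img
  })
}

#' Write and read a cross-section image as PNG plus JSON sidecar
#'
#' The 8-bit RGB image goes to `path`; the mm-per-pixel scale, axis
#' column, start row and trajectory length go to a JSON sidecar
#' (`<path>.json`) so the geometry survives the round trip.
#'
#' @param image A `cross_section_image`.
#' @param path PNG file path.
#' @return [write_cross_section()] returns `path` invisibly;
#'   [read_cross_section()] returns a `cross_section_image` (without
#'   truth mask).
#' @export
write_cross_section <- function(image, path) {
  png::writePNG(image$pixels, path)
  meta <- image$meta
  jsonlite::write_json(list(scale_mm_per_px = meta$scale,
                            axis_column = meta$axis_col,
                            start_row = meta$start_row,
                            trajectory_length_mm = meta$trajectory_length,
                            width_mm = meta$width_mm,
                            height_mm = meta$height_mm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cross_section
#' @export
read_cross_section <- function(path) {
  px <- png::readPNG(path)
  j <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta <- list(scale = j$scale_mm_per_px, axis_col = j$axis_column,
               start_row = j$start_row,
               trajectory_length = j$trajectory_length_mm,
               width_mm = j$width_mm, height_mm = j$height_mm)
  structure(list(pixels = px, scale = meta$scale, meta = meta,
                 truth_mask = NULL),
            class = "cross_section_image")
}
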