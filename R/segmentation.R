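#' Two-class HSV colour model
#'
#' Foreground (ablated, magenta) and background (non-ablated, off-white)
#' median colours plus channel weights for the weighted Euclidean distance
#' in HSV space.  Hue is circular on \code{[0, 1)}; the hue difference is
#' `min(|dh|, 1 - |dh|)`.  The value channel is down-weighted by default
#' for robustness to lighting.
#'
#' @param fg_hsv,bg_hsv HSV triples (hue on 0-1).
#' @param weights Non-negative channel weights `(w_h, w_s, w_v)`.
#' @return An object of class `color_model`.
#' @export
color_model <- function(fg_hsv, bg_hsv, weights = c(1, 1, 0.5)) {
  if (isTRUE(all.equal(fg_hsv, bg_hsv)))
    stop_ablashape("foreground and background colours must differ", "validation_error")
  if (any(weights < 0) || all(weights == 0))
    stop_ablashape("`weights` must be non-negative with at least one positive",
                   "validation_error")
  structure(list(fg = fg_hsv, bg = bg_hsv, weights = weights),
            class = "color_model")
}

image_hsv <- function(image) {
  px <- if (inherits(image, "cross_section_image")) image$pixels else image
  d <- dim(px)
  m <- rgb2hsv(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]),
               maxColorValue = 1)
  list(h = m[1, ], s = m[2, ], v = m[3, ], dim = d[1:2])
}

# squared weighted distance of pixel HSV vectors to a reference colour
weighted_dist2 <- function(h, s, v, ref, w) {
  dh <- abs(h - ref[1]); dh <- pmin(dh, 1 - dh)
  (w[1] * dh)^2 + (w[2] * (s - ref[2]))^2 + (w[3] * (v - ref[3]))^2
}

circular_median <- function(h, center) {
  rot <- (h - center + 0.5) %% 1
  (median(rot) - 0.5 + center) %% 1
}

#' Estimate the image-specific colour model
#'
#' Pixels are provisionally labelled by the nearest prior colour; the
#' channel-wise medians of each class (hue circularly, around the prior
#' hue) become the image-specific model.  One refinement pass only.
#'
#' @param image A `cross_section_image` or an H x W x 3 RGB array.
#' @param priors A [color_model()] of prior colours.
#' @return A [color_model()] with per-image median colours.
#' @export
estimate_color_model <- function(image, priors) {
  hsv_px <- image_hsv(image)
  w <- priors$weights
  d_fg <- weighted_dist2(hsv_px$h, hsv_px$s, hsv_px$v, priors$fg, w)
  d_bg <- weighted_dist2(hsv_px$h, hsv_px$s, hsv_px$v, priors$bg, w)
  is_fg <- d_fg < d_bg
  n <- length(is_fg)
  if (sum(is_fg) < 0.01 * n || sum(!is_fg) < 0.01 * n)
    stop_ablashape("degenerate image: one colour class captures < 1 % of pixels",
                   "degenerate_image_error")
  med <- function(sel, prior) c(circular_median(hsv_px$h[sel], prior[1]),
                                median(hsv_px$s[sel]),
                                median(hsv_px$v[sel]))
  color_model(med(is_fg, priors$fg), med(!is_fg, priors$bg), w)
}

#' Classify pixels against a colour model
#'
#' A pixel is foreground iff its weighted HSV distance to the foreground
#' median is strictly smaller than to the background median; exact ties
#' go to background (conservative: under- rather than over-segmentation
#' of the ablated area).  The decision surface is the perpendicular
#' bisector of the two medians in weighted HSV space, i.e. thresholding
#' at the colour midway between them.
#'
#' @param image A `cross_section_image` or RGB array.
#' @param model A [color_model()].
#' @return Logical H x W mask.
#' @export
classify_pixels <- function(image, model) {
  hsv_px <- image_hsv(image)
  w <- model$weights
  d_fg <- weighted_dist2(hsv_px$h, hsv_px$s, hsv_px$v, model$fg, w)
  d_bg <- weighted_dist2(hsv_px$h, hsv_px$s, hsv_px$v, model$bg, w)
  matrix(d_fg < d_bg, hsv_px$dim[1], hsv_px$dim[2])
}

#' Segment an ablation cross-section image
#'
#' The colour-based two-class segmentation: estimate per-image median
#' colours from the priors, classify every pixel by the weighted-HSV
#' midpoint rule, keep the largest 4-connected foreground component and
#' fill interior holes.
#'
#' @param image A `cross_section_image` (or RGB array).
#' @param priors A [color_model()]; defaults to the renderer's default
#'   magenta/off-white pair.
#' @param weights Channel weights, passed to the priors if supplied as a
#'   bare pair of colours.
#' @return Logical H x W mask of the ablated area.
#' @export
segment_image <- function(image, priors = NULL, weights = c(1, 1, 0.5)) {
  if (is.null(priors)) {
    rp <- render_params()
    priors <- color_model(rp$fg_hsv, rp$bg_hsv, weights)
  }
  model <- estimate_color_model(image, priors)
  m <- classify_pixels(image, model)
  fill_holes(largest_component(m))
}
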