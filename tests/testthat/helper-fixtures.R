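# Fixtures are built in code: synthetic masks in mm coordinates with the
# package's image metadata convention, quick profiles and a coarse grid
# for fast simulations.

synthetic_mask <- function(height_mm, width_mm, scale, inside_fn,
                           start_z = height_mm / 2, trajectory_length = 0) {
  H <- round(height_mm / scale)
  W <- round(width_mm / scale)
  axis_col <- (W + 1) / 2
  start_row <- (height_mm - start_z) / scale + 0.5
  zp <- (start_row - seq_len(H)) * scale
  x <- (seq_len(W) - axis_col) * scale
  mask <- outer(zp, x, inside_fn)
  list(mask = mask,
       meta = list(scale = scale, axis_col = axis_col, start_row = start_row,
                   trajectory_length = trajectory_length,
                   width_mm = width_mm, height_mm = height_mm))
}

ellipse_mask <- function(a, b, scale = 0.25, height_mm = 60, width_mm = 50,
                         center_z = 0, trajectory_length = 0) {
  synthetic_mask(height_mm, width_mm, scale,
                 function(z, x) ((z - center_z) / a)^2 + (x / b)^2 <= 1,
                 trajectory_length = trajectory_length)
}

rect_mask <- function(half_len, half_wid, scale = 0.25, height_mm = 60,
                      width_mm = 50, trajectory_length = 0) {
  synthetic_mask(height_mm, width_mm, scale,
                 function(z, x) abs(z) <= half_len & abs(x) <= half_wid,
                 trajectory_length = trajectory_length)
}

quick_profile <- function(ivs, name = "TEST", label = "LONG") {
  ablation_profile(name, label,
                   lapply(ivs, function(v) ablation_interval(v[1], v[2], v[3])))
}

quick_grid <- function() simulation_grid(radial_extent = 15, axial_extent = 40,
                                         dr = 1, dz = 1)

quick_params <- function(...) thermal_params(cooling_sink = 0, ...)

# exact HSV -> RGB in doubles (no 8-bit quantization), for colour fixtures
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6); f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  switch(as.character(i %% 6),
         "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
         "3" = c(p, q, v), "4" = c(t, p, v), "5" = c(v, p, q))
}

solid_image <- function(H, W, rgb_triples, labels) {
  px <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    m <- matrix(0, H, W)
    for (k in seq_along(rgb_triples)) m[labels == k] <- rgb_triples[[k]][ch]
    px[, , ch] <- m
  }
  px
}
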