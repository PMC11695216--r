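default_priors <- function() {
  rp <- render_params()
  color_model(rp$fg_hsv, rp$bg_hsv)
}

test_that("median colour estimation recovers a two-colour image exactly", {
  fg <- hsv_to_rgb(300 / 360, 0.7, 0.8)
  bg <- hsv_to_rgb(40 / 360, 0.06, 0.95)
  labels <- matrix(2, 40, 40); labels[10:25, 10:25] <- 1
  img <- solid_image(40, 40, list(fg, bg), labels)
  model <- estimate_color_model(img, default_priors())
  expect_equal(model$fg, c(300 / 360, 0.7, 0.8), tolerance = 1e-10)
  expect_equal(model$bg, c(40 / 360, 0.06, 0.95), tolerance = 1e-10)
})

test_that("noisy class medians concentrate around the true colours", {
  rp <- render_params(scale = 0.5, noise_sd = 0.02)
  disc <- ellipse_mask(8, 8, scale = 0.5, height_mm = 30, width_mm = 30)
  img <- render_cross_section(disc$mask, disc$meta, rp, seed = 12)
  model <- estimate_color_model(img, default_priors())
  expect_equal(model$fg, rp$fg_hsv, tolerance = 0.05)
  expect_equal(model$bg, rp$bg_hsv, tolerance = 0.05)
})

test_that("single-colour images raise a degenerate-image error", {
  img <- solid_image(20, 20, list(hsv_to_rgb(0.8, 0.7, 0.8)),
                     matrix(1, 20, 20))
  expect_error(estimate_color_model(img, default_priors()),
               class = "degenerate_image_error")
})

test_that("pixels equal to a median classify to that class; ties to background", {
  fg_rgb <- c(1, 0, 0)      # hsv (0, 1, 1)
  bg_rgb <- c(1, 1, 1)      # hsv (0, 0, 1)
  mid_rgb <- c(1, 0.5, 0.5) # hsv (0, 0.5, 1): exactly midway in weighted HSV
  model <- color_model(c(0, 1, 1), c(0, 0, 1))
  img <- solid_image(1, 3, list(fg_rgb, bg_rgb, mid_rgb),
                     matrix(c(1, 2, 3), 1, 3))
  out <- classify_pixels(img, model)
  expect_true(out[1, 1])
  expect_false(out[1, 2])
  expect_false(out[1, 3])   # documented tie rule: background
})

test_that("hue distance wraps circularly", {
  # foreground hue near 1, pixel hue just past the wrap point
  model <- color_model(c(0.95, 1, 1), c(0.4, 1, 1))
  px <- hsv_to_rgb(0.02, 1, 1)
  img <- solid_image(1, 1, list(px), matrix(1, 1, 1))
  expect_true(classify_pixels(img, model)[1, 1])
})

test_that("the decision surface is the weighted-midpoint bisector", {
  set.seed(41)
  for (rep in 1:4) {
    fg <- c(runif(1), runif(1, 0.3, 1), runif(1, 0.3, 1))
    bg <- c(runif(1), runif(1, 0, 0.4), runif(1, 0.5, 1))
    w <- runif(3, 0.2, 2)
    model <- color_model(fg, bg, w)
    hs <- seq(0.01, 0.99, length.out = 8)
    ss <- seq(0.05, 0.95, length.out = 5)
    grid <- expand.grid(h = hs, s = ss, v = ss)
    rgbs <- t(apply(grid, 1, function(r) hsv_to_rgb(r[1], r[2], r[3])))
    img <- array(0, c(nrow(grid), 1, 3))
    img[, 1, ] <- rgbs
    got <- classify_pixels(img, model)[, 1]
    # independent nearest-centre oracle with circular hue
    hsv_px <- t(apply(rgbs, 1, function(p) grDevices::rgb2hsv(p[1], p[2], p[3],
                                                              maxColorValue = 1)[, 1]))
    oracle <- apply(hsv_px, 1, function(p) {
      d <- function(ref) {
        dh <- min(abs(p[1] - ref[1]), 1 - abs(p[1] - ref[1]))
        sqrt((w[1] * dh)^2 + (w[2] * (p[2] - ref[2]))^2 + (w[3] * (p[3] - ref[3]))^2)
      }
      d(fg) < d(bg)
    })
    expect_equal(got, unname(oracle))
  }
})

test_that("segmentation keeps the largest component and fills holes", {
  inside <- function(z, x) {
    disc <- z^2 + x^2 <= 8^2
    hole <- z^2 + (x - 2)^2 <= 1.5^2
    speck <- (z - 12)^2 + (x - 10)^2 <= 1.2^2
    (disc & !hole) | speck
  }
  m <- synthetic_mask(40, 40, 0.25, inside)
  img <- render_cross_section(m$mask, m$meta,
                              render_params(scale = 0.25, noise_sd = 0), seed = 1)
  seg <- segment_image(img)
  truth_disc <- synthetic_mask(40, 40, 0.25, function(z, x) z^2 + x^2 <= 8^2)
  # speckle removed, hole filled: segmentation equals the filled disc
  expect_gt(dice_coefficient(seg, truth_disc$mask), 0.98)
})

test_that("label_components separates diagonal blobs under 4-connectivity", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE           # touch only diagonally
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  m2 <- matrix(FALSE, 6, 6); m2[2, 2:4] <- TRUE; m2[3, 4] <- TRUE
  expect_equal(max(label_components(m2)), 1L)
})

test_that("fill_holes only fills interior background", {
  m <- matrix(FALSE, 8, 8)
  m[2:7, 2:7] <- TRUE
  m[4:5, 4:5] <- FALSE                       # interior hole
  filled <- fill_holes(m)
  expect_true(all(filled[2:7, 2:7]))
  expect_false(any(filled[1, ]))             # border background untouched
})

test_that("classification is a pure per-pixel function", {
  rp <- render_params(scale = 0.5)
  disc <- ellipse_mask(8, 8, scale = 0.5, height_mm = 30, width_mm = 30)
  img <- render_cross_section(disc$mask, disc$meta, rp, seed = 7)
  model <- estimate_color_model(img, default_priors())
  full <- classify_pixels(img, model)
  # classifying a permuted copy and unpermuting gives the same labels
  px <- img$pixels
  set.seed(3)
  perm <- sample(nrow(px) * ncol(px))
  shuffled <- array(0, c(length(perm), 1, 3))
  for (ch in 1:3) shuffled[, 1, ch] <- as.vector(px[, , ch])[perm]
  lab_shuffled <- classify_pixels(shuffled, model)[, 1]
  unperm <- integer(length(perm)); unperm[perm] <- seq_along(perm)
  expect_equal(matrix(lab_shuffled[unperm], nrow(px), ncol(px)), full)
})
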