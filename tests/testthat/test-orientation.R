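stripes_image <- function(n = 96, period = 8, angle_deg = 0) {
  c0 <- (n - 1) / 2
  th <- angle_deg / 180 * pi
  X <- outer(rep(1, n), seq_len(n) - 1) - c0
  Y <- outer(seq_len(n), rep(1, n)) - c0
  # intensity varies perpendicular to the stripe direction
  phase <- (-sin(th) * X + cos(th) * Y) * 2 * pi / period
  cell_image(100 + 50 * sin(phase), 0.1)
}

test_that("the structure tensor recovers stripe orientation", {
  f0 <- orientation_field(stripes_image(angle_deg = 0), tensor_sigma_px = 3)
  hi <- f0$coherence > 0.9
  expect_lt(stats::median(abs(f0$theta_deg[hi])), 1)

  f45 <- orientation_field(stripes_image(angle_deg = 45), tensor_sigma_px = 3)
  hi <- f45$coherence > 0.9
  expect_lt(stats::median(abs(abs(f45$theta_deg[hi]) - 45)), 2)
})

test_that("white noise has low coherence", {
  img <- withr::with_seed(7, matrix(stats::runif(96 * 96), 96, 96))
  f <- orientation_field(cell_image(100 * img, 0.1), tensor_sigma_px = 3)
  expect_lt(stats::median(f$coherence), 0.3)
})

test_that("relative-angle histograms are masked, folded and normalised", {
  ci <- stripes_image(angle_deg = 89)  # nearly vertical stripes
  m <- full_mask(dim(ci)); m[1:5, ] <- FALSE
  f <- orientation_field(ci, tensor_sigma_px = 3)
  h <- orientation_histogram(f, m, axis_deg = 0, bin_width_deg = 2)
  expect_equal(sum(h$weight), attr(h, "n_eff"))
  # mass concentrated at the +89 deg bin
  expect_gt(h$weight[h$bin_center_deg == 89] / attr(h, "n_eff"), 0.9)
  expect_error(orientation_histogram(f, matrix(FALSE, 96, 96), 0), "empty")
  expect_error(orientation_histogram(f, m, axis_deg = 95), "axis_deg")
})

test_that("uniform orientations give a flat histogram", {
  n <- 2e5
  ang <- withr::with_seed(11, stats::runif(n, -90, 90))
  pts <- tibble::tibble(ridge_id = seq_len(n), point_idx = 0L,
                        x = 0, y = 0, tangent_deg = ang,
                        width_px = NA_real_, response = 1)
  rs <- sarcnet:::as_ridge_set(pts, ridge_params(), c(10, 10), 0.1)
  h <- orientation_histogram(rs, axis_deg = 0, bin_width_deg = 10,
                             weighting = "count")
  expect_lt(max(h$weight) / min(h$weight), 1.5)
})

test_that("main_direction reports axial mean, fractions and category", {
  mkhist <- function(centers, weights, bw = 2) {
    h <- orientation_histogram(
      sarcnet:::as_ridge_set(
        tibble::tibble(ridge_id = seq_along(centers), point_idx = 0L,
                       x = 0, y = 0, tangent_deg = centers,
                       width_px = NA_real_, response = 1),
        ridge_params(), c(10, 10), 0.1),
      axis_deg = 0, bin_width_deg = bw, weighting = "count")
    h$weight <- h$weight * 0
    for (i in seq_along(centers)) {
      k <- which.min(abs(h$bin_center_deg - centers[i]))
      h$weight[k] <- h$weight[k] + weights[i]
    }
    attr(h, "n_eff") <- sum(h$weight)
    h
  }
  res <- main_direction(mkhist(89, 1))
  expect_equal(res$main_direction_deg, 89)
  expect_equal(res$resultant_length, 1)
  expect_equal(res$frac_60_90, 1)
  expect_equal(res$orientation_category, "high")

  res2 <- main_direction(mkhist(c(45, -45), c(1, 1)))
  expect_lt(res2$resultant_length, 1e-9)
  expect_true(res2$dispersed)

  res3 <- main_direction(mkhist(c(15, 45, 75), c(2, 1, 1)))
  expect_equal(res3$frac_0_30 + res3$frac_30_60 + res3$frac_60_90, 1)
  expect_equal(res3$frac_0_30, 0.5)
})

test_that("theta-bar is invariant under joint rotation of image and mask", {
  ci <- stripes_image(angle_deg = 20)
  m <- full_mask(dim(ci))
  f <- orientation_field(ci, tensor_sigma_px = 3)
  h <- orientation_histogram(f, m, axis_deg = 0)
  t1 <- main_direction(h)$main_direction_deg
  # rotate both by 90 degrees and rotate the reference axis with them
  # (axis 0 maps to -90 under the same rotation)
  rot <- cell_image(t(unclass(ci))[rev(seq_len(ncol(ci))), ], 0.1)
  f2 <- orientation_field(rot, tensor_sigma_px = 3)
  h2 <- orientation_histogram(f2, m, axis_deg = -90)
  t2 <- main_direction(h2)$main_direction_deg
  expect_lt(abs(t1 - t2), 2)
})

test_that("ridge-tangent histograms are length weighted", {
  pts <- tibble::tibble(
    ridge_id = c(1L, 1L, 1L, 2L, 2L),
    point_idx = c(0:2, 0:1),
    x = c(0, 10, 20, 0, 1), y = 0,
    tangent_deg = c(0, 0, 0, 60, 60),
    width_px = NA_real_, response = 1)
  rs <- sarcnet:::as_ridge_set(pts, ridge_params(), c(50, 50), 0.1)
  h <- orientation_histogram(rs, axis_deg = 0, bin_width_deg = 10)
  # bins are left-open: delta = 0 falls in (-10, 0], 60 in (50, 60]
  w0 <- h$weight[h$bin_center_deg == -5]
  w60 <- h$weight[h$bin_center_deg == 55]
  expect_equal(w0, 20)   # 20 px of tangent-0 polyline
  expect_equal(w60, 1)   # 1 px of tangent-60 polyline
})

test_that("orientation maps encode angle as hue and structure as value", {
  ci <- stripes_image(angle_deg = 0)
  f <- orientation_field(ci, tensor_sigma_px = 3)
  rgb <- render_orientation_map(f)
  expect_equal(dim(rgb), c(96, 96, 3))
  expect_true(all(rgb >= 0 & rgb <= 1))
  expect_equal(dim(attr(rgb, "wheel"))[3], 3)
  # uniform stripes: one dominant hue among bright pixels
  hsvv <- grDevices::rgb2hsv(rbind(as.numeric(rgb[, , 1]),
                                   as.numeric(rgb[, , 2]),
                                   as.numeric(rgb[, , 3])),
                             maxColorValue = 1)
  bright <- hsvv["v", ] > 0.5
  expect_lt(stats::sd(hsvv["h", bright]), 0.05)
  # noise: mostly low saturation
  nimg <- withr::with_seed(5, cell_image(
    100 + matrix(stats::rnorm(96 * 96, 0, 5), 96, 96), 0.1))
  fn <- orientation_field(nimg, tensor_sigma_px = 3)
  rgbn <- render_orientation_map(fn)
  hsvn <- grDevices::rgb2hsv(rbind(as.numeric(rgbn[, , 1]),
                                   as.numeric(rgbn[, , 2]),
                                   as.numeric(rgbn[, , 3])),
                             maxColorValue = 1)
  expect_lt(stats::median(hsvn["s", ]), 0.3)
})

test_that("autoplot returns a ggplot for linear and rose layouts", {
  ci <- stripes_image(angle_deg = 40)
  h <- orientation_histogram(orientation_field(ci, tensor_sigma_px = 3),
                             full_mask(dim(ci)), axis_deg = 0)
  expect_s3_class(ggplot2::autoplot(h), "ggplot")
  expect_s3_class(ggplot2::autoplot(h, rose = TRUE), "ggplot")
})
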