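test_that("a constant image yields an empty ridge set, not an error", {
  rs <- detect_ridges(cell_image(matrix(5, 64, 64), 0.1))
  expect_s3_class(rs, "ridge_set")
  expect_equal(nrow(rs), 0)
  expect_false(any(ridge_footprint(rs, c(64, 64))))
})

test_that("a single Gaussian line is recovered with sub-pixel accuracy", {
  ci <- gaussian_line_image(64, row0 = 32, sigma = 1.5)
  rs <- detect_ridges(ci, params = ridge_params(sigma_px = 1.5,
                                                min_length_px = 10))
  expect_equal(max(rs$ridge_id), 1)
  expect_lt(max(abs(rs$y - 32)), 0.2)
  expect_lt(max(abs(rs$tangent_deg)), 2)
})

test_that("oblique lines give correct tangents and small lateral error", {
  ci <- gaussian_line_image(96, sigma = 1.5, angle_deg = 30)
  rs <- detect_ridges(ci, params = ridge_params(sigma_px = 1.5,
                                                min_length_px = 10))
  expect_lt(abs(stats::median(rs$tangent_deg) - 30), 2)
  th <- 30 / 180 * pi
  d <- abs(-sin(th) * (rs$x - 47.5) + cos(th) * (rs$y - 47.5))
  expect_lt(max(d), 0.5)
})

test_that("width estimation matches the 1-D analytic gradient-extremum oracle", {
  for (sigma_line in c(1.5, 2)) {
    ci <- gaussian_line_image(64, sigma = sigma_line)
    rs <- detect_ridges(ci, params = ridge_params(
      expected_width_px = 2 * sigma_line, min_length_px = 10))
    rs <- estimate_widths(ci, rs)
    # oracle: dense scan of the analytic profile's gradient extrema
    d <- seq(0, 8, by = 1e-4)
    grad <- abs(d / sigma_line^2 * exp(-d^2 / (2 * sigma_line^2)))
    oracle <- 2 * d[which.max(grad)]   # = 2 sigma_line
    est <- mean(rs$width_px[rs$width_px > 0])
    expect_lt(abs(est - oracle) / oracle, 0.10)
  }
})

test_that("unresolvably thin lines are flagged width 0", {
  ci <- gaussian_line_image(64, row0 = 32, sigma = 0.45, amp = 1000)
  rs <- estimate_widths(ci, detect_ridges(ci, params = ridge_params(
    sigma_px = 1.2, min_length_px = 10)))
  expect_gte(mean(rs$width_px == 0), 0.9)
})

test_that("widths are unaffected by a parallel neighbour 20 px away", {
  n <- 96
  img1 <- matrix(0, n, n)
  for (r in seq_len(n)) img1[r, ] <- 100 * exp(-((r - 1) - 38)^2 / (2 * 1.5^2))
  img2 <- img1
  for (r in seq_len(n)) {
    img2[r, ] <- img2[r, ] + 100 * exp(-((r - 1) - 58)^2 / (2 * 1.5^2))
  }
  p <- ridge_params(sigma_px = 1.5, min_length_px = 10, max_width_px = 8)
  w1 <- estimate_widths(cell_image(img1, 0.1),
                        detect_ridges(cell_image(img1, 0.1), params = p))
  w2 <- estimate_widths(cell_image(img2, 0.1),
                        detect_ridges(cell_image(img2, 0.1), params = p))
  w2_top <- w2[abs(w2$y - 38) < 2, ]
  expect_lt(abs(mean(w2_top$width_px[w2_top$width_px > 0]) -
                mean(w1$width_px[w1$width_px > 0])), 0.15)
})

test_that("footprint areas follow the stamped geometry in both modes", {
  # hand-built straight ridge: 50 px long, width 3 px
  pts <- tibble::tibble(ridge_id = 1L, point_idx = 0:49,
                        x = 20 + (0:49), y = 40, tangent_deg = 0,
                        width_px = 3, response = 1)
  rs <- sarcnet:::as_ridge_set(pts, ridge_params(sigma_px = 1.5),
                               c(80, 100), 0.1)
  aw <- sum(ridge_footprint(rs, mode = "width"))
  expect_lt(abs(aw - 150) / 150, 0.10)
  ask <- sum(ridge_footprint(rs, mode = "skeleton"))
  expect_lt(abs(ask - 50) / 50, 0.10)
  expect_error(ridge_footprint(rs, mode = "bogus"))
})

test_that("raising the lower threshold never increases total length", {
  ci <- lattice_image()
  base <- detect_ridges(ci, params = ridge_params(sigma_px = 1.5,
                                                  min_length_px = 10))
  lens <- vapply(c(0.5, 1, 2, 4, 8), function(lo) {
    ridge_total_length(detect_ridges(ci, params = ridge_params(
      sigma_px = 1.5, min_length_px = 10,
      upper_thresh = 10, lower_thresh = lo)))
  }, numeric(1))
  expect_true(all(diff(lens) <= 1e-9))
})

test_that("detection is equivariant under 90-degree rotation", {
  ci <- lattice_image()
  rs <- detect_ridges(ci, params = ridge_params(sigma_px = 1.5,
                                                min_length_px = 10))
  rot <- cell_image(t(unclass(ci))[rev(seq_len(ncol(ci))), ], 0.1)
  rs_rot <- detect_ridges(rot, params = ridge_params(sigma_px = 1.5,
                                                     min_length_px = 10))
  n1 <- max(rs$ridge_id); n2 <- max(rs_rot$ridge_id)
  expect_lte(abs(n1 - n2), ceiling(0.05 * n1))
  shift <- abs(sarcnet:::fold_axial(stats::median(rs_rot$tangent_deg) -
                                    stats::median(rs$tangent_deg)))
  expect_lt(abs(shift - 90), 2)
})

test_that("noiseless lattices are recovered nearly completely and accurately", {
  ci <- lattice_image(nrow = 128, ncol = 96, spacing_px = 19, sigma = 1.5)
  rows0 <- attr(ci, "rows0")
  rs <- detect_ridges(ci, params = ridge_params(sigma_px = 1.5,
                                                min_length_px = 10))
  # every rendered line recovered: one polyline per lattice row
  expect_equal(max(rs$ridge_id), length(rows0))
  # lateral error below 0.5 px against the nearest true row
  err <- vapply(seq_len(nrow(rs)),
                function(i) min(abs(rs$y[i] - rows0)), numeric(1))
  expect_lt(max(err), 0.5)
  # >= 95% of the usable length (borders excluded) recovered
  expect_gte(ridge_total_length(rs), 0.95 * length(rows0) * (96 - 2 * 6))
})
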