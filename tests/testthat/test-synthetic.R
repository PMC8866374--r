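test_that("identical spec and seed give bit-identical image and truth", {
  sp <- synthetic_spec(pixel_size_um = 0.1, target_coverage_pct = 15,
                       seed = 42)
  a <- render_sarcomere_image(sp)
  b <- render_sarcomere_image(sp)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$truth$orientations, b$truth$orientations)
  expect_identical(a$truth$realized_coverage_pct,
                   b$truth$realized_coverage_pct)
})

test_that("rod masks reproduce the adult aspect ratio of ~5", {
  sp <- synthetic_spec(shape = "rod", cell_length_um = 100,
                       cell_width_um = 20, pixel_size_um = 0.1, seed = 1)
  sd <- shape_descriptors(make_cell_mask(sp), 0.1)
  expect_lt(abs(sd$aspect_ratio - 5), 0.1)
})

test_that("blobs degenerate to discs when irregularity vanishes", {
  sp <- synthetic_spec(shape = "blob", radius_um = 10, irregularity = 0,
                       pixel_size_um = 0.1, seed = 1)
  sd <- shape_descriptors(make_cell_mask(sp), 0.1)
  expect_gte(sd$circularity, 0.95)
})

test_that("high concentration pins orientations to the mean", {
  sp <- synthetic_spec(orient_mu_deg = 90, orient_kappa = 5000,
                       pixel_size_um = 0.1, target_coverage_pct = 15,
                       seed = 2)
  out <- render_sarcomere_image(sp)
  # axial distance to 90 degrees
  d <- abs(sarcnet:::fold_axial(out$truth$orientations$delta_deg - 90))
  expect_lt(max(d), 3)
})

test_that("realized coverage tracks the target within half a point", {
  for (target in c(15, 23.13, 32)) {
    out <- render_sarcomere_image(synthetic_spec(
      pixel_size_um = 0.1, target_coverage_pct = target, seed = 3))
    expect_lt(abs(out$truth$realized_coverage_pct - target), 0.5)
    expect_false(out$truth$saturated)
  }
})

test_that("an exhausted placement budget saturates with a flag and a value", {
  sp <- synthetic_spec(pixel_size_um = 0.1, target_coverage_pct = 60,
                       segment_length_range_um = c(1.5, 2),
                       max_bundles = 40L, seed = 4)
  out <- render_sarcomere_image(sp)
  expect_true(out$truth$saturated)
  expect_lt(out$truth$realized_coverage_pct, 60)
  expect_gt(out$truth$realized_coverage_pct, 0)
})

test_that("doubling the spacing halves the line density along the bundle axis", {
  lines_per_um <- function(spacing) {
    out <- render_sarcomere_image(synthetic_spec(
      spacing_um = spacing, pixel_size_um = 0.1,
      target_coverage_pct = 15, seed = 5))
    seg <- out$truth$segments
    seg$cx <- (seg$x1 + seg$x2) / 2; seg$cy <- (seg$y1 + seg$y2) / 2
    per <- split(seg, seg$bundle)
    per <- per[vapply(per, nrow, integer(1)) >= 3]
    mean(vapply(per, function(d) {
      extent <- sqrt((max(d$cx) - min(d$cx))^2 + (max(d$cy) - min(d$cy))^2)
      (nrow(d) - 1) / (extent * 0.1)
    }, numeric(1)))
  }
  r <- lines_per_um(1.5) / lines_per_um(3.0)
  expect_lt(abs(r - 2) / 2, 0.05)
})

test_that("recorded ground-truth coverage equals an independent pixel oracle", {
  out <- render_sarcomere_image(synthetic_spec(
    shape = "rod", cell_length_um = 20, cell_width_um = 8,
    pixel_size_um = 0.1, target_coverage_pct = 20, seed = 6))
  m <- matrix(as.logical(out$truth$mask), nrow(out$truth$mask))
  seg <- out$truth$segments
  h <- nrow(m); w <- ncol(m)
  px <- rep(seq_len(w) - 1, each = h)
  py <- rep(seq_len(h) - 1, times = w)
  # brute force: minimum distance of every pixel centre to any segment
  covered <- rep(FALSE, h * w)
  for (i in seq_len(nrow(seg))) {
    d <- sarcnet:::dist_point_segment(px, py, seg$x1[i], seg$y1[i],
                                      seg$x2[i], seg$y2[i])
    covered <- covered | (d <= out$truth$sigma_eff_px)
  }
  oracle <- 100 * sum(matrix(covered, h, w) & m) / sum(m)
  expect_equal(out$truth$realized_coverage_pct, oracle, tolerance = 1e-12)
})

test_that("realized axial mean converges to mu at high concentration", {
  out <- render_sarcomere_image(synthetic_spec(
    orient_mu_deg = 86.08, orient_kappa = 8, pixel_size_um = 0.1,
    cell_length_um = 50, cell_width_um = 15,
    target_coverage_pct = 30, seed = 7))
  ors <- out$truth$orientations
  expect_gte(nrow(ors), 300)
  m <- axial_mean(ors$delta_deg, ors$length_um)$mean_deg
  # one orientation draw per *bundle*: bound the deviation at 3 standard
  # errors of the axial von Mises mean over the realized bundle count
  n_b <- length(unique(ors$bundle))
  sd_axial <- sqrt(-2 * log(sarcnet:::bessel_A(8))) / 2 * 180 / pi
  expect_lt(abs(abs(m) - 86.08), 3 * sd_axial / sqrt(n_b))
  # and the sampler itself obeys the law of large numbers at n = 500
  draws <- withr::with_seed(7, sarcnet:::rvonmises_axial_deg(500, 86.08, 8))
  expect_lt(abs(abs(axial_mean(draws)$mean_deg) - 86.08), 2)
})

test_that("presets differ in the documented directions", {
  ad <- synthetic_preset("adult", seed = 1)
  st <- synthetic_preset("stancon", seed = 1)
  expect_equal(ad$shape, "rod")
  expect_equal(st$shape, "blob")
  expect_gt(ad$orient_kappa, st$orient_kappa)
  expect_gt(ad$target_coverage_pct, st$target_coverage_pct)
})

test_that("fixture sets are written completely and reproducibly", {
  dir <- withr::local_tempdir()
  config <- list(
    tiny = list(spec = synthetic_spec(shape = "rod", cell_length_um = 20,
                                      cell_width_um = 8, pixel_size_um = 0.1,
                                      target_coverage_pct = 15, seed = 10),
                n = 2),
    blobby = list(spec = synthetic_spec(shape = "blob", radius_um = 6,
                                        pixel_size_um = 0.1,
                                        target_coverage_pct = 15, seed = 20),
                  n = 1))
  man <- emit_fixture_set(config, file.path(dir, "fx"))
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(file.path(dir, "fx", man$image))))
  expect_true(all(file.exists(file.path(dir, "fx", man$mask))))
  expect_true(all(file.exists(file.path(dir, "fx", man$truth))))
  expect_true(file.exists(file.path(dir, "fx", "manifest.csv")))
  # refusal without force, reproducibility with it
  expect_error(emit_fixture_set(config, file.path(dir, "fx")), "force")
  j1 <- readLines(file.path(dir, "fx", man$truth[1]))
  emit_fixture_set(config, file.path(dir, "fx"), force = TRUE)
  expect_identical(readLines(file.path(dir, "fx", man$truth[1])), j1)
})

test_that("spec validation rejects unresolvable or out-of-range settings", {
  expect_error(synthetic_spec(pixel_size_um = 0.2, zdisc_fwhm_um = 0.2),
               "resolvable")
  expect_error(synthetic_spec(target_coverage_pct = 80), "coverage")
  expect_error(synthetic_spec(spacing_um = 0), "spacing")
  expect_error(make_cell_mask(synthetic_spec(cell_length_um = 40,
                                             margin_um = 0,
                                             pixel_size_um = 0.1)),
               "frame")
})
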