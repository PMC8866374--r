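test_that("TIFF images round-trip bit-identically with calibration attached", {
  img <- matrix(sample.int(65535, 64 * 64, replace = TRUE) - 1L, 64, 64)
  ci <- cell_image(img, 0.1, id = "rt")
  path <- withr::local_tempfile(fileext = ".tif")
  write_cell_image(ci, path)
  back <- read_cell_image(path, 0.1)
  expect_identical(unname(back[, ]), unname(matrix(as.numeric(img), 64, 64)))
  expect_equal(pixel_size(back), 0.1)
})

test_that("degenerate rasters read as stored", {
  path <- withr::local_tempfile(fileext = ".tif")
  write_cell_image(cell_image(matrix(0, 64, 64), 0.1), path)
  expect_equal(max(read_cell_image(path, 0.1)), 0)

  one <- matrix(0, 64, 64); one[10, 20] <- 65535
  write_cell_image(cell_image(one, 0.1), path)
  expect_equal(max(read_cell_image(path, 0.1)), 65535)
})

test_that("multi-channel images require an explicit channel", {
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(32 * 32 * 3), dim = c(32, 32, 3)), path)
  expect_error(read_cell_image(path, 0.1), "channel")
  expect_s3_class(read_cell_image(path, 0.1, channel = 2), "cell_image")
})

test_that("cell_image validates its invariants", {
  expect_error(cell_image(matrix(0, 10, 10), 0.1), "32 x 32")
  expect_error(cell_image(matrix(0, 64, 64), -1), "positive")
  expect_error(cell_image(matrix(c(NA, rep(0, 64 * 64 - 1)), 64, 64), 0.1),
               "finite")
})

test_that("polygon rasterisation follows the centres-inside rule", {
  # full-frame polygon
  m <- rasterize_polygon(cbind(c(-0.5, 31.5, 31.5, -0.5),
                               c(-0.5, -0.5, 31.5, 31.5)), c(32, 32))
  expect_true(all(m))
  # axis-aligned 10x10 square -> exactly 100 pixels
  sq <- rasterize_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), c(32, 32))
  expect_equal(sum(sq), 100)
  # circle radius 20 px: area within 2% of pi r^2
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  circ <- rasterize_polygon(cbind(25 + 20 * cos(th), 25 + 20 * sin(th)),
                            c(50, 50))
  expect_lt(abs(sum(circ) - pi * 400) / (pi * 400), 0.02)
})

test_that("self-intersecting polygons are rejected", {
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(rasterize_polygon(bowtie, c(20, 20)), "self-intersecting")
})

test_that("mask files and polygon JSON load and validate", {
  m <- disc_mask(radius = 12, pad = 6)
  path <- withr::local_tempfile(fileext = ".png")
  write_cell_mask(m, path)
  back <- read_cell_mask(path, dim(m))
  expect_identical(unname(back[, ]), unname(m))
  expect_error(read_cell_mask(path, dim(m) + 5), "shape")

  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    vertices = cbind(c(2, 20, 20, 2), c(2, 2, 20, 20))), digits = NA), jpath)
  pm <- read_cell_mask(jpath, c(36, 36))
  expect_equal(sum(pm), 18 * 18)
  expect_equal(attr(pm, "provenance"), "polygon")
})

test_that("cell_mask enforces size and connectivity", {
  expect_error(cell_mask(matrix(FALSE, 20, 20)), "100")
  two <- matrix(FALSE, 40, 40)
  two[2:15, 2:15] <- TRUE; two[25:38, 25:38] <- TRUE
  expect_error(cell_mask(two), "connected")
  expect_s3_class(cell_mask(two, largest = TRUE), "cell_mask")
  # a filled-hole donut is one component
  donut <- disc_mask(12, 6); donut[15:21, 15:21] <- FALSE
  expect_s3_class(cell_mask(donut), "cell_mask")
})

test_that("reports round-trip metric values losslessly in CSV and JSON", {
  rec <- tibble::tibble(id = c("a", "b"),
                        density_pct = c(23.13, 1 / 3),
                        sarcomere_length_um = c(1.9000001, 2.123456789))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(rec, csv)
  expect_equal(read_report(csv), rec)
  jsn <- withr::local_tempfile(fileext = ".json")
  write_report(rec, jsn)
  expect_equal(as.data.frame(read_report(jsn)), as.data.frame(rec))
})

test_that("report writer handles edge cases", {
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(tibble::tibble(id = character(0), d = numeric(0)), csv)
  expect_identical(readLines(csv), "id,d")

  recs <- lapply(1:50, function(i) list(id = i, v = i / 7))
  jsn <- withr::local_tempfile(fileext = ".json")
  write_report(recs, jsn)
  expect_equal(nrow(read_report(jsn)), 50)

  expect_error(write_report(list(list(a = 1), list(b = 2)), csv),
               "heterogeneous")
})

test_that("calcium traces validate sampling and load from CSV", {
  expect_error(calcium_trace(1:10, 1:10), "50")
  t_bad <- c(seq(0, 48), 50.5)
  expect_error(calcium_trace(t_bad, rep(0, 50)), "uniform")
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(t_ms = seq(0, 990, by = 10),
                                  f = rnorm(100)), csv)
  expect_s3_class(read_calcium_trace(csv), "calcium_trace")
  # frame-indexed input with fps
  readr::write_csv(tibble::tibble(frame = 0:99, f = rnorm(100)), csv)
  tr <- read_calcium_trace(csv, fps = 83)
  expect_equal(tr$t_ms[2] - tr$t_ms[1], 1000 / 83)
})
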