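test_that("axial means follow the doubled-angle construction", {
  expect_equal(axial_mean(30)$mean_deg, 30)
  expect_equal(axial_mean(30)$r_bar, 1)
  # antipodal on the doubled circle: resultant vanishes
  deg <- axial_mean(c(0, 90))
  expect_lt(deg$r_bar, 1e-12)
  expect_true(is.na(deg$mean_deg))
  expect_true(deg$dispersed)
  # {80, 90, -80}: doubled {160, 180, -160} average to 180 -> 90 axial
  expect_equal(axial_mean(c(80, 90, -80))$mean_deg, 90, tolerance = 1e-6)
})

test_that("axial statistics are invariant under 180-degree shifts", {
  a <- withr::with_seed(3, stats::runif(50, -90, 90))
  m1 <- axial_mean(a)
  m2 <- axial_mean(a + 180)
  expect_equal(m1$mean_deg, m2$mean_deg, tolerance = 1e-9)
  expect_equal(m1$r_bar, m2$r_bar, tolerance = 1e-12)
})

test_that("kappa inversion reproduces A(kappa) across the range", {
  for (k in c(0.2, 1, 4, 50, 800)) {
    r <- besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
    expect_lt(abs(sarcnet:::kappa_ml(r) - k) / k, 1e-6)
  }
  expect_equal(sarcnet:::kappa_ml(0), 0)
  expect_equal(sarcnet:::kappa_ml(1), Inf)
})

test_that("the Watson-Williams statistic matches an independent evaluation", {
  g1 <- c(10, 20, 30, 15, 25)
  g2 <- c(40, 50, 60, 45, 55)
  ww <- watson_williams(list(g1, g2))

  # independent oracle: direct formula evaluation with its own kappa solver
  res <- function(a) {
    a2 <- 2 * a * pi / 180
    c(sum(cos(a2)), sum(sin(a2)))
  }
  r1 <- res(g1); r2 <- res(g2)
  R1 <- sqrt(sum(r1^2)); R2 <- sqrt(sum(r2^2))
  Rp <- sqrt(sum((r1 + r2)^2))
  N <- 10; r <- 2
  rbw <- (R1 + R2) / N
  kap <- stats::uniroot(function(k) besselI(k, 1) / besselI(k, 0) - rbw,
                        c(1e-6, 500), tol = 1e-12)$root
  K <- 1 + 3 / (8 * kap)
  F_oracle <- K * (N - r) * (R1 + R2 - Rp) / ((r - 1) * (N - R1 - R2))
  p_oracle <- stats::pf(F_oracle, 1, 8, lower.tail = FALSE)

  expect_equal(ww$F_stat, F_oracle, tolerance = 1e-8)
  expect_equal(ww$p_value, p_oracle, tolerance = 1e-8)
  expect_equal(ww$df1, 1)
  expect_equal(ww$df2, 8)
})

test_that("duplicated groups give F = 0, p = 1", {
  g <- c(10, 25, 40, 18, 33, 27)
  ww <- watson_williams(list(a = g, b = g))
  expect_equal(ww$F_stat, 0, tolerance = 1e-9)
  expect_equal(ww$p_value, 1, tolerance = 1e-9)
})

test_that("the test is invariant under a common rotation of all groups", {
  a <- withr::with_seed(5, sarcnet:::rvonmises_axial_deg(30, 40, 4))
  b <- withr::with_seed(6, sarcnet:::rvonmises_axial_deg(30, 60, 4))
  f0 <- watson_williams(list(a, b))$F_stat
  f1 <- watson_williams(list(a + 25, b + 25))$F_stat
  f2 <- watson_williams(list(a + 180, b + 180))$F_stat
  expect_equal(f0, f1, tolerance = 1e-9)
  expect_equal(f0, f2, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(watson_williams(list(c(1, 2, 3, 4, 5))), "2 groups")
  expect_error(watson_williams(list(c(1, 2), c(3, 4))), "at least")
  expect_error(
    watson_williams(list(rep(30, 6), c(10, 20, 30, 40, 50, 60))),
    "dispersion")
})

test_that("data-frame input and tidiers work", {
  d <- tibble::tibble(
    angle_deg = c(withr::with_seed(1, sarcnet:::rvonmises_axial_deg(20, 40, 6)),
                  withr::with_seed(2, sarcnet:::rvonmises_axial_deg(20, 70, 6))),
    group = rep(c("a", "b"), each = 20))
  ww <- watson_williams(d)
  td <- tidy(ww)
  expect_equal(nrow(td), 2)
  expect_equal(td$n, c(20, 20))
  gl <- glance(ww)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("statistic", "p.value", "kappa", "R_bar") %in% names(gl)))
  expect_lt(gl$p.value, 0.001)  # 50-degree separation at kappa 6 is detectable
})

test_that("rose re-binning conserves mass and places it correctly", {
  pts <- tibble::tibble(ridge_id = 1:3, point_idx = 0L, x = 0, y = 0,
                        tangent_deg = c(5, 5, -33), width_px = NA_real_,
                        response = 1)
  rs <- sarcnet:::as_ridge_set(pts, ridge_params(), c(10, 10), 0.1)
  h <- orientation_histogram(rs, axis_deg = 0, bin_width_deg = 2,
                             weighting = "count")
  rose <- rose_counts(h, 10)
  expect_equal(sum(rose$weight), sum(h$weight))
  expect_equal(rose$weight[rose$bin_center_deg == 5], 2)   # (0, 10]
  expect_equal(rose$weight[rose$bin_center_deg == -35], 1) # (-40, -30]
  expect_error(rose_counts(h, 7), "divide")
  expect_error(rose_counts(h, 3), "multiple")
  # uniform fine histogram re-bins to equal rose bins
  h$weight <- rep(1, nrow(h))
  attr(h, "n_eff") <- sum(h$weight)
  r2 <- rose_counts(h, 10)
  expect_lt(max(r2$weight) - min(r2$weight), 1e-9)
})
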