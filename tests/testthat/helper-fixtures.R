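# shared in-code fixtures; everything is generated at test time

# horizontal line with Gaussian transverse profile centred on row `row0`
# (0-based), optionally rotated by `angle_deg`
gaussian_line_image <- function(n = 64, row0 = (n - 1) / 2, sigma = 1.5,
                                amp = 100, angle_deg = 0,
                                pixel_size_um = 0.1) {
  th <- angle_deg / 180 * pi
  c0 <- (n - 1) / 2
  img <- matrix(0, n, n)
  for (r in seq_len(n)) {
    y <- r - 1
    x <- seq_len(n) - 1
    d <- -sin(th) * (x - c0) + cos(th) * (y - row0)
    img[r, ] <- amp * exp(-d^2 / (2 * sigma^2))
  }
  cell_image(img, pixel_size_um)
}

# stack of parallel horizontal Gaussian lines (a 1-D sarcomere lattice)
lattice_image <- function(nrow = 128, ncol = 96, spacing_px = 19,
                          sigma = 1.5, amp = 100, pixel_size_um = 0.1) {
  img <- matrix(0, nrow, ncol)
  rows0 <- seq(10, nrow - 11, by = spacing_px)
  for (r0 in rows0) {
    for (r in seq_len(nrow)) {
      img[r, ] <- img[r, ] + amp * exp(-((r - 1) - r0)^2 / (2 * sigma^2))
    }
  }
  structure(cell_image(img, pixel_size_um), rows0 = rows0)
}

disc_mask <- function(radius = 50, pad = 20) {
  n <- 2 * (radius + pad)
  c0 <- (n - 1) / 2
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  matrix((g$r - 1 - c0)^2 + (g$c - 1 - c0)^2 <= radius^2, n, n)
}

rect_mask <- function(h_px = 10, w_px = 50, pad = 15) {
  m <- matrix(FALSE, h_px + 2 * pad, w_px + 2 * pad)
  m[pad + seq_len(h_px), pad + seq_len(w_px)] <- TRUE
  m
}

full_mask <- function(shape) matrix(TRUE, shape[1], shape[2])

# default generator settings used across recovery tests: the study
# conditions (pixel size, FWHM, SNR) stated for the emulated acquisitions
test_rod_spec <- function(seed, spacing_um = 1.90, mu = 86.08, kappa = 8,
                          coverage = 30, pixel_size_um = 0.05) {
  synthetic_spec(shape = "rod", cell_length_um = 40, cell_width_um = 12,
                 spacing_um = spacing_um, orient_mu_deg = mu,
                 orient_kappa = kappa, target_coverage_pct = coverage,
                 zdisc_fwhm_um = 0.2, psf_sigma_um = 0.08,
                 amplitude = 1000, noise_sd = 200,
                 pixel_size_um = pixel_size_um, seed = seed)
}

test_blob_spec <- function(seed, coverage = 23.13, pixel_size_um = 0.05) {
  synthetic_spec(shape = "blob", radius_um = 10, irregularity = 0.2,
                 spacing_um = 1.80, orient_mu_deg = 42.07,
                 orient_kappa = 1.5, target_coverage_pct = coverage,
                 zdisc_fwhm_um = 0.2, psf_sigma_um = 0.08,
                 amplitude = 1000, noise_sd = 200,
                 pixel_size_um = pixel_size_um, seed = seed)
}
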