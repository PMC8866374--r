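# Internal numerical helpers shared across modules.
#
# Conventions (package-wide):
#  * rasters are numeric matrices, [row, col]; row index is y, column index is x
#  * pixel coordinates are 0-based: pixel (i, j) (1-based R indices) has
#    centre (x, y) = (j - 1, i - 1)
#  * angles are in degrees, counter-clockwise from the +x (column) axis
#  * orientations are axial (period 180 deg) and folded to [-90, 90)

DEG <- 180 / pi

#' @noRd
fold_axial <- function(a) {
  ((a + 90) %% 180) - 90
}

# fold into (-90, 90]: the convention used for signed relative-angle histograms
#' @noRd
fold_axial_right <- function(a) {
  f <- fold_axial(a)
  f[f == -90] <- 90
  f
}

#' @noRd
deg_atan2 <- function(y, x) atan2(y, x) * DEG

# --- Gaussian derivative kernels -------------------------------------------

# 1-D sampled Gaussian and its first/second derivatives, radius 3.5 sigma.
#' @noRd
gauss_kernel_1d <- function(sigma, order = 0L) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3.5 * sigma))
  t <- seq(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = -t / sigma^2 * g,
    "2" = (t^2 - sigma^2) / sigma^4 * g,
    stop("order must be 0, 1 or 2")
  )
}

# Separable Gaussian-derivative filtering of a matrix (y = rows, x = cols).
# order = c(order_x, order_y). Boundary: replicate.
#' @noRd
gauss_filter <- function(img, sigma, order = c(0L, 0L)) {
  kx <- gauss_kernel_1d(sigma, order[1])
  ky <- gauss_kernel_1d(sigma, order[2])
  # kernel varies along columns for x, along rows for y
  k <- outer(ky, kx)
  conv2_replicate(img, k)
}

# FFT convolution with replicated borders via EBImage, plain-matrix in/out.
# EBImage::filter2 computes correlation with the kernel centred; our kernels
# are built so that positive x-derivative responds positively to intensity
# increasing with column index (verified in tests).
#' @noRd
conv2_replicate <- function(img, k) {
  out <- EBImage::filter2(img, k, boundary = "replicate")
  matrix(as.numeric(out), nrow = nrow(img), ncol = ncol(img))
}

# --- interpolation ----------------------------------------------------------

# Vectorised bilinear interpolation at 0-based (x, y); coordinates are clamped
# to the image domain.
#' @noRd
bilinear_at <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), h - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Vectorised Catmull-Rom bicubic interpolation at 0-based (x, y). Unlike
# bilinear interpolation this is C1, so extrema of sampled profiles do not
# snap to grid nodes; used wherever sub-pixel extremum positions matter.
# Falls back to edge clamping within a 1-px margin.
#' @noRd
bicubic_at <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(pmax(floor(x), 1), w - 3)
  y0 <- pmin(pmax(floor(y), 1), h - 3)
  fx <- x - x0; fy <- y - y0
  cw <- function(f) {
    f2 <- f * f; f3 <- f2 * f
    list(0.5 * (-f3 + 2 * f2 - f),
         0.5 * (3 * f3 - 5 * f2 + 2),
         0.5 * (-3 * f3 + 4 * f2 + f),
         0.5 * (f3 - f2))
  }
  wx <- cw(fx); wy <- cw(fy)
  out <- numeric(length(x))
  for (j in 0:3) {
    col1 <- x0 + j  # 1-based column index of tap (x0 - 1 + j)
    acc <- wy[[1]] * img[cbind(y0,     col1)] +
           wy[[2]] * img[cbind(y0 + 1, col1)] +
           wy[[3]] * img[cbind(y0 + 2, col1)] +
           wy[[4]] * img[cbind(y0 + 3, col1)]
    out <- out + wx[[j + 1]] * acc
  }
  out
}

# 2x bicubic supersampling: output pixel (i', j') 0-based sits at original
# position (i'/2, j'/2); size (2h-1) x (2w-1)
#' @noRd
upsample2 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  h2 <- 2 * h - 1; w2 <- 2 * w - 1
  xs <- rep((seq_len(w2) - 1) / 2, each = h2)
  ys <- rep((seq_len(h2) - 1) / 2, times = w2)
  matrix(bicubic_at(img, xs, ys), h2, w2)
}

# --- 1-D peak finding -------------------------------------------------------

# Local maxima with topographic prominence and a minimum peak separation.
# Returns integer indices, ordered by position. Prominence of a peak is its
# height above the higher of the two deepest valleys separating it from
# higher terrain (or the signal end).
#' @noRd
find_peaks <- function(y, min_prominence = 0, min_distance = 1L) {
  n <- length(y)
  if (n < 3) return(integer(0))
  is_peak <- which(diff(sign(diff(y))) < 0) + 1L
  # plateaus: keep leading edge of flat tops
  is_peak <- is_peak[y[is_peak] > y[pmax(is_peak - 1L, 1L)] |
                     y[is_peak] > y[pmin(is_peak + 1L, n)]]
  if (!length(is_peak)) return(integer(0))
  prom <- vapply(is_peak, function(p) {
    hp <- y[p]
    l <- p; lmin <- hp
    while (l > 1L && y[l] <= hp) { l <- l - 1L; lmin <- min(lmin, y[l]) }
    if (y[l] <= hp) lmin <- min(lmin, y[l])
    r <- p; rmin <- hp
    while (r < n && y[r] <= hp) { r <- r + 1L; rmin <- min(rmin, y[r]) }
    if (y[r] <= hp) rmin <- min(rmin, y[r])
    hp - max(lmin, rmin)
  }, numeric(1))
  keep <- is_peak[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  # enforce separation, keeping taller peaks first
  ord <- keep[order(y[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (p in ord) {
    if (!length(chosen) || all(abs(chosen - p) >= min_distance)) {
      chosen <- c(chosen, p)
    }
  }
  sort(chosen)
}

# Sub-pixel refinement of a sampled extremum by parabolic interpolation.
# Returns offset in samples, clamped to [-0.5, 0.5].
#' @noRd
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  off <- ifelse(abs(den) < .Machine$double.eps, 0, 0.5 * (ym1 - yp1) / den)
  pmin(pmax(off, -0.5), 0.5)
}

# --- circular sampling and concentration -----------------------------------

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy envelope), radians.
#' @noRd
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.6))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    out <- c(out, th[ok])
  }
  out[seq_len(n)] + mu
}

# Axial von Mises sample in degrees: delta = phi/2 with phi ~ VM(2 mu, kappa),
# folded to [-90, 90).
#' @noRd
rvonmises_axial_deg <- function(n, mu_deg, kappa) {
  phi <- rvonmises(n, 2 * mu_deg / DEG, kappa)
  fold_axial(phi / 2 * DEG)
}

# A(kappa) = I1(kappa)/I0(kappa), numerically stable.
#' @noRd
bessel_A <- function(kappa) {
  ifelse(kappa > 1e3,
    1 - 1 / (2 * kappa) - 1 / (8 * kappa^2) - 1 / (8 * kappa^3),
    besselI(kappa, 1, expon.scaled = TRUE) /
      besselI(kappa, 0, expon.scaled = TRUE))
}

# Maximum-likelihood concentration: invert A(kappa) = r_bar by Newton
# iteration from the Banerjee et al. starting value.
#' @noRd
kappa_ml <- function(r_bar, tol = 1e-10, max_iter = 100L) {
  if (!is.finite(r_bar) || r_bar <= 0) return(0)
  if (r_bar >= 1 - 1e-12) return(Inf)
  k <- r_bar * (2 - r_bar^2) / (1 - r_bar^2)
  for (i in seq_len(max_iter)) {
    A <- bessel_A(k)
    Ap <- 1 - A / k - A^2
    step <- (A - r_bar) / Ap
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < tol * max(1, k)) return(k_new)
    k <- k_new
  }
  warning("kappa ML inversion did not reach tolerance; returning last iterate")
  k
}

# weighted mean / SEM helpers used in cohort summaries
#' @noRd
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
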