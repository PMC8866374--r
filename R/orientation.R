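# Filament orientation relative to the cell's long axis.
#
# The dense orientation source is the structure tensor: Gaussian gradients
# (scale grad_sigma) are accumulated into J = G_sigma * (grad I grad I^T);
# the dominant *structure* orientation at a pixel is perpendicular to the
# dominant gradient direction, i.e. along the line. Energy (trace of J)
# and coherence ((l1 - l2)/(l1 + l2)) weight the histogram so that
# structured, anisotropic pixels dominate and background contributes
# nothing. Ridge tangents provide a sparse, length-weighted cross-check.
# All downstream statistics are axial (period 180 deg).

#' Per-pixel structure-tensor orientation field
#'
#' @param image A [cell_image()] (or matrix).
#' @param mask Optional [cell_mask()]; retained in the result for
#'   downstream masking (the tensor itself is computed everywhere).
#' @param tensor_sigma_px Integration scale of the tensor smoothing; a good
#'   default is the expected z-disc width in pixels.
#' @param grad_sigma_px Differentiation scale for the gradients.
#' @return An `orientation_field`: list of matrices `theta_deg` (line
#'   orientation, axial, \[-90, 90)), `energy` (tensor trace), `coherence`
#'   (\[0, 1\]), plus `mask`.
#' @export
orientation_field <- function(image, mask = NULL, tensor_sigma_px = 2,
                              grad_sigma_px = 1) {
  if (tensor_sigma_px <= 0) stop("tensor_sigma_px must be > 0", call. = FALSE)
  img <- unclass(image); attributes(img) <- attributes(img)["dim"]
  gx <- gauss_filter(img, grad_sigma_px, c(1L, 0L))
  gy <- gauss_filter(img, grad_sigma_px, c(0L, 1L))
  Jxx <- gauss_filter(gx * gx, tensor_sigma_px)
  Jxy <- gauss_filter(gx * gy, tensor_sigma_px)
  Jyy <- gauss_filter(gy * gy, tensor_sigma_px)
  tr <- Jxx + Jyy
  # dominant gradient orientation + 90 deg = line orientation
  theta <- fold_axial(0.5 * deg_atan2(2 * Jxy, Jxx - Jyy) + 90)
  coher <- ifelse(tr > 1e-12 * max(tr, 1e-300),
                  sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / tr, 0)
  structure(list(theta_deg = theta, energy = tr, coherence = coher,
                 mask = if (is.null(mask)) NULL else {
                   matrix(as.logical(mask), nrow(img), ncol(img))
                 }),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field %d x %d px, median coherence %.2f>\n",
              nrow(x$theta_deg), ncol(x$theta_deg),
              stats::median(x$coherence)))
  invisible(x)
}

#' Tidy view of an orientation field
#' @param x An `orientation_field`.
#' @param ... Unused.
#' @return Tibble with `x`, `y` (0-based), `theta_deg`, `energy`,
#'   `coherence`, `in_mask`.
#' @method as_tibble orientation_field
#' @export
as_tibble.orientation_field <- function(x, ...) {
  h <- nrow(x$theta_deg); w <- ncol(x$theta_deg)
  tibble::tibble(
    x = rep(seq_len(w) - 1L, each = h),
    y = rep(seq_len(h) - 1L, times = w),
    theta_deg = as.numeric(x$theta_deg),
    energy = as.numeric(x$energy),
    coherence = as.numeric(x$coherence),
    in_mask = if (is.null(x$mask)) TRUE else as.logical(x$mask)
  )
}

#' Histogram of filament orientation relative to the cell axis
#'
#' The relative angle `delta = fold(theta - axis)` is binned over
#' (-90, 90]. With a structure-tensor source the per-pixel weight is
#' `energy x coherence` (a pure-count mode exists for ridge tangents, where
#' the natural weight is segment length instead).
#'
#' @param source An `orientation_field` or a `ridge_set`.
#' @param mask Optional [cell_mask()]; required if neither `source` nor this
#'   argument carries one for a field source.
#' @param axis_deg Cell long-axis orientation in degrees (\[-90, 90)).
#' @param bin_width_deg Bin width; must divide 180 (default 2).
#' @param weighting `"energy_coherence"` (field), `"length"` (ridges) or
#'   `"count"`.
#' @return An `orientation_histogram` tibble: `bin_center_deg`, `weight`;
#'   attributes `bin_width_deg`, `n_eff`, `source`, `axis_deg`.
#' @export
orientation_histogram <- function(source, mask = NULL, axis_deg = 0,
                                  bin_width_deg = 2, weighting = NULL) {
  if (axis_deg < -90 || axis_deg >= 90) {
    stop("axis_deg must lie in [-90, 90)", call. = FALSE)
  }
  if (180 %% bin_width_deg != 0) {
    stop("bin_width_deg must divide 180", call. = FALSE)
  }
  if (inherits(source, "orientation_field")) {
    weighting <- weighting %||% "energy_coherence"
    m <- if (!is.null(mask)) matrix(as.logical(mask), nrow(source$theta_deg))
         else source$mask
    if (is.null(m)) stop("a mask is required for a field source", call. = FALSE)
    if (!any(m)) stop("empty mask", call. = FALSE)
    theta <- source$theta_deg[m]
    wgt <- switch(weighting,
      energy_coherence = (source$energy * source$coherence)[m],
      count = rep(1, sum(m)),
      stop("unknown weighting for field source: ", weighting))
    src_name <- "structure_tensor"
  } else if (inherits(source, "ridge_set")) {
    weighting <- weighting %||% "length"
    if (!nrow(source)) stop("empty ridge set", call. = FALSE)
    theta <- source$tangent_deg
    wgt <- switch(weighting,
      length = point_lengths(source),
      count = rep(1, nrow(source)),
      stop("unknown weighting for ridge source: ", weighting))
    src_name <- "ridge_tangent"
  } else {
    stop("source must be an orientation_field or ridge_set", call. = FALSE)
  }
  delta <- fold_axial_right(theta - axis_deg)
  edges <- seq(-90, 90, by = bin_width_deg)
  idx <- findInterval(delta, edges, left.open = TRUE, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  wsum <- vapply(seq_len(length(edges) - 1),
                 function(k) sum(wgt[idx == k]), numeric(1))
  out <- tibble::tibble(
    bin_center_deg = (edges[-1] + edges[-length(edges)]) / 2,
    weight = wsum
  )
  attr(out, "bin_width_deg") <- bin_width_deg
  attr(out, "n_eff") <- sum(wsum)
  attr(out, "source") <- src_name
  attr(out, "axis_deg") <- axis_deg
  class(out) <- c("orientation_histogram", class(out))
  out
}

# per-point polyline length weights (half of each adjacent segment);
# assumes rows ordered by (ridge_id, point_idx), as detect_ridges emits them
#' @noRd
point_lengths <- function(ridges) {
  unlist(lapply(split(seq_len(nrow(ridges)), ridges$ridge_id), function(ii) {
    if (length(ii) == 1) return(0)
    seg <- sqrt(diff(ridges$x[ii])^2 + diff(ridges$y[ii])^2)
    (c(seg, 0) + c(0, seg)) / 2
  }), use.names = FALSE)
}

#' Main direction and interval fractions of an orientation histogram
#'
#' Axial circular mean on doubled bin-centre angles; the main direction is
#' reported as the absolute relative angle in \[0, 90\] (90 deg = filaments
#' perpendicular to the cell axis, the mature configuration). Fractions of
#' mass in the |delta| bands \[0, 30), \[30, 60), \[60, 90\] sum to one, and
#' the orientation category is `low` (< 30), `medium` or `high` (>= 60).
#'
#' @param hist An `orientation_histogram`.
#' @return One-row tibble of class `directionality_result`:
#'   `main_direction_deg`, `resultant_length`, `frac_0_30`, `frac_30_60`,
#'   `frac_60_90`, `orientation_category`, `dispersed` (`TRUE` when the
#'   axial resultant length is below 0.05 and the mean is unstable).
#' @export
main_direction <- function(hist) {
  n_eff <- attr(hist, "n_eff")
  if (is.null(n_eff) || n_eff <= 0) stop("histogram has no mass", call. = FALSE)
  am <- axial_mean(hist$bin_center_deg, hist$weight)
  theta_bar <- if (is.na(am$mean_deg)) NA_real_ else abs(am$mean_deg)
  adeg <- abs(hist$bin_center_deg)
  f1 <- sum(hist$weight[adeg < 30]) / n_eff
  f2 <- sum(hist$weight[adeg >= 30 & adeg < 60]) / n_eff
  f3 <- sum(hist$weight[adeg >= 60]) / n_eff
  category <- if (is.na(theta_bar)) NA_character_
    else if (theta_bar < 30) "low"
    else if (theta_bar >= 60) "high"
    else "medium"
  out <- tibble::tibble(
    main_direction_deg = theta_bar,
    resultant_length = am$r_bar,
    frac_0_30 = f1, frac_30_60 = f2, frac_60_90 = f3,
    orientation_category = category,
    dispersed = am$dispersed
  )
  class(out) <- c("directionality_result", class(out))
  out
}

#' Colour-coded orientation map
#'
#' Hue encodes the relative angle on a 180-degree-periodic wheel,
#' saturation the coherence, and value the energy (gamma-compressed to the
#' 99th percentile). A colour-wheel legend raster is attached as attribute
#' `"wheel"`.
#'
#' @param field An `orientation_field`.
#' @param mask Optional [cell_mask()]; outside pixels are black.
#' @param axis_deg Reference axis subtracted before colouring (default 0:
#'   absolute orientations).
#' @return An `rows x cols x 3` RGB array in \[0, 1\].
#' @export
render_orientation_map <- function(field, mask = NULL, axis_deg = 0) {
  theta <- fold_axial_right(field$theta_deg - axis_deg)
  hue <- (theta + 90) / 180
  e <- field$energy
  e99 <- stats::quantile(e[e > 0], 0.99, names = FALSE)
  if (!is.finite(e99) || e99 <= 0) e99 <- 1
  val <- sqrt(pmin(e / e99, 1))
  sat <- pmin(pmax(field$coherence, 0), 1)
  m <- if (!is.null(mask)) matrix(as.logical(mask), nrow(theta)) else field$mask
  if (!is.null(m)) val[!m] <- 0
  cols <- grDevices::hsv(as.numeric(hue), as.numeric(sat), as.numeric(val))
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, dim = c(nrow(theta), ncol(theta), 3))
  out[, , 1] <- rgb[1, ]; out[, , 2] <- rgb[2, ]; out[, , 3] <- rgb[3, ]
  attr(out, "wheel") <- orientation_wheel()
  out
}

# small colour-wheel legend (64 x 64), hue = axial angle
#' @noRd
orientation_wheel <- function(n = 64) {
  cx <- (n + 1) / 2
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  dx <- g$c - cx; dy <- g$r - cx
  rad <- sqrt(dx^2 + dy^2)
  ang <- fold_axial_right(deg_atan2(dy, dx))
  hue <- (ang + 90) / 180
  v <- as.numeric(rad <= n / 2)
  cols <- grDevices::col2rgb(grDevices::hsv(hue, 1, v)) / 255
  out <- array(0, dim = c(n, n, 3))
  out[, , 1] <- cols[1, ]; out[, , 2] <- cols[2, ]; out[, , 3] <- cols[3, ]
  out
}

#' Write an RGB array as PNG
#' @param rgb `rows x cols x 3` array in \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orientation_map <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Plot an orientation histogram (linear or rose)
#'
#' @param object An `orientation_histogram`.
#' @param rose If `TRUE`, draw a polar rose (10-degree bins by default via
#'   [rose_counts()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot orientation_histogram
#' @export
autoplot.orientation_histogram <- function(object, rose = FALSE, ...) {
  if (rose && attr(object, "bin_width_deg") < 10) {
    object <- rose_counts(object, 10)
  }
  p <- ggplot2::ggplot(object,
        ggplot2::aes(x = .data$bin_center_deg, y = .data$weight)) +
    ggplot2::geom_col(width = attr(object, "bin_width_deg") * 0.95,
                      fill = "grey30") +
    ggplot2::labs(x = "orientation relative to cell axis (deg)",
                  y = "weight") +
    ggplot2::theme_minimal()
  if (rose) {
    p <- p + ggplot2::coord_polar(start = pi / 2, direction = -1) +
      ggplot2::scale_x_continuous(limits = c(-90, 270),
                                  breaks = seq(-90, 90, 30))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
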