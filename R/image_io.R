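#' Construct a calibrated cell image
#'
#' A `cell_image` is the unit of analysis: a 2D intensity raster of the
#' alpha-actinin channel of a single cell with its physical pixel size
#' attached. Intensities are kept exactly as supplied; no rescaling is
#' performed anywhere in the package.
#'
#' @param pixels Numeric matrix (rows = y, columns = x) of non-negative,
#'   finite intensities; at least 32 x 32.
#' @param pixel_size_um Physical size of one pixel in micrometres (> 0).
#' @param id Free-text label carried into reports.
#' @return A `cell_image` object (a numeric matrix with calibration
#'   attributes).
#' @export
cell_image <- function(pixels, pixel_size_um, id = "cell") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 32 || ncol(pixels) < 32) {
    stop("cell_image: raster must be at least 32 x 32 pixels", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("cell_image: intensities must be finite", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("cell_image: intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("cell_image: pixel_size_um must be a single positive number",
         call. = FALSE)
  }
  structure(pixels,
            pixel_size_um = as.numeric(pixel_size_um),
            id = as.character(id),
            class = c("cell_image", "matrix", "array"))
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("<cell_image '%s': %d x %d px, %.4g um/px, range [%g, %g]>\n",
              attr(x, "id"), nrow(x), ncol(x), attr(x, "pixel_size_um"),
              min(x), max(x)))
  invisible(x)
}

#' Pixel size of a cell image
#' @param image A [cell_image()].
#' @return Pixel size in micrometres per pixel.
#' @export
pixel_size <- function(image) {
  ps <- attr(image, "pixel_size_um")
  if (is.null(ps)) stop("object carries no pixel_size_um attribute",
                        call. = FALSE)
  ps
}

#' Read a grayscale microscopy image
#'
#' Reads an 8/16-bit grayscale TIFF or PNG and attaches the physical pixel
#' size (which super-resolution headers rarely carry, so it is a mandatory
#' argument). Intensities are returned exactly as stored in the file.
#' Multi-channel files require an explicit `channel`; nothing is selected
#' silently.
#'
#' @param path Path to a TIFF or PNG file.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param channel Integer channel index for multi-channel files.
#' @param id Label; defaults to the file name.
#' @return A [cell_image()].
#' @export
read_cell_image <- function(path, pixel_size_um, channel = NULL,
                            id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- png::readPNG(path)
    info <- attr(px, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 16
    px <- round(px * (2^depth - 1))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(px)) == 3) {
    if (is.null(channel)) {
      stop("multi-channel image: supply `channel` explicitly", call. = FALSE)
    }
    if (channel < 1 || channel > dim(px)[3]) {
      stop("channel out of range", call. = FALSE)
    }
    px <- px[, , channel]
  }
  cell_image(px, pixel_size_um, id = id)
}

#' Write a cell image as 16-bit grayscale TIFF
#'
#' Intensities are written as integers; values must fit the 16-bit range.
#'
#' @param image A [cell_image()] (or plain matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_image <- function(image, path) {
  m <- unclass(image)
  attributes(m) <- attributes(m)["dim"]
  if (max(m) > 65535) stop("intensities exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(round(m) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

# --- masks ------------------------------------------------------------------

#' Construct a cell mask
#'
#' Boolean raster marking the cell silhouette. Valid masks cover at least 100
#' pixels and form a single connected component once interior holes are
#' filled (cell borders in the source studies are traced as one outline).
#'
#' @param mask Logical (or 0/1) matrix.
#' @param provenance One of `"file"`, `"polygon"`, `"threshold"`,
#'   `"synthetic"`.
#' @param largest If `TRUE`, keep only the largest connected component
#'   instead of failing on fragmented input.
#' @return A `cell_mask` object (logical matrix with attributes).
#' @export
cell_mask <- function(mask, provenance = "file", largest = FALSE) {
  mask <- as.matrix(mask)
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (any(is.na(m))) stop("mask contains NA", call. = FALSE)
  if (largest) m <- keep_largest_component(m)
  if (sum(m) < 100) {
    stop("cell_mask: fewer than 100 foreground pixels", call. = FALSE)
  }
  filled <- fill_holes(m)
  lab <- EBImage::bwlabel(filled)
  if (max(lab) > 1) {
    stop("cell_mask: mask is not a single connected component ",
         "(use largest = TRUE to keep the biggest)", call. = FALSE)
  }
  structure(m, provenance = provenance,
            class = c("cell_mask", "matrix", "array"))
}

#' @noRd
fill_holes <- function(m) {
  f <- EBImage::fillHull(EBImage::Image(m * 1))
  matrix(as.numeric(f) > 0.5, nrow(m), ncol(m))
}

#' @noRd
keep_largest_component <- function(m) {
  lab <- EBImage::bwlabel(m * 1)
  if (max(lab) <= 1) return(m)
  tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  matrix(as.integer(lab) == which.max(tab), nrow(m), ncol(m))
}

#' Read a cell mask from a raster file or polygon JSON
#'
#' Raster masks (TIFF/PNG) are thresholded at half of their maximum; polygon
#' files are JSON objects `{"vertices": [[x, y], ...]}` with 0-based pixel
#' coordinates, rasterised with the pixel-centres-inside rule.
#'
#' @param path Path to TIFF/PNG raster or `.json` polygon file.
#' @param image_shape Integer vector `c(rows, cols)` the mask must match.
#' @return A [cell_mask()].
#' @export
read_cell_mask <- function(path, image_shape) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    poly <- jsonlite::fromJSON(path)
    v <- poly$vertices
    if (is.null(v)) stop("polygon JSON lacks 'vertices'", call. = FALSE)
    m <- rasterize_polygon(as.matrix(v), image_shape)
    return(cell_mask(m, provenance = "polygon"))
  }
  raw <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported mask format: .", ext, call. = FALSE)
  }
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  if (!all(dim(raw) == image_shape)) {
    stop("mask shape ", paste(dim(raw), collapse = "x"),
         " does not match image shape ",
         paste(image_shape, collapse = "x"), call. = FALSE)
  }
  m <- raw > max(raw) / 2
  if (!any(m)) stop("mask is empty", call. = FALSE)
  cell_mask(m, provenance = "file")
}

#' Rasterise a polygon with the pixel-centres-inside rule
#'
#' Even-odd scanline fill: a pixel is foreground when its centre (integer
#' 0-based coordinates) lies inside the polygon, using half-open edge rules
#' so shared edges are never counted twice.
#'
#' @param vertices Two-column matrix of `(x, y)` vertices, 0-based pixel
#'   coordinates.
#' @param shape Integer vector `c(rows, cols)`.
#' @return Logical matrix.
#' @export
rasterize_polygon <- function(vertices, shape) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3) {
    stop("polygon needs >= 3 (x, y) vertices", call. = FALSE)
  }
  if (polygon_self_intersects(v)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  h <- shape[1]; w <- shape[2]
  out <- matrix(FALSE, h, w)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(v[-1, 1], v[1, 1]); y2 <- c(v[-1, 2], v[1, 2])
  for (yc in seq(0, h - 1)) {
    crosses <- ((y1 <= yc) & (yc < y2)) | ((y2 <= yc) & (yc < y1))
    if (!any(crosses)) next
    xc <- x1[crosses] + (yc - y1[crosses]) *
      (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
    xc <- sort(xc)
    for (k in seq(1, length(xc) - 1, by = 2)) {
      lo <- ceiling(xc[k]); hi <- ceiling(xc[k + 1]) - 1
      lo <- max(lo, 0); hi <- min(hi, w - 1)
      if (lo <= hi) out[yc + 1, (lo:hi) + 1] <- TRUE
    }
  }
  out
}

#' @noRd
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]))
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # closing edge shares a vertex with edge 1
      p <- seg[i, 1:2]; p2 <- seg[i, 3:4]
      q <- seg[j, 1:2]; q2 <- seg[j, 3:4]
      d1 <- cross(p2[1] - p[1], p2[2] - p[2], q[1] - p[1], q[2] - p[2])
      d2 <- cross(p2[1] - p[1], p2[2] - p[2], q2[1] - p[1], q2[2] - p[2])
      d3 <- cross(q2[1] - q[1], q2[2] - q[2], p[1] - q[1], p[2] - q[2])
      d4 <- cross(q2[1] - q[1], q2[2] - q[2], p2[1] - q[1], p2[2] - q[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Write a mask as a PNG
#' @param mask Logical matrix / [cell_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  png::writePNG(m, path)
  invisible(path)
}

#' Derive a mask by Otsu thresholding (fallback when no outline exists)
#'
#' Convenience for images without a traced border: Otsu threshold on the
#' intensity histogram, hole filling, then the largest connected component.
#' The result is flagged `provenance = "threshold"` in every report because
#' manual outlines are the reference procedure.
#'
#' @param image A [cell_image()].
#' @return A [cell_mask()].
#' @export
mask_from_threshold <- function(image) {
  m <- unclass(image)
  rng <- max(m) - min(m)
  if (rng == 0) stop("constant image: cannot threshold", call. = FALSE)
  norm <- (m - min(m)) / rng
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bin <- fill_holes(norm > th)
  cell_mask(keep_largest_component(bin), provenance = "threshold")
}

# --- calcium traces ---------------------------------------------------------

#' Construct a calcium fluorescence trace
#'
#' @param t_ms Time points in milliseconds; strictly increasing, uniformly
#'   spaced (relative tolerance 1e-6), at least 50 samples.
#' @param f Fluorescence intensities (arbitrary units).
#' @return A tibble of class `calcium_trace` with columns `t_ms`, `f`.
#' @export
calcium_trace <- function(t_ms, f) {
  if (length(t_ms) != length(f)) stop("t and f lengths differ", call. = FALSE)
  if (length(t_ms) < 50) stop("calcium trace needs >= 50 samples",
                              call. = FALSE)
  dt <- diff(t_ms)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt)) {
    stop("sampling must be uniform (relative tolerance 1e-6)", call. = FALSE)
  }
  out <- tibble::tibble(t_ms = as.numeric(t_ms), f = as.numeric(f))
  class(out) <- c("calcium_trace", class(out))
  out
}

#' Read a calcium trace from CSV
#'
#' Expects columns `t_ms` (or `t`) and `f`. With `fps` given, the first
#' column is instead interpreted as a frame index and time is reconstructed
#' as `frame / fps * 1000` ms.
#'
#' @param path CSV path.
#' @param fps Frames per second for frame-indexed input (optional).
#' @return A [calcium_trace()].
#' @export
read_calcium_trace <- function(path, fps = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  fcol <- if ("f" %in% names(d)) d$f else d[[2]]
  if (!is.null(fps)) {
    frames <- d[[1]]
    return(calcium_trace((frames - frames[1]) * 1000 / fps, fcol))
  }
  tcol <- if ("t_ms" %in% names(d)) d$t_ms else d[[1]]
  calcium_trace(tcol, fcol)
}

# --- reports ----------------------------------------------------------------

#' Write a per-cell metrics report
#'
#' Numeric fields round-trip losslessly (CSV uses shortest-exact formatting;
#' JSON writes full precision). One row / object per cell.
#'
#' @param records A data frame, or a list of identically named lists.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  if (!format %in% c("csv", "json")) {
    stop("format must be 'csv' or 'json'", call. = FALSE)
  }
  if (!is.data.frame(records)) {
    if (length(records)) {
      keys <- lapply(records, names)
      if (!all(vapply(keys, identical, logical(1), keys[[1]]))) {
        stop("heterogeneous record keys", call. = FALSE)
      }
    }
    records <- dplyr::bind_rows(lapply(records, tibble::as_tibble))
  }
  if (format == "csv") {
    readr::write_csv(records, path)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path CSV or JSON report path.
#' @return A tibble.
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE)
  } else if (ext == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    stop("unsupported report format: .", ext, call. = FALSE)
  }
}
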