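# Axial circular statistics for filament orientations.
#
# Filament orientations are undirected (a z-line at +80 deg is the same
# structure as one at -100 deg), so every statistic here works on DOUBLED
# angles: theta -> 2*theta maps the 180-degree-periodic axial circle onto the
# full circle, where ordinary circular statistics apply; results are halved
# back. Without doubling, a tight population straddling +/-90 deg would
# wrongly appear bimodal and its mean would be meaningless.

#' Axial circular mean and resultant length
#'
#' @param angles_deg Orientations in degrees (any representative of the
#'   axial class; period 180).
#' @param weights Optional non-negative weights (default: equal).
#' @return A list with `mean_deg` (folded to (-90, 90]; `NA` when the
#'   doubled-angle resultant vanishes), `r_bar` (axial mean resultant length
#'   in \[0, 1\]) and `dispersed` (`TRUE` when `r_bar` < 0.05, i.e. the mean
#'   is unstable).
#' @export
#' @examples
#' axial_mean(c(80, 90, -80))   # mean 90: the three are axially adjacent
axial_mean <- function(angles_deg, weights = NULL) {
  if (length(angles_deg) < 1) stop("need at least one angle", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  w_tot <- sum(weights)
  if (w_tot <= 0) stop("total weight is zero", call. = FALSE)
  a2 <- 2 * angles_deg / DEG
  C <- sum(weights * cos(a2))
  S <- sum(weights * sin(a2))
  R <- sqrt(C^2 + S^2)
  r_bar <- R / w_tot
  mean_deg <- if (R < 1e-12 * w_tot) NA_real_ else {
    fold_axial_right(0.5 * deg_atan2(S, C))
  }
  list(mean_deg = mean_deg, r_bar = r_bar, dispersed = r_bar < 0.05)
}

#' Watson-Williams test for equal mean directions (axial data)
#'
#' Circular analogue of one-way ANOVA: compares the mean orientation of
#' `r >= 2` groups via an F statistic computed from group and pooled
#' resultant lengths on doubled angles, with the concentration-based
#' correction factor `K = 1 + 3/(8 kappa)`. The concentration `kappa` is the
#' maximum-likelihood von Mises estimate obtained by Newton inversion of
#' `A(kappa) = I1(kappa)/I0(kappa)` at the weighted mean resultant length.
#' The test assumes reasonably concentrated samples; following common
#' practice the result carries `assumption_ok = FALSE` (rather than failing)
#' when the mean resultant length drops below 0.45.
#'
#' @param groups Either a list of numeric vectors of orientations in
#'   degrees, or a data frame with the orientation and grouping columns
#'   named by `angle_col` / `group_col`.
#' @param angle_col,group_col Column names used when `groups` is a data
#'   frame.
#' @return An object of class `watson_williams`: a list with `F_stat`,
#'   `df1`, `df2`, `p_value`, `K`, `kappa_hat`, `R_bar` (pooled weighted mean
#'   resultant length), `assumption_ok`, and a per-group tibble `groups`.
#'   Use [tidy()] / [glance()] for tibble views.
#' @export
#' @examples
#' watson_williams(list(a = c(10, 20, 30), b = c(40, 50, 60)))
watson_williams <- function(groups, angle_col = "angle_deg",
                            group_col = "group") {
  if (is.data.frame(groups)) {
    groups <- split(groups[[angle_col]], groups[[group_col]])
  }
  r <- length(groups)
  if (r < 2) stop("need at least 2 groups", call. = FALSE)
  n_i <- vapply(groups, length, integer(1))
  if (any(n_i < 3)) stop("each group needs at least 3 observations",
                         call. = FALSE)
  if (any(n_i < 10)) {
    warning("group sizes below 10: the F approximation is rough")
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(r))

  a2 <- lapply(groups, function(a) 2 * a / DEG)
  C_i <- vapply(a2, function(a) sum(cos(a)), numeric(1))
  S_i <- vapply(a2, function(a) sum(sin(a)), numeric(1))
  R_i <- sqrt(C_i^2 + S_i^2)
  if (any(R_i / n_i > 1 - 1e-12)) {
    stop("a group has zero angular dispersion; the test statistic diverges",
         call. = FALSE)
  }
  N <- sum(n_i)
  R_pool <- sqrt(sum(C_i)^2 + sum(S_i)^2)
  R_bar_w <- sum(R_i) / N
  kappa_hat <- kappa_ml(R_bar_w)
  K <- 1 + 3 / (8 * kappa_hat)
  F_stat <- K * ((N - r) * (sum(R_i) - R_pool)) /
    ((r - 1) * (N - sum(R_i)))
  F_stat <- max(F_stat, 0)  # guard tiny negative rounding when R_pool ~ sum(R_i)
  df1 <- r - 1
  df2 <- N - r
  p <- stats::pf(F_stat, df1, df2, lower.tail = FALSE)

  per_group <- tibble::tibble(
    group = names(groups),
    n = as.integer(n_i),
    mean_deg = vapply(groups, function(a) axial_mean(a)$mean_deg, numeric(1)),
    r_bar = R_i / n_i
  )
  structure(
    list(F_stat = F_stat, df1 = df1, df2 = df2, p_value = p, K = K,
         kappa_hat = kappa_hat, R_bar = R_bar_w,
         assumption_ok = R_bar_w >= 0.45, groups = per_group),
    class = "watson_williams")
}

#' @export
print.watson_williams <- function(x, ...) {
  cat("Watson-Williams test (axial orientations)\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F_stat, x$p_value))
  cat(sprintf("  kappa_hat = %.4g, K = %.4g, pooled R_bar = %.4g%s\n",
              x$kappa_hat, x$K, x$R_bar,
              if (x$assumption_ok) "" else "  [R_bar < 0.45: low concentration]"))
  print(x$groups)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-group summary of a Watson-Williams fit
#' @param x A [watson_williams()] result.
#' @param ... Unused.
#' @return Tibble with one row per group: `group`, `n`, `mean_deg`, `r_bar`.
#' @method tidy watson_williams
#' @export
tidy.watson_williams <- function(x, ...) {
  x$groups
}

#' One-row summary of a Watson-Williams fit
#' @param x A [watson_williams()] result.
#' @param ... Unused.
#' @return One-row tibble with the test statistic, degrees of freedom,
#'   p-value, correction factor, concentration estimate and assumption flag.
#' @method glance watson_williams
#' @export
glance.watson_williams <- function(x, ...) {
  tibble::tibble(
    statistic = x$F_stat, df1 = x$df1, df2 = x$df2, p.value = x$p_value,
    K = x$K, kappa = x$kappa_hat, R_bar = x$R_bar,
    assumption_ok = x$assumption_ok
  )
}

#' Re-bin an orientation histogram for a rose diagram
#'
#' Aggregates a fine orientation histogram (see [orientation_histogram()])
#' into coarser bins over (-90, 90], conserving total mass exactly. The
#' target width must divide 180 and be a multiple of the source width.
#'
#' @param hist An `orientation_histogram` tibble.
#' @param bin_deg Target bin width in degrees (default 10).
#' @return A tibble with `bin_center_deg`, `weight`; attribute
#'   `bin_width_deg` updated.
#' @export
rose_counts <- function(hist, bin_deg = 10) {
  src_w <- attr(hist, "bin_width_deg")
  if (is.null(src_w)) stop("not an orientation histogram", call. = FALSE)
  if (180 %% bin_deg != 0) stop("bin_deg must divide 180", call. = FALSE)
  if (abs(bin_deg / src_w - round(bin_deg / src_w)) > 1e-9 || bin_deg < src_w) {
    stop("bin_deg must be a multiple of the source bin width", call. = FALSE)
  }
  edges <- seq(-90, 90, by = bin_deg)
  # assign each fine bin (by its centre) to a coarse (-90, 90] interval
  idx <- findInterval(hist$bin_center_deg, edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  w <- vapply(seq_len(length(edges) - 1),
              function(k) sum(hist$weight[idx == k]), numeric(1))
  out <- tibble::tibble(
    bin_center_deg = (edges[-1] + edges[-length(edges)]) / 2,
    weight = w
  )
  attr(out, "bin_width_deg") <- bin_deg
  attr(out, "n_eff") <- sum(w)
  attr(out, "source") <- attr(hist, "source")
  class(out) <- c("orientation_histogram", class(out))
  out
}
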