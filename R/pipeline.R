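# Cohort-level orchestration: per-cell analysis and group comparison.

#' Analysis configuration
#'
#' All tunables of the per-cell pipeline with their defaults, resolved once
#' and carried through reports so every result is reproducible from its
#' configuration. Pixel-dependent quantities are specified in micrometres
#' and converted at use.
#'
#' @param expected_zdisc_width_um Expected (PSF-broadened) z-disc width;
#'   sets the ridge-detection scale and the tensor integration scale.
#' @param sigma_px Override of the detection scale (otherwise derived).
#' @param upper_thresh,lower_thresh Hysteresis overrides (otherwise
#'   response-quantile defaults).
#' @param min_length_um Minimum ridge length kept.
#' @param max_width_um Cap of the one-sided width search.
#' @param tensor_sigma_um Structure-tensor integration scale.
#' @param bin_width_deg Orientation histogram bin width.
#' @param orientation_source `"structure_tensor"` or `"ridge_tangent"`.
#' @param footprint_mode `"width"` or `"skeleton"` for the density
#'   footprint.
#' @param density_breaks Medium-category density interval, percent.
#' @param n_length_targets,n_width_targets Protocol sample sizes (20
#'   spacings, 50 filament widths per cell).
#' @param profile_len_um,peak_prominence_frac,min_peak_sep_um,
#'   spacing_window_um Sarcomere-length profile settings (see
#'   [sarcomere_length()]).
#' @param threshold_fallback Allow Otsu masks when no mask is given
#'   (flagged in the report).
#' @return A `sarcnet_config` list.
#' @export
sarcnet_config <- function(expected_zdisc_width_um = 0.25,
                           sigma_px = NULL,
                           upper_thresh = NULL, lower_thresh = NULL,
                           min_length_um = 0.5, max_width_um = 0.8,
                           tensor_sigma_um = 0.25,
                           bin_width_deg = 2,
                           orientation_source = "structure_tensor",
                           footprint_mode = "width",
                           density_breaks = c(20, 30),
                           n_length_targets = 20, n_width_targets = 50,
                           profile_len_um = 6, peak_prominence_frac = 0.2,
                           min_peak_sep_um = 1.0,
                           spacing_window_um = c(1.0, 3.0),
                           threshold_fallback = FALSE) {
  structure(as.list(environment()), class = "sarcnet_config")
}

#' Write / read a configuration (YAML round-trip)
#' @param config A [sarcnet_config()].
#' @param path YAML path.
#' @return `path` invisibly ([write_config()]); a `sarcnet_config`
#'   ([read_config()]).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sarcnet_config, vals)
}

# resolve pixel-dependent ridge parameters
#' @noRd
ridge_params_from_config <- function(config, pixel_size_um) {
  ridge_params(
    sigma_px = config$sigma_px,
    expected_width_px = config$expected_zdisc_width_um / pixel_size_um,
    upper_thresh = config$upper_thresh,
    lower_thresh = config$lower_thresh,
    min_length_px = config$min_length_um / pixel_size_um,
    max_width_px = config$max_width_um / pixel_size_um
  )
}

#' Analyse a single cell
#'
#' Runs the full structural pipeline — shape descriptors, long axis, ridge
#' detection, widths, density footprint, orientation statistics, sarcomere
#' length, z-disc thickness — and returns one tidy row. Individual metric
#' failures are flagged, not fatal.
#'
#' @param image A [cell_image()].
#' @param mask A [cell_mask()]; when `NULL` and
#'   `config$threshold_fallback` is `TRUE`, an Otsu mask is derived and
#'   flagged.
#' @param config A [sarcnet_config()].
#' @param id Row label; defaults to the image id.
#' @return One-row tibble with shape, density, orientation, length and
#'   thickness metrics plus a semicolon-separated `flags` column.
#' @export
analyze_cell <- function(image, mask = NULL, config = sarcnet_config(),
                         id = attr(image, "id")) {
  ps <- pixel_size(image)
  flags <- character(0)
  if (is.null(mask)) {
    if (!config$threshold_fallback) {
      stop("no mask supplied and threshold_fallback is disabled",
           call. = FALSE)
    }
    mask <- mask_from_threshold(image)
    flags <- c(flags, "threshold_mask")
  }

  shp <- shape_descriptors(mask, ps)
  axis <- long_axis(mask)
  if (axis$unreliable) flags <- c(flags, "axis_unreliable")

  params <- ridge_params_from_config(config, ps)
  ridges <- detect_ridges(image, mask, params)
  ridges <- estimate_widths(image, ridges)
  fp <- ridge_footprint(ridges, dim(image), mode = config$footprint_mode)
  dens <- sarcomere_density(fp, mask)
  if (!nrow(ridges)) flags <- c(flags, "no_ridges")

  dir_res <- tryCatch({
    src <- if (config$orientation_source == "structure_tensor") {
      orientation_field(image, mask,
                        tensor_sigma_px = config$tensor_sigma_um / ps)
    } else ridges
    hist <- orientation_histogram(src, mask, axis_deg = axis$angle_deg,
                                  bin_width_deg = config$bin_width_deg)
    main_direction(hist)
  }, error = function(e) NULL)
  if (is.null(dir_res)) {
    flags <- c(flags, "orientation_failed")
    dir_res <- tibble::tibble(
      main_direction_deg = NA_real_, resultant_length = NA_real_,
      frac_0_30 = NA_real_, frac_30_60 = NA_real_, frac_60_90 = NA_real_,
      orientation_category = NA_character_, dispersed = NA)
  } else if (isTRUE(dir_res$dispersed)) {
    flags <- c(flags, "orientation_dispersed")
  }

  ls_res <- sarcomere_length(image, ridges, ps,
                             n_target = config$n_length_targets,
                             profile_len_um = config$profile_len_um,
                             prominence_frac = config$peak_prominence_frac,
                             min_sep_um = config$min_peak_sep_um,
                             window_um = config$spacing_window_um)
  if (ls_res$unreliable) flags <- c(flags, "length_unreliable")
  wz_res <- zdisc_thickness(ridges, ps, n_target = config$n_width_targets)
  if (wz_res$unreliable) flags <- c(flags, "thickness_unreliable")

  dplyr::bind_cols(
    tibble::tibble(id = id %||% "cell", pixel_size_um = ps),
    shp[, c("area_um2", "perimeter_um", "aspect_ratio", "circularity",
            "roundness", "long_axis_deg")],
    tibble::tibble(
      density_pct = dens,
      density_category = as.character(classify_density(
        dens, config$density_breaks))),
    dir_res,
    tibble::tibble(
      sarcomere_length_um = ls_res$mean_um,
      sarcomere_length_sem = ls_res$sem_um,
      n_spacings = ls_res$n_spacings,
      zdisc_width_um = wz_res$mean_um,
      n_widths = wz_res$n_widths,
      n_ridges = if (nrow(ridges)) max(ridges$ridge_id) else 0L,
      flags = paste(flags, collapse = ";"))
  )
}

#' Analyse a cohort of cells
#'
#' @param cells Tibble (or list) with one row per cell: columns `image`
#'   (list of [cell_image()] or file paths), optional `mask` (list of
#'   [cell_mask()] / paths), optional `id`, `group`, and `pixel_size_um`
#'   (required for path input).
#' @param config A [sarcnet_config()].
#' @return Tibble with one row per cell; failed cells carry `NA` metrics
#'   and an `analysis_failed` flag instead of aborting the cohort.
#' @export
analyze_cells <- function(cells, config = sarcnet_config()) {
  cells <- tibble::as_tibble(cells)
  n <- nrow(cells)
  purrr::map_dfr(seq_len(n), function(i) {
    img <- cells$image[[i]]
    if (is.character(img)) {
      img <- read_cell_image(img, cells$pixel_size_um[[i]])
    }
    msk <- if ("mask" %in% names(cells)) cells$mask[[i]] else NULL
    if (is.character(msk)) msk <- read_cell_mask(msk, dim(img))
    id <- if ("id" %in% names(cells)) cells$id[[i]] else attr(img, "id")
    row <- tryCatch(
      analyze_cell(img, msk, config, id = id),
      error = function(e) tibble::tibble(
        id = id %||% sprintf("cell%d", i),
        flags = paste0("analysis_failed:", conditionMessage(e))))
    if ("group" %in% names(cells)) {
      row <- dplyr::mutate(row, group = cells$group[[i]], .after = "id")
    }
    row
  })
}

#' Compare metric distributions across cohorts
#'
#' Linear metrics are compared by one-way ANOVA with Bonferroni-corrected
#' pairwise t tests (or Dunnett contrasts against `control` when given,
#' mirroring common usage); the circular main direction is compared with
#' the Watson-Williams test. Contingency tables of the density and
#' orientation categories and the mean orientation-interval fractions are
#' tabulated per group.
#'
#' @param report Per-cell tibble from [analyze_cells()] with a `group`
#'   column.
#' @param group_col Grouping column name.
#' @param control Optional control group name (switches the post hoc to
#'   Dunnett contrasts).
#' @param metrics Linear metrics to test.
#' @return A `cohort_summary` list: `group_means` (mean +/- SEM per metric
#'   and group), `anova`, `pairwise`, `circular` ([watson_williams()]
#'   result or `NULL`), `density_contingency`,
#'   `orientation_contingency`, `interval_fractions`.
#' @export
compare_groups <- function(report, group_col = "group", control = NULL,
                           metrics = c("density_pct", "sarcomere_length_um",
                                       "zdisc_width_um", "aspect_ratio",
                                       "circularity", "roundness")) {
  if (!group_col %in% names(report)) {
    stop("report lacks a '", group_col, "' column", call. = FALSE)
  }
  g <- factor(report[[group_col]])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 3)) stop("every group needs at least 3 cells",
                              call. = FALSE)
  metrics <- intersect(metrics, names(report))

  group_means <- report |>
    dplyr::group_by(.data[[group_col]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(c(metrics, "main_direction_deg")),
                    list(mean = ~mean(.x, na.rm = TRUE), sem = ~sem(.x))),
      .groups = "drop")

  anova_tbl <- purrr::map_dfr(metrics, function(mname) {
    d <- data.frame(y = report[[mname]], g = g)
    d <- d[is.finite(d$y), ]
    if (length(unique(d$g)) < 2 || nrow(d) < 4 || stats::var(d$y) == 0) {
      return(tibble::tibble(metric = mname, F_stat = NA_real_,
                            p_value = NA_real_))
    }
    fit <- stats::aov(y ~ g, data = d)
    s <- summary(fit)[[1]]
    tibble::tibble(metric = mname, F_stat = s[["F value"]][1],
                   p_value = s[["Pr(>F)"]][1])
  })

  pairwise <- purrr::map_dfr(metrics, function(mname) {
    d <- data.frame(y = report[[mname]], g = g)
    d <- d[is.finite(d$y), ]
    if (length(unique(d$g)) < 2 || stats::var(d$y) == 0) return(NULL)
    if (!is.null(control)) {
      d$g <- stats::relevel(factor(d$g), ref = control)
      fit <- stats::aov(y ~ g, data = d)
      gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
      tibble::tibble(metric = mname,
                     comparison = names(gl$test$coefficients),
                     estimate = unname(gl$test$coefficients),
                     p_adj = unname(gl$test$pvalues),
                     method = "dunnett")
    } else {
      pt <- stats::pairwise.t.test(d$y, d$g, p.adjust.method = "bonferroni")
      pv <- as.data.frame(as.table(pt$p.value))
      pv <- pv[!is.na(pv$Freq), ]
      tibble::tibble(metric = mname,
                     comparison = paste(pv$Var1, "-", pv$Var2),
                     estimate = NA_real_, p_adj = pv$Freq,
                     method = "bonferroni")
    }
  })

  circ <- NULL
  md <- report$main_direction_deg
  ok <- is.finite(md)
  if (sum(ok) && all(table(g[ok]) >= 5) && length(unique(g[ok])) >= 2) {
    circ <- tryCatch(
      watson_williams(split(md[ok], droplevels(g[ok]))),
      error = function(e) NULL)
  }

  dens_cont <- if ("density_category" %in% names(report)) {
    as.data.frame.matrix(table(g, factor(report$density_category,
                                         c("low", "medium", "high"))))
  } else NULL
  ori_cont <- if ("orientation_category" %in% names(report)) {
    as.data.frame.matrix(table(g, factor(report$orientation_category,
                                         c("low", "medium", "high"))))
  } else NULL
  frac <- report |>
    dplyr::group_by(.data[[group_col]]) |>
    dplyr::summarise(dplyr::across(
      dplyr::any_of(c("frac_0_30", "frac_30_60", "frac_60_90")),
      ~mean(.x, na.rm = TRUE)), .groups = "drop")

  structure(list(group_means = group_means, anova = anova_tbl,
                 pairwise = pairwise, circular = circ,
                 density_contingency = dens_cont,
                 orientation_contingency = ori_cont,
                 interval_fractions = frac),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n==============\n\nGroup means (+/- SEM):\n")
  print(x$group_means)
  cat("\nOne-way ANOVA (linear metrics):\n")
  print(x$anova)
  if (!is.null(x$circular)) {
    cat("\nMain direction (Watson-Williams):\n")
    print(glance(x$circular))
  }
  if (!is.null(x$density_contingency)) {
    cat("\nDensity categories:\n")
    print(x$density_contingency)
  }
  invisible(x)
}
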