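# Spatial analysis: spheroid morphology (area, migration distances) and
# FLIRR gradients along Euclidean-distance coordinates. Intact spheroids are
# profiled by distance from the spheroid edge (15 um bins, > 75 um treated
# as the core); partially intact or fully scattered samples by distance from
# the (former) spheroid center (125 um bins).

mask_values <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$values else mask
}

mask_pixel_size <- function(mask, pixel_size_um) {
  if (inherits(mask, "binary_mask")) mask$pixel_size_um else pixel_size_um
}

#' Spheroid area in pixels
#'
#' Total area as the count of foreground pixels of the segmented mask.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @return Integer pixel count.
#' @export
spheroid_area <- function(mask) {
  sum(mask_values(mask))
}

#' Euclidean distance from the spheroid edge
#'
#' For every foreground pixel, the Euclidean distance (in micrometres) to
#' the nearest background pixel, computed exactly on the pixel lattice and
#' scaled by the pixel size. With `reference_pixels = "boundary"` distances
#' are measured to the nearest mask-boundary pixel instead (0 on the
#' boundary itself); the two conventions differ by at most one pixel.
#'
#' @param mask a [binary_mask()] or logical matrix; must be non-empty.
#' @param pixel_size_um pixel size, required when `mask` is a plain matrix.
#' @param reference_pixels `"background"` (default) or `"boundary"`.
#' @return A list of class `distance_map`: `values` (um, NA outside the
#'   mask), `mask`, `reference = "edge"`, `pixel_size_um`.
#' @export
distance_from_edge <- function(mask, pixel_size_um = NULL,
                               reference_pixels = c("background", "boundary")) {
  reference_pixels <- match.arg(reference_pixels)
  mv <- mask_values(mask)
  ps <- mask_pixel_size(mask, pixel_size_um)
  if (is.null(ps))
    abort("pixel_size_um is required", "spheroflim_invalid_argument")
  if (!any(mv))
    abort("mask is empty", "spheroflim_degenerate_input")
  if (all(mv))
    abort("mask has no background; edge distance is undefined",
          "spheroflim_degenerate_input")
  if (reference_pixels == "background") {
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(mv * 1)))
  } else {
    bg_dil <- EBImage::imageData(
      EBImage::dilate(EBImage::Image((!mv) * 1),
                      EBImage::makeBrush(3, "box"))) > 0
    boundary <- mv & bg_dil
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image((!boundary) * 1)))
  }
  values <- matrix(NA_real_, nrow(mv), ncol(mv))
  values[mv] <- d[mv] * ps
  structure(list(values = values, mask = mv, reference = "edge",
                 center = NULL, pixel_size_um = ps),
            class = "distance_map")
}

#' Locate the spheroid center
#'
#' Center of mass of the largest connected component of the mask
#' (fractional coordinates, not rounded), or user-supplied coordinates for
#' samples whose former spheroid center is identified externally (e.g. from
#' the void in a collagen image).
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param mode `"largest_component"` or `"user_supplied"`.
#' @param user_center `(row, col)` coordinates for `"user_supplied"`.
#' @return Numeric `(row, col)` center.
#' @export
find_center <- function(mask, mode = c("largest_component", "user_supplied"),
                        user_center = NULL) {
  mode <- match.arg(mode)
  if (mode == "user_supplied") {
    if (is.null(user_center) || length(user_center) != 2L)
      abort("user_center must be (row, col)", "spheroflim_invalid_argument")
    return(as.numeric(user_center))
  }
  mv <- mask_values(mask)
  if (!any(mv))
    abort("mask is empty", "spheroflim_degenerate_input")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mv * 1)))
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)
  px <- which(lab == biggest, arr.ind = TRUE)
  c(mean(px[, 1]), mean(px[, 2]))
}

#' Euclidean distance from a center coordinate
#'
#' Per foreground pixel, the Euclidean distance (micrometres) from the given
#' (possibly fractional) center.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param center `(row, col)` center, inside the image bounds.
#' @param pixel_size_um pixel size, required when `mask` is a plain matrix.
#' @return A list of class `distance_map` with `reference = "center"`.
#' @export
distance_from_center <- function(mask, center, pixel_size_um = NULL) {
  mv <- mask_values(mask)
  ps <- mask_pixel_size(mask, pixel_size_um)
  if (is.null(ps))
    abort("pixel_size_um is required", "spheroflim_invalid_argument")
  if (center[1] < 1 || center[1] > nrow(mv) ||
      center[2] < 1 || center[2] > ncol(mv))
    abort("center lies outside the image", "spheroflim_invalid_argument")
  idx <- which(mv, arr.ind = TRUE)
  values <- matrix(NA_real_, nrow(mv), ncol(mv))
  values[mv] <- sqrt((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2) * ps
  structure(list(values = values, mask = mv, reference = "center",
                 center = as.numeric(center), pixel_size_um = ps),
            class = "distance_map")
}

#' Morphology and migration summary of a distance map
#'
#' Pools the per-pixel distances and reports the 5/25/50/75/95th percentiles
#' (the boxplot convention: whiskers at 5 and 95 percent, box at 25 and 75)
#' together with the mask area.
#'
#' @param distmap a [distance_from_edge()] or [distance_from_center()] map.
#' @return A list of class `morphology_summary`: `area_pixels`,
#'   `distances_um`, `percentiles` (named p5/p25/p50/p75/p95).
#' @export
migration_summary <- function(distmap) {
  stopifnot(inherits(distmap, "distance_map"))
  d <- distmap$values[distmap$mask]
  if (!length(d))
    abort("distance map is empty", "spheroflim_degenerate_input")
  q <- quantile(d, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  structure(list(area_pixels = sum(distmap$mask), distances_um = d,
                 percentiles = setNames(q, c("p5", "p25", "p50", "p75", "p95"))),
            class = "morphology_summary")
}

#' @export
print.morphology_summary <- function(x, ...) {
  p <- x$percentiles
  cat(sprintf(
    "<morphology_summary> area %d px; distance um: p5 %.1f | p25 %.1f | median %.1f | p75 %.1f | p95 %.1f\n",
    x$area_pixels, p["p5"], p["p25"], p["p50"], p["p75"], p["p95"]))
  invisible(x)
}

#' Bin FLIRR values along a distance coordinate
#'
#' Edge mode partitions masked pixels into five 15-um bins
#' `[0,15), ..., [60,75)` plus a single core bin (>= 75 um), the convention
#' for intact spheroids; center mode uses consecutive 125-um bins from 0 to
#' the observed maximum distance. Every valid FLIRR pixel is assigned to
#' exactly one bin; per-bin medians, quartiles and 5/95th percentiles are
#' reported.
#'
#' @param flirr a [compute_flirr()] map.
#' @param distmap a [distance_from_edge()] or [distance_from_center()] map
#'   on the same geometry.
#' @param bin_kind `"edge"` (15-um bins, >= 75 um core) or `"center"`
#'   (125-um bins). Defaults to the distance map's reference.
#' @param edge_bin_um,core_from_um,center_bin_um bin widths and the core
#'   cut-off, in micrometres.
#' @return A list of class `binned_flirr_profile`: `table` (data frame with
#'   bin, bin_low_um, bin_high_um, n, median, q25, q75, p5, p95), `values`
#'   (list of per-bin FLIRR vectors), `bin_kind`.
#' @export
bin_flirr_by_distance <- function(flirr, distmap, bin_kind = NULL,
                                  edge_bin_um = 15, core_from_um = 75,
                                  center_bin_um = 125) {
  stopifnot(inherits(flirr, "flirr_map"), inherits(distmap, "distance_map"))
  if (!all(dim(flirr$values) == dim(distmap$values)))
    abort("FLIRR map and distance map geometries differ",
          "spheroflim_invalid_argument")
  if (is.null(bin_kind))
    bin_kind <- if (distmap$reference == "edge") "edge" else "center"
  bin_kind <- match.arg(bin_kind, c("edge", "center"))
  sel <- flirr$mask & distmap$mask & !is.na(distmap$values)
  v <- flirr$values[sel]
  d <- distmap$values[sel]
  if (!length(v))
    abort("no valid FLIRR pixels with distances", "spheroflim_degenerate_input")
  if (bin_kind == "edge") {
    breaks <- c(seq(0, core_from_um, by = edge_bin_um), Inf)
    labels <- c(sprintf("[%g,%g)", head(breaks, -2), breaks[-c(1, length(breaks))]),
                "core")
  } else {
    top <- max(d)
    n_bins <- max(1L, ceiling((top + 1e-9) / center_bin_um))
    breaks <- seq(0, n_bins * center_bin_um, by = center_bin_um)
    labels <- sprintf("[%g,%g)", head(breaks, -1), breaks[-1])
  }
  bin <- cut(d, breaks = breaks, labels = labels, right = FALSE,
             include.lowest = TRUE)
  groups <- split(v, bin)         # keeps empty levels
  summ <- function(x) {
    if (!length(x)) return(rep(NA_real_, 5))
    quantile(x, c(0.5, 0.25, 0.75, 0.05, 0.95), names = FALSE)
  }
  stats <- t(vapply(groups, summ, numeric(5)))
  tab <- data.frame(bin = labels,
                    bin_low_um = head(breaks, -1),
                    bin_high_um = breaks[-1],
                    n = vapply(groups, length, integer(1)),
                    median = stats[, 1], q25 = stats[, 2], q75 = stats[, 3],
                    p5 = stats[, 4], p95 = stats[, 5],
                    row.names = NULL)
  structure(list(table = tab, values = groups, bin_kind = bin_kind),
            class = "binned_flirr_profile")
}

#' @export
print.binned_flirr_profile <- function(x, ...) {
  cat(sprintf("<binned_flirr_profile> %s binning, %d bins\n",
              x$bin_kind, nrow(x$table)))
  print(x$table, digits = 3)
  invisible(x)
}

#' Linear FLIRR gradient along a distance coordinate
#'
#' Ordinary-least-squares slope of per-pixel FLIRR on per-pixel distance
#' (distance converted to millimetres), i.e. the metabolic gradient in
#' FLIRR/mm. `use = "bin_medians"` fits on per-bin median FLIRR at bin
#' midpoints instead of raw pixels.
#'
#' @param flirr a [compute_flirr()] map.
#' @param distmap a matching distance map.
#' @param use `"pixels"` (default) or `"bin_medians"`.
#' @param ... bin settings passed to [bin_flirr_by_distance()] when
#'   `use = "bin_medians"`.
#' @return A list of class `flirr_gradient`: `slope` (FLIRR/mm),
#'   `intercept`, `std_error`, `n`.
#' @export
gradient_slope <- function(flirr, distmap, use = c("pixels", "bin_medians"),
                           ...) {
  use <- match.arg(use)
  stopifnot(inherits(flirr, "flirr_map"), inherits(distmap, "distance_map"))
  if (use == "pixels") {
    sel <- flirr$mask & distmap$mask & !is.na(distmap$values)
    y <- flirr$values[sel]
    x_mm <- distmap$values[sel] / 1000
  } else {
    prof <- bin_flirr_by_distance(flirr, distmap, ...)
    ok <- prof$table$n > 0 & is.finite(prof$table$bin_high_um)
    y <- prof$table$median[ok]
    x_mm <- (prof$table$bin_low_um[ok] + prof$table$bin_high_um[ok]) / 2000
  }
  if (length(unique(x_mm)) < 2L)
    abort("need at least 2 distinct distances for a slope",
          "spheroflim_degenerate_input")
  fit <- lm(y ~ x_mm)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 std_error = unname(sm[2, 2]), n = length(y)),
            class = "flirr_gradient")
}

#' @export
print.flirr_gradient <- function(x, ...) {
  cat(sprintf("<flirr_gradient> %.3g FLIRR/mm (se %.3g, n = %d)\n",
              x$slope, x$std_error, x$n))
  invisible(x)
}
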