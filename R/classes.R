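# Lightweight S3 containers shared across the pipeline stages.
# All images are numeric matrices indexed [row, col]; decay cubes are
# [row, col, time-bin] arrays. Time bins are indexed from t = 0 at the left
# edge of bin 1, with model evaluation at bin centers.

abort <- function(msg, class) {
  stop(structure(class = c(class, "spheroflim_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Construct an instrument response profile
#'
#' @param values numeric vector of non-negative temporal weights; normalized
#'   internally to sum to 1.
#' @param bin_width_ps temporal bin width in picoseconds.
#' @param fwhm_ps nominal full width at half maximum in picoseconds
#'   (`NA` when unknown, e.g. for measured profiles).
#' @return An object of class `irf_profile`.
#' @export
irf_profile <- function(values, bin_width_ps, fwhm_ps = NA_real_) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || any(values < 0))
    abort("IRF values must be finite and non-negative", "spheroflim_invalid_argument")
  s <- sum(values)
  if (s <= 0)
    abort("IRF must contain positive mass", "spheroflim_invalid_argument")
  structure(list(values = values / s, bin_width_ps = bin_width_ps,
                 fwhm_ps = fwhm_ps),
            class = "irf_profile")
}

#' @export
print.irf_profile <- function(x, ...) {
  cat(sprintf("<irf_profile> %d bins x %.3g ps, fwhm %s ps\n",
              length(x$values), x$bin_width_ps,
              ifelse(is.na(x$fwhm_ps), "?", format(x$fwhm_ps))))
  invisible(x)
}

#' Construct a TCSPC decay image
#'
#' @param counts integer-valued array `[row, col, time]` of photon counts.
#' @param bin_width_ps temporal bin width in picoseconds.
#' @param period_ns laser repetition period in nanoseconds.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param channel `"NADH"` or `"FAD"`.
#' @return An object of class `decay_image`.
#' @export
decay_image <- function(counts, bin_width_ps, period_ns, pixel_size_um,
                        channel = c("NADH", "FAD")) {
  channel <- match.arg(channel)
  if (length(dim(counts)) != 3L)
    abort("counts must be a 3-D [row, col, time] array", "spheroflim_invalid_argument")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers", "spheroflim_invalid_argument")
  structure(list(counts = counts, bin_width_ps = bin_width_ps,
                 period_ns = period_ns, pixel_size_um = pixel_size_um,
                 channel = channel),
            class = "decay_image")
}

#' @export
print.decay_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<decay_image> %s %dx%d px, %d bins x %.3g ps, %.3g um/px, %d photons\n",
              x$channel, d[1], d[2], d[3], x$bin_width_ps, x$pixel_size_um,
              sum(x$counts)))
  invisible(x)
}

#' Construct a binary mask
#'
#' @param values logical matrix (`TRUE` = foreground).
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param provenance which pipeline produced the mask.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, pixel_size_um,
                        provenance = c("truth", "intact_pipeline",
                                       "migratory_pipeline")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(values)) abort("mask must be a matrix", "spheroflim_invalid_argument")
  storage.mode(values) <- "logical"
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %dx%d px (%s), %d foreground px\n",
              nrow(x$values), ncol(x$values), x$provenance, sum(x$values)))
  invisible(x)
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %s, %dx%d px @ %.3g um/px, %d mask px\n",
              x$scene_kind, nrow(x$mask), ncol(x$mask), x$pixel_size_um,
              sum(x$mask)))
  invisible(x)
}

#' @export
print.lifetime_maps <- function(x, ...) {
  cat(sprintf("<lifetime_maps> %s, %dx%d px, %d fitted px\n",
              x$channel, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' @export
print.flirr_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<flirr_map> %dx%d px, %d valid px, median %.3g\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              if (length(v)) median(v) else NA))
  invisible(x)
}

#' @export
print.pdf_estimate <- function(x, ...) {
  cat(sprintf("<pdf_estimate> %d grid points on [%.2f, %.2f], n = %d\n",
              length(x$grid), min(x$grid), max(x$grid), x$n_samples))
  invisible(x)
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> reference = %s, %d px, max %.1f um\n",
              x$reference, sum(x$mask), max(x$values[x$mask], 0)))
  invisible(x)
}

# internal: min-max normalization to [0, 1]; errors on constant input
normalize01 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng)))
    abort("image contains non-finite values", "spheroflim_invalid_argument")
  if (rng[2] <= rng[1])
    abort("image has zero dynamic range", "spheroflim_degenerate_input")
  (x - rng[1]) / (rng[2] - rng[1])
}

# internal: derive a per-unit 32-bit sub-seed from a global seed and an index
derive_seed <- function(seed, index) {
  ((as.double(seed) %% 1000003) * 10007 + as.double(index) * 97) %% 2147483647
}
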