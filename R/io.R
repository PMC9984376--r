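# File interchange. Decay cubes travel as multi-page TIFF (one page per
# temporal bin, counts stored as normalized 32-bit samples, lossless for
# integer counts) with a JSON metadata sidecar; IRFs as two-column CSV
# (time_ps, value); masks as 8-bit TIFF; parameter/FLIRR maps as scaled
# 32-bit TIFF with a JSON sidecar recording the scale.

TIFF_SCALE <- 2^32 - 1

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a decay image to a multi-page TIFF plus JSON metadata sidecar
#'
#' One TIFF page per temporal bin; counts round-trip bit-identically for
#' values below 2^32. Metadata (`n_bins`, `bin_width_ps`, `period_ns`,
#' `pixel_size_um`, `channel`) is stored next to the TIFF in
#' `<path sans .tif>.json`.
#'
#' @param decay a [decay_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_decay <- function(decay, path) {
  stopifnot(inherits(decay, "decay_image"))
  d <- dim(decay$counts)
  pages <- lapply(seq_len(d[3]), function(k) decay$counts[, , k] / TIFF_SCALE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  meta <- list(n_bins = d[3], bin_width_ps = decay$bin_width_ps,
               period_ns = decay$period_ns,
               pixel_size_um = decay$pixel_size_um, channel = decay$channel)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a decay image written by [write_decay()]
#'
#' @param path TIFF path with its JSON sidecar alongside.
#' @return A [decay_image()]; errors name any missing metadata field, and a
#'   page count differing from the declared `n_bins` is a format error.
#' @export
read_decay <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    abort(sprintf("metadata sidecar not found: %s", sp), "spheroflim_format_error")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("n_bins", "bin_width_ps", "period_ns", "pixel_size_um", "channel"))
    if (is.null(meta[[f]]))
      abort(sprintf("decay metadata missing field \"%s\"", f),
            "spheroflim_format_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_bins)
    abort(sprintf("TIFF has %d pages but metadata declares %d temporal bins",
                  length(pages), meta$n_bins), "spheroflim_format_error")
  counts <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) counts[, , k] <- round(pages[[k]] * TIFF_SCALE)
  if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"
  decay_image(counts, bin_width_ps = meta$bin_width_ps,
              period_ns = meta$period_ns, pixel_size_um = meta$pixel_size_um,
              channel = meta$channel)
}

#' Write an IRF profile as a two-column CSV
#'
#' Columns `time_ps` (bin centers) and `value`.
#'
#' @param irf an [irf_profile()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_irf <- function(irf, path) {
  stopifnot(inherits(irf, "irf_profile"))
  t_ps <- (seq_along(irf$values) - 0.5) * irf$bin_width_ps
  write.csv(data.frame(time_ps = t_ps, value = irf$values), path,
            row.names = FALSE)
  invisible(path)
}

#' Read a measured IRF profile from a two-column CSV
#'
#' Expects numeric columns `time_ps` and `value` (or any two numeric
#' columns, taken in order); values must be non-negative. The profile is
#' normalized to unit mass; the bin width is inferred from the time column.
#'
#' @param path CSV path.
#' @return An [irf_profile()] with `fwhm_ps` estimated from the half-maximum
#'   crossings of the profile.
#' @export
read_irf <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 2L || !is.numeric(df[[1]]) || !is.numeric(df[[2]]))
    abort("IRF CSV needs two numeric columns (time_ps, value)",
          "spheroflim_format_error")
  v <- df[[2]]
  if (anyNA(v) || any(v < 0))
    abort("IRF values must be non-negative", "spheroflim_format_error")
  bw <- if (nrow(df) > 1L) median(diff(df[[1]])) else NA_real_
  irf_profile(v, bin_width_ps = bw, fwhm_ps = irf_fwhm(v, bw))
}

# internal: discrete FWHM of a profile via linear interpolation of the
# half-maximum crossings; NA when not measurable (e.g. delta or flat)
irf_fwhm <- function(v, bin_width_ps) {
  if (is.na(bin_width_ps) || max(v) <= 0) return(NA_real_)
  half <- max(v) / 2
  above <- which(v > half)
  if (!length(above)) return(NA_real_)
  lo <- min(above); hi <- max(above)
  left <- if (lo == 1L) lo - 0.5 else
    lo - (v[lo] - half) / (v[lo] - v[lo - 1L])
  right <- if (hi == length(v)) hi + 0.5 else
    hi + (v[hi] - half) / (v[hi] - v[hi + 1L])
  (right - left) * bin_width_ps
}

#' Write a binary mask as an 8-bit TIFF
#'
#' @param mask a [binary_mask()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  tiff::writeTIFF(mask$values * 1, path, bits.per.sample = 8,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_um = mask$pixel_size_um,
                            provenance = mask$provenance),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path TIFF path.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    abort(sprintf("metadata sidecar not found: %s", sp), "spheroflim_format_error")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  v <- tiff::readTIFF(path) > 0.5
  binary_mask(v, meta$pixel_size_um, meta$provenance)
}

#' Write a real-valued map (lifetime parameter, FLIRR, distance) as TIFF
#'
#' Values are scaled into `[0, 1]` by their recorded maximum (stored in the
#' JSON sidecar); NA pixels are stored as 0 with a validity page.
#'
#' @param values numeric matrix (NA allowed).
#' @param path output TIFF path.
#' @param pixel_size_um pixel size recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_map <- function(values, path, pixel_size_um = NA_real_) {
  finite <- is.finite(values)
  scale <- max(abs(values[finite]), 1)
  lo <- min(values[finite], 0)
  v <- (ifelse(finite, values, lo) - lo) / (scale - lo + (scale == lo))
  tiff::writeTIFF(list(v, finite * 1), path, bits.per.sample = 32,
                  compression = "none")
  jsonlite::write_json(list(scale = scale, offset = lo,
                            pixel_size_um = pixel_size_um),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a map written by [write_map()]
#'
#' @param path TIFF path.
#' @return Numeric matrix with NA at invalid pixels.
#' @export
read_map <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- pages[[1]] * (meta$scale - meta$offset) + meta$offset
  v[pages[[2]] < 0.5] <- NA_real_
  v
}
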