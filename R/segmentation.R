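# Binary-mask generation from time-integrated NAD(P)H intensity images.
# Two pipelines: one for fields containing a full or partial spheroid
# (Otsu + morphology), one for fields containing only scattered migrating
# cells (top-hat + anisotropic diffusion + multiscale Hessian enhancement +
# locally adaptive threshold + region-based active contour). Both normalize
# first, so masks are invariant to positive rescaling of the intensity.

#' Time-integrated intensity image from a decay image
#'
#' Sums photon counts over all temporal bins per pixel.
#'
#' @param decay a [decay_image()].
#' @return A list of class `intensity_image` with fields `values`
#'   (numeric matrix) and `pixel_size_um`.
#' @export
intensity_from_decay <- function(decay) {
  stopifnot(inherits(decay, "decay_image"))
  v <- rowSums(decay$counts, dims = 2)
  structure(list(values = v, pixel_size_um = decay$pixel_size_um),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %dx%d px, total %d counts\n",
              nrow(x$values), ncol(x$values), round(sum(x$values))))
  invisible(x)
}

as_intensity <- function(x) {
  if (inherits(x, "intensity_image")) return(x)
  if (inherits(x, "decay_image")) return(intensity_from_decay(x))
  abort("expected an intensity_image or decay_image", "spheroflim_invalid_argument")
}

# internal: drop connected components that touch the image border
clear_border <- function(bw) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  if (max(lab) == 0) return(bw)
  edge_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  edge_labels <- edge_labels[edge_labels > 0]
  bw & !(lab %in% edge_labels)
}

#' Segment a full or partial spheroid from an intensity image
#'
#' Fixed pipeline: min-max normalize to `[0, 1]`; two-class Otsu threshold
#' (256 histogram bins); morphological dilation with a disk structuring
#' element; hole filling; removal of components touching the image border.
#'
#' @param intensity an `intensity_image` (or a [decay_image()], summed
#'   internally).
#' @param dilate_radius_px radius of the disk structuring element (default 3).
#' @return A [binary_mask()] with provenance `"intact_pipeline"`.
#' @export
segment_intact <- function(intensity, dilate_radius_px = 3L) {
  intensity <- as_intensity(intensity)
  n <- normalize01(intensity$values)
  th <- EBImage::otsu(EBImage::Image(n), range = c(0, 1), levels = 256)
  bw <- n > th
  brush <- EBImage::makeBrush(2L * dilate_radius_px + 1L, shape = "disc")
  bw <- EBImage::imageData(EBImage::dilate(EBImage::Image(bw * 1), brush)) > 0
  bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  bw <- clear_border(bw)
  binary_mask(bw, intensity$pixel_size_um, "intact_pipeline")
}

# internal: Perona-Malik anisotropic diffusion (edge-preserving denoising).
# Conduction uses the exponential gradient-modulus stopping function; the
# scale K defaults to the 90th percentile of the initial gradient magnitude.
aniso_diffusion <- function(x, iterations = 10L, lambda = 0.2, K = NULL) {
  n <- nrow(x); m <- ncol(x)
  shifts <- function(x) list(
    N = rbind(x[1, , drop = FALSE], x[-n, , drop = FALSE]) - x,
    S = rbind(x[-1, , drop = FALSE], x[n, , drop = FALSE]) - x,
    W = cbind(x[, 1, drop = FALSE], x[, -m, drop = FALSE]) - x,
    E = cbind(x[, -1, drop = FALSE], x[, m, drop = FALSE]) - x)
  if (is.null(K)) {
    d0 <- shifts(x)
    K <- quantile(abs(c(d0$N, d0$S, d0$W, d0$E)), 0.9, names = FALSE)
    if (K <= 0) return(x)
  }
  for (it in seq_len(iterations)) {
    d <- shifts(x)
    g <- function(v) exp(-(v / K)^2)
    x <- x + lambda * (g(d$N) * d$N + g(d$S) * d$S + g(d$W) * d$W +
                         g(d$E) * d$E)
  }
  x
}

# internal: Gaussian-smoothed Hessian of a 2-D image at scale sigma
hessian_at_scale <- function(x, sigma) {
  g <- EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = sigma))
  n <- nrow(g); m <- ncol(g)
  pad_r <- function(a) rbind(a[1, , drop = FALSE], a, a[n, , drop = FALSE])
  pad_c <- function(a) cbind(a[, 1, drop = FALSE], a, a[, m, drop = FALSE])
  gp <- pad_c(pad_r(g))           # replicate-padded (n+2) x (m+2)
  i <- 2:(n + 1); j <- 2:(m + 1)
  hrr <- gp[i + 1, j] - 2 * gp[i, j] + gp[i - 1, j]
  hcc <- gp[i, j + 1] - 2 * gp[i, j] + gp[i, j - 1]
  hrc <- (gp[i + 1, j + 1] - gp[i + 1, j - 1] -
            gp[i - 1, j + 1] + gp[i - 1, j - 1]) / 4
  list(hrr = hrr, hcc = hcc, hrc = hrc)
}

# internal: multiscale Hessian blob enhancement (bright blobs on dark
# background). Response at each scale is the gamma-normalized geometric mean
# of the negated eigenvalues where both are negative; the maximum over
# scales is returned.
multiscale_hessian <- function(x, sigmas = c(2, 4, 6)) {
  out <- matrix(0, nrow(x), ncol(x))
  for (s in sigmas) {
    H <- hessian_at_scale(x, s)
    tr <- H$hrr + H$hcc
    dt <- H$hrr * H$hcc - H$hrc^2
    disc <- sqrt(pmax(tr^2 / 4 - dt, 0))
    l1 <- tr / 2 - disc
    l2 <- tr / 2 + disc                       # l1 <= l2
    resp <- ifelse(l2 < 0, s^2 * sqrt(pmax(l1 * l2, 0)), 0)
    out <- pmax(out, resp)
  }
  out
}

# internal: box local mean with replicate boundary handling
local_mean <- function(x, half) {
  n <- nrow(x); m <- ncol(x)
  ri <- pmin(pmax(seq_len(n), 1L), n)
  # cumulative-sum box filter along rows then columns with edge clamping
  box1 <- function(a, h) {
    nn <- nrow(a)
    cs <- rbind(0, apply(a, 2, cumsum))
    lo <- pmax(seq_len(nn) - h, 1L)
    hi <- pmin(seq_len(nn) + h, nn)
    (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  t(box1(t(box1(x, half)), half))
}

# internal: locally adaptive threshold. Foreground where the image exceeds
# the local mean plus a noise floor of k robust standard deviations, with
# k = 10 * (1 - sensitivity); sigma is estimated as the MAD of the whole
# image. sensitivity = 1 reduces to pure local-mean thresholding.
adaptive_threshold <- function(x, neighborhood = NULL, sensitivity = 0.5) {
  if (is.null(neighborhood))
    neighborhood <- max(3L, 2L * floor(ncol(x) / 16) + 1L)
  half <- max(1L, (neighborhood - 1L) %/% 2L)
  lm_ <- local_mean(x, half)
  sigma <- mad(x)
  if (sigma <= 0) sigma <- sd(x)
  k <- 10 * (1 - sensitivity)
  x > (lm_ + k * sigma)
}

# internal: region-based (Chan-Vese style) active contour refinement.
# Alternates the optimal two-phase means with a curvature-regularizing
# Gaussian smoothing of the indicator; stops when the mask is stable.
active_contour <- function(img, init, iterations = 100L, smooth_sigma = 1) {
  u <- init
  if (!any(u) || all(u)) return(init)
  for (it in seq_len(iterations)) {
    c1 <- mean(img[u]); c2 <- mean(img[!u])
    f <- (img - c2)^2 - (img - c1)^2          # >0 where inside is favoured
    us <- EBImage::imageData(EBImage::gblur(EBImage::Image(u * 1),
                                            sigma = smooth_sigma))
    u_new <- (us - 0.5) + f / (max(abs(f)) + 1e-12) > 0
    if (!any(u_new) || all(u_new)) break
    if (identical(u_new, u)) { u <- u_new; break }
    u <- u_new
  }
  u
}

#' Segment scattered migrating cells from an intensity image
#'
#' Fixed pipeline for fields without a coherent spheroid body: white top-hat
#' (small-structure enhancement) > min-max normalization > anisotropic
#' diffusion (edge-preserving denoising) > multiscale Hessian blob
#' enhancement > second top-hat > locally adaptive threshold > region-based
#' active-contour refinement seeded with the thresholded mask on the
#' contrast-enhanced image.
#'
#' @param intensity an `intensity_image` (or a [decay_image()]).
#' @param tophat_radius_px disk radius of the top-hat structuring element.
#' @param diffusion_iters Perona-Malik iterations.
#' @param hessian_sigmas scales (px) for the multiscale Hessian filter.
#' @param neighborhood adaptive-threshold window size in px (odd; default
#'   about 1/8 of the image width).
#' @param sensitivity adaptive-threshold sensitivity in `[0, 1]`; higher
#'   values admit dimmer structures.
#' @param contour_iters active-contour iterations.
#' @return A [binary_mask()] with provenance `"migratory_pipeline"`.
#' @export
segment_migratory <- function(intensity, tophat_radius_px = 15L,
                              diffusion_iters = 10L,
                              hessian_sigmas = c(2, 4, 6),
                              neighborhood = NULL, sensitivity = 0.5,
                              contour_iters = 100L) {
  intensity <- as_intensity(intensity)
  se <- EBImage::makeBrush(2L * tophat_radius_px + 1L, shape = "disc")
  # EBImage grayscale morphology assumes the [0, 1] range, so images are
  # rescaled by their maximum (a scale-invariant linear map) before each
  # top-hat; the top-hat itself commutes with positive scaling.
  unit_range <- function(a) {
    mx <- max(a)
    if (mx <= 0) abort("image has zero dynamic range", "spheroflim_degenerate_input")
    a / mx
  }
  x <- EBImage::imageData(
    EBImage::whiteTopHat(EBImage::Image(unit_range(intensity$values)), se))
  x <- normalize01(x)
  x <- aniso_diffusion(x, iterations = diffusion_iters)
  x <- multiscale_hessian(x, sigmas = hessian_sigmas)
  x <- EBImage::imageData(
    EBImage::whiteTopHat(EBImage::Image(unit_range(x)), se))
  enhanced <- x
  seed_mask <- adaptive_threshold(enhanced, neighborhood, sensitivity)
  bw <- active_contour(enhanced, seed_mask, iterations = contour_iters)
  binary_mask(bw, intensity$pixel_size_um, "migratory_pipeline")
}
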