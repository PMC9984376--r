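# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

intensity_fixture <- function(values, pixel_size_um = 0.8) {
  structure(list(values = values, pixel_size_um = pixel_size_um),
            class = "intensity_image")
}

# brute-force exact Euclidean distance transform: for each foreground pixel,
# scan all background pixels (oracle for distance_from_edge)
brute_force_edt <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(fg))) {
    out[fg[k, 1], fg[k, 2]] <-
      sqrt(min((bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2))
  }
  out
}

# lattice enumeration of a disk: count of integer points with
# (i-cr)^2 + (j-cc)^2 <= r^2 inside an n x n grid
disk_lattice_count <- function(n, cr, cc, r) {
  cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - cr)^2 + (j - cc)^2 <= r^2) cnt <- cnt + 1L
  cnt
}

# field of Gaussian intensity bumps on a Poisson background
gaussian_blob_field <- function(n, centers, sigma_px, peak, bg, seed) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  sig <- matrix(0, n, n)
  for (k in seq_len(nrow(centers)))
    sig <- sig + exp(-((rows - centers[k, 1])^2 +
                         (cols - centers[k, 2])^2) / (2 * sigma_px^2))
  set.seed(seed)
  matrix(rpois(n * n, bg + peak * sig), n, n)
}

# jittered-grid blob centers with guaranteed separation
blob_centers <- function(n_blobs, field, margin = 35, seed = 1) {
  per_side <- ceiling(sqrt(n_blobs))
  g <- seq(margin, field - margin, length.out = per_side)
  ctr <- as.matrix(expand.grid(g, g))[seq_len(n_blobs), , drop = FALSE]
  set.seed(seed)
  ctr + matrix(runif(2 * n_blobs, -6, 6), ncol = 2)
}

# dense grid-search oracle for the bi-exponential fit: minimizes the same
# unweighted SSR as fit_decay over a lattice of (alpha1, tau1, tau2) with
# the amplitude profiled analytically
grid_search_fit <- function(decay, irf, period_ns,
                            alphas = seq(0, 1, length.out = 21),
                            taus = exp(seq(log(0.05), log(8),
                                           length.out = 25))) {
  n <- length(decay)
  C <- spheroflim:::conv_operator(irf$values, n)
  bw_ns <- period_ns / n
  best <- list(ssr = Inf)
  for (a in alphas) for (t1 in taus) for (t2 in taus) {
    if (t1 > t2) next
    m <- decay_model(a, t1, t2, n, bw_ns)
    s <- as.vector(C %*% m)
    A <- max(sum(decay * s) / sum(s * s), 0)
    ssr <- sum((decay - A * s)^2)
    if (is.finite(ssr) && ssr < best$ssr)
      best <- list(ssr = ssr, alpha1 = a, tau1 = t1, tau2 = t2, A = A)
  }
  best
}

# noiseless expected decay (coarse grid) for given truth, via the exported
# forward-model pieces
expected_binned_decay <- function(alpha1, tau1, tau2, irf, total,
                                  n_native = 256, t_out = 64,
                                  period_ns = 12.5) {
  m <- decay_model(alpha1, tau1, tau2, n_native, period_ns / n_native)
  s <- convolve_irf(m, irf)
  s <- s / sum(s) * total
  as.vector(rowsum(s, rep(seq_len(t_out), each = n_native / t_out)))
}
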