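# Phantom generator: IRF discretization, scene geometry, forward model.

test_that("discretized Gaussian IRF has the requested width and unit mass", {
  bw <- 12500 / 256
  irf <- make_irf(339, n_bins = 256, bin_width_ps = bw, center_bin = 16)
  expect_equal(sum(irf$values), 1, tolerance = 1e-9)
  # measured discrete FWHM within one bin width of the nominal value
  v <- irf$values
  half <- max(v) / 2
  ab <- which(v > half)
  lo <- min(ab); hi <- max(ab)
  left <- lo - (v[lo] - half) / (v[lo] - v[lo - 1])
  right <- hi + (v[hi] - half) / (v[hi] - v[hi + 1])
  expect_lt(abs((right - left) * bw - 339), bw)
  # delta limit
  d <- make_irf(0, n_bins = 64, bin_width_ps = bw, center_bin = 10)
  expect_identical(d$values[10], 1)
  expect_equal(sum(d$values), 1)
  # normalization holds across widths
  for (f in c(50, 396, 1200))
    expect_equal(sum(make_irf(f, 128, bw, 12)$values), 1, tolerance = 1e-9)
  expect_error(make_irf(-1, 64, bw), class = "spheroflim_invalid_argument")
  expect_error(make_irf(100, 64, bw, center_bin = 65),
               class = "spheroflim_invalid_argument")
})

test_that("intact disk phantom matches lattice enumeration and is connected", {
  sc <- make_phantom("intact", size = 512, pixel_size_um = 0.8,
                     radius_px = 150,
                     gradient = list(alpha2 = c(0.6, 0.6),
                                     tau1 = c(0.4, 0.4),
                                     tau2 = c(2.5, 2.5)))
  expect_identical(sum(sc$mask),
                   disk_lattice_count(512, 256.5, 256.5, 150))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(sc$mask * 1)))
  expect_equal(max(lab), 1)
  expect_false(any(sc$mask[1, ]) || any(sc$mask[512, ]) ||
                 any(sc$mask[, 1]) || any(sc$mask[, 512]))
  # alpha maps are complementary fractions
  expect_true(all(abs(sc$alpha1[sc$mask] + sc$alpha2[sc$mask] - 1) == 0))
})

test_that("gradient fields interpolate monotonically from edge to core", {
  sc <- make_phantom("intact", size = 128, radius_px = 40,
                     gradient = list(alpha2 = c(edge = 0.8, core = 0.5),
                                     tau1 = c(0.4, 0.4), tau2 = c(2.5, 2.5)))
  d <- sc$edge_dist_um[sc$mask]
  a2 <- sc$alpha2[sc$mask]
  o <- order(d)
  expect_true(all(diff(a2[o]) <= 1e-12))
  expect_equal(max(a2), 0.8, tolerance = 0.01)   # boundary pixels sit ~1 px in
  # tau bounds respected on the mask
  expect_true(all(sc$tau1[sc$mask] >= 0.02 & sc$tau2[sc$mask] <= 100))
})

test_that("scattered scenes place the requested number of disjoint blobs", {
  sc <- make_phantom("scattered", size = 256, radius_px = 80, n_blobs = 12,
                     blob_radius_px = 5, seed = 3)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(sc$mask * 1)))
  expect_equal(max(lab), 12)
  sc2 <- make_phantom("partial", size = 256, radius_px = 50, n_blobs = 6,
                      blob_radius_px = 5, seed = 3)
  lab2 <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(sc2$mask * 1)))
  expect_equal(max(lab2), 7)    # core + satellites
  expect_error(make_phantom("intact", size = 64, radius_px = 40),
               class = "spheroflim_invalid_argument")
})

test_that("IRF convolution conserves total intensity", {
  set.seed(11)
  for (rep in 1:5) {
    irf <- make_irf(runif(1, 100, 800), n_bins = 128,
                    bin_width_ps = 12500 / 128, center_bin = 12)
    m <- decay_model(runif(1), runif(1, 0.1, 1), runif(1, 1, 5),
                     128, 12.5 / 128)
    full <- convolve_irf(m, irf, truncate = FALSE)
    expect_equal(sum(full), sum(m), tolerance = 1e-6)
    # truncation can only lose mass; wrap folds it back
    expect_lte(sum(convolve_irf(m, irf)), sum(full) + 1e-12)
    expect_equal(sum(convolve_irf(m, irf, wrap = TRUE)), sum(m),
                 tolerance = 1e-9)
  }
})

test_that("simulated totals follow the Poisson photon budget", {
  irf <- make_irf(339, 256, 12500 / 256, 16)
  sc <- make_phantom("intact", size = 48, radius_px = 14,
                     gradient = list(alpha2 = c(0.6, 0.6),
                                     tau1 = c(0.4, 0.4), tau2 = c(2.5, 2.5)))
  dk <- simulate_decay_image(sc, irf, photons_per_pixel = 500, seed = 9)
  lambda <- 500 * sum(sc$mask)
  expect_lt(abs(sum(dk$counts) - lambda), 5 * sqrt(lambda))
  # zero budget
  dk0 <- simulate_decay_image(sc, irf, photons_per_pixel = 0, seed = 9)
  expect_equal(sum(dk0$counts), 0)
  # determinism
  dk2 <- simulate_decay_image(sc, irf, photons_per_pixel = 500, seed = 9)
  expect_identical(dk$counts, dk2$counts)
  dk3 <- simulate_decay_image(sc, irf, photons_per_pixel = 500, seed = 10)
  expect_false(identical(dk$counts, dk3$counts))
})

test_that("mono-exponential decays are log-linear with slope -1/tau", {
  # alpha1 = 1, delta IRF, huge photon budget: log counts vs t is a line
  irf <- make_irf(0, 256, 12500 / 256, center_bin = 1)
  sc <- make_phantom("intact", size = 16, radius_px = 4,
                     gradient = list(alpha2 = c(0, 0),
                                     tau1 = c(1.2, 1.2), tau2 = c(3, 3)))
  dk <- simulate_decay_image(sc, irf, photons_per_pixel = 1e6, seed = 2)
  px <- which(sc$mask, arr.ind = TRUE)[1, ]
  y <- dk$counts[px[1], px[2], ]
  t_ns <- (seq_len(256) - 0.5) * 12.5 / 256
  keep <- y > 20
  fit <- lm(log(y[keep]) ~ t_ns[keep], weights = y[keep])
  expect_equal(unname(coef(fit)[2]), -1 / 1.2, tolerance = 0.01)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("noiseless phantom decays round-trip through the fitter", {
  irf <- make_irf(339, 256, 12500 / 256, 16)
  sc <- make_phantom("intact", size = 24, radius_px = 8,
                     gradient = list(alpha2 = c(edge = 0.7, core = 0.5),
                                     tau1 = c(0.4, 0.4), tau2 = c(2.5, 2.5)))
  cube <- spheroflim:::expected_decay_cube(sc, irf, 1e4, 256, 12.5)
  pxs <- which(sc$mask, arr.ind = TRUE)
  for (k in c(1, 50, 120)) {
    i <- pxs[k, 1]; j <- pxs[k, 2]
    y64 <- as.vector(rowsum(cube[i, j, ], rep(1:64, each = 4)))
    fr <- fit_decay(y64, irf, period_ns = 12.5, seed = 4)
    expect_equal(fr$alpha2, sc$alpha2[i, j], tolerance = 1e-3)
    expect_equal(fr$tau1, sc$tau1[i, j], tolerance = 1e-3)
    expect_equal(fr$tau2, sc$tau2[i, j], tolerance = 1e-3)
  }
})

test_that("scene_with_gradient shares geometry but swaps parameter fields", {
  sc <- make_phantom("intact", size = 64, radius_px = 20)
  sf <- scene_with_gradient(sc, list(alpha2 = c(0.25, 0.25),
                                     tau1 = c(0.3, 0.3), tau2 = c(2, 2)))
  expect_identical(sf$mask, sc$mask)
  expect_identical(sf$center, sc$center)
  expect_true(all(sf$alpha1[sf$mask] == 0.75))
})
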