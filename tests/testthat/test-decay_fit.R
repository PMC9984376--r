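# Binning semantics and the constrained bi-exponential fitter.

test_that("spatial_temporal_bin matches a direct summation oracle", {
  set.seed(3)
  d <- c(12, 10, 8)
  counts <- array(rpois(prod(d), 5), dim = d)
  dk <- decay_image(counts, 48.8, 12.5, 0.8, "NADH")
  mask <- matrix(runif(d[1] * d[2]) > 0.3, d[1], d[2])
  bn <- spatial_temporal_bin(dk, mask, window = 5, t_out = 4)
  half_lo <- 2; half_hi <- 2
  for (px in list(c(1, 1), c(6, 5), c(12, 10), c(3, 9))) {
    if (!mask[px[1], px[2]]) next
    rr <- max(1, px[1] - half_lo):min(d[1], px[1] + half_hi)
    cc <- max(1, px[2] - half_lo):min(d[2], px[2] + half_hi)
    expected <- numeric(4)
    for (i in rr) for (j in cc) if (mask[i, j])
      expected <- expected + as.vector(rowsum(counts[i, j, ], rep(1:4, each = 2)))
    expect_equal(bn$counts[px[1], px[2], ], expected)
  }
  # unmasked pixels carry no output
  expect_true(all(bn$counts[rep(!mask, 4)] == 0))
})

test_that("binning degenerate cases: grouped sums and identity window", {
  counts <- array(1L, dim = c(6, 6, 256))
  dk <- decay_image(counts, 48.8, 12.5, 0.8, "NADH")
  mask <- matrix(TRUE, 6, 6)
  bn <- spatial_temporal_bin(dk, mask, window = 20, t_out = 64)
  # all-ones decay: every output bin = 4 x window pixel count (= 36, clipped)
  expect_true(all(bn$counts == 4 * 36))
  bn1 <- spatial_temporal_bin(dk, mask, window = 1, t_out = 256)
  expect_equal(bn1$counts, array(1, dim = c(6, 6, 256)))
  expect_error(spatial_temporal_bin(dk, mask, window = 3, t_out = 60),
               class = "spheroflim_invalid_argument")
  expect_error(spatial_temporal_bin(dk, matrix(TRUE, 5, 5), 3, 64),
               class = "spheroflim_invalid_argument")
})

test_that("fit_decay recovers noiseless decays to high accuracy", {
  irf <- make_irf(339, 256, 12500 / 256, 16)
  y <- expected_binned_decay(0.7, 0.4, 2.5, irf, 1e4)
  fr <- fit_decay(y, irf, period_ns = 12.5, seed = 1)
  expect_equal(fr$alpha1, 0.7, tolerance = 0.005)
  expect_equal(fr$tau1, 0.4, tolerance = 0.005)
  expect_equal(fr$tau2, 2.5, tolerance = 0.005)
  expect_true(fr$converged)
  expect_identical(fr$alpha1 + fr$alpha2, 1)
})

test_that("degenerate decays are handled by contract", {
  irf <- make_irf(339, 256, 12500 / 256, 16)
  # mono-exponential truth: second component flagged unidentifiable
  y <- expected_binned_decay(1, 0.8, 2.5, irf, 1e5)
  fr <- fit_decay(y, irf, seed = 2)
  expect_lte(fr$alpha2, 0.01)
  expect_equal(fr$tau1, 0.8, tolerance = 0.01)
  expect_false(fr$tau2_identifiable)
  # equal lifetimes: alpha split free, identifiable taus at the common
  # value, tiny residual (an empty component's tau carries no information)
  y2 <- expected_binned_decay(0.5, 1.5, 1.5, irf, 1e5)
  fr2 <- fit_decay(y2, irf, seed = 3)
  if (fr2$tau1_identifiable) expect_equal(fr2$tau1, 1.5, tolerance = 0.015)
  if (fr2$tau2_identifiable) expect_equal(fr2$tau2, 1.5, tolerance = 0.015)
  expect_true(fr2$tau1_identifiable || fr2$tau2_identifiable)
  expect_lt(fr2$residual_norm, 1e-6 * sum(y2^2))
  expect_error(fit_decay(rep(0, 64), irf), class = "spheroflim_no_signal")
})

test_that("fitted parameters respect constraints on noisy decays", {
  irf <- make_irf(396, 256, 12500 / 256, 16)
  set.seed(14)
  for (k in 1:6) {
    truth <- c(runif(1), runif(1, 0.1, 0.8), runif(1, 1, 4))
    E <- expected_binned_decay(truth[1], truth[2], truth[3], irf, 3000)
    y <- rpois(64, E)
    fr <- fit_decay(y, irf, seed = k)
    expect_identical(fr$alpha1 + fr$alpha2, 1)
    expect_true(fr$alpha1 >= 0 && fr$alpha1 <= 1)
    expect_true(fr$tau1 >= 0.02 && fr$tau2 <= 100)
    expect_lte(fr$tau1, fr$tau2)
  }
})

test_that("fit_decay matches a dense grid-search optimum on 16-bin decays", {
  irf <- make_irf(0, n_bins = 16, bin_width_ps = 12500 / 16, center_bin = 2)
  set.seed(21)
  for (k in 1:3) {
    E <- expected_binned_decay(c(0.6, 0.35, 0.8)[k], c(0.5, 0.3, 1)[k],
                               c(2.4, 3, 2)[k], irf, 5e4,
                               n_native = 16, t_out = 16)
    y <- rpois(16, E)
    gs <- grid_search_fit(y, irf, period_ns = 12.5)
    fr <- fit_decay(y, irf, period_ns = 12.5,
                    config = fit_config(n_restarts = 8), seed = k)
    # the continuous optimizer must do at least as well as the lattice
    expect_lte(fr$residual_norm, gs$ssr * (1 + 1e-9) + 1e-9)
  }
})

test_that("fit_image is deterministic, mask-aware, and order-independent", {
  irf <- make_irf(339, 256, 12500 / 256, 16)
  sc <- make_phantom("intact", size = 20, radius_px = 6,
                     gradient = list(alpha2 = c(0.3, 0.3),
                                     tau1 = c(0.4, 0.4), tau2 = c(2.5, 2.5)))
  dk <- simulate_decay_image(sc, irf, 200, seed = 4)
  mask <- binary_mask(sc$mask, 0.8, "truth")
  bn <- spatial_temporal_bin(dk, mask, window = 8, t_out = 64)
  lt1 <- fit_image(bn, irf, fit_config(n_restarts = 3), seed = 6)
  lt2 <- fit_image(bn, irf, fit_config(n_restarts = 3), seed = 6)
  expect_identical(lt1$alpha2, lt2$alpha2)
  expect_identical(lt1$tau1, lt2$tau1)
  # fitted values only on the mask, contracts hold pixelwise
  expect_true(all(is.na(lt1$alpha1[!lt1$mask])))
  on <- lt1$mask
  expect_true(all(lt1$alpha1[on] + lt1$alpha2[on] == 1))
  expect_true(all(lt1$tau1[on] >= 0.02 & lt1$tau2[on] <= 100))
  # interior pixel near truth at this photon budget
  ctr <- round(sc$center)
  expect_equal(lt1$alpha2[ctr[1], ctr[2]], 0.3, tolerance = 0.05)
  # empty mask: no error, empty maps
  bn0 <- spatial_temporal_bin(dk, matrix(FALSE, 20, 20), 8, 64)
  lt0 <- fit_image(bn0, irf, fit_config(n_restarts = 2), seed = 1)
  expect_equal(sum(lt0$mask), 0)
})
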