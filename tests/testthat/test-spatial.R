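# Distance transforms, morphology, distance-binned FLIRR profiles, slopes.

flirr_fixture <- function(values, mask, pixel_size_um = 0.8) {
  v <- matrix(NA_real_, nrow(mask), ncol(mask))
  v[mask] <- values
  structure(list(values = v, mask = mask, pixel_size_um = pixel_size_um,
                 n_dropped = 0L),
            class = "flirr_map")
}

disk_mask <- function(n, r, cr = (n + 1) / 2, cc = (n + 1) / 2) {
  rows <- matrix(seq_len(n), n, n)
  (rows - cr)^2 + (t(rows) - cc)^2 <= r^2
}

test_that("spheroid area counts foreground pixels", {
  expect_identical(spheroid_area(matrix(TRUE, 10, 10)), 100L)
  expect_identical(spheroid_area(matrix(FALSE, 4, 4)), 0L)
  m <- disk_mask(512, 150)
  expect_identical(spheroid_area(m), disk_lattice_count(512, 256.5, 256.5, 150))
})

test_that("edge distance transform is exact against brute force", {
  set.seed(41)
  for (k in 1:8) {
    m <- matrix(runif(32 * 32) > runif(1, 0.3, 0.7), 32, 32)
    if (!any(m) || all(m)) next
    dm <- distance_from_edge(m, pixel_size_um = 1)
    bf <- brute_force_edt(m)
    expect_equal(dm$values[m], bf[m])
  }
})

test_that("edge distances follow disk geometry and boundary conventions", {
  m <- disk_mask(128, 50)
  dm <- distance_from_edge(m, pixel_size_um = 0.8)
  expect_lt(abs(max(dm$values[m]) - 50 * 0.8), 0.8)
  # pixels adjacent to background are within one pixel of the edge
  expect_lte(min(dm$values[m]), 1 * 0.8)
  # boundary-reference convention: zero on the mask boundary itself
  dm2 <- distance_from_edge(m, pixel_size_um = 0.8,
                            reference_pixels = "boundary")
  expect_equal(min(dm2$values[m]), 0)
  expect_lt(max(abs(dm$values[m] - dm2$values[m])), 2 * 0.8)
  expect_error(distance_from_edge(matrix(FALSE, 8, 8), 1),
               class = "spheroflim_degenerate_input")
})

test_that("center finding: mass center, largest component, user override", {
  m <- disk_mask(64, 20)
  ctr <- find_center(m)
  expect_lt(max(abs(ctr - c(32.5, 32.5))), 0.5)
  # largest of two components wins
  m2 <- matrix(FALSE, 64, 64)
  m2[5:29, 5:24] <- TRUE      # 500 px
  m2[50:56, 50:56] <- TRUE    # 49 px
  ctr2 <- find_center(m2)
  expect_equal(ctr2, c(17, 14.5))
  expect_identical(find_center(m2, "user_supplied", c(120, 240)),
                   c(120, 240))
  expect_error(find_center(matrix(FALSE, 4, 4)),
               class = "spheroflim_degenerate_input")
})

test_that("center distances are Euclidean in micrometres", {
  m <- matrix(TRUE, 16, 16)
  dm <- distance_from_center(m, center = c(5, 5), pixel_size_um = 0.8)
  expect_equal(dm$values[8, 9], 5 * 0.8)       # offset (3, 4) -> 5 px
  expect_equal(dm$values[5, 5], 0)
  disk <- disk_mask(128, 40)
  dmd <- distance_from_center(disk, c(64.5, 64.5), 0.8)
  expect_lt(abs(max(dmd$values[disk]) - 40 * 0.8), 0.8)
  expect_error(distance_from_center(m, c(50, 2), 0.8),
               class = "spheroflim_invalid_argument")
})

test_that("migration summaries report ordered percentiles", {
  m <- disk_mask(64, 1.2)                       # small cluster at distance d
  dm <- distance_from_center(m, c(10.5, 32.5), pixel_size_um = 1)
  s <- migration_summary(dm)
  expect_identical(s$area_pixels, sum(m))
  expect_true(all(diff(s$percentiles) >= 0))
  # constant distances collapse all percentiles
  ring <- matrix(FALSE, 32, 32); ring[16, c(4, 28)] <- TRUE
  s2 <- migration_summary(distance_from_center(ring, c(16, 16), 1))
  expect_true(all(s2$percentiles == 12))
  # uniform annulus: analytic median radius sqrt((r1^2 + r2^2) / 2)
  n <- 256
  rows <- matrix(seq_len(n), n, n)
  rr <- sqrt((rows - 128.5)^2 + (t(rows) - 128.5)^2)
  ann <- rr >= 40 & rr <= 100
  s3 <- migration_summary(distance_from_center(ann, c(128.5, 128.5), 1))
  expect_lt(abs(s3$percentiles["p50"] - sqrt((40^2 + 100^2) / 2)), 1)
})

test_that("edge binning yields five 15-um bins plus a core partition", {
  m <- disk_mask(256, 120)                      # max edge distance 96 um
  dm <- distance_from_edge(m, pixel_size_um = 0.8)
  fl <- flirr_fixture(rep(0.7, sum(m)), m)
  prof <- bin_flirr_by_distance(fl, dm)
  expect_identical(nrow(prof$table), 6L)
  expect_identical(prof$table$bin[6], "core")
  expect_identical(sum(prof$table$n), sum(m))   # partition of masked pixels
  expect_true(all(prof$table$median == 0.7))    # constant FLIRR
  # monotone medians under an imposed gradient (truth-constructed FLIRR)
  sc <- make_phantom("intact", size = 256, pixel_size_um = 0.8,
                     radius_px = 120,
                     gradient = list(alpha2 = c(edge = 0.72, core = 0.40),
                                     tau1 = c(0.4, 0.4), tau2 = c(2.5, 2.5)))
  fl2 <- flirr_fixture(sc$alpha2[sc$mask] / 0.8, sc$mask)
  dm2 <- distance_from_edge(sc$mask, 0.8)
  prof2 <- bin_flirr_by_distance(fl2, dm2)
  expect_true(all(diff(prof2$table$median) < 0))
  expect_error(
    bin_flirr_by_distance(fl, distance_from_edge(disk_mask(64, 20), 0.8)),
    class = "spheroflim_invalid_argument")
})

test_that("center binning covers the observed range in 125-um steps", {
  m <- disk_mask(256, 110)
  dm <- distance_from_center(m, c(128.5, 128.5), pixel_size_um = 3)
  fl <- flirr_fixture(runif(sum(m), 0.4, 0.6), m)
  prof <- bin_flirr_by_distance(fl, dm, bin_kind = "center")
  expect_identical(sum(prof$table$n), sum(m))
  expect_true(all(diff(prof$table$bin_low_um) == 125))
  expect_gte(max(prof$table$bin_high_um), max(dm$values[m]))
})

test_that("gradient slopes recover linear FLIRR-distance relations", {
  m <- disk_mask(128, 50)
  dm <- distance_from_center(m, c(64.5, 64.5), pixel_size_um = 3)
  d_mm <- dm$values[m] / 1000
  fl_exact <- flirr_fixture(0.4 + 0.5 * d_mm, m, 3)
  gs <- suppressWarnings(gradient_slope(fl_exact, dm))
  expect_equal(gs$slope, 0.5, tolerance = 1e-9)
  expect_equal(gs$intercept, 0.4, tolerance = 1e-9)
  # constant FLIRR: zero slope
  gs0 <- suppressWarnings(gradient_slope(flirr_fixture(rep(0.8, sum(m)), m, 3), dm))
  expect_equal(gs0$slope, 0, tolerance = 1e-12)
  # noisy linear relation recovered within 3 standard errors
  set.seed(43)
  fl_noisy <- flirr_fixture(0.4 + 0.9 * d_mm + rnorm(sum(m), 0, 0.05), m, 3)
  gsn <- gradient_slope(fl_noisy, dm)
  expect_lt(abs(gsn$slope - 0.9), 3 * gsn$std_error)
  # bin-median variant also runs
  gsb <- gradient_slope(fl_noisy, dm, use = "bin_medians")
  expect_true(is.finite(gsb$slope))
  # degenerate: single distance value
  one <- matrix(FALSE, 32, 32); one[10, c(10, 22)] <- TRUE
  dm1 <- distance_from_center(one, c(10, 16), 1)
  expect_error(gradient_slope(flirr_fixture(c(0.5, 0.6), one, 1), dm1),
               class = "spheroflim_degenerate_input")
})
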