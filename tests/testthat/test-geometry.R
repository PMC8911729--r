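test_that("energy-to-wavelength conversion matches the hc constant", {
  expect_equal(energy_to_wavelength(1.23984), 1.0)
  expect_equal(energy_to_wavelength(14), 0.08856, tolerance = 1e-4)
  expect_equal(energy_to_wavelength(12.398), 0.10000, tolerance = 1e-4)
  expect_error(energy_to_wavelength(0), "positive")
  expect_error(energy_to_wavelength(-2), "positive")
})

test_that("pixel_to_q reproduces hand-evaluated geometry", {
  geom <- detector_geometry(5.5, 172, c(840, 737), 14, c(1679, 1475))
  # beam center pixel
  at0 <- pixel_to_q(840, 737, geom)
  expect_equal(at0$q, 0)
  expect_equal(at0$chi, 0)
  # 100 px from center: 2*theta = atan(0.0172/5.5), q = (4pi/lambda) sin(theta)
  lam <- 1.23984 / 14
  q_hand <- (4 * pi / lam) * sin(atan(100 * 172e-6 / 5.5) / 2)
  expect_equal(pixel_to_q(840, 837, geom)$q, q_hand, tolerance = 1e-12)
  expect_equal(q_hand, 0.2219, tolerance = 2e-4)
  # chi axis convention: +x (columns) -> 0, +y (rows) -> 90
  expect_equal(pixel_to_q(840, 900, geom)$chi, 0)
  expect_equal(pixel_to_q(900, 737, geom)$chi, 90)
  expect_equal(pixel_to_q(840, 600, geom)$chi, 180)
})

test_that("pixel positions round-trip through (q, chi)", {
  geom <- detector_geometry(5.5, 172, c(100.3, 120.7), 14, c(256, 256))
  set.seed(1)
  row <- runif(200, 1, 256); col <- runif(200, 1, 256)
  pq <- pixel_to_q(row, col, geom)
  r_px <- q_to_radius_px(pq$q, geom)
  row2 <- geom$beam_center[1] + r_px * sin(pq$chi * pi / 180)
  col2 <- geom$beam_center[2] + r_px * cos(pq$chi * pi / 180)
  expect_lt(max(abs(row2 - row), abs(col2 - col)), 1e-6)
})

test_that("radial integration is exact on constant frames and conserves mass", {
  geom <- desk_geometry(64L)
  fr <- detector_frame(matrix(7, 64, 64))
  prof <- radial_integrate(fr, geom, c(0.1, 1.2), 30L)
  expect_true(all(abs(prof$intensity[prof$counts_per_bin > 0] - 7) < 1e-12))
  # mass balance against raw pixel counts inside the q range
  set.seed(2)
  fr2 <- detector_frame(matrix(rpois(64^2, 20), 64, 64))
  prof2 <- radial_integrate(fr2, geom, c(0.1, 1.2), 30L)
  qpix <- pixel_to_q(rep(1:64, 64), rep(1:64, each = 64), geom)$q
  inside <- qpix >= 0.1 & qpix <= 1.2
  expect_equal(sum(prof2$intensity * prof2$counts_per_bin, na.rm = TRUE),
               sum(t(fr2$counts)[inside]))
})

test_that("a sharp synthetic ring lands in the correct q bin", {
  geom <- desk_geometry(128L)
  qpix <- matrix(pixel_to_q(rep(1:128, times = 128),
                            rep(1:128, each = 128), geom)$q, 128, 128)
  qstar <- 0.45
  counts <- 10 + 1000 * exp(-(qpix - qstar)^2 / (2 * 0.01^2))
  prof <- radial_integrate(detector_frame(counts), geom, c(0.1, 0.9), 60L)
  expect_equal(prof$grid[which.max(prof$intensity)], qstar, tolerance = 0.9 * 0.8 / 60)
})

test_that("degenerate chi sectors and masks raise errors", {
  geom <- desk_geometry(64L)
  fr <- detector_frame(matrix(1, 64, 64))
  expect_error(radial_integrate(fr, geom, c(0.1, 1.0), 10L,
                                chi_sector = c(45, 45)), "zero angular width")
  allmask <- detector_frame(matrix(1, 64, 64), matrix(TRUE, 64, 64))
  expect_error(radial_integrate(allmask, geom, c(0.1, 1.0), 10L), "no unmasked")
  expect_error(azimuthal_integrate(fr, geom, c(50, 60)), "coverage")
  expect_error(radial_integrate(fr, geom, c(1, 0.1), 10L), "increasing")
})

test_that("azimuthal profiles are flat for isotropic rings and rotate with the frame", {
  geom <- desk_geometry(128L)
  pq <- pixel_to_q(rep(1:128, times = 128), rep(1:128, each = 128), geom)
  qpix <- matrix(pq$q, 128, 128)
  chipix <- matrix(pq$chi, 128, 128)
  ring <- qpix > 0.40 & qpix < 0.52
  iso <- detector_frame(matrix(5, 128, 128))
  prof <- azimuthal_integrate(iso, geom, c(0.40, 0.52), 36L)
  expect_true(all(abs(prof$intensity - 5) < 1e-12))
  # two arcs at 161 and 341 degrees give paired maxima
  arc <- function(c0) exp(-((chipix - c0 + 180) %% 360 - 180)^2 / (2 * 8^2))
  fr <- detector_frame(1 + 500 * ring * (arc(161) + arc(341)))
  pr <- azimuthal_integrate(fr, geom, c(0.40, 0.52), 72L)
  top2 <- order(pr$intensity, decreasing = TRUE)[1:2]
  peaks <- sort(pr$grid[top2])
  expect_equal(peaks[1], 161, tolerance = 4)
  expect_equal(peaks[2], 341, tolerance = 4)
  # 90-degree rotation about the beam center shifts I(chi) by 90 degrees
  rot90 <- function(M) t(M)[, rev(seq_len(ncol(M)))]
  pr_rot <- azimuthal_integrate(detector_frame(rot90(fr$counts)), geom,
                                c(0.40, 0.52), 72L)
  k <- 90 / (360 / 72)
  shifted <- pr$intensity[((seq_len(72) - 1 - k) %% 72) + 1]
  expect_equal(pr_rot$intensity, shifted, tolerance = 1e-10)
})

test_that("distance refinement recovers a known sample-to-detector distance", {
  geom <- desk_geometry(512L)
  spacings <- 58.38 / 1:3   # silver-behenate-like orders
  radii <- q_to_radius_px(2 * pi / spacings, geom)
  # start from a geometry with the wrong distance
  start <- detector_geometry(4.0, geom$pixel_size_um, geom$beam_center,
                             geom$energy_kev, geom$frame_shape)
  ref <- refine_distance(radii, spacings, start)
  expect_equal(ref$distance_m, 5.5, tolerance = 1e-3 * 5.5)
  expect_null(attr(ref, "warning"))
  # single ring: closed-form distance
  one <- refine_distance(radii[1], spacings[1], start)
  expect_equal(one$distance_m, 5.5, tolerance = 1e-6 * 5.5)
  expect_error(refine_distance(numeric(0), numeric(0), start), "at least one")
  # inconsistent rings attach a warning
  bad <- refine_distance(radii * c(1, 1.2, 0.8), spacings, start)
  expect_false(is.null(attr(bad, "warning")))
})
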