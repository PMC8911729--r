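test_that("the 5th-order fit reproduces the worked D-period example", {
  # peak centered at q05 = 0.4812 nm^-1 on an exponential background
  prof <- make_radial_profile(0.4812, 100, 0.004, bg_amp = 50)
  fit <- fit_collagen(prof)
  expect_true(fit$fit$converged)
  expect_equal(fit$fit$center, 0.4812, tolerance = 1e-6)
  expect_equal(round(fit$D, 2), 65.29)
  expect_true(fit$d_plausible)
})

test_that("a noiseless background-free Gaussian is recovered exactly", {
  prof <- make_radial_profile(0.4833, 80, 0.003)
  fit <- fit_collagen(prof)
  expect_lt(abs(fit$fit$center - 0.4833), 1e-5)
  expect_equal(fit$I_c, 80 * 0.003 * sqrt(2 * pi), tolerance = 1e-6)
  expect_equal(fit$w_q, 0.003, tolerance = 1e-6)
  expect_equal(fit_fwhm(fit$fit), 2 * sqrt(2 * log(2)) * 0.003, tolerance = 1e-6)
})

test_that("Poisson-noise replicates recover D without bias", {
  errs <- vapply(1:60, function(i) {
    prof <- make_radial_profile(0.4812, 400, 0.004, bg_amp = 200,
                                noise_seed = 300 + i)
    fit_collagen(prof)$D - 10 * pi / 0.4812
  }, numeric(1))
  expect_lt(abs(mean(errs, na.rm = TRUE)), 0.02)
})

test_that("degenerate and unsupported windows are handled", {
  flat <- profile1d("radial_q", seq(0.4, 0.52, length.out = 30),
                    rep(3, 30), rep(10L, 30))
  f <- fit_collagen(flat)
  expect_false(f$fit$converged)
  expect_true(is.na(f$D))
  expect_error(fit_collagen(make_radial_profile(0.48, 10, 0.01,
                                                q = seq(0.42, 0.50, length.out = 50))),
               "window outside")
})

test_that("the IFC fit derives the interfibrillar spacing from its center", {
  prof <- make_radial_profile(0.1257, 40, 0.012, bg_amp = 100)
  f <- fit_ifc(prof)
  expect_equal(f$D_ifc, 4 * pi / 0.1257, tolerance = 1e-4)
  expect_equal(round(f$D_ifc, 1), 100.0)
  prof2 <- make_radial_profile(4 * pi / 88, 40, 0.012, bg_amp = 100,
                               q = seq(0.05, 0.60, length.out = 220))
  f2 <- fit_ifc(prof2, window = c(0.12, 0.165))
  expect_equal(f2$D_ifc, 88.0, tolerance = 0.2)
  expect_true(f2$d_plausible)
})

test_that("azimuthal fit finds paired peaks and honors the wrap replicate", {
  pr <- make_chi_profile(161, 20)
  fa <- fit_azimuthal(pr)
  expect_true(fa$converged)
  expect_false(fa$isotropic)
  expect_equal(fa$chi0, 161 %% 180, tolerance = 0.2)
  expect_equal(fa$w_chi, 20, tolerance = 0.2)
  # peak mass wrapping past 0 degrees
  pr2 <- make_chi_profile(10, 30)
  fa2 <- fit_azimuthal(pr2)
  expect_equal(fa2$chi0, 10, tolerance = 0.5)
  # uniform profile flags isotropic
  flat <- profile1d("azimuthal_chi", seq(2, 358, by = 4),
                    rep(7, 90), rep(30L, 90))
  expect_true(fit_azimuthal(flat)$isotropic)
})

test_that("azimuthal fits are invariant under circular shifts", {
  base <- make_chi_profile(161, 25, noise_seed = 21)
  f0 <- fit_azimuthal(base)
  for (s in c(30, 90, 137)) {
    # shift by whole bins (4-degree bins, 137 -> 136 degrees actual)
    actual <- round(s / 4) * 4
    fs <- fit_azimuthal(shift_chi_profile(base, actual))
    expect_equal(fs$chi0, (f0$chi0 + actual) %% 180, tolerance = 0.1)
    expect_lt(abs(fs$w_chi - f0$w_chi), 0.1)
  }
})

test_that("doubling the background amplitude barely moves the fitted D", {
  p1 <- make_radial_profile(0.4812, 100, 0.004, bg_amp = 50)
  p2 <- make_radial_profile(0.4812, 100, 0.004, bg_amp = 100)
  expect_lt(abs(fit_collagen(p1)$D - fit_collagen(p2)$D), 0.01)
})

test_that("total intensity matches analytic and fine-grid areas", {
  q <- seq(0.1, 0.6, length.out = 51)
  expect_equal(total_intensity(profile1d("radial_q", q, rep(1, 51),
                                         rep(5L, 51))), 0.5)
  # triangle of height 2 over [0.1, 0.6]
  tri <- 2 * (1 - abs(q - 0.35) / 0.25)
  expect_equal(total_intensity(profile1d("radial_q", q, tri, rep(5L, 51))),
               0.5 * 0.5 * 2, tolerance = 1e-3)
  # random profile vs a fine-grid Riemann oracle on the same interpolant
  set.seed(30)
  y <- runif(51)
  prof <- profile1d("radial_q", q, y, rep(5L, 51))
  fine <- seq(0.1, 0.6, length.out = 20001)
  riemann <- sum(approx(q, y, fine)$y) * diff(fine[1:2])
  expect_equal(total_intensity(prof), riemann, tolerance = 1e-3)
  expect_error(total_intensity(profile1d("radial_q", q, rep(NA_real_, 51),
                                         rep(0L, 51))), "populated")
})

test_that("order ratios are unity for equal-area orders and flag missing peaks", {
  D <- 65
  centers <- (3:6) * 2 * pi / D
  sig <- 0.004
  prof <- make_radial_profile(centers, rep(100, 4) * sig / sig, rep(sig, 4),
                              q = seq(0.2, 0.62, length.out = 400), bg_amp = 30)
  orr <- order_ratios(prof, orders = c(3, 4, 6), D_guess = D)
  expect_true(all(orr$converged))
  expect_equal(orr$ratio, rep(1, 4), tolerance = 0.02)
  # multi-order consistency: centers scale as n * 2pi/D
  expect_lt(max(abs(orr$center / orr$order - 2 * pi / D)), 0.42 / 400)
  # an empty window yields a flagged order
  prof2 <- make_radial_profile(centers[c(1, 3)], c(100, 100), rep(sig, 2),
                               q = seq(0.2, 0.62, length.out = 400), bg_amp = 0)
  orr2 <- order_ratios(prof2, orders = c(4), D_guess = D)
  expect_false(orr2$converged[orr2$order == 4])
  expect_true(is.na(orr2$ratio[orr2$order == 4]))
})

test_that("D recovery holds across a grid of truth parameters", {
  grid <- expand.grid(D = c(64, 65, 66), sigma = c(0.002, 0.004, 0.006),
                      snr = c(10, 30))
  errs <- unlist(lapply(seq_len(nrow(grid)), function(g) {
    D <- grid$D[g]; sig <- grid$sigma[g]; snr <- grid$snr[g]
    vapply(1:5, function(i) {
      amp <- snr^2  # Poisson: peak SNR = sqrt(amp)
      prof <- make_radial_profile(10 * pi / D, amp, sig, bg_amp = amp / 4,
                                  noise_seed = 7000 + 13 * g + i)
      fit_collagen(prof, window = c(0.44, 0.53))$D - D
    }, numeric(1))
  }))
  expect_lt(median(abs(errs), na.rm = TRUE), 0.02)
})
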