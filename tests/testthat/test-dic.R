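# DIC tests run on modest speckle images so the whole suite stays quick;
# the fields use the same subset/step defaults scaled down.

cfg_small <- dic_config(subset_size = 17L, step = 4L, search_radius = 4L,
                        strain_window = 5L)

test_that("self-correlation has no zero-displacement bias", {
  img <- speckle_pair(size = 72L, feature_scale = 6, seed = 40)$reference
  fld <- dic_correlate(img, img, cfg_small)
  expect_true(all(fld$valid))
  expect_lt(max(abs(fld$u[fld$valid])), 1e-3)
  expect_lt(max(abs(fld$v[fld$valid])), 1e-3)
  expect_true(all(fld$correlation[fld$valid] > 0.999))
})

test_that("integer shifts are recovered exactly and equivariantly", {
  for (d in list(c(3, -2), c(-1, 4))) {
    vw <- speckle_views(72L, d, feature_scale = 6, seed = 41)
    fld <- dic_correlate(vw$reference, vw$deformed, cfg_small)
    expect_gt(sum(fld$valid), 0.9 * length(fld$valid))
    # exactness holds wherever the shifted subset stays fully inside
    h <- (cfg_small$subset_size - 1) / 2
    rin <- fld$centers_row + d[1] >= h + 1 & fld$centers_row + d[1] <= 72 - h
    cin <- fld$centers_col + d[2] >= h + 1 & fld$centers_col + d[2] <= 72 - h
    interior <- outer(rin, cin, `&`) & fld$valid
    expect_gt(sum(interior), 100)
    expect_lt(max(abs(fld$v[interior] - d[1])), 1e-3)
    expect_lt(max(abs(fld$u[interior] - d[2])), 1e-3)
    # border subsets may lean on the mirror extension but stay subpixel-true
    expect_lt(max(abs(fld$v[fld$valid] - d[1])), 0.05)
    expect_lt(max(abs(fld$u[fld$valid] - d[2])), 0.05)
  }
})

test_that("subpixel shifts are recovered well below the noise floor bound", {
  sp <- speckle_pair(size = 72L, feature_scale = 6,
                     warp = warp_affine(t = c(0.5, -0.3)), seed = 42)
  fld <- dic_correlate(sp$reference, sp$deformed, cfg_small)
  ok <- fld$valid
  expect_gt(sum(ok), 50)
  expect_lt(sqrt(mean((fld$v[ok] - 0.5)^2)), 0.05)
  expect_lt(sqrt(mean((fld$u[ok] + 0.3)^2)), 0.05)
})

test_that("swapping reference and deformed negates the field", {
  sp <- speckle_pair(size = 72L, feature_scale = 6,
                     warp = warp_affine(t = c(0.4, 0.6)), seed = 43)
  f1 <- dic_correlate(sp$reference, sp$deformed, cfg_small)
  f2 <- dic_correlate(sp$deformed, sp$reference, cfg_small)
  both <- f1$valid & f2$valid
  expect_gt(sum(both), 40)
  expect_lt(max(abs(f1$u[both] + f2$u[both])), 0.02)
  expect_lt(max(abs(f1$v[both] + f2$v[both])), 0.02)
})

test_that("constant subsets are invalid, shape mismatches error", {
  img <- speckle_pair(size = 72L, feature_scale = 6, seed = 44)$reference
  flat <- img; flat[1:40, 1:40] <- 3
  fld <- dic_correlate(flat, flat, cfg_small)
  inner <- fld$centers_row < 30 & TRUE
  expect_false(any(fld$valid[fld$centers_row < 28, fld$centers_col < 28]))
  expect_error(dic_correlate(img, img[1:60, ], cfg_small), "shapes differ")
  expect_error(dic_config(subset_size = 10L), "odd")
})

test_that("strain from plane displacement fields is exact", {
  img <- speckle_pair(size = 72L, feature_scale = 6, seed = 45)$reference
  fld <- dic_correlate(img, img, cfg_small)
  # uniform displacement -> zero strain
  fld0 <- fld; fld0$u[] <- 3.3; fld0$v[] <- -1.1; fld0$valid[] <- TRUE
  st0 <- dic_strain(fld0, cfg_small)
  expect_lt(max(abs(c(st0$exx[st0$valid], st0$eyy[st0$valid],
                      st0$exy[st0$valid]))), 1e-12)
  # u = 0.02 x -> exx = 0.02 only
  fldx <- fld0
  fldx$u <- 0.02 * matrix(fldx$centers_col, length(fldx$centers_row),
                          length(fldx$centers_col), byrow = TRUE)
  fldx$v[] <- 0
  stx <- dic_strain(fldx, cfg_small)
  expect_equal(max(abs(stx$exx[stx$valid] - 0.02)), 0, tolerance = 1e-10)
  expect_lt(max(abs(stx$eyy[stx$valid])), 1e-12)
  expect_lt(max(abs(stx$exy[stx$valid])), 1e-12)
})

test_that("strain of a smooth field matches a finite-difference oracle", {
  img <- speckle_pair(size = 72L, feature_scale = 6, seed = 46)$reference
  fld <- dic_correlate(img, img, cfg_small)
  ufun <- function(x, y) 0.3 * sin(x / 40) + 0.1 * cos(y / 30)
  vfun <- function(x, y) 0.2 * cos(x / 35) - 0.2 * sin(y / 45)
  ys <- matrix(fld$centers_row, length(fld$centers_row), length(fld$centers_col))
  xs <- matrix(fld$centers_col, length(fld$centers_row), length(fld$centers_col),
               byrow = TRUE)
  fld$u <- ufun(xs, ys); fld$v <- vfun(xs, ys); fld$valid[] <- TRUE
  st <- dic_strain(fld, cfg_small)
  h <- 1e-4
  dudx <- (ufun(xs + h, ys) - ufun(xs - h, ys)) / (2 * h)
  dvdy <- (vfun(xs, ys + h) - vfun(xs, ys - h)) / (2 * h)
  # plane-fit gradients track the derivative where the window is complete
  # (truncated boundary windows on a curved field carry an O(h) bias)
  k <- (cfg_small$strain_window - 1) / 2
  nr <- length(fld$centers_row); nc <- length(fld$centers_col)
  interior <- matrix(FALSE, nr, nc)
  interior[(k + 1):(nr - k), (k + 1):(nc - k)] <- TRUE
  interior <- interior & st$valid
  expect_lt(max(abs(st$exx[interior] - dudx[interior])), 1e-4)
  expect_lt(max(abs(st$eyy[interior] - dvdy[interior])), 1e-4)
})

test_that("point displacement interpolation is exact on planes and at centers", {
  img <- speckle_pair(size = 72L, feature_scale = 6, seed = 47)$reference
  fld <- dic_correlate(img, img, cfg_small)
  fld$valid[] <- TRUE
  ys <- matrix(fld$centers_row, length(fld$centers_row), length(fld$centers_col))
  xs <- matrix(fld$centers_col, length(fld$centers_row), length(fld$centers_col),
               byrow = TRUE)
  fld$u <- 0.5 + 0.01 * xs + 0.02 * ys
  fld$v <- -0.2 + 0.03 * xs - 0.01 * ys
  # subset centers return their own displacement
  p0 <- cbind(fld$centers_row[2], fld$centers_col[3])
  d0 <- dic_displace_points(p0, fld)
  expect_equal(d0$u, fld$u[2, 3])
  expect_equal(d0$v, fld$v[2, 3])
  # bilinear interpolation reproduces planes exactly inside the hull
  set.seed(48)
  pts <- cbind(runif(50, min(fld$centers_row), max(fld$centers_row)),
               runif(50, min(fld$centers_col), max(fld$centers_col)))
  dd <- dic_displace_points(pts, fld)
  expect_lt(max(abs(dd$u - (0.5 + 0.01 * pts[, 2] + 0.02 * pts[, 1]))), 1e-10)
  expect_lt(max(abs(dd$v - (-0.2 + 0.03 * pts[, 2] - 0.01 * pts[, 1]))), 1e-10)
  expect_false(any(dd$extrapolated))
  # uniform field shifts any point by the field value, outside the hull too
  fld$u[] <- 1.5; fld$v[] <- -2.5
  far <- dic_displace_points(cbind(c(2, 70), c(2, 70)), fld)
  expect_equal(far$u, c(1.5, 1.5))
  expect_equal(far$v, c(-2.5, -2.5))
  expect_true(all(far$extrapolated))
})
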