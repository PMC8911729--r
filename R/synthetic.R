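# Forward simulation of scattering frames, scan grids and deformed scan
# pairs with known ground truth. The per-pixel intensity model is:
# an exponential diffuse background; meridional collagen orders n = 1..6
# as Gaussian rings in q at n*2*pi/D with angular Gaussian lobes at chi0
# and chi0+180, order amplitudes proportional to |c_n|^2 of a two-level
# axial step density (c_n = sin(pi*n*f)/(pi*n) for gap fraction
# f = 1 - overlap_fraction); and a broad interfibrillar ring with orders
# m = 1, 2 of the IFC spacing, lobes rotated 90 degrees from chi0.
# Counts are Poisson; a beamstop disk is masked.

#' Ground-truth fibril parameters for the frame simulator
#'
#' @param D Collagen D-period (nm).
#' @param overlap_fraction Fraction of the D-period occupied by the
#'   molecular overlap zone, in (0, 1); gap fraction is its complement
#'   and controls even/odd order intensities.
#' @param chi0 Mean fibril angle (degrees).
#' @param chi_spread Angular Gaussian spread of the orientation lobes
#'   (degrees).
#' @param collagen_weight Peak amplitude scale (expected counts) of the
#'   5th collagen order at the lobe center.
#' @param collagen_width Radial Gaussian sigma of the collagen rings
#'   (nm^-1).
#' @param ifc_spacing Interfibrillar spacing (nm).
#' @param ifc_width Radial Gaussian sigma of the IFC rings (nm^-1).
#' @param ifc_weight Peak amplitude (expected counts) of the 1st IFC
#'   order.
#' @param bg_amplitude,bg_decay Exponential diffuse background
#'   `bg_amplitude * exp(-q * bg_decay)` (counts; nm).
#' @param flux Overall multiplier on the expected counts.
#' @return Object of class `fibril_truth`.
#' @export
fibril_truth <- function(D = 65, overlap_fraction = 0.55, chi0 = 161,
                         chi_spread = 20, collagen_weight = 1200,
                         collagen_width = 0.004, ifc_spacing = 94,
                         ifc_width = 0.016, ifc_weight = 400,
                         bg_amplitude = 200, bg_decay = 6, flux = 1) {
  stopifnot(D > 0, ifc_spacing > 0, overlap_fraction > 0,
            overlap_fraction < 1, collagen_weight >= 0, ifc_weight >= 0,
            bg_amplitude >= 0, flux >= 0)
  structure(list(D = D, overlap_fraction = overlap_fraction, chi0 = chi0,
                 chi_spread = chi_spread, collagen_weight = collagen_weight,
                 collagen_width = collagen_width, ifc_spacing = ifc_spacing,
                 ifc_width = ifc_width, ifc_weight = ifc_weight,
                 bg_amplitude = bg_amplitude, bg_decay = bg_decay,
                 flux = flux),
            class = "fibril_truth")
}

#' Fourier coefficient of the two-level axial step density
#'
#' `c_n = sin(pi * n * f) / (pi * n)` for gap fraction `f`; squared
#' magnitudes set the relative intensities of the meridional orders.
#'
#' @param n Diffraction order(s).
#' @param gap_fraction Gap fraction of the D-period in (0, 1).
#' @return Numeric vector of coefficients.
#' @export
step_density_coeff <- function(n, gap_fraction) {
  sin(pi * n * gap_fraction) / (pi * n)
}

#' Desk-scale detector geometry
#'
#' A square frame with the pixel size rescaled from the full
#' 1475 x 1679 px / 172 um detector so the covered q range is preserved
#' at reduced resolution; beam center at the frame center.
#'
#' @param size Frame edge in pixels (default 512).
#' @param distance_m,energy_kev Geometry constants (defaults 5.5 m,
#'   14 keV).
#' @return A [detector_geometry()].
#' @export
desk_geometry <- function(size = 512L, distance_m = 5.5, energy_kev = 14) {
  size <- as.integer(size)
  detector_geometry(distance_m, 172 * 1679 / size,
                    c(size / 2 + 0.5, size / 2 + 0.5), energy_kev,
                    c(size, size))
}

# circular angular lobe pair: Gaussian in the 360-degree arc distance
# from c0 and from c0 + 180
lobe_pair <- function(chi, c0, spread) {
  d1 <- abs((chi - c0 + 180) %% 360 - 180)
  d2 <- abs((chi - c0) %% 360 - 180)
  exp(-d1^2 / (2 * spread^2)) + exp(-d2^2 / (2 * spread^2))
}

# Expected (noise-free) intensity of the frame model at given q, chi.
expected_intensity <- function(truth, q, chi) {
  ii <- truth$flux * truth$bg_amplitude * exp(-q * truth$bg_decay)
  if (truth$collagen_weight > 0) {
    f_gap <- 1 - truth$overlap_fraction
    c5 <- step_density_coeff(5, f_gap)
    amp_scale <- truth$flux * truth$collagen_weight /
      max(c5^2, .Machine$double.eps)
    lob <- lobe_pair(chi, truth$chi0, truth$chi_spread)
    for (n in 1:6) {
      qn <- n * 2 * pi / truth$D
      cn <- step_density_coeff(n, f_gap)
      if (cn^2 * amp_scale < 1e-12) next
      ii <- ii + amp_scale * cn^2 *
        exp(-(q - qn)^2 / (2 * truth$collagen_width^2)) * lob
    }
  }
  if (truth$ifc_weight > 0) {
    lob_ifc <- lobe_pair(chi, truth$chi0 + 90, truth$chi_spread)
    for (m in 1:2) {
      qm <- m * 2 * pi / truth$ifc_spacing
      am <- truth$flux * truth$ifc_weight * c(1, 0.5)[m]
      ii <- ii + am * exp(-(q - qm)^2 / (2 * truth$ifc_width^2)) * lob_ifc
    }
  }
  ii
}

#' Simulate a detector frame
#'
#' Poisson-samples the frame intensity model (see the file header) and
#' masks a central beamstop disk. Identical seeds give bit-identical
#' frames.
#'
#' @param truth A [fibril_truth()].
#' @param geometry A [detector_geometry()].
#' @param seed Integer RNG seed.
#' @param beamstop_px Beamstop disk radius in pixels (default scaled so
#'   the 1st IFC order is partly shadowed, as on the real instrument).
#' @param qc Optional precomputed `geometry_qchi(geometry)` (shared
#'   across frames of a scan).
#' @return A [detector_frame()] with attribute `expected_total` (the
#'   noise-free unmasked photon total).
#' @export
simulate_frame <- function(truth, geometry, seed = 1L,
                           beamstop_px = NULL, qc = NULL) {
  stopifnot(inherits(truth, "fibril_truth"),
            inherits(geometry, "detector_geometry"))
  if (is.null(qc)) qc <- geometry_qchi(geometry)
  if (is.null(beamstop_px))
    beamstop_px <- max(4, round(0.0145 * max(geometry$frame_shape)))
  ii <- expected_intensity(truth, qc$q, qc$chi)
  sh <- geometry$frame_shape
  rows <- matrix(seq_len(sh[1]), sh[1], sh[2])
  cols <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
  mask <- (rows - geometry$beam_center[1])^2 +
    (cols - geometry$beam_center[2])^2 <= beamstop_px^2
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(length(ii), as.vector(ii)), sh[1], sh[2])
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  fr <- detector_frame(counts, mask)
  attr(fr, "expected_total") <- sum(ii[!mask])
  fr
}

# --- continuous tissue model over the reference scan plane ------------

# smooth band-limited scalar field: bilinear interpolation of a coarse
# iid normal grid, unit variance
smooth_field <- function(n_rows, n_cols, feature_scale, seed) {
  ncr <- max(2L, ceiling(n_rows / feature_scale)) + 3L
  ncc <- max(2L, ceiling(n_cols / feature_scale)) + 3L
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(ncr * ncc), ncr, ncc)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  function(row, col) {
    # map scan coords to coarse-grid coords (offset so the border cells pad)
    gr <- pmin(pmax((row - 1) / feature_scale + 2, 1), ncr - 1e-9)
    gc <- pmin(pmax((col - 1) / feature_scale + 2, 1), ncc - 1e-9)
    r0 <- pmin(floor(gr), ncr - 1L); c0 <- pmin(floor(gc), ncc - 1L)
    tr <- gr - r0; tc <- gc - c0
    Z[cbind(r0, c0)] * (1 - tr) * (1 - tc) +
      Z[cbind(r0 + 1, c0)] * tr * (1 - tc) +
      Z[cbind(r0, c0 + 1)] * (1 - tr) * tc +
      Z[cbind(r0 + 1, c0 + 1)] * tr * tc
  }
}

#' Continuous heterogeneous tissue model over a scan plane
#'
#' Defines spatially varying ground-truth fields (collagen intensity,
#' D-period, orientation, IFC intensity) as smooth band-limited textures
#' over continuous reference scan coordinates, so a warped scan can
#' sample the same tissue at displaced positions. The collagen and IFC
#' weights vary log-normally (microspatial heterogeneity providing the
#' diffraction contrast that DIC tracks); D and chi0 vary additively.
#'
#' @param n_rows,n_cols Reference scan extent (scan points).
#' @param base A [fibril_truth()] giving the mean parameters.
#' @param feature_scale Correlation length of the textures in scan steps
#'   (default 4).
#' @param Ic_logsd Log-sd of the collagen weight texture (default 0.8).
#' @param D_sd Sd of the D-period texture in nm (default 0.05).
#' @param chi0_sd Sd of the orientation texture in degrees (default 25).
#' @param ifc_logsd Log-sd of the IFC weight texture (default 0.8).
#' @param seed Integer seed for the textures.
#' @return Object of class `tissue_model`: a list of vectorised field
#'   functions `(row, col) -> value` plus the base truth.
#' @export
tissue_model <- function(n_rows, n_cols, base = fibril_truth(),
                         feature_scale = 4, Ic_logsd = 0.8, D_sd = 0.05,
                         chi0_sd = 25, ifc_logsd = 0.8, seed = 1L) {
  seed <- as.integer(seed)
  zw <- smooth_field(n_rows, n_cols, feature_scale, seed)
  zd <- smooth_field(n_rows, n_cols, feature_scale, seed + 104729L)
  zc <- smooth_field(n_rows, n_cols, feature_scale, seed + 224737L)
  zi <- smooth_field(n_rows, n_cols, feature_scale, seed + 350377L)
  structure(list(
    n_rows = n_rows, n_cols = n_cols, base = base,
    collagen_weight = function(row, col)
      base$collagen_weight * exp(Ic_logsd * zw(row, col) - Ic_logsd^2 / 2),
    D = function(row, col) base$D + D_sd * zd(row, col),
    chi0 = function(row, col) (base$chi0 + chi0_sd * zc(row, col)) %% 180,
    ifc_weight = function(row, col)
      base$ifc_weight * exp(ifc_logsd * zi(row, col) - ifc_logsd^2 / 2)
  ), class = "tissue_model")
}

# truth for one scan point of a tissue model, with optional imposed
# fibril strain and reorientation toward the loading axis
point_truth <- function(model, row, col, d_factor = 1,
                        reorient_factor = 0, loading_axis = 90) {
  b <- model$base
  chi <- model$chi0(row, col)
  if (reorient_factor != 0)
    chi <- (loading_axis + (1 - reorient_factor) * arc180(loading_axis, chi)) %% 180
  fibril_truth(D = model$D(row, col) * d_factor,
               overlap_fraction = b$overlap_fraction, chi0 = chi,
               chi_spread = b$chi_spread,
               collagen_weight = model$collagen_weight(row, col),
               collagen_width = b$collagen_width,
               ifc_spacing = b$ifc_spacing, ifc_width = b$ifc_width,
               ifc_weight = model$ifc_weight(row, col),
               bg_amplitude = b$bg_amplitude, bg_decay = b$bg_decay,
               flux = b$flux)
}

#' Simulate a scan of frames over a grid
#'
#' One frame per grid point, sampled from the tissue model at the point
#' position. Frames are generated lazily through `frame_fn` so large
#' grids never hold all frames in memory; per-point seeds derive
#' deterministically from `seed`.
#'
#' @param model A [tissue_model()].
#' @param grid A [scan_grid()]; defaults to the model extent.
#' @param geometry A [detector_geometry()].
#' @param seed Integer base seed.
#' @param warp Optional `scan_warp`: the scan samples the tissue at the
#'   warp-inverse of each grid position (a deformed acquisition).
#'   Positions mapping outside the reference tissue give background-only
#'   frames (`tissue = FALSE` in the truth table).
#' @param d_factor,reorient_factor,loading_axis Imposed deformation of
#'   the sampled tissue: multiplier on the local D-period and fractional
#'   reorientation of chi0 toward the loading axis.
#' @return Object of class `sim_scan`: `truth` (per-point table),
#'   `frame_fn(i)` returning the [detector_frame()] of truth-table row
#'   i, plus grid/geometry metadata.
#' @export
simulate_scan <- function(model, grid = NULL, geometry = desk_geometry(256L),
                          seed = 1L, warp = NULL, d_factor = 1,
                          reorient_factor = 0, loading_axis = 90) {
  stopifnot(inherits(model, "tissue_model"))
  if (is.null(grid)) grid <- scan_grid(model$n_rows, model$n_cols)
  pts <- expand.grid(y_index = seq_len(grid$n_rows),
                     x_index = seq_len(grid$n_cols))
  pts <- pts[order(pts$y_index, pts$x_index), ]
  src_r <- pts$y_index; src_c <- pts$x_index
  if (!is.null(warp)) {
    src <- warp$inv(pts$y_index, pts$x_index)
    src_r <- src$row; src_c <- src$col
  }
  tissue <- src_r >= 0.5 & src_r <= model$n_rows + 0.5 &
    src_c >= 0.5 & src_c <= model$n_cols + 0.5
  truth <- data.frame(
    y_index = pts$y_index, x_index = pts$x_index,
    src_row = src_r, src_col = src_c, tissue = tissue,
    D = ifelse(tissue, model$D(src_r, src_c) * d_factor, NA_real_),
    chi0 = NA_real_, collagen_weight = NA_real_, ifc_weight = NA_real_)
  chi <- model$chi0(src_r, src_c)
  if (reorient_factor != 0)
    chi <- (loading_axis + (1 - reorient_factor) * arc180(loading_axis, chi)) %% 180
  truth$chi0[tissue] <- chi[tissue]
  truth$collagen_weight[tissue] <- model$collagen_weight(src_r, src_c)[tissue]
  truth$ifc_weight[tissue] <- model$ifc_weight(src_r, src_c)[tissue]
  qc <- geometry_qchi(geometry)
  base <- model$base
  frame_fn <- function(i) {
    tr <- truth[i, ]
    ft <- if (tr$tissue)
      point_truth(model, tr$src_row, tr$src_col, d_factor,
                  reorient_factor, loading_axis)
    else fibril_truth(D = base$D, overlap_fraction = base$overlap_fraction,
                      chi0 = base$chi0, chi_spread = base$chi_spread,
                      collagen_weight = 0, collagen_width = base$collagen_width,
                      ifc_spacing = base$ifc_spacing, ifc_width = base$ifc_width,
                      ifc_weight = 0, bg_amplitude = base$bg_amplitude,
                      bg_decay = base$bg_decay, flux = base$flux)
    simulate_frame(ft, geometry, seed = as.integer(seed) + 977L * i, qc = qc)
  }
  structure(list(truth = truth, frame_fn = frame_fn, grid = grid,
                 geometry = geometry, seed = as.integer(seed)),
            class = "sim_scan")
}

# --- warps over the scan plane ---------------------------------------

#' Affine warp of the scan plane
#'
#' `(row', col') = A (row - origin) + origin + t`; bijective for
#' invertible `A`, with an exact inverse.
#'
#' @param A 2x2 matrix acting on `(row, col)` offsets.
#' @param t Length-2 translation `(row, col)`.
#' @param origin Length-2 fixed point of `A` (default `c(1, 1)`).
#' @return Object of class `scan_warp` with functions `fwd(row, col)`
#'   and `inv(row, col)`, both returning `list(row, col)`.
#' @export
warp_affine <- function(A = diag(2), t = c(0, 0), origin = c(1, 1)) {
  Ai <- solve(A)
  mk <- function(M, tt) function(row, col) {
    dr <- row - origin[1]; dc <- col - origin[2]
    list(row = M[1, 1] * dr + M[1, 2] * dc + origin[1] + tt[1],
         col = M[2, 1] * dr + M[2, 2] * dc + origin[2] + tt[2])
  }
  structure(list(fwd = mk(A, t),
                 inv = function(row, col) {
                   dr <- row - origin[1] - t[1]; dc <- col - origin[2] - t[2]
                   list(row = Ai[1, 1] * dr + Ai[1, 2] * dc + origin[1],
                        col = Ai[2, 1] * dr + Ai[2, 2] * dc + origin[2])
                 },
                 A = A, t = t, origin = origin),
            class = "scan_warp")
}

#' Uniaxial stretch warp
#'
#' Vertical (row-direction) stretch by `stretch` about a fixed reference
#' row, mimicking tension applied from one grip with the opposite edge
#' held.
#'
#' @param stretch Engineering strain (e.g. 0.20).
#' @param origin_row Fixed row (default 1, the reference edge).
#' @return A [warp_affine()] `scan_warp`.
#' @export
warp_stretch <- function(stretch = 0.20, origin_row = 1) {
  warp_affine(diag(c(1 + stretch, 1)), origin = c(origin_row, 1))
}

#' Simulate an undeformed/deformed scan pair with ground truth
#'
#' The reference scan samples the tissue model on its grid; the deformed
#' scan samples the same (warped) tissue on a regular grid covering the
#' warped extent, with an imposed uniform fibril strain and a fractional
#' reorientation of chi0 toward the loading axis. The returned
#' correspondence table (reference point -> nearest deformed grid point
#' under the true warp) is the matching oracle.
#'
#' @param model A [tissue_model()].
#' @param warp A `scan_warp` (bijective on the scan domain).
#' @param geometry A [detector_geometry()].
#' @param seed Integer base seed.
#' @param fibril_strain Imposed relative D-period change (default
#'   0.0015).
#' @param reorient_factor Fraction by which the deviation of chi0 from
#'   the loading axis shrinks (default 0.5).
#' @param loading_axis Degrees (default 90, vertical).
#' @return List with `ref` and `def` [simulate_scan()] objects,
#'   `correspondence` (data.frame: ref indices, true deformed position,
#'   nearest deformed grid point, `inside` flag) and the imposed
#'   parameters.
#' @export
simulate_deformed_scan <- function(model, warp = warp_stretch(0.20),
                                   geometry = desk_geometry(256L),
                                   seed = 1L, fibril_strain = 0.0015,
                                   reorient_factor = 0.5,
                                   loading_axis = 90) {
  stopifnot(inherits(model, "tissue_model"), inherits(warp, "scan_warp"))
  ref_grid <- scan_grid(model$n_rows, model$n_cols)
  corners <- warp$fwd(c(1, 1, model$n_rows, model$n_rows),
                      c(1, model$n_cols, 1, model$n_cols))
  def_grid <- scan_grid(max(2L, ceiling(max(corners$row))),
                        max(2L, ceiling(max(corners$col))))
  ref <- simulate_scan(model, ref_grid, geometry, seed = seed)
  def <- simulate_scan(model, def_grid, geometry, seed = seed + 500009L,
                       warp = warp, d_factor = 1 + fibril_strain,
                       reorient_factor = reorient_factor,
                       loading_axis = loading_axis)
  pts <- expand.grid(ref_row = seq_len(ref_grid$n_rows),
                     ref_col = seq_len(ref_grid$n_cols))
  tru <- warp$fwd(pts$ref_row, pts$ref_col)
  corr <- data.frame(ref_row = pts$ref_row, ref_col = pts$ref_col,
                     true_row = tru$row, true_col = tru$col,
                     def_row = round(tru$row), def_col = round(tru$col))
  corr$inside <- corr$def_row >= 1 & corr$def_row <= def_grid$n_rows &
    corr$def_col >= 1 & corr$def_col <= def_grid$n_cols
  list(ref = ref, def = def, correspondence = corr, warp = warp,
       imposed = list(fibril_strain = fibril_strain,
                      reorient_factor = reorient_factor,
                      loading_axis = loading_axis))
}

#' Synthetic speckle image pair under a known warp
#'
#' Band-limited random texture (Gaussian-filtered white noise); the
#' second image is the first resampled through the warp inverse with the
#' same degree-6 spline the DIC engine uses, so the imposed displacement
#' field `fwd(x) - x` is the exact recovery target.
#'
#' @param size Image edge (px).
#' @param feature_scale Mean speckle feature size in px (>= 3).
#' @param warp A `scan_warp` acting on pixel coordinates.
#' @param seed Integer seed.
#' @param degree Interpolation degree for the resampling (default 6).
#' @return List `reference`, `deformed` (matrices), `truth_u(row, col)`
#'   returning the imposed `list(u, v)` displacements, and `warp`.
#' @export
speckle_pair <- function(size = 128L, feature_scale = 8, warp = NULL,
                         seed = 1L, degree = 6L) {
  if (feature_scale < 3) stop("feature_scale must be >= 3 px")
  size <- as.integer(size)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(size^2), size, size)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  fr <- c(0:(size %/% 2), -rev(seq_len(size - size %/% 2 - 1))) / size
  s <- feature_scale / (2 * sqrt(2 * log(2)))
  H <- exp(-2 * pi^2 * s^2 * outer(fr^2, fr^2, `+`))
  sp <- Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / size^2
  ref <- (sp - min(sp)) / diff(range(sp)) * 1000
  if (is.null(warp)) warp <- warp_affine()
  def <- resample_image(ref, function(row, col) warp$inv(row, col), degree)
  list(reference = ref, deformed = def,
       truth_u = function(row, col) {
         w <- warp$fwd(row, col)
         list(u = w$col - col, v = w$row - row)
       },
       warp = warp)
}
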