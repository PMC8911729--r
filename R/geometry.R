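#' Detector geometry for small-angle scattering
#'
#' Bundles the experiment geometry needed to convert detector pixel
#' positions into scattering wavevector \eqn{q} and azimuth \eqn{\chi}:
#' sample-to-detector distance, pixel size, beam-center position, X-ray
#' energy and the frame shape. The wavelength is derived from the energy
#' via \eqn{\lambda = 1.23984 / E} (nm, keV).
#'
#' @param distance_m Sample-to-detector distance in metres (> 0).
#' @param pixel_size_um Detector pixel size in micrometres (> 0).
#' @param beam_center Numeric length-2 vector `c(row, col)` giving the
#'   direct-beam position in (possibly fractional) pixel coordinates,
#'   1-based as usual in R.
#' @param energy_kev X-ray energy in keV (> 0).
#' @param frame_shape Integer length-2 vector `c(rows, cols)`.
#' @return An object of class `detector_geometry`.
#' @examples
#' geom <- detector_geometry(5.5, 172, c(840, 737), 14, c(1679, 1475))
#' geom$wavelength_nm
#' @export
detector_geometry <- function(distance_m, pixel_size_um, beam_center,
                              energy_kev, frame_shape) {
  stopifnot(is.numeric(distance_m), length(distance_m) == 1L,
            is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            length(beam_center) == 2L, length(frame_shape) == 2L)
  if (distance_m <= 0) stop("distance_m must be positive")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  frame_shape <- as.integer(frame_shape)
  if (any(frame_shape < 1L)) stop("frame_shape must be positive")
  # beam center may sit just off the active area, but not absurdly far
  margin <- 0.5 * max(frame_shape)
  if (beam_center[1] < 1 - margin || beam_center[1] > frame_shape[1] + margin ||
      beam_center[2] < 1 - margin || beam_center[2] > frame_shape[2] + margin)
    stop("beam_center far outside frame bounds")
  structure(list(
    distance_m    = as.numeric(distance_m),
    pixel_size_um = as.numeric(pixel_size_um),
    beam_center   = as.numeric(beam_center),
    energy_kev    = as.numeric(energy_kev),
    wavelength_nm = energy_to_wavelength(energy_kev),
    frame_shape   = frame_shape
  ), class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("<detector_geometry>\n",
      sprintf("  distance: %.4g m, pixel: %.4g um, energy: %.4g keV (lambda %.5f nm)\n",
              x$distance_m, x$pixel_size_um, x$energy_kev, x$wavelength_nm),
      sprintf("  frame: %d x %d px, beam center: (%.2f, %.2f)\n",
              x$frame_shape[1], x$frame_shape[2],
              x$beam_center[1], x$beam_center[2]))
  invisible(x)
}

#' Convert photon energy to wavelength
#'
#' Standard X-ray conversion \eqn{\lambda[nm] = 1.23984 / E[keV]}.
#'
#' @param energy_kev Photon energy in keV (> 0).
#' @return Wavelength in nm.
#' @examples
#' energy_to_wavelength(14)   # 0.08856 nm
#' @export
energy_to_wavelength <- function(energy_kev) {
  if (!is.numeric(energy_kev) || any(!is.finite(energy_kev)) ||
      any(energy_kev <= 0))
    stop("energy must be a positive finite number (keV)")
  1.23984 / energy_kev
}

#' Detector frame: counts plus exclusion mask
#'
#' @param counts Non-negative numeric matrix of photon counts.
#' @param mask Logical matrix, `TRUE` = excluded pixel (beamstop, dead
#'   pixel, module gap). Defaults to all-`FALSE`.
#' @return An object of class `detector_frame`.
#' @export
detector_frame <- function(counts, mask = NULL) {
  stopifnot(is.matrix(counts))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(counts), ncol(counts))
  stopifnot(is.matrix(mask), identical(dim(mask), dim(counts)))
  mask <- mask | !is.finite(counts)
  if (any(counts[!mask] < 0)) stop("negative counts in unmasked pixels")
  structure(list(counts = counts, mask = mask), class = "detector_frame")
}

#' Map pixel positions to scattering coordinates
#'
#' For pixel offsets from the beam center, the scattering angle is
#' \eqn{2\theta = \arctan(r / L)} with \eqn{r} the in-plane radius and
#' \eqn{L} the sample-to-detector distance (no small-angle approximation),
#' and \eqn{q = (4\pi/\lambda)\sin\theta}. The azimuth \eqn{\chi} is
#' measured counterclockwise from the detector +x (column) axis, in
#' degrees in [0, 360), with +y along increasing row index.
#'
#' @param row,col Numeric vectors of pixel coordinates (1-based,
#'   fractional allowed); recycled to a common length.
#' @param geometry A [detector_geometry()].
#' @return A list with numeric vectors `q` (nm^-1) and `chi` (degrees).
#'   The beam-center pixel maps to `q = 0`, `chi = 0` by convention.
#' @export
pixel_to_q <- function(row, col, geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  n <- max(length(row), length(col))
  row <- rep_len(as.numeric(row), n); col <- rep_len(as.numeric(col), n)
  dr <- row - geometry$beam_center[1]
  dc <- col - geometry$beam_center[2]
  r_m <- geometry$pixel_size_um * 1e-6 * sqrt(dr^2 + dc^2)
  theta <- atan(r_m / geometry$distance_m) / 2
  q <- (4 * pi / geometry$wavelength_nm) * sin(theta)
  chi <- (atan2(dr, dc) * 180 / pi) %% 360
  chi[dr == 0 & dc == 0] <- 0
  list(q = q, chi = chi)
}

#' Invert q to a radial pixel distance
#'
#' @param q Wavevector (nm^-1).
#' @param geometry A [detector_geometry()].
#' @return Radius from the beam center in pixels.
#' @export
q_to_radius_px <- function(q, geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  theta <- asin(q * geometry$wavelength_nm / (4 * pi))
  geometry$distance_m * tan(2 * theta) / (geometry$pixel_size_um * 1e-6)
}

# q and chi evaluated at every pixel center of the frame (matrices)
geometry_qchi <- function(geometry) {
  sh <- geometry$frame_shape
  rows <- matrix(seq_len(sh[1]), sh[1], sh[2])
  cols <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
  pq <- pixel_to_q(as.vector(rows), as.vector(cols), geometry)
  list(q = matrix(pq$q, sh[1], sh[2]), chi = matrix(pq$chi, sh[1], sh[2]))
}

#' 1D scattering profile
#'
#' Container for a reduced 1D profile: intensity versus radial wavevector
#' `q` (nm^-1) or azimuth `chi` (degrees). Bins with no contributing
#' pixels carry `NA` intensity and `counts_per_bin = 0`.
#'
#' @param axis_kind `"radial_q"` or `"azimuthal_chi"`.
#' @param grid Strictly increasing numeric vector of bin centers.
#' @param intensity Numeric vector of per-bin mean intensities (`NA` where
#'   empty).
#' @param counts_per_bin Integer vector of contributing pixel counts.
#' @return An object of class `profile1d`.
#' @export
profile1d <- function(axis_kind = c("radial_q", "azimuthal_chi"),
                      grid, intensity, counts_per_bin = NULL) {
  axis_kind <- match.arg(axis_kind)
  stopifnot(length(grid) == length(intensity))
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (is.null(counts_per_bin))
    counts_per_bin <- ifelse(is.na(intensity), 0L, 1L)
  stopifnot(length(counts_per_bin) == length(grid))
  structure(list(axis_kind = axis_kind, grid = as.numeric(grid),
                 intensity = as.numeric(intensity),
                 counts_per_bin = as.integer(counts_per_bin)),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d: %s, %d bins [%.4g, %.4g], %d populated>\n",
              x$axis_kind, length(x$grid), min(x$grid), max(x$grid),
              sum(x$counts_per_bin > 0)))
  invisible(x)
}

bin_index <- function(x, lo, hi, n_bins) {
  idx <- floor((x - lo) / (hi - lo) * n_bins) + 1L
  idx[x == hi] <- n_bins
  idx[idx < 1L | idx > n_bins] <- NA_integer_
  idx
}

bin_centers <- function(lo, hi, n_bins) lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins

# Shared binner: mean of values (and of the abscissa) per bin over a
# precomputed index vector. Labelling bins by the mean abscissa of their
# contributing pixels, rather than the geometric bin center, removes the
# sub-bin discretization bias of the sampled pixel radii.
bin_mean <- function(idx, values, n_bins, absc = NULL) {
  keep <- !is.na(idx)
  idx <- idx[keep]; values <- values[keep]
  cnt <- tabulate(idx, nbins = n_bins)
  tot <- rep(0, n_bins)
  if (length(idx)) {
    s <- rowsum(values, idx)
    tot[as.integer(rownames(s))] <- s[, 1]
  }
  intensity <- ifelse(cnt > 0, tot / pmax(cnt, 1L), NA_real_)
  out <- list(intensity = intensity, counts = cnt)
  if (!is.null(absc)) {
    ax <- rep(NA_real_, n_bins)
    if (length(idx)) {
      sa <- rowsum(absc[keep], idx)
      ax[as.integer(rownames(sa))] <- sa[, 1]
    }
    out$absc_mean <- ax / pmax(cnt, 1L)
  }
  out
}

#' Radial (azimuthally averaged) integration of a frame
#'
#' Each unmasked pixel is assigned to a q bin by its center position; the
#' per-bin intensity is the mean of contributing pixel counts, so bins
#' with different pixel populations are directly comparable. Empty bins
#' are flagged (`NA`), never interpolated.
#'
#' @param frame A [detector_frame()].
#' @param geometry A [detector_geometry()].
#' @param q_range Length-2 increasing numeric, q limits in nm^-1.
#' @param n_bins Number of q bins (>= 2).
#' @param chi_sector Optional length-2 numeric `(from, to)` in degrees;
#'   restricts integration to the azimuthal sector swept counterclockwise
#'   from `from` to `to` (may cross 0/360).
#' @return A `radial_q` [profile1d()].
#' @export
radial_integrate <- function(frame, geometry, q_range, n_bins,
                             chi_sector = NULL) {
  stopifnot(inherits(frame, "detector_frame"),
            inherits(geometry, "detector_geometry"))
  if (!identical(dim(frame$counts), geometry$frame_shape))
    stop("frame shape does not match geometry$frame_shape")
  if (length(q_range) != 2L || q_range[2] <= q_range[1])
    stop("q_range must be increasing")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  qc <- geometry_qchi(geometry)
  use <- !frame$mask
  if (!is.null(chi_sector)) {
    if (length(chi_sector) != 2L) stop("chi_sector must have length 2")
    width <- (chi_sector[2] - chi_sector[1]) %% 360
    if (width == 0) stop("chi_sector has zero angular width")
    rel <- (qc$chi - chi_sector[1]) %% 360
    use <- use & (rel <= width)
  }
  if (!any(use)) stop("no unmasked pixels in the requested sector")
  qv <- qc$q[use]
  idx <- bin_index(qv, q_range[1], q_range[2], n_bins)
  bm <- bin_mean(idx, frame$counts[use], n_bins, absc = qv)
  grid <- bin_centers(q_range[1], q_range[2], n_bins)
  grid[bm$counts > 0] <- bm$absc_mean[bm$counts > 0]
  profile1d("radial_q", grid, bm$intensity, bm$counts)
}

#' Azimuthal integration of a frame over a q band
#'
#' Pixels with q inside `[inner, outer]` are averaged per chi bin over the
#' full 0-360 degree range.
#'
#' @param frame A [detector_frame()].
#' @param geometry A [detector_geometry()].
#' @param q_band Length-2 numeric `(inner, outer)` in nm^-1, 0 < inner < outer.
#' @param n_bins Number of chi bins (>= 8).
#' @return An `azimuthal_chi` [profile1d()].
#' @export
azimuthal_integrate <- function(frame, geometry, q_band, n_bins = 72L) {
  stopifnot(inherits(frame, "detector_frame"),
            inherits(geometry, "detector_geometry"))
  if (length(q_band) != 2L || q_band[1] <= 0 || q_band[2] <= q_band[1])
    stop("q_band must satisfy 0 < inner < outer")
  if (n_bins < 8L) stop("n_bins must be >= 8")
  qc <- geometry_qchi(geometry)
  sel <- !frame$mask & qc$q >= q_band[1] & qc$q <= q_band[2]
  if (!any(sel)) stop("q_band outside detector coverage (no unmasked pixels)")
  cv <- qc$chi[sel]
  idx <- bin_index(cv, 0, 360, n_bins)
  bm <- bin_mean(idx, frame$counts[sel], n_bins, absc = cv)
  grid <- bin_centers(0, 360, n_bins)
  grid[bm$counts > 0] <- bm$absc_mean[bm$counts > 0]
  profile1d("azimuthal_chi", grid, bm$intensity, bm$counts)
}

#' Refine the sample-to-detector distance from calibrant rings
#'
#' Given observed ring radii (pixels) of a calibrant with known lattice
#' spacings (e.g. silver behenate, d = 58.38 nm), chooses the distance
#' minimising the squared mismatch between observed and predicted radii,
#' where a spacing d diffracts at \eqn{q = 2\pi/d}.
#'
#' @param ring_radii_px Numeric vector of observed ring radii in pixels.
#' @param known_spacings_nm Numeric vector of the corresponding real-space
#'   spacings in nm (same length).
#' @param geometry A [detector_geometry()] supplying pixel size, energy
#'   and an initial distance.
#' @param tol_rel Relative residual above which an inconsistency warning
#'   is attached (default 1e-3).
#' @return A `detector_geometry` with refined `distance_m`; attribute
#'   `"residual_rel"` carries the rms relative radius residual, and
#'   attribute `"warning"` a message when rings are inconsistent.
#' @export
refine_distance <- function(ring_radii_px, known_spacings_nm, geometry,
                            tol_rel = 1e-3) {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (length(ring_radii_px) < 1L) stop("at least one ring is required")
  if (length(ring_radii_px) != length(known_spacings_nm))
    stop("ring_radii_px and known_spacings_nm lengths differ")
  if (any(known_spacings_nm <= 0) || any(ring_radii_px <= 0))
    stop("radii and spacings must be positive")
  q <- 2 * pi / known_spacings_nm
  theta <- asin(q * geometry$wavelength_nm / (4 * pi))
  tan2t <- tan(2 * theta)
  p_m <- geometry$pixel_size_um * 1e-6
  r_m <- ring_radii_px * p_m
  # one unknown; least squares on radii has the closed form of a ratio
  # when linearised, refined by 1-D optimisation around it
  L0 <- sum(r_m * tan2t) / sum(tan2t^2)
  obj <- function(L) sum((L * tan2t - r_m)^2)
  L <- stats::optimize(obj, interval = c(0.2 * L0, 5 * L0))$minimum
  resid <- sqrt(mean((L * tan2t / p_m - ring_radii_px)^2)) /
    mean(ring_radii_px)
  out <- detector_geometry(L, geometry$pixel_size_um, geometry$beam_center,
                           geometry$energy_kev, geometry$frame_shape)
  attr(out, "residual_rel") <- resid
  if (resid > tol_rel)
    attr(out, "warning") <- sprintf(
      "calibrant rings inconsistent: rms relative residual %.3g", resid)
  out
}
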