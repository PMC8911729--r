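# Fibril-level nanomechanics: matching scan points across load steps via
# the DIC displacement field, and turning matched per-point fit records
# into fibril strain, reorientation and distribution statistics.

#' Match scan points between an undeformed and a deformed scan
#'
#' Each reference scan point is displaced through the DIC field computed
#' on the rendered maps, converted to deformed-grid indices and snapped
#' to the nearest deformed scan point. The snap distance (in scan steps)
#' is recorded; pairs snapping farther than one step are flagged, and
#' displaced points landing outside the deformed scan are dropped.
#' Snapping (rather than interpolating fitted parameters between scan
#' points) keeps every compared value tied to a single measured tissue
#' volume.
#'
#' @param ref_grid,def_grid [scan_grid()]s of the two scans.
#' @param field `displacement_field` from [dic_correlate()] run on the
#'   rendered maps of the same two scans.
#' @param map_scale Map pixels per scan step (default 1: one rendered
#'   pixel per scan point).
#' @return data.frame with one row per retained reference point:
#'   `ref_row`, `ref_col`, `def_row`, `def_col` (grid indices, 1-based),
#'   `snap_dist` (scan steps), `flagged` (snap > 1 step or displacement
#'   extrapolated), `dropped_n` attribute counting out-of-scan points.
#' @export
match_points <- function(ref_grid, def_grid, field, map_scale = 1) {
  stopifnot(inherits(ref_grid, "scan_grid"), inherits(def_grid, "scan_grid"),
            inherits(field, "displacement_field"))
  pts <- expand.grid(ref_row = seq_len(ref_grid$n_rows),
                     ref_col = seq_len(ref_grid$n_cols))
  px <- cbind((pts$ref_row - 1) * map_scale + 1,
              (pts$ref_col - 1) * map_scale + 1)
  disp <- dic_displace_points(px, field)
  def_r <- (disp$def_row - 1) / map_scale + 1
  def_c <- (disp$def_col - 1) / map_scale + 1
  snap_r <- pmin(pmax(round(def_r), 1L), def_grid$n_rows)
  snap_c <- pmin(pmax(round(def_c), 1L), def_grid$n_cols)
  inside <- def_r >= 0.5 & def_r <= def_grid$n_rows + 0.5 &
    def_c >= 0.5 & def_c <= def_grid$n_cols + 0.5
  snap_dist <- sqrt((def_r - snap_r)^2 + (def_c - snap_c)^2)
  out <- data.frame(ref_row = pts$ref_row, ref_col = pts$ref_col,
                    def_row = snap_r, def_col = snap_c,
                    u_px = disp$u, v_px = disp$v,
                    snap_dist = snap_dist,
                    extrapolated = disp$extrapolated,
                    flagged = snap_dist > 1)
  dropped <- sum(!inside)
  if (dropped > 0)
    message(sprintf("match_points: dropped %d displaced points outside the deformed scan", dropped))
  out <- out[inside, , drop = FALSE]
  attr(out, "dropped_n") <- dropped
  out
}

#' Join per-point fit tables onto matched pairs
#'
#' @param matches Output of [match_points()].
#' @param ref_fits,def_fits Per-point fit tables (as from [fit_scan()]),
#'   with `x_index`, `y_index` columns.
#' @param columns Fit columns to carry (suffixed `_ref`/`_def`).
#' @return data.frame of matched pairs with both records attached.
#' @export
pair_fit_records <- function(matches, ref_fits, def_fits,
                             columns = c("D", "w_q", "chi0", "w_chi", "I_c")) {
  key <- function(r, c) paste(r, c, sep = ",")
  ri <- match(key(matches$ref_row, matches$ref_col),
              key(ref_fits$y_index, ref_fits$x_index))
  di <- match(key(matches$def_row, matches$def_col),
              key(def_fits$y_index, def_fits$x_index))
  out <- matches
  for (col in columns) {
    out[[paste0(col, "_ref")]] <- ref_fits[[col]][ri]
    out[[paste0(col, "_def")]] <- def_fits[[col]][di]
  }
  out
}

#' Fibril strain from matched D-periods
#'
#' The axial collagen fibril strain between load states is the relative
#' change of the D-period, `eps_F = (D_def - D_ref) / D_ref`.
#'
#' @param D_ref,D_def D-periods (nm) of the matched reference and
#'   deformed points; vectors allowed.
#' @return Dimensionless strain; `NA` where either D is missing.
#' @examples
#' fibril_strain(64.7, 64.8)   # 1.546e-3
#' @export
fibril_strain <- function(D_ref, D_def) {
  out <- (D_def - D_ref) / D_ref
  out[!is.finite(out)] <- NA_real_
  out
}

#' Fibril-to-tissue strain ratio
#'
#' @param eps_f Fibril strain (dimensionless, e.g. 0.0017).
#' @param eps_t Applied macroscopic tissue strain (e.g. 0.20).
#' @return `eps_f / eps_t`.
#' @examples
#' strain_partition_ratio(0.0017, 0.20)   # 8.5e-3
#' @export
strain_partition_ratio <- function(eps_f, eps_t) {
  if (any(eps_t == 0)) stop("tissue strain must be nonzero")
  eps_f / eps_t
}

#' Pre-strain stress scale from D-period variation
#'
#' Converts a relative D-period variation into an equivalent fibril
#' stress via a linear-elastic fibril modulus, rounded to one
#' significant figure (an order-of-magnitude estimate).
#'
#' @param rel_variation Relative D-period variation (e.g. 0.0023).
#' @param modulus_mpa Collagen fibril modulus in MPa (default 500).
#' @return Stress in MPa, one significant figure.
#' @examples
#' prestrain_stress_mpa(0.0023)   # ~1 MPa
#' @export
prestrain_stress_mpa <- function(rel_variation, modulus_mpa = 500) {
  signif(rel_variation * modulus_mpa, 1)
}

# signed shortest arc from a to b on the 180-degree-periodic circle
arc180 <- function(a, b) {
  d <- (b - a) %% 180
  ifelse(d > 90, d - 180, d)
}

#' Fibril reorientation between load states
#'
#' Angular quantities live on the 180-degree-periodic orientation circle;
#' deviations use the shortest arc. The reorientation toward the loading
#' axis is the reduction in deviation from that axis, so positive values
#' mean the fibril rotated toward the axis.
#'
#' @param chi0_ref,chi0_def Mean fibril angles (degrees, mod 180).
#' @param w_ref,w_def Azimuthal peak widths (degrees); optional.
#' @param loading_axis Loading direction in degrees (default 90,
#'   vertical).
#' @return data.frame with `dev_ref`, `dev_def` (absolute deviation from
#'   the axis, degrees in [0, 90]), `toward_axis` (positive = reorienting
#'   toward the axis), and `d_w_chi` (width change, `NA` if widths not
#'   given).
#' @export
reorientation <- function(chi0_ref, chi0_def, w_ref = NA, w_def = NA,
                          loading_axis = 90) {
  dev_ref <- abs(arc180(loading_axis, chi0_ref))
  dev_def <- abs(arc180(loading_axis, chi0_def))
  data.frame(dev_ref = dev_ref, dev_def = dev_def,
             toward_axis = dev_ref - dev_def,
             d_w_chi = w_def - w_ref)
}

#' Histogram plus kernel density summary of a parameter distribution
#'
#' Gaussian-kernel KDE with Silverman's rule-of-thumb bandwidth,
#' evaluated on a 512-point grid; the mode is the grid argmax.
#'
#' @param values Numeric vector (n >= 5 after removing `NA`).
#' @param weights Optional non-negative weights.
#' @param bins Number of histogram bins (default 30).
#' @return A `distribution_summary`: `histogram` (edges, counts), `kde`
#'   (grid, density), `mode`, `mean`, `sd`, `n`.
#' @export
distribution_summary <- function(values, weights = NULL, bins = 30L) {
  keep <- is.finite(values)
  values <- values[keep]
  if (!is.null(weights)) weights <- weights[keep] / sum(weights[keep])
  if (length(values) < 5L) stop("need at least 5 values")
  m <- if (is.null(weights)) mean(values) else sum(weights * values)
  s <- if (is.null(weights)) stats::sd(values)
    else sqrt(sum(weights * (values - m)^2) * length(values) /
                (length(values) - 1))
  if (s == 0) {
    grid <- seq(m - 1, m + 1, length.out = 512)
    dens <- numeric(512); dens[which.min(abs(grid - m))] <- 1 / diff(grid[1:2])
    kde <- list(x = grid, y = dens)
    mode <- m
  } else {
    kde <- stats::density(values, bw = "nrd0", kernel = "gaussian",
                          n = 512, weights = weights)
    mode <- kde$x[which.max(kde$y)]
  }
  h <- graphics::hist(values, breaks = bins, plot = FALSE)
  structure(list(histogram = list(edges = h$breaks, counts = h$counts),
                 kde = list(grid = kde$x, density = kde$y),
                 mode = mode, mean = m, sd = s, n = length(values)),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("<distribution_summary: n = %d, mean %.5g, sd %.3g, mode %.5g>\n",
              x$n, x$mean, x$sd, x$mode))
  invisible(x)
}

#' Line profile of nanoscale parameters along a reference scan row
#'
#' Orders the matched pairs of one reference row by column and tabulates
#' the before/after values of D-period, radial width, azimuthal width
#' and deviation of the mean fibril angle from the loading axis. No
#' interpolation is performed; flagged points keep their row with `NA`
#' markers.
#'
#' @param pairs Matched-pair table from [pair_fit_records()].
#' @param row Reference row to profile.
#' @param loading_axis Loading direction in degrees (default 90).
#' @return data.frame ordered by `ref_col` with `_ref`/`_def` columns of
#'   `D`, `w_q`, `w_chi` and `dev` (|chi0 - loading_axis| on the
#'   periodic circle).
#' @export
line_profile <- function(pairs, row, loading_axis = 90) {
  sel <- pairs$ref_row == row
  if (!any(sel)) stop("no matched pairs on the requested row")
  p <- pairs[sel, , drop = FALSE]
  p <- p[order(p$ref_col), , drop = FALSE]
  data.frame(ref_row = p$ref_row, ref_col = p$ref_col,
             D_ref = p$D_ref, D_def = p$D_def,
             w_q_ref = p$w_q_ref, w_q_def = p$w_q_def,
             w_chi_ref = p$w_chi_ref, w_chi_def = p$w_chi_def,
             dev_ref = abs(arc180(loading_axis, p$chi0_ref)),
             dev_def = abs(arc180(loading_axis, p$chi0_def)))
}

# circular (180-periodic) standard deviation about the loading axis
circular_sd180 <- function(chi0, center = 90) {
  d <- arc180(center, chi0)
  sqrt(mean(d^2, na.rm = TRUE))
}
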