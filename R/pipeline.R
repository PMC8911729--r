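# Scan-level pipeline: reduce each frame to profiles, fit the collagen /
# IFC / orientation models per point, and track matched points across a
# load step via diffraction-contrast DIC.

# bin count giving roughly half-pixel-wide q bins at the center of the
# collagen window, capped for speed
auto_nbins <- function(geometry, q_range, at = 0.48) {
  r <- q_to_radius_px(at, geometry)
  dq <- pixel_to_q(geometry$beam_center[1],
                   geometry$beam_center[2] + r + 1, geometry)$q - at
  max(40L, min(400L, round(diff(q_range) / (dq / 2))))
}

#' Reduce and fit a single frame
#'
#' Radial integration plus collagen, IFC and azimuthal-orientation fits;
#' the azimuthal profile is taken over the collagen-order q band.
#'
#' @param frame A [detector_frame()].
#' @param geometry A [detector_geometry()].
#' @param q_range Radial integration range (nm^-1).
#' @param n_bins Radial bin count (default: about half-pixel bins).
#' @param collagen_window,ifc_window Fit windows (nm^-1).
#' @param chi_bins Azimuthal bin count (default 72).
#' @param chi_band q band for I(chi) (default the collagen window).
#' @param background Background model for the radial fits.
#' @param with_ifc Fit the IFC peak (default TRUE).
#' @return One-row data.frame: `I_total`, `I_c`, `D`, `w_q`, `I_ifc`,
#'   `D_ifc`, `chi0`, `w_chi`, `converged` (collagen fit), `az_converged`,
#'   `isotropic`, `flags`.
#' @export
fit_frame <- function(frame, geometry, q_range = c(0.05, 0.60),
                      n_bins = NULL, collagen_window = c(0.40, 0.52),
                      ifc_window = c(0.115, 0.15), chi_bins = 72L,
                      chi_band = collagen_window,
                      background = c("exponential", "linear"),
                      with_ifc = TRUE) {
  background <- match.arg(background)
  if (is.null(n_bins))
    n_bins <- max(auto_nbins(geometry, q_range),
                  ceiling(diff(q_range) / (diff(collagen_window) / 24)),
                  if (with_ifc) ceiling(diff(q_range) / (diff(ifc_window) / 12)) else 0L)
  prof <- radial_integrate(frame, geometry, q_range, n_bins)
  col_fit <- fit_collagen(prof, collagen_window, background)
  ifc_fit <- if (with_ifc) fit_ifc(prof, ifc_window, background) else NULL
  az <- tryCatch(
    fit_azimuthal(azimuthal_integrate(frame, geometry, chi_band, chi_bins)),
    error = function(e) NULL)
  flags <- character(0)
  if (!isTRUE(col_fit$fit$converged)) flags <- c(flags, "collagen_failed")
  if (isTRUE(col_fit$fit$converged) && !col_fit$d_plausible)
    flags <- c(flags, "D_implausible")
  if (with_ifc && !isTRUE(ifc_fit$fit$converged)) flags <- c(flags, "ifc_failed")
  if (is.null(az) || !az$converged) flags <- c(flags, "azimuthal_failed")
  else if (az$isotropic) flags <- c(flags, "isotropic")
  data.frame(
    I_total = total_intensity(prof),
    I_c = col_fit$I_c, D = col_fit$D, w_q = col_fit$w_q,
    I_ifc = if (with_ifc) ifc_fit$I_ifc else NA_real_,
    D_ifc = if (with_ifc) ifc_fit$D_ifc else NA_real_,
    chi0 = if (!is.null(az)) az$chi0 else NA_real_,
    w_chi = if (!is.null(az)) az$w_chi else NA_real_,
    converged = isTRUE(col_fit$fit$converged),
    az_converged = !is.null(az) && isTRUE(az$converged) && !az$isotropic,
    isotropic = !is.null(az) && isTRUE(az$isotropic),
    flags = paste(flags, collapse = ";"))
}

#' Reduce and fit every frame of a scan
#'
#' @param scan A `sim_scan` from [simulate_scan()], or a list with
#'   elements `truth` (data.frame with `y_index`, `x_index`) and
#'   `frame_fn(i)`.
#' @param ... Passed to [fit_frame()].
#' @param progress Print a dot every 50 frames.
#' @return data.frame with `x_index`, `y_index` and the [fit_frame()]
#'   columns, one row per scan point.
#' @export
fit_scan <- function(scan, ..., progress = FALSE) {
  n <- nrow(scan$truth)
  rows <- vector("list", n)
  geometry <- scan$geometry
  for (i in seq_len(n)) {
    r <- fit_frame(scan$frame_fn(i), geometry, ...)
    r$x_index <- scan$truth$x_index[i]
    r$y_index <- scan$truth$y_index[i]
    rows[[i]] <- r
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  do.call(rbind, rows)
}

#' Track scan points across a load step
#'
#' Renders the collagen peak-intensity maps of two fitted scans, runs
#' DIC between them, matches each reference scan point to its deformed
#' counterpart, and attaches both fit records.
#'
#' @param ref_fits,def_fits [fit_scan()] tables of the two load states.
#' @param ref_grid,def_grid [scan_grid()]s (deformed may be larger).
#' @param config A [dic_config()]; for native-resolution scan maps use a
#'   small subset (default here: 9 px subset, 1 px step, 5-subset strain
#'   window, pyramid seeding).
#' @param intensity Fit column rendered as DIC contrast (default
#'   `"I_c"`).
#' @return List: `field` (displacement field on the map), `matches`,
#'   `pairs` (matched-pair table with `_ref`/`_def` fit columns),
#'   `maps` (the two rendered images).
#' @export
track_load_step <- function(ref_fits, def_fits, ref_grid, def_grid,
                            config = dic_config(subset_size = 9L, step = 1L,
                                                strain_window = 5L,
                                                search_radius = 4L,
                                                correlation_min = 0.4,
                                                initial_guess = "pyramid"),
                            intensity = "I_c") {
  nr <- max(ref_grid$n_rows, def_grid$n_rows)
  nc <- max(ref_grid$n_cols, def_grid$n_cols)
  canvas <- scan_grid(nr, nc, ref_grid$step_um)
  pad <- function(fits) {
    m <- assemble_map(fits, canvas, intensity)
    v <- m$values
    v[is.na(v)] <- 0
    rng <- stats::quantile(m$values[m$valid_mask], c(0.01, 0.99), names = FALSE)
    list(img = render_grayscale(parameter_map(v), range = rng,
                                bit_depth = 16L),
         mask = !m$valid_mask)
  }
  ref <- pad(ref_fits)
  def <- pad(def_fits)
  field <- dic_correlate(ref$img + 0, def$img + 0, config,
                         ref_mask = ref$mask)
  ref_img <- ref$img
  def_img <- def$img
  matches <- match_points(ref_grid, def_grid, field, map_scale = 1)
  pairs <- pair_fit_records(matches, ref_fits, def_fits)
  list(field = field, matches = matches, pairs = pairs,
       maps = list(reference = ref_img, deformed = def_img))
}
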