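# File interfaces: TIFF frames and maps, structured text geometry
# configs, two-column profile files, and delimited result tables.

FRAME_TIFF_SCALE <- 2^20  # fixed count scale for 32-bit TIFF storage

#' Write / read a detector frame as TIFF
#'
#' Counts are stored in a single-channel 32-bit TIFF at a fixed scale
#' (exact for integer counts below 2^20); the mask, if any, goes to a
#' companion 8-bit TIFF (`<path>.mask.tif`).
#'
#' @param frame A [detector_frame()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(frame, path) {
  stopifnot(inherits(frame, "detector_frame"))
  if (max(frame$counts, na.rm = TRUE) >= FRAME_TIFF_SCALE)
    stop("counts exceed the storable range")
  cts <- frame$counts
  cts[!is.finite(cts)] <- 0
  tiff::writeTIFF(cts / FRAME_TIFF_SCALE, path, bits.per.sample = 32L)
  if (any(frame$mask))
    tiff::writeTIFF(frame$mask * 1, mask_path(path), bits.per.sample = 8L)
  invisible(path)
}

mask_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".mask.tif")

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  cts <- round(tiff::readTIFF(path) * FRAME_TIFF_SCALE)
  mp <- mask_path(path)
  mask <- if (file.exists(mp)) tiff::readTIFF(mp) > 0.5 else NULL
  detector_frame(cts, mask)
}

#' Write / read a detector geometry config
#'
#' Structured text (YAML) with keys `distance_m`, `pixel_size_um`,
#' `beam_center_row`, `beam_center_col`, `energy_kev`, `frame_rows`,
#' `frame_cols`.
#'
#' @param geometry A [detector_geometry()].
#' @param path Config file path.
#' @return `path` invisibly / the [detector_geometry()].
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "detector_geometry"))
  yaml::write_yaml(list(
    distance_m = geometry$distance_m,
    pixel_size_um = geometry$pixel_size_um,
    beam_center_row = geometry$beam_center[1],
    beam_center_col = geometry$beam_center[2],
    energy_kev = geometry$energy_kev,
    frame_rows = geometry$frame_shape[1],
    frame_cols = geometry$frame_shape[2]), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- yaml::read_yaml(path)
  detector_geometry(g$distance_m, g$pixel_size_um,
                    c(g$beam_center_row, g$beam_center_col),
                    g$energy_kev, c(g$frame_rows, g$frame_cols))
}

# short deterministic hash of the geometry values (polynomial string
# hash modulo a Mersenne prime)
geometry_hash <- function(geometry) {
  txt <- paste(format(c(geometry$distance_m, geometry$pixel_size_um,
                        geometry$beam_center, geometry$energy_kev,
                        geometry$frame_shape), digits = 10), collapse = "|")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write / read a 1D profile as two-column text
#'
#' Grid and intensity columns, with `#`-prefixed header lines recording
#' the axis kind and optional provenance (q band, geometry hash).
#'
#' @param profile A [profile1d()].
#' @param path Output path.
#' @param q_band Optional q band annotation (azimuthal profiles).
#' @param geometry Optional [detector_geometry()]; its hash is recorded.
#' @return `path` invisibly / the [profile1d()].
#' @export
write_profile <- function(profile, path, q_band = NULL, geometry = NULL) {
  stopifnot(inherits(profile, "profile1d"))
  hdr <- c(paste0("# axis_kind: ", profile$axis_kind))
  if (!is.null(q_band))
    hdr <- c(hdr, paste0("# q_band: ", paste(q_band, collapse = " ")))
  if (!is.null(geometry))
    hdr <- c(hdr, paste0("# geometry_hash: ", geometry_hash(geometry)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(grid = profile$grid, intensity = profile$intensity,
               counts_per_bin = profile$counts_per_bin),
    con, row.names = FALSE, col.names = TRUE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  axis <- sub("^# axis_kind:\\s*", "", grep("axis_kind", hdr, value = TRUE))
  if (!length(axis)) axis <- "radial_q"
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  cpb <- if ("counts_per_bin" %in% names(tab)) tab$counts_per_bin else NULL
  profile1d(axis, tab$grid, tab$intensity, cpb)
}

#' Write / read a result table as delimited text
#'
#' Tab-separated with optional `#` header comment lines (e.g. the DIC
#' configuration echo).
#'
#' @param table data.frame.
#' @param path Output path.
#' @param header Character vector of comment lines (without `#`).
#' @return `path` invisibly / the data.frame.
#' @export
write_result_table <- function(table, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(table, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}

#' Write a parameter map as a TIFF pair plus table
#'
#' Values TIFF (32-bit, affinely scaled to [0, 1] over the valid range,
#' recorded in the companion config) and mask TIFF.
#'
#' @param map A [parameter_map()].
#' @param path Base path (values at `<path>`, mask at `<path>.mask.tif`,
#'   scaling at `<path>.yml`).
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  stopifnot(inherits(map, "parameter_map"))
  v <- map$values
  rng <- range(v[map$valid_mask])
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  sc <- (v - rng[1]) / diff(rng)
  sc[!map$valid_mask] <- 0
  tiff::writeTIFF(sc, path, bits.per.sample = 32L)
  tiff::writeTIFF(map$valid_mask * 1, mask_path(path), bits.per.sample = 8L)
  yaml::write_yaml(list(parameter = map$parameter_name, units = map$units,
                        lo = rng[1], hi = rng[2]), paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  sc <- tiff::readTIFF(path)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  mask <- tiff::readTIFF(mask_path(path)) > 0.5
  v <- meta$lo + sc * (meta$hi - meta$lo)
  v[!mask] <- NA_real_
  parameter_map(v, mask, meta$parameter, meta$units)
}
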