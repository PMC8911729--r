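# Assembly of per-point fit results into 2D parameter maps and their
# rendering as grayscale images for diffraction-contrast DIC.

#' Scan grid description
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param step_um Stage step between scan points in micrometres.
#' @param origin Stage coordinates of the first point, `c(x, y)`.
#' @param order Raster convention: `"row_major"` (x fastest, the usual
#'   scanning-stage output) or `"col_major"`.
#' @return Object of class `scan_grid`.
#' @export
scan_grid <- function(n_rows, n_cols, step_um = 15,
                      origin = c(0, 0), order = c("row_major", "col_major")) {
  order <- match.arg(order)
  stopifnot(n_rows >= 1, n_cols >= 1, step_um > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 step_um = as.numeric(step_um), origin = as.numeric(origin),
                 order = order),
            class = "scan_grid")
}

#' 2D parameter map over a scan grid
#'
#' @param values Numeric matrix (n_rows x n_cols); entries under an
#'   invalid mask cell are stored as `NA`.
#' @param valid_mask Logical matrix, `TRUE` = valid cell.
#' @param parameter_name,units Metadata strings.
#' @return Object of class `parameter_map`.
#' @export
parameter_map <- function(values, valid_mask = NULL, parameter_name = "",
                          units = "") {
  stopifnot(is.matrix(values))
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  stopifnot(identical(dim(valid_mask), dim(values)))
  valid_mask <- valid_mask & is.finite(values)
  values[!valid_mask] <- NA_real_
  structure(list(values = values, valid_mask = valid_mask,
                 parameter_name = parameter_name, units = units),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map '%s' [%s]: %d x %d, %d valid, range [%.4g, %.4g]>\n",
              x$parameter_name, x$units, nrow(x$values), ncol(x$values),
              sum(x$valid_mask),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Assemble a fit table into a parameter map
#'
#' Takes a per-scan-point fit table (one row per point, with integer
#' `x_index`, `y_index` columns, 1-based) and places the chosen
#' parameter column on the grid. Points that are absent, non-finite, or
#' carry `converged = FALSE` are masked.
#'
#' @param fit_table data.frame with `x_index` (column index), `y_index`
#'   (row index) and the parameter column; an optional logical
#'   `converged` column masks failed points.
#' @param grid A [scan_grid()].
#' @param parameter Name of the column to map.
#' @param units Units string recorded on the map.
#' @return A [parameter_map()].
#' @export
assemble_map <- function(fit_table, grid, parameter, units = "") {
  stopifnot(is.data.frame(fit_table), inherits(grid, "scan_grid"))
  if (!all(c("x_index", "y_index", parameter) %in% names(fit_table)))
    stop("fit_table lacks x_index/y_index/", parameter)
  xi <- as.integer(fit_table$x_index); yi <- as.integer(fit_table$y_index)
  if (any(xi < 1L | xi > grid$n_cols | yi < 1L | yi > grid$n_rows))
    stop("fit_table indices outside the scan grid")
  if (anyDuplicated(cbind(yi, xi)))
    stop("duplicate scan point in fit_table")
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  vals[cbind(yi, xi)] <- as.numeric(fit_table[[parameter]])
  if ("converged" %in% names(fit_table)) {
    bad <- !is.na(fit_table$converged) & !fit_table$converged
    vals[cbind(yi[bad], xi[bad])] <- NA_real_
  }
  parameter_map(vals, parameter_name = parameter, units = units)
}

#' Flatten a parameter map back to a fit table
#'
#' Inverse of [assemble_map()] on complete tables; masked cells are
#' omitted.
#'
#' @param map A [parameter_map()].
#' @return data.frame with `x_index`, `y_index` and the parameter column.
#' @export
disassemble_map <- function(map) {
  stopifnot(inherits(map, "parameter_map"))
  idx <- which(map$valid_mask, arr.ind = TRUE)
  out <- data.frame(x_index = idx[, 2], y_index = idx[, 1],
                    value = map$values[idx])
  names(out)[3] <- if (nzchar(map$parameter_name)) map$parameter_name else "value"
  out[order(out$y_index, out$x_index), , drop = FALSE]
}

#' Mask map cells below a scattering-intensity threshold
#'
#' Reproduces the threshold-based sparse representation: parameter values
#' are kept only where the companion intensity map exceeds a minimum, so
#' spacings are not reported from points with negligible peak intensity.
#'
#' @param map Parameter [parameter_map()] to be thresholded.
#' @param intensity_map [parameter_map()] of the gating intensity, same
#'   shape.
#' @param threshold Minimum intensity; cells strictly below it (or
#'   invalid in the intensity map) are masked.
#' @return The thresholded [parameter_map()].
#' @export
threshold_mask <- function(map, intensity_map, threshold) {
  stopifnot(inherits(map, "parameter_map"),
            inherits(intensity_map, "parameter_map"))
  if (!identical(dim(map$values), dim(intensity_map$values)))
    stop("map shapes differ")
  keep <- map$valid_mask & intensity_map$valid_mask &
    !is.na(intensity_map$values) & intensity_map$values >= threshold
  keep[is.na(keep)] <- FALSE
  vals <- map$values
  vals[!keep] <- NA_real_
  parameter_map(vals, keep, map$parameter_name, map$units)
}

#' Render a parameter map to a grayscale image
#'
#' Linear scaling of `[lo, hi]` onto the integer gray range, clipped at
#' the ends; masked cells render as 0. Deterministic, suitable as DIC
#' input. By default the range is the 1st-99th percentile of valid cells
#' so isolated hot cells do not compress the contrast.
#'
#' @param map A [parameter_map()].
#' @param range Length-2 numeric `(lo, hi)`, `lo < hi`; default the
#'   1st-99th percentile of valid values.
#' @param bit_depth 8 or 16.
#' @return Integer matrix of gray levels in `[0, 2^bit_depth - 1]` with
#'   attributes `range` and `bit_depth`.
#' @export
render_grayscale <- function(map, range = NULL, bit_depth = 16L) {
  stopifnot(inherits(map, "parameter_map"))
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (is.null(range)) {
    v <- map$values[map$valid_mask]
    if (!length(v)) stop("no valid cells to render")
    range <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
    if (range[1] == range[2]) range <- range[1] + c(-0.5, 0.5)
  }
  if (range[1] >= range[2]) stop("range must be increasing")
  gmax <- 2^bit_depth - 1
  sc <- (map$values - range[1]) / (range[2] - range[1])
  sc[sc < 0] <- 0; sc[sc > 1] <- 1
  img <- matrix(as.integer(round(sc * gmax)), nrow(map$values))
  img[!map$valid_mask] <- 0L
  attr(img, "range") <- range
  attr(img, "bit_depth") <- as.integer(bit_depth)
  img
}

#' Invert a rendered grayscale image back to parameter values
#'
#' @param img Integer matrix from [render_grayscale()] (attributes
#'   `range` and `bit_depth` required unless given explicitly).
#' @param range,bit_depth Override the stored rendering parameters.
#' @return Numeric matrix of reconstructed values (quantized to
#'   `1/2^bit_depth` of the range).
#' @export
unrender_grayscale <- function(img, range = attr(img, "range"),
                               bit_depth = attr(img, "bit_depth")) {
  stopifnot(!is.null(range), !is.null(bit_depth))
  range[1] + (img / (2^bit_depth - 1)) * (range[2] - range[1])
}
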