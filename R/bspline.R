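# Separable cardinal B-spline interpolation of images.
#
# Implements the classic two-step scheme: a recursive prefilter turns
# pixel samples into B-spline coefficients, and evaluation is a separable
# weighted sum of (degree+1)^2 coefficients. Degree 6 is the default used
# by the DIC engine for gray-level interpolation; any degree >= 2 works.
# Boundaries use whole-sample mirror symmetry throughout.

#' Centered B-spline basis function
#'
#' Evaluates the centered cardinal B-spline of a given degree, or its
#' first derivative, by the standard two-term recursion.
#'
#' @param x Numeric vector of evaluation points.
#' @param degree Spline degree (non-negative integer).
#' @param deriv 0 for the value, 1 for the first derivative.
#' @return Numeric vector.
#' @keywords internal
bspline_basis <- function(x, degree, deriv = 0L) {
  if (deriv > 0L) {
    if (degree == 0L) stop("derivative of degree-0 B-spline not supported")
    return(bspline_basis(x + 0.5, degree - 1L) -
           bspline_basis(x - 0.5, degree - 1L))
  }
  if (degree == 0L) {
    v <- as.numeric(abs(x) < 0.5)
    v[abs(x) == 0.5] <- 0.5
    return(v)
  }
  n <- degree
  (((n + 1) / 2 + x) * bspline_basis(x + 0.5, n - 1L) +
   ((n + 1) / 2 - x) * bspline_basis(x - 0.5, n - 1L)) / n
}

# Poles of the direct B-spline filter: roots inside the unit circle of the
# symmetric z-transform of the sampled B-spline kernel.
bspline_poles <- function(degree) {
  if (degree < 2L) return(numeric(0))
  half <- floor(degree / 2)
  b <- bspline_basis(seq(-half, half), degree)
  r <- polyroot(rev(b))
  z <- Re(r[abs(Mod(r)) < 1 & abs(Im(r)) < 1e-8])
  sort(z)
}

# Mirror (whole-sample symmetric) index fold into 1..n.
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j >= n, p - j, j)
  j + 1L
}

# Recursive prefilter along the columns-direction (i.e. down each column)
# for one pole, matrix-vectorized across columns.
filter_pole_cols <- function(M, z, tol = 1e-12) {
  n <- nrow(M)
  if (n == 1L) return(M)
  horizon <- min(n, ceiling(log(tol) / log(abs(z))))
  # causal init: mirror extension x[-k] = x[k]
  c0 <- M[1, , drop = FALSE]
  zk <- z
  for (k in seq_len(horizon - 1L)) {
    c0 <- c0 + zk * M[k + 1L, , drop = FALSE]
    zk <- zk * z
  }
  M[1, ] <- c0
  for (k in 2:n) M[k, ] <- M[k, ] + z * M[k - 1L, ]
  M[n, ] <- (z / (z * z - 1)) * (z * M[n - 1L, ] + M[n, ])
  for (k in (n - 1L):1L) M[k, ] <- z * (M[k + 1L, ] - M[k, ])
  M
}

#' B-spline coefficient image
#'
#' Prefilters an image so that separable B-spline evaluation of the
#' result interpolates the original pixel values exactly at pixel centers.
#'
#' @param img Numeric matrix.
#' @param degree Spline degree (default 6).
#' @return Object of class `bspline_image` holding the coefficient matrix.
#' @export
bspline_prefilter <- function(img, degree = 6L) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  poles <- bspline_poles(degree)
  C <- img
  if (length(poles)) {
    gain <- prod((1 - poles) * (1 - 1 / poles))
    C <- C * gain^2  # gain applies once per filtered dimension
    for (z in poles) C <- filter_pole_cols(C, z)
    C <- t(C)
    for (z in poles) C <- filter_pole_cols(C, z)
    C <- t(C)
  }
  structure(list(coef = C, degree = as.integer(degree), dim = dim(img)),
            class = "bspline_image")
}

# Per-tap interpolation weights are degree-d polynomials of the
# fractional offset; their coefficients are interpolated once from the
# exact recursive basis and cached by (degree, deriv).
.tap_poly_cache <- new.env(parent = emptyenv())

tap_poly <- function(degree, deriv = 0L) {
  key <- paste0(degree, ".", deriv)
  hit <- .tap_poly_cache[[key]]
  if (!is.null(hit)) return(hit)
  ntap <- degree + 1L
  # t = x - first_tap spans a unit interval free of spline breakpoints
  t_lo <- (degree - 1) / 2
  tmid <- t_lo + 0.5
  nodes <- t_lo + (seq_len(ntap) - 0.5) / ntap
  V <- outer(nodes - tmid, 0:degree, `^`)
  coef <- sapply(seq_len(ntap), function(j)
    solve(V, bspline_basis(nodes - (j - 1L), degree, deriv)))
  out <- list(tmid = tmid, coef = coef, ntap = ntap)
  .tap_poly_cache[[key]] <- out
  out
}

horner_taps <- function(t, tp) {
  tc <- t - tp$tmid
  W <- matrix(0, length(t), tp$ntap)
  deg <- nrow(tp$coef) - 1L
  for (j in seq_len(tp$ntap)) {
    acc <- rep(tp$coef[deg + 1L, j], length(t))
    for (k in deg:1) acc <- acc * tc + tp$coef[k, j]
    W[, j] <- acc
  }
  W
}

#' Evaluate a B-spline image at arbitrary points
#'
#' @param sp A [bspline_prefilter()] result.
#' @param row,col Numeric vectors of (fractional, 1-based) coordinates.
#' @param deriv `"none"`, `"row"` or `"col"`: value or first partial
#'   derivative along the row (y) or column (x) direction.
#' @return Numeric vector of interpolated values; coordinates outside the
#'   image are evaluated on its mirror extension.
#' @export
bspline_eval <- function(sp, row, col, deriv = c("none", "row", "col")) {
  stopifnot(inherits(sp, "bspline_image"))
  deriv <- match.arg(deriv)
  deg <- sp$degree
  ntap <- deg + 1L
  half <- (deg + 1) / 2
  n <- length(row)
  stopifnot(length(col) == n)
  # fold onto the mirror period so far-out (or non-finite) query points
  # stay representable; values are unchanged for in-range coordinates
  fold <- function(x, nn) {
    x[!is.finite(x) | abs(x) > 1e9] <- 1
    if (nn == 1L) return(rep(1, length(x)))
    p <- 2 * (nn - 1)
    t <- (x - 1) %% p
    ifelse(t > nn - 1, p - t, t) + 1
  }
  row <- fold(row, sp$dim[1])
  col <- fold(col, sp$dim[2])
  fr <- as.integer(ceiling(row - half))
  fc <- as.integer(ceiling(col - half))
  acc <- numeric(n)
  nr <- sp$dim[1]; nc <- sp$dim[2]
  wr <- horner_taps(row - fr, tap_poly(deg, as.integer(deriv == "row")))
  wc <- horner_taps(col - fc, tap_poly(deg, as.integer(deriv == "col")))
  ir <- matrix(0L, n, ntap); ic <- matrix(0L, n, ntap)
  for (j in seq_len(ntap)) {
    ir[, j] <- mirror_index(fr + j - 1L, nr)
    ic[, j] <- mirror_index(fc + j - 1L, nc)
  }
  for (jr in seq_len(ntap)) for (jc in seq_len(ntap)) {
    acc <- acc + (wr[, jr] * wc[, jc]) *
      sp$coef[ir[, jr] + (ic[, jc] - 1L) * nr]
  }
  acc
}

#' Resample an image through a coordinate mapping
#'
#' Returns the image whose pixel (r, c) takes the value of `img`
#' interpolated at `map(r, c)`; used to impose known warps on synthetic
#' images with the same interpolation model the DIC engine uses.
#'
#' @param img Numeric matrix.
#' @param map Function taking matrices `row`, `col` (target coordinates)
#'   and returning `list(row=, col=)` source coordinates.
#' @param degree Interpolation degree (default 6).
#' @return Numeric matrix of the same shape.
#' @export
resample_image <- function(img, map, degree = 6L) {
  sp <- bspline_prefilter(img, degree)
  nr <- nrow(img); nc <- ncol(img)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  src <- map(rows, cols)
  matrix(bspline_eval(sp, as.numeric(src$row), as.numeric(src$col)), nr, nc)
}
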