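# Subset-based digital image correlation (DIC) on diffraction-contrast
# maps. Integer-pixel ZNCC search followed by subpixel refinement with an
# inverse-compositional Gauss-Newton iteration on a translation + affine
# subset shape function; deformed gray levels are evaluated through a
# degree-6 B-spline interpolant and subset pixels carry a round
# (circular, raised-cosine tapered) weight window.

#' DIC processing configuration
#'
#' @param subset_size Odd subset edge length in pixels (default 25).
#' @param step Subset-center spacing in pixels (default 3).
#' @param window Weighting window; only `"round_weighted"` is provided: a
#'   circular support of radius `(subset_size-1)/2` with a raised-cosine
#'   radial taper beginning at `taper_start` of the radius.
#' @param interpolation_order B-spline degree for gray-level
#'   interpolation (default 6).
#' @param strain_window Odd number of subsets per side of the local
#'   plane-fit neighbourhood used for strain (default 7).
#' @param search_radius Integer search radius in pixels (default 5).
#' @param correlation_min Minimum ZNCC for a subset to be valid
#'   (default 0.5).
#' @param max_iter,conv_tol Gauss-Newton iteration cap (default 50) and
#'   convergence threshold on the update norm in pixels (default 1e-4).
#' @param taper_start Fraction of the subset radius at which the
#'   raised-cosine taper begins (default 0.5).
#' @param initial_guess `"none"` or `"pyramid"`: with `"pyramid"`, a
#'   2x-downsampled whole-image correlation pre-pass seeds the integer
#'   search, extending the effective range for large deformations.
#' @return Object of class `dic_config`.
#' @export
dic_config <- function(subset_size = 25L, step = 3L,
                       window = "round_weighted",
                       interpolation_order = 6L, strain_window = 7L,
                       search_radius = 5L, correlation_min = 0.5,
                       max_iter = 50L, conv_tol = 1e-4, taper_start = 0.5,
                       initial_guess = c("none", "pyramid")) {
  subset_size <- as.integer(subset_size)
  strain_window <- as.integer(strain_window)
  if (subset_size %% 2L == 0L) stop("subset_size must be odd")
  if (strain_window %% 2L == 0L) stop("strain_window must be odd")
  if (step < 1L) stop("step must be >= 1")
  window <- match.arg(window, "round_weighted")
  structure(list(subset_size = subset_size, step = as.integer(step),
                 window = window,
                 interpolation_order = as.integer(interpolation_order),
                 strain_window = strain_window,
                 search_radius = as.integer(search_radius),
                 correlation_min = correlation_min,
                 max_iter = as.integer(max_iter), conv_tol = conv_tol,
                 taper_start = taper_start,
                 initial_guess = match.arg(initial_guess)),
            class = "dic_config")
}

round_window_weights <- function(subset_size, taper_start) {
  h <- (subset_size - 1) / 2
  off <- seq(-h, h)
  rho <- sqrt(outer(off^2, off^2, `+`))
  w <- numeric(length(rho)); dim(w) <- dim(rho)
  w[rho <= taper_start * h] <- 1
  tz <- rho > taper_start * h & rho <= h
  w[tz] <- 0.5 * (1 + cos(pi * (rho[tz] - taper_start * h) /
                            ((1 - taper_start) * h)))
  w
}

# Whole-image integer shift estimate on 2x-downsampled images.
coarse_shift <- function(reference, deformed, radius) {
  ds <- function(M) {
    nr <- 2L * (nrow(M) %/% 2L); nc <- 2L * (ncol(M) %/% 2L)
    M <- M[seq_len(nr), seq_len(nc)]
    (M[seq(1, nr, 2), seq(1, nc, 2)] + M[seq(2, nr, 2), seq(1, nc, 2)] +
     M[seq(1, nr, 2), seq(2, nc, 2)] + M[seq(2, nr, 2), seq(2, nc, 2)]) / 4
  }
  a <- ds(reference); b <- ds(deformed)
  best <- c(0L, 0L); best_c <- -Inf
  for (dv in -radius:radius) for (du in -radius:radius) {
    r1 <- max(1, 1 - dv):min(nrow(a), nrow(a) - dv)
    c1 <- max(1, 1 - du):min(ncol(a), ncol(a) - du)
    if (length(r1) < 8 || length(c1) < 8) next
    x <- a[r1, c1]; y <- b[r1 + dv, c1 + du]
    cc <- suppressWarnings(stats::cor(as.vector(x), as.vector(y)))
    if (is.finite(cc) && cc > best_c) { best_c <- cc; best <- c(du, dv) }
  }
  2L * best
}

#' Correlate a reference and a deformed image
#'
#' Computes a displacement field on a regular grid of subset centers.
#' Each subset is first located by integer-pixel zero-normalized
#' cross-correlation (ZNCC) within the search radius, then refined by an
#' inverse-compositional Gauss-Newton iteration over a translation +
#' affine shape function. Subsets with (near) zero gray-level variance,
#' failed convergence, correlation below `correlation_min`, or warped
#' outside the image are marked invalid.
#'
#' @param reference,deformed Numeric matrices of identical shape, each
#'   dimension at least twice the subset size.
#' @param config A [dic_config()].
#' @param ref_mask Optional logical matrix (`TRUE` = excluded pixel);
#'   masked pixels get zero subset weight and subsets with more than half
#'   their window weight masked are invalid.
#' @return A `displacement_field`: vectors `centers_row`, `centers_col`
#'   and matrices `u` (x/column displacement, px), `v` (y/row
#'   displacement, px), `correlation`, `valid`, plus the `config`.
#' @export
dic_correlate <- function(reference, deformed, config = dic_config(),
                          ref_mask = NULL) {
  stopifnot(is.matrix(reference), is.matrix(deformed))
  if (!identical(dim(reference), dim(deformed)))
    stop("reference and deformed shapes differ")
  s <- config$subset_size
  nr <- nrow(reference); nc <- ncol(reference)
  if (nr < 2L * s || nc < 2L * s)
    stop("images must be at least twice the subset size in each dimension")
  reference <- matrix(as.numeric(reference), nr, nc)
  deformed <- matrix(as.numeric(deformed), nr, nc)
  h <- (s - 1L) %/% 2L
  centers_row <- seq(h + 1L, nr - h, by = config$step)
  centers_col <- seq(h + 1L, nc - h, by = config$step)
  ncr <- length(centers_row); ncc <- length(centers_col)

  W <- round_window_weights(s, config$taper_start)
  off <- seq(-h, h)
  oy <- matrix(off, s, s); ox <- matrix(off, s, s, byrow = TRUE)
  wvec <- as.vector(W); oyv <- as.vector(oy); oxv <- as.vector(ox)
  npix <- s * s

  # subset gather: linear indices of subset pixels for all centers
  cgrid <- expand.grid(r = centers_row, c = centers_col)
  nsub <- nrow(cgrid)
  clin <- cgrid$r + (cgrid$c - 1L) * nr
  offlin <- oyv + oxv * nr
  IDX <- outer(clin, offlin, `+`)           # nsub x npix
  Fm <- matrix(reference[IDX], nsub, npix)

  # per-subset weights (ref-side masking)
  Wm <- matrix(wvec, nsub, npix, byrow = TRUE)
  if (!is.null(ref_mask)) {
    Wm[matrix(ref_mask[IDX], nsub, npix)] <- 0
  }
  sw <- rowSums(Wm)
  mask_ok <- sw > 0.5 * sum(wvec)
  fbar <- rowSums(Wm * Fm) / pmax(sw, 1e-300)
  Fc <- Fm - fbar
  varf <- rowSums(Wm * Fc^2)
  scale_ref <- pmax(rowSums(Wm * Fm^2), 1e-300)
  texture_ok <- varf > 1e-12 * scale_ref
  FcW <- Fc * Wm

  seed <- c(0L, 0L)
  if (config$initial_guess == "pyramid")
    seed <- coarse_shift(reference, deformed, max(4L, config$search_radius))

  # integer-pixel ZNCC search, vectorized across subsets per offset
  R <- config$search_radius
  best_cc <- rep(-Inf, nsub); best_du <- integer(nsub); best_dv <- integer(nsub)
  for (dv in (seed[2] - R):(seed[2] + R)) {
    for (du in (seed[1] - R):(seed[1] + R)) {
      rr <- cgrid$r + dv; cc_ <- cgrid$c + du
      inb <- rr >= h + 1L & rr <= nr - h & cc_ >= h + 1L & cc_ <= nc - h
      if (!any(inb)) next
      idx <- IDX[inb, , drop = FALSE] + (dv + du * nr)
      G <- matrix(deformed[idx], sum(inb), npix)
      Wi <- Wm[inb, , drop = FALSE]
      swi <- sw[inb]
      gbar <- rowSums(Wi * G) / pmax(swi, 1e-300)
      varg <- rowSums(Wi * G^2) - swi * gbar^2
      num <- rowSums(FcW[inb, , drop = FALSE] * G)
      cc2 <- num / sqrt(pmax(varf[inb] * varg, 1e-300))
      cc2[varg <= 0] <- -Inf
      upd <- which(inb)[cc2 > best_cc[inb]]
      if (length(upd)) {
        sel <- cc2 > best_cc[inb]
        best_cc[upd] <- cc2[sel]
        best_du[upd] <- du; best_dv[upd] <- dv
      }
    }
  }

  # spline models of both images: deformed for warped gray levels,
  # reference for subset gradients (evaluated once at all pixels)
  deg <- config$interpolation_order
  sp_def <- bspline_prefilter(deformed, deg)
  sp_ref <- bspline_prefilter(reference, deg)
  allr <- matrix(seq_len(nr), nr, nc); allc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  Gx <- matrix(bspline_eval(sp_ref, as.numeric(allr), as.numeric(allc), "col"), nr, nc)
  Gy <- matrix(bspline_eval(sp_ref, as.numeric(allr), as.numeric(allc), "row"), nr, nc)

  u <- matrix(NA_real_, ncr, ncc); v <- matrix(NA_real_, ncr, ncc)
  corr <- matrix(NA_real_, ncr, ncc); valid <- matrix(FALSE, ncr, ncc)

  for (i in seq_len(nsub)) {
    ri <- match(cgrid$r[i], centers_row); ci <- match(cgrid$c[i], centers_col)
    if (!mask_ok[i] || !texture_ok[i] || !is.finite(best_cc[i])) next
    wi <- Wm[i, ]
    f <- Fm[i, ]
    fc <- Fc[i, ]
    sigf <- sqrt(varf[i])
    fx <- Gx[IDX[i, ]]; fy <- Gy[IDX[i, ]]
    J <- cbind(fx, fy, fx * oxv, fx * oyv, fy * oxv, fy * oyv)
    H <- crossprod(J, J * wi)
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(Hi)) next
    # warp matrix: x' = (1+p3) xi + p4 eta + p1 ; y' = p5 xi + (1+p6) eta + p2
    M <- diag(3); M[1, 3] <- best_du[i]; M[2, 3] <- best_dv[i]
    ok <- FALSE
    for (it in seq_len(config$max_iter)) {
      gx <- cgrid$c[i] + M[1, 1] * oxv + M[1, 2] * oyv + M[1, 3]
      gy <- cgrid$r[i] + M[2, 1] * oxv + M[2, 2] * oyv + M[2, 3]
      g <- bspline_eval(sp_def, gy, gx)
      gbar <- sum(wi * g) / sw[i]
      gc <- g - gbar
      sigg <- sqrt(sum(wi * gc^2))
      if (!is.finite(sigg) || sigg < 1e-12 * sigf) break
      r_ <- fc / sigf - gc / sigg
      dp <- tryCatch(-sigf * (Hi %*% crossprod(J, wi * r_)),
                     error = function(e) NULL)
      if (is.null(dp) || any(!is.finite(dp))) break
      Md <- matrix(c(1 + dp[3], dp[4], dp[1],
                     dp[5], 1 + dp[6], dp[2],
                     0, 0, 1), 3, 3, byrow = TRUE)
      Mdi <- tryCatch(solve(Md), error = function(e) NULL)
      if (is.null(Mdi)) break
      M <- M %*% Mdi
      # a translation beyond the image scale means divergence
      if (abs(M[1, 3]) + abs(M[2, 3]) > nr + nc) break
      upd <- sqrt(dp[1]^2 + dp[2]^2 + h^2 * sum(dp[3:6]^2))
      if (upd < config$conv_tol) { ok <- TRUE; break }
    }
    if (!ok) next
    gx <- cgrid$c[i] + M[1, 1] * oxv + M[1, 2] * oyv + M[1, 3]
    gy <- cgrid$r[i] + M[2, 1] * oxv + M[2, 2] * oyv + M[2, 3]
    out_frac <- sum(wi[gx < 0.5 | gx > nc + 0.5 | gy < 0.5 | gy > nr + 0.5]) / sw[i]
    g <- bspline_eval(sp_def, gy, gx)
    gbar <- sum(wi * g) / sw[i]
    gc <- g - gbar
    sigg <- sqrt(sum(wi * gc^2))
    zncc <- sum(wi * fc * gc) / (sigf * sigg)
    u[ri, ci] <- M[1, 3]; v[ri, ci] <- M[2, 3]
    corr[ri, ci] <- zncc
    valid[ri, ci] <- is.finite(zncc) && zncc >= config$correlation_min &&
      out_frac <= 0.1
  }
  structure(list(centers_row = centers_row, centers_col = centers_col,
                 u = u, v = v, correlation = corr, valid = valid,
                 config = config),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field: %d x %d subsets (step %d px), %d valid, median |u,v| = (%.3g, %.3g) px>\n",
              length(x$centers_row), length(x$centers_col), x$config$step,
              sum(x$valid),
              stats::median(abs(x$u[x$valid])),
              stats::median(abs(x$v[x$valid]))))
  invisible(x)
}

#' Local strain from a displacement field
#'
#' At each subset, fits planes `u(x, y)` and `v(x, y)` by least squares
#' over the surrounding `strain_window` x `strain_window` valid subsets;
#' the plane gradients give the in-plane strain components
#' `exx = du/dx`, `eyy = dv/dy`, `exy = (du/dy + dv/dx)/2` (px/px).
#' Cells whose window holds fewer than 6 valid subsets, or fewer than
#' half the window, are invalid.
#'
#' @param field A `displacement_field` from [dic_correlate()].
#' @param config A [dic_config()]; its `strain_window` is used.
#' @return A `strain_field`: `centers_row`, `centers_col`, matrices
#'   `exx`, `eyy`, `exy`, `valid`.
#' @export
dic_strain <- function(field, config = field$config) {
  stopifnot(inherits(field, "displacement_field"))
  k <- (config$strain_window - 1L) %/% 2L
  ncr <- length(field$centers_row); ncc <- length(field$centers_col)
  exx <- eyy <- exy <- matrix(NA_real_, ncr, ncc)
  valid <- matrix(FALSE, ncr, ncc)
  need <- max(6L, ceiling(0.5 * config$strain_window^2))
  for (ri in seq_len(ncr)) for (ci in seq_len(ncc)) {
    rr <- max(1L, ri - k):min(ncr, ri + k)
    cc_ <- max(1L, ci - k):min(ncc, ci + k)
    sel <- field$valid[rr, cc_, drop = FALSE]
    if (sum(sel) < need) next
    ys <- matrix(field$centers_row[rr], length(rr), length(cc_))
    xs <- matrix(field$centers_col[cc_], length(rr), length(cc_), byrow = TRUE)
    X <- cbind(1, xs[sel], ys[sel])
    cu <- tryCatch(qr.solve(X, field$u[rr, cc_, drop = FALSE][sel]),
                   error = function(e) NULL)
    cv <- tryCatch(qr.solve(X, field$v[rr, cc_, drop = FALSE][sel]),
                   error = function(e) NULL)
    if (is.null(cu) || is.null(cv)) next
    exx[ri, ci] <- cu[2]
    eyy[ri, ci] <- cv[3]
    exy[ri, ci] <- (cu[3] + cv[2]) / 2
    valid[ri, ci] <- TRUE
  }
  structure(list(centers_row = field$centers_row,
                 centers_col = field$centers_col,
                 exx = exx, eyy = eyy, exy = exy, valid = valid),
            class = "strain_field")
}

#' Displace reference points through a displacement field
#'
#' Bilinear interpolation of `(u, v)` from the subset-center grid to each
#' query point; the deformed position is the point plus its interpolated
#' displacement. Points outside the convex hull of subset centers (or in
#' cells without any valid corner) fall back to a global affine fit of
#' the valid displacement field and are flagged `extrapolated`.
#'
#' @param points Two-column matrix or data.frame of reference pixel
#'   coordinates `(row, col)`.
#' @param field A `displacement_field`.
#' @return data.frame with `row`, `col`, `u`, `v`, `def_row`, `def_col`,
#'   `extrapolated` (logical flag).
#' @export
dic_displace_points <- function(points, field) {
  stopifnot(inherits(field, "displacement_field"))
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  cr <- field$centers_row; cc_ <- field$centers_col
  n <- nrow(points)
  u <- v <- rep(NA_real_, n)
  extrap <- rep(FALSE, n)
  vidx <- which(field$valid, arr.ind = TRUE)
  if (nrow(vidx) == 0L) stop("displacement field has no valid subsets")
  vy <- cr[vidx[, 1]]; vx <- cc_[vidx[, 2]]
  # low-order (affine) model of the field for out-of-hull extrapolation
  X <- cbind(1, vx, vy)
  au <- qr.solve(X, field$u[vidx])
  av <- qr.solve(X, field$v[vidx])
  for (i in seq_len(n)) {
    py <- points[i, 1]; px <- points[i, 2]
    inside <- py >= cr[1] && py <= cr[length(cr)] &&
      px >= cc_[1] && px <= cc_[length(cc_)]
    got <- FALSE
    if (inside) {
      iy <- findInterval(py, cr, rightmost.closed = TRUE)
      ix <- findInterval(px, cc_, rightmost.closed = TRUE)
      iy <- min(max(iy, 1L), length(cr) - 1L)
      ix <- min(max(ix, 1L), length(cc_) - 1L)
      ty <- (py - cr[iy]) / (cr[iy + 1] - cr[iy])
      tx <- (px - cc_[ix]) / (cc_[ix + 1] - cc_[ix])
      wts <- c((1 - ty) * (1 - tx), (1 - ty) * tx, ty * (1 - tx), ty * tx)
      ids <- rbind(c(iy, ix), c(iy, ix + 1), c(iy + 1, ix), c(iy + 1, ix + 1))
      ok <- field$valid[ids]
      if (any(ok) && sum(wts[ok]) > 1e-9) {
        wts <- wts[ok] / sum(wts[ok])
        u[i] <- sum(wts * field$u[ids[ok, , drop = FALSE]])
        v[i] <- sum(wts * field$v[ids[ok, , drop = FALSE]])
        extrap[i] <- !all(ok)
        got <- TRUE
      }
    }
    if (!got) {
      u[i] <- sum(au * c(1, px, py))
      v[i] <- sum(av * c(1, px, py))
      extrap[i] <- TRUE
    }
  }
  data.frame(row = points[, 1], col = points[, 2], u = u, v = v,
             def_row = points[, 1] + v, def_col = points[, 2] + u,
             extrapolated = extrap)
}
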