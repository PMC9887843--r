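## Translation-only registration of the NIR frame onto the red frame.
## The rigid side-by-side camera mount justifies a pure translation model;
## the shift is found by normalized cross-correlation over integer offsets
## and refined to sub-pixel precision by parabolic interpolation.

#' Rigid translation between two camera frames
#'
#' Convention: a shift `(dx, dy)` moves image content by `dx` columns and
#' `dy` rows, i.e. `shifted[y, x] = original[y - dy, x - dx]`.
#'
#' @param dx Column shift in pixels (may be fractional).
#' @param dy Row shift in pixels.
#' @param score Alignment quality in \[0, 1\] (peak normalized
#'   cross-correlation).
#' @return An object of class `rigid_shift`.
#' @export
rigid_shift <- function(dx, dy, score = NA_real_) {
  stopifnot(is.numeric(dx), is.numeric(dy), length(dx) == 1L,
            length(dy) == 1L, is.finite(dx), is.finite(dy))
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 score = as.numeric(score)),
            class = "rigid_shift")
}

#' @export
print.rigid_shift <- function(x, ...) {
  cat(sprintf("<rigid_shift> dx = %+0.3f px, dy = %+0.3f px, score = %.4f\n",
              x$dx, x$dy, x$score))
  invisible(x)
}

#' @rdname rigid_shift
#' @param shift A `rigid_shift`.
#' @return `invert_shift()` returns the opposite translation.
#' @export
invert_shift <- function(shift) {
  stopifnot(inherits(shift, "rigid_shift"))
  rigid_shift(-shift$dx, -shift$dy, shift$score)
}

.as_matrix_filled <- function(img) {
  if (inherits(img, "reflectance_image")) {
    v <- img$values
    if (!all(img$mask)) v[!img$mask] <- mean(v[img$mask])
    v
  } else {
    stopifnot(is.matrix(img))
    img
  }
}

#' Estimate the translation between two images
#'
#' Finds the `(dx, dy)` maximizing the normalized cross-correlation of
#' `nir` against `red` over all integer shifts within `search_radius`,
#' then refines each axis to sub-pixel precision with a parabolic fit
#' through the correlation peak and its neighbours.  Returns the shift of
#' the `nir` content relative to `red` (so aligning `nir` onto `red`
#' requires applying the inverted shift, see [invert_shift()]).
#'
#' @param red,nir [reflectance_image()]s or matrices of equal size.
#' @param search_radius Maximum absolute integer shift tested, in pixels;
#'   must not exceed a quarter of the smaller image dimension.
#' @return A [rigid_shift()] with `score` = peak correlation.
#' @export
estimate_shift <- function(red, nir, search_radius = 10) {
  a <- .as_matrix_filled(red)
  b <- .as_matrix_filled(nir)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  h <- nrow(a); w <- ncol(a)
  r <- as.integer(search_radius)
  if (r < 1L || r > min(h, w) / 4) {
    stop("search_radius must be >= 1 and <= min(dim)/4")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("no features: zero-variance image")
  }
  offs <- -r:r
  cc <- matrix(-2, 2L * r + 1L, 2L * r + 1L)  # rows: dy, cols: dx
  for (iy in seq_along(offs)) {
    dy <- offs[iy]
    ri <- max(1L, 1L - dy):min(h, h - dy)
    for (ix in seq_along(offs)) {
      dx <- offs[ix]
      ci <- max(1L, 1L - dx):min(w, w - dx)
      va <- a[ri, ci]
      vb <- b[ri + dy, ci + dx]
      v <- suppressWarnings(stats::cor(as.vector(va), as.vector(vb)))
      if (is.finite(v)) cc[iy, ix] <- v
    }
  }
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sub <- function(i, along) {       # parabolic refinement along one axis
    vals <- if (along == 1) cc[, pk[2]] else cc[pk[1], ]
    if (i <= 1L || i >= length(vals)) return(0)
    c0 <- vals[i]; cm <- vals[i - 1L]; cp <- vals[i + 1L]
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  dy <- offs[pk[1]] + sub(pk[1], 1)
  dx <- offs[pk[2]] + sub(pk[2], 2)
  rigid_shift(dx, dy, score = max(0, min(1, max(cc))))
}

#' Translate an image by a rigid shift
#'
#' Bilinear resampling: `out[y, x] = in[y - dy, x - dx]`.  Output pixels
#' whose source location falls outside the input frame, or draws on an
#' invalid input pixel, are masked.
#'
#' @param img A [reflectance_image()].
#' @param shift A [rigid_shift()] or numeric `c(dx, dy)`.
#' @param fill Value written at masked output pixels (default 0).
#' @return A shifted [reflectance_image()].
#' @export
apply_shift <- function(img, shift, fill = 0) {
  stopifnot(inherits(img, "reflectance_image"))
  if (is.numeric(shift) && length(shift) == 2L) {
    shift <- rigid_shift(shift[1], shift[2])
  }
  stopifnot(inherits(shift, "rigid_shift"))
  v <- img$values; m <- img$mask
  h <- nrow(v); w <- ncol(v)
  ys <- seq_len(h) - shift$dy
  xs <- seq_len(w) - shift$dx
  iy0 <- floor(ys); fy <- ys[1] - iy0[1]
  ix0 <- floor(xs); fx <- xs[1] - ix0[1]
  use_y1 <- fy > 1e-12; use_x1 <- fx > 1e-12
  iy1 <- if (use_y1) iy0 + 1L else iy0
  ix1 <- if (use_x1) ix0 + 1L else ix0
  vr <- which(iy0 >= 1 & iy1 <= h)
  vc <- which(ix0 >= 1 & ix1 <= w)
  out <- matrix(fill, h, w)
  mout <- matrix(FALSE, h, w)
  if (length(vr) && length(vc)) {
    y0 <- iy0[vr]; y1 <- iy1[vr]; x0 <- ix0[vc]; x1 <- ix1[vc]
    out[vr, vc] <-
      (1 - fy) * (1 - fx) * v[y0, x0, drop = FALSE] +
      (1 - fy) * fx       * v[y0, x1, drop = FALSE] +
      fy       * (1 - fx) * v[y1, x0, drop = FALSE] +
      fy       * fx       * v[y1, x1, drop = FALSE]
    mm <- m[y0, x0, drop = FALSE]
    if (use_x1) mm <- mm & m[y0, x1, drop = FALSE]
    if (use_y1) mm <- mm & m[y1, x0, drop = FALSE]
    if (use_y1 && use_x1) mm <- mm & m[y1, x1, drop = FALSE]
    mout[vr, vc] <- mm
  }
  out[!mout] <- fill
  ## numerical guard: bilinear mixing of in-range values stays in range
  out <- pmin(pmax(out, 0), 100)
  reflectance_image(out, img$band, mout)
}
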