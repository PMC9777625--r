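# Undecimated (a trous) Haar wavelet frame.
#
# Level i (i = 0, 1, 2) filters f^(i) with two-tap kernels whose taps sit at
# offsets {0, 2^i}: low-pass h = (1/2, 1/2), high-pass g = (-1/2, 1/2).
# |H(w)|^2 + |G(w)|^2 = 1 for this pair, so with periodic boundary each level
# conserves energy exactly — the basis of the conservation tests.

partner_index <- function(n, l, boundary) {
  p <- seq_len(n) + l
  if (boundary == "periodic") {
    ((p - 1L) %% n) + 1L
  } else {  # half-sample symmetric mirror: ..., n-1, n | n, n-1, ...
    over <- p > n
    p[over] <- 2L * n + 1L - p[over]
    p
  }
}

filt_rows <- function(X, l, kind, boundary) {
  p <- partner_index(nrow(X), l, boundary)
  if (kind == "h") (X + X[p, , drop = FALSE]) / 2
  else (X[p, , drop = FALSE] - X) / 2
}

filt_cols <- function(X, l, kind, boundary) {
  p <- partner_index(ncol(X), l, boundary)
  if (kind == "h") (X + X[, p, drop = FALSE]) / 2
  else (X[, p, drop = FALSE] - X) / 2
}

#' Undecimated Haar wavelet-frame decomposition
#'
#' Recursively splits the image into one low-pass and three high-pass
#' sub-bands per level, using the two-tap Haar pair with holes (taps at
#' offsets 0 and \code{2^i} at level i) so every sub-band keeps the input's
#' size. Orientations: \code{j = 1} is high-pass along x (columns),
#' \code{j = 2} high-pass along y (rows), \code{j = 3} high-pass along both.
#'
#' @param image a \code{\link{us_image}} or numeric matrix.
#' @param levels number of decomposition levels (default 3).
#' @param boundary "mirror" (half-sample symmetric, default) or "periodic".
#'   The wavelet energies are invariant to the filters' phase and sign, so
#'   the boundary rule only affects pixels near the border.
#' @return object of class \code{haar_pyramid}: \code{f} (list of low-pass
#'   rasters f^(0..levels)), \code{d} (per level, list of the 3 high-pass
#'   rasters), \code{levels}, \code{boundary}.
#' @export
haar_frame_decompose <- function(image, levels = 3,
                                 boundary = c("mirror", "periodic")) {
  boundary <- match.arg(boundary)
  X <- if (inherits(image, "us_image")) image$pixels else as.matrix(image)
  support <- 2^levels * 2
  if (nrow(X) < support || ncol(X) < support) {
    abort(sprintf("image (%d x %d) smaller than the %d-px filter support for %d levels.",
                  nrow(X), ncol(X), support, levels))
  }
  f <- vector("list", levels + 1L)
  d <- vector("list", levels)
  f[[1]] <- X
  for (i in seq_len(levels)) {
    l <- 2L^(i - 1L)
    hx <- filt_cols(f[[i]], l, "h", boundary)
    gx <- filt_cols(f[[i]], l, "g", boundary)
    f[[i + 1L]] <- filt_rows(hx, l, "h", boundary)
    d[[i]] <- list(
      filt_rows(gx, l, "h", boundary),  # j = 1: g_x h_y
      filt_rows(hx, l, "g", boundary),  # j = 2: h_x g_y
      filt_rows(gx, l, "g", boundary)   # j = 3: g_x g_y
    )
  }
  structure(list(f = f, d = d, levels = levels, boundary = boundary),
            class = "haar_pyramid")
}

#' Wavelet-frame energy features over the ROI
#'
#' Mean squared sub-band value over Omega: \code{W_ij = ||d_j^(i)||^2 /
#' |Omega|} for the nine high-pass bands and \code{W0 = ||f^(L)||^2 /
#' |Omega|} for the final low-pass, with the norms restricted to ROI pixels.
#'
#' @param pyr a \code{haar_pyramid} computed on the image containing Omega.
#' @param roi a \code{roi_region} (or logical mask, or NULL for the whole
#'   image).
#' @return named numeric vector \code{W0, W_1_1, ..., W_3_3} (10 values for
#'   3 levels), all nonnegative.
#' @export
wavelet_energies <- function(pyr, roi = NULL) {
  stopifnot(inherits(pyr, "haar_pyramid"))
  mask <- if (is.null(roi)) {
    matrix(TRUE, nrow(pyr$f[[1]]), ncol(pyr$f[[1]]))
  } else if (is.matrix(roi)) roi else roi$mask
  n <- sum(mask)
  if (n < 1L) abort("empty ROI.")
  out <- c(W0 = sum(pyr$f[[pyr$levels + 1L]][mask]^2) / n)
  for (i in seq_len(pyr$levels)) for (j in 1:3) {
    out[sprintf("W_%d_%d", i, j)] <- sum(pyr$d[[i]][[j]][mask]^2) / n
  }
  out
}
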