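#' Quantize ROI intensities into Ng uniform gray levels
#'
#' Intensities inside Omega are binned into \code{ng} uniform levels
#' \code{0..ng-1}. By default the bins span the ROI's own \[min, max\]
#' (making all downstream GLCM features invariant to affine intensity
#' shifts); \code{range = "full"} uses the image's declared intensity range
#' instead. The ROI maximum maps to level \code{ng - 1}; a constant ROI maps
#' wholly to level 0.
#'
#' @param image a \code{\link{us_image}} (or numeric matrix).
#' @param roi a \code{roi_region} on the same grid.
#' @param ng number of gray levels (default 16).
#' @param range "roi" (min–max over Omega, default) or "full".
#' @return object of class \code{quantized_roi}: \code{levels} (integer
#'   matrix, NA outside Omega), \code{ng}, \code{bin_edges}.
#' @export
quantize <- function(image, roi, ng = 16, range = c("roi", "full")) {
  range <- match.arg(range)
  image <- as_us_image(image)
  px <- image$pixels
  stopifnot(identical(dim(px), dim(roi$mask)))
  if (roi$pixel_count < 1L) abort("empty ROI.")
  if (ng < 2) abort("ng must be >= 2.")
  vals <- px[roi$mask]
  lim <- if (range == "roi") c(min(vals), max(vals))
         else if (image$scale == "raw") c(0, 255) else c(0, 1)
  # co-occurrence pairs live entirely inside Omega, so the level raster can
  # be stored on the mask's bounding box without changing any GLCM
  rows <- range(which(rowSums(roi$mask) > 0))
  cols <- range(which(colSums(roi$mask) > 0))
  sub_mask <- roi$mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  sub_px <- px[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  levels <- matrix(NA_integer_, nrow(sub_mask), ncol(sub_mask))
  if (lim[2] <= lim[1]) {
    levels[sub_mask] <- 0L
  } else {
    lv <- floor((sub_px[sub_mask] - lim[1]) / (lim[2] - lim[1]) * ng)
    levels[sub_mask] <- as.integer(pmin(lv, ng - 1L))
  }
  structure(
    list(levels = levels, ng = as.integer(ng),
         bin_edges = seq(lim[1], lim[2], length.out = ng + 1)),
    class = "quantized_roi"
  )
}

# displacement unit vectors (row, col): 0 deg = up, 45 = up-right,
# 90 = right, 135 = down-right
theta_offset <- function(theta) {
  switch(as.character(theta),
    "0"   = c(-1L, 0L),
    "45"  = c(-1L, 1L),
    "90"  = c(0L, 1L),
    "135" = c(1L, 1L),
    abort(sprintf("unsupported direction theta = %s (use 0, 45, 90, 135).", theta))
  )
}

#' Gray-level co-occurrence matrix for one displacement and direction
#'
#' Counts pairs of ROI pixels \code{(i, i + d * u_theta)} whose quantized
#' levels are \code{(a, b)}; both pixels must lie in Omega. In directed mode
#' ordered pairs are counted as such; symmetric mode also counts each pair
#' reversed, making P equal to its transpose. P is normalized by the raw
#' pair count Z so its entries sum to 1.
#'
#' @param q a \code{quantized_roi} from \code{\link{quantize}}.
#' @param d displacement in pixels (1–5).
#' @param theta direction in degrees: 0 (up), 45, 90 (right), 135.
#' @param directed logical; FALSE gives the symmetric GLCM.
#' @return object of class \code{glcm_matrix}: \code{P} (ng x ng, rows = a),
#'   \code{d}, \code{theta}, \code{Z}, \code{directed}.
#' @export
compute_glcm <- function(q, d, theta, directed = TRUE) {
  stopifnot(inherits(q, "quantized_roi"))
  if (!d %in% 1:5) abort("d must be in 1..5.")
  off <- theta_offset(theta) * as.integer(d)
  L <- q$levels
  ng <- q$ng
  nr <- nrow(L); nc <- ncol(L)
  rs_lo <- max(1L, 1L - off[1]); rs_hi <- min(nr, nr - off[1])
  cs_lo <- max(1L, 1L - off[2]); cs_hi <- min(nc, nc - off[2])
  if (rs_lo > rs_hi || cs_lo > cs_hi) {
    abort(sprintf("no valid pixel pair in Omega for d=%d, theta=%d.", d, theta))
  }
  rs <- rs_lo:rs_hi
  cs <- cs_lo:cs_hi
  A <- L[rs, cs, drop = FALSE]
  B <- L[rs + off[1], cs + off[2], drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  counts <- tabulate(A[ok] * ng + B[ok] + 1L, nbins = ng * ng)
  cmat <- matrix(counts, ng, ng, byrow = TRUE)  # rows index a, cols index b
  if (!directed) cmat <- cmat + t(cmat)
  Z <- sum(cmat)
  if (Z == 0) abort(sprintf("no valid pixel pair in Omega for d=%d, theta=%d.", d, theta))
  structure(
    list(P = cmat / Z, d = as.integer(d), theta = as.integer(theta),
         Z = Z, directed = directed),
    class = "glcm_matrix"
  )
}

#' The seven Haralick measures of one GLCM
#'
#' Evaluates, on a normalized co-occurrence matrix P with levels
#' \code{a, b in 0..ng-1}:
#' \enumerate{
#'   \item inverse difference moment: sum over a != b of P(a,b) / (a-b)^2;
#'   \item correlation: cov(a, b) / (sigma_a sigma_b) under P (0, with a
#'     \code{zero_variance} flag, when either marginal SD is 0);
#'   \item contrast: sum (a-b)^2 P(a,b);
#'   \item maximum: max P(a,b);
#'   \item energy: sum P(a,b)^2;
#'   \item dissimilarity: sum |a-b| P(a,b);
#'   \item entropy: -sum P log P (natural log, 0 log 0 = 0).
#' }
#'
#' @param glcm a \code{glcm_matrix} (or a bare normalized matrix).
#' @return named numeric vector \code{a1..a7}; attribute
#'   \code{zero_variance} is TRUE when correlation was undefined.
#' @export
haralick_measures <- function(glcm) {
  P <- if (inherits(glcm, "glcm_matrix")) glcm$P else as.matrix(glcm)
  ng <- nrow(P)
  lv <- 0:(ng - 1)
  A <- matrix(lv, ng, ng)        # row level a
  B <- matrix(lv, ng, ng, byrow = TRUE)
  dif <- A - B
  offd <- dif != 0
  h1 <- sum(P[offd] / dif[offd]^2)
  pa <- rowSums(P); pb <- colSums(P)
  mu_a <- sum(lv * pa); mu_b <- sum(lv * pb)
  var_a <- sum((lv - mu_a)^2 * pa); var_b <- sum((lv - mu_b)^2 * pb)
  zero_var <- var_a <= 0 || var_b <= 0
  h2 <- if (zero_var) 0 else sum((A - mu_a) * (B - mu_b) * P) / sqrt(var_a * var_b)
  h3 <- sum(dif^2 * P)
  h4 <- max(P)
  h5 <- sum(P^2)
  h6 <- sum(abs(dif) * P)
  pos <- P > 0
  h7 <- -sum(P[pos] * log(P[pos]))
  out <- c(a1 = h1, a2 = h2, a3 = h3, a4 = h4, a5 = h5, a6 = h6, a7 = h7)
  attr(out, "zero_variance") <- zero_var
  out
}

#' All 140 Haralick features of a quantized ROI
#'
#' One GLCM per (d, theta) configuration — 5 displacements x 4 directions —
#' each summarized by the 7 measures, in canonical order (d outer, theta
#' middle, measure inner). Thin ROIs can have no valid pixel pair for a
#' large vertical displacement; such degenerate configurations are imputed
#' from the largest displacement available for the same direction, with a
#' warning naming them.
#'
#' @param q a \code{quantized_roi}.
#' @param d_set,theta_set displacement and direction grids.
#' @param directed GLCM mode, see \code{\link{compute_glcm}}.
#' @return named numeric vector of length \code{length(d_set) *
#'   length(theta_set) * 7} (140 for the defaults), names
#'   \code{H_d<d>_t<theta>_a<a>}.
#' @export
haralick_all <- function(q, d_set = 1:5, theta_set = c(0, 45, 90, 135),
                         directed = TRUE) {
  vals <- list()
  degen <- character()
  for (th in theta_set) {
    per_d <- vector("list", length(d_set))
    names(per_d) <- as.character(d_set)
    for (k in seq_along(d_set)) {
      g <- tryCatch(compute_glcm(q, d_set[k], th, directed = directed),
                    error = function(e) NULL)
      if (!is.null(g)) per_d[[k]] <- haralick_measures(g)
    }
    avail <- which(!vapply(per_d, is.null, logical(1)))
    if (!length(avail)) {
      abort(sprintf("ROI admits no pixel pair for any displacement at theta=%d.", th))
    }
    donor <- max(avail)
    for (k in seq_along(d_set)) {
      if (is.null(per_d[[k]])) {
        degen <- c(degen, sprintf("d=%d,theta=%d", d_set[k], th))
        per_d[[k]] <- per_d[[donor]]
      }
      vals[[sprintf("d%d_t%d", d_set[k], th)]] <- per_d[[k]]
    }
  }
  if (length(degen)) {
    warn(sprintf("degenerate GLCM configuration(s) imputed from largest available d: %s",
                 paste(degen, collapse = "; ")))
  }
  out <- numeric(0)
  for (d in d_set) for (th in theta_set) {
    v <- vals[[sprintf("d%d_t%d", d, th)]]
    names(v) <- sprintf("H_d%d_t%d_a%d", d, th, 1:7)
    out <- c(out, v)
  }
  out
}
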