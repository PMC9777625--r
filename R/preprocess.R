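#' Percentile-clipped intensity normalization
#'
#' Linearly maps the \code{p_low}/\code{p_high} intensity percentiles to 0/1
#' and clips to \[0, 1\]. Percentile clipping makes the map robust to a few
#' saturated pixels (caliper dots, bright adventitia specks). A constant
#' image maps to all zeros.
#'
#' @param image a \code{\link{us_image}} (raw or already normalized).
#' @param p_low,p_high percentiles in \[0, 100\], \code{p_low < p_high}.
#' @return a normalized \code{us_image} with intensities in \[0, 1\].
#' @export
normalize_intensity <- function(image, p_low = 1, p_high = 99) {
  image <- as_us_image(image)
  if (!(p_low < p_high) || p_low < 0 || p_high > 100) {
    abort("need 0 <= p_low < p_high <= 100.")
  }
  v <- image$pixels
  q <- quantile(v, c(p_low, p_high) / 100, names = FALSE)
  out <- if (q[2] <= q[1]) {
    array(0, dim(v))
  } else {
    pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  }
  dim(out) <- dim(v)
  us_image(out, image_id = image$image_id, patient_id = image$patient_id,
           side = image$side, angle = image$angle, scale = "normalized")
}

label_components <- function(mask) {
  # 4-connected component labelling by flood fill over the candidate set
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  cand <- which(mask)
  nextlab <- 0L
  for (s in cand) {
    if (labels[s] != 0L) next
    nextlab <- nextlab + 1L
    queue <- s
    labels[s] <- nextlab
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
      nb <- c(if (r > 1L) i - 1L, if (r < nr) i + 1L,
              if (c > 1L) i - nr, if (c < nc) i + nr)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- nextlab
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Detect and inpaint bright caliper-dot markers
#'
#' Near-saturated connected components no larger than \code{max_area} pixels
#' (the default 50 px covers a caliper dot of up to 4 px radius while
#' staying far below anatomical structures such as the adventitia band) are masked and replaced by harmonic infill: masked
#' pixels are iteratively set to the mean of their 4-neighbors, with
#' unmasked pixels held fixed, until convergence. All other pixels are
#' unchanged and zero detections is a valid outcome.
#'
#' @param image a \code{\link{us_image}}; thresholding is relative to the
#'   intensity scale, so raw and normalized images both work.
#' @param threshold detection threshold as a fraction of the full intensity
#'   range (default 0.98).
#' @param max_area maximum component area in pixels to treat as a marker.
#' @param tol convergence tolerance of the infill iteration, as a fraction
#'   of the intensity range.
#' @return list with \code{image} (inpainted) and \code{marker_mask}
#'   (logical matrix of detected marker pixels).
#' @export
detect_and_inpaint_markers <- function(image, threshold = 0.98, max_area = 50,
                                       tol = 1e-6) {
  image <- as_us_image(image)
  rng <- if (image$scale == "raw") 255 else 1
  px <- image$pixels
  cand <- px >= threshold * rng
  marker_mask <- matrix(FALSE, nrow(px), ncol(px))
  if (any(cand)) {
    labels <- label_components(cand)
    sizes <- tabulate(labels[labels > 0L])
    keep <- which(sizes <= max_area)
    if (length(keep)) marker_mask <- matrix(labels %in% keep, nrow(px), ncol(px))
  }
  if (any(marker_mask)) {
    px <- harmonic_infill(px, marker_mask, tol = tol * rng)
  }
  out <- us_image(px, image_id = image$image_id, patient_id = image$patient_id,
                  side = image$side, angle = image$angle, scale = image$scale)
  list(image = out, marker_mask = marker_mask)
}

harmonic_infill <- function(px, mask, tol, max_iter = 10000L) {
  nr <- nrow(px); nc <- ncol(px)
  idx <- which(mask)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  nbmat <- cbind(ifelse(r > 1L, idx - 1L, NA_integer_),
                 ifelse(r < nr, idx + 1L, NA_integer_),
                 ifelse(c > 1L, idx - nr, NA_integer_),
                 ifelse(c < nc, idx + nr, NA_integer_))
  nb_n <- rowSums(!is.na(nbmat))
  px[idx] <- mean(px[!mask])
  for (it in seq_len(max_iter)) {
    vals <- matrix(px[nbmat], nrow = length(idx))
    newv <- rowSums(vals, na.rm = TRUE) / nb_n
    delta <- max(abs(newv - px[idx]))
    px[idx] <- newv
    if (delta < tol) break
  }
  px
}
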