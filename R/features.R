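#' Texture extraction parameters
#'
#' Bundles every tunable of the 152-feature extraction: the gray-level count
#' \code{ng} (16 by default), the displacement and direction grids of the
#' GLCM block, directed vs symmetric co-occurrence counting, the
#' quantization range, the number of wavelet levels and the wavelet boundary
#' rule.
#'
#' @param ng gray levels for GLCM quantization (default 16).
#' @param d_set GLCM displacements in pixels (default 1:5).
#' @param theta_set GLCM directions in degrees (default 0, 45, 90, 135).
#' @param glcm_mode "directed" (ordered pairs, default) or "symmetric".
#' @param quant_range "roi" (min–max over Omega, default) or "full".
#' @param wavelet_levels decomposition depth (default 3).
#' @param wavelet_boundary "mirror" (default) or "periodic".
#' @return a list of class \code{texture_params}.
#' @export
texture_params <- function(ng = 16, d_set = 1:5, theta_set = c(0, 45, 90, 135),
                           glcm_mode = c("directed", "symmetric"),
                           quant_range = c("roi", "full"),
                           wavelet_levels = 3,
                           wavelet_boundary = c("mirror", "periodic")) {
  structure(
    list(ng = ng, d_set = d_set, theta_set = theta_set,
         glcm_mode = match.arg(glcm_mode), quant_range = match.arg(quant_range),
         wavelet_levels = wavelet_levels,
         wavelet_boundary = match.arg(wavelet_boundary)),
    class = "texture_params"
  )
}

#' Canonical feature names
#'
#' The fixed column order of every feature vector and feature table:
#' \code{mu}, \code{sigma}, the Haralick block sorted by (d, theta, a), then
#' \code{W0} and the wavelet block sorted by (i, j). Length 152 for the
#' default parameters.
#'
#' @param params a \code{\link{texture_params}}.
#' @return character vector of feature names.
#' @export
feature_names <- function(params = texture_params()) {
  # d outer, theta middle, a inner
  h <- unlist(lapply(params$d_set, function(d)
    lapply(params$theta_set, function(th) sprintf("H_d%d_t%d_a%d", d, th, 1:7))))
  w <- c("W0", as.vector(t(outer(seq_len(params$wavelet_levels), 1:3,
                                 function(i, j) sprintf("W_%d_%d", i, j)))))
  c("mu", "sigma", h, w)
}

#' First-order intensity statistics over the ROI
#'
#' Population mean and standard deviation (divisor |Omega|) of the image
#' intensities inside Omega.
#'
#' @param image a \code{\link{us_image}} or numeric matrix.
#' @param roi a \code{roi_region} on the same grid.
#' @return named numeric vector \code{c(mu, sigma)}.
#' @export
first_order_stats <- function(image, roi) {
  image <- as_us_image(image)
  stopifnot(identical(dim(image$pixels), dim(roi$mask)))
  if (roi$pixel_count < 1L) abort("empty ROI.")
  v <- image$pixels[roi$mask]
  mu <- mean(v)
  c(mu = mu, sigma = sqrt(mean((v - mu)^2)))
}

#' Extract the full texture feature vector of one image ROI
#'
#' Computes, inside Omega: the first-order mean and SD, the Haralick block
#' (one GLCM per displacement/direction configuration, 7 measures each) and
#' the Haar wavelet-frame energies — 152 values for the default parameters,
#' in canonical order.
#'
#' @param image a preprocessed \code{\link{us_image}} (any intensity scale;
#'   the GLCM block is scale-invariant under the default ROI-range
#'   quantization).
#' @param roi a \code{roi_region}.
#' @param params a \code{\link{texture_params}}.
#' @return named numeric vector in \code{\link{feature_names}} order.
#' @export
extract_feature_vector <- function(image, roi, params = texture_params()) {
  image <- as_us_image(image)
  fo <- first_order_stats(image, roi)
  q <- quantize(image, roi, ng = params$ng, range = params$quant_range)
  har <- haralick_all(q, d_set = params$d_set, theta_set = params$theta_set,
                      directed = params$glcm_mode == "directed")
  pyr <- haar_frame_decompose(image, levels = params$wavelet_levels,
                              boundary = params$wavelet_boundary)
  wav <- wavelet_energies(pyr, roi)
  out <- c(fo, har, wav)
  stopifnot(identical(names(out), feature_names(params)), all(is.finite(out)))
  out
}

#' Per-image feature table for a whole cohort
#'
#' Runs preprocessing (percentile normalization and caliper-dot inpainting,
#' both optional) and feature extraction on every image of a cohort,
#' returning one row per image: \code{image_id}, \code{patient_id},
#' \code{group_label}, then the feature columns in canonical order.
#'
#' @param cohort a \code{carotid_cohort} (see \code{\link{generate_cohort}}
#'   / \code{\link{read_cohort}}).
#' @param params a \code{\link{texture_params}}.
#' @param normalize,inpaint logical; apply \code{\link{normalize_intensity}}
#'   (p 1/99) and \code{\link{detect_and_inpaint_markers}} before
#'   extraction.
#' @return a tibble with \code{2 + nfeatures + 1} metadata/feature columns.
#' @export
feature_table <- function(cohort, params = texture_params(),
                          normalize = TRUE, inpaint = TRUE) {
  imgs <- cohort$images
  missing_roi <- vapply(imgs$roi, is.null, logical(1))
  if (any(missing_roi)) {
    abort(paste0("missing ROI for image(s): ",
                 paste(imgs$image_id[missing_roi], collapse = ", ")))
  }
  if (nrow(imgs) == 0L) {
    cols <- c("image_id", "patient_id", "group_label", feature_names(params))
    return(as_tibble(setNames(rep(list(character(0)), 3), cols[1:3])) |>
             bind_cols(as_tibble(setNames(rep(list(numeric(0)),
                                              length(cols) - 3), cols[-(1:3)]))))
  }
  rows <- purrr::pmap(list(imgs$image, imgs$roi, imgs$image_id), function(im, roi, id) {
    im <- as_us_image(im)
    if (normalize) im <- normalize_intensity(im)
    if (inpaint) im <- detect_and_inpaint_markers(im)$image
    extract_feature_vector(im, roi, params)
  })
  feat <- as_tibble(do.call(rbind, rows))
  bind_cols(
    tibble(image_id = imgs$image_id, patient_id = imgs$patient_id,
           group_label = imgs$group_label),
    feat
  )
}

#' Write / read a feature table as CSV
#'
#' Full-precision (round-trip lossless) CSV with the canonical column
#' order.
#'
#' @param table a feature table tibble.
#' @param path CSV path.
#' @return \code{write_feature_table}: the path, invisibly;
#'   \code{read_feature_table}: the tibble.
#' @export
write_feature_table <- function(table, path) {
  out <- table |>
    mutate(across(where(is.numeric), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  # base read.csv: correctly-rounded double parsing, so %.17g CSVs
  # round-trip bit-exactly
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(image_id = "character",
                                       patient_id = "character",
                                       group_label = "character"))
  as_tibble(df)
}
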