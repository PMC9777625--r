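#' Ultrasound image container
#'
#' A light S3 wrapper around a 2-D numeric intensity matrix with acquisition
#' metadata. Pixel values are either raw 8-bit intensities (0–255, as read
#' from PNG) or normalized to \[0, 1\] (after
#' \code{\link{normalize_intensity}}); the \code{scale} field records which.
#'
#' Coordinate convention, used everywhere in the package: 0-based
#' \code{(row, col)} with pixel centers at integer coordinates; row 0 is the
#' top image row. Polygons are ordered vertex lists in the same coordinates,
#' implicitly closed.
#'
#' @param pixels numeric matrix of intensities (rows x cols).
#' @param image_id,patient_id identifiers (character scalars or NA).
#' @param side,angle optional acquisition metadata.
#' @param scale "raw" (0–255) or "normalized" (0–1).
#' @return an object of class \code{us_image}.
#' @export
us_image <- function(pixels, image_id = NA_character_, patient_id = NA_character_,
                     side = NA_character_, angle = NA_real_,
                     scale = c("raw", "normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    abort("`pixels` must be a non-empty numeric matrix.")
  }
  if (any(!is.finite(pixels))) abort("image intensities must be finite.")
  lim <- if (scale == "raw") c(0, 255) else c(0, 1)
  if (min(pixels) < lim[1] - 1e-9 || max(pixels) > lim[2] + 1e-9) {
    abort(sprintf("intensities outside the declared %s range [%g, %g].",
                  scale, lim[1], lim[2]))
  }
  structure(
    list(pixels = pixels, image_id = image_id, patient_id = patient_id,
         side = side, angle = angle, scale = scale),
    class = "us_image"
  )
}

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf("<us_image> %s  %d x %d px  scale=%s  patient=%s\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), x$scale, x$patient_id))
  invisible(x)
}

#' @export
dim.us_image <- function(x) dim(x$pixels)

as_us_image <- function(x, ...) {
  if (inherits(x, "us_image")) x else us_image(x, ...)
}

#' Read a grayscale ultrasound image from PNG
#'
#' Reads an 8-bit grayscale PNG, preserving pixel values exactly (returned on
#' the raw 0–255 scale). Multichannel images are rejected: B-mode frames are
#' single-channel and a silent channel collapse could hide a data problem.
#'
#' @param path path to an 8-bit grayscale PNG file.
#' @param image_id,patient_id optional identifiers; default to the file stem.
#' @param side,angle optional acquisition metadata.
#' @return a \code{\link{us_image}} with raw 0–255 intensities.
#' @export
read_image <- function(path, image_id = NULL, patient_id = NA_character_,
                       side = NA_character_, angle = NA_real_) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  px <- tryCatch(png::readPNG(path), error = function(e) {
    abort(sprintf("cannot read %s as PNG: %s", path, conditionMessage(e)))
  })
  if (length(dim(px)) == 3L) {
    abort(sprintf("%s has %d channels; expected single-channel grayscale.",
                  path, dim(px)[3]))
  }
  # readPNG returns k/255 for 8-bit data; recover the integer code exactly
  us_image(round(px * 255), image_id = image_id %||% sub("\\.png$", "", basename(path)),
           patient_id = patient_id, side = side, angle = angle, scale = "raw")
}

#' Write an ultrasound image as 8-bit grayscale PNG
#'
#' Raw-scale images are written as-is (rounded to the nearest 8-bit code);
#' normalized images are mapped back to 0–255.
#'
#' @param image a \code{\link{us_image}}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- image$pixels
  if (image$scale == "normalized") px <- px * 255
  png::writePNG(round(px) / 255, target = path)
  invisible(path)
}
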