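#' Region-of-interest container
#'
#' Holds a polygon (ordered \code{(row, col)} vertices, 0-based pixel-center
#' coordinates, implicitly closed), its boolean rasterization on the image
#' grid, and the pixel count |Omega|. Build one with
#' \code{\link{rasterize_roi}}.
#'
#' @name roi_region
NULL

new_roi_region <- function(polygon, mask) {
  structure(
    list(polygon = polygon, mask = mask, pixel_count = sum(mask)),
    class = "roi_region"
  )
}

#' @export
print.roi_region <- function(x, ...) {
  cat(sprintf("<roi_region> %d vertices, |Omega| = %d on a %d x %d grid\n",
              nrow(x$polygon), x$pixel_count, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

as_polygon_matrix <- function(polygon) {
  if (is.list(polygon) && !is.data.frame(polygon)) {
    polygon <- do.call(rbind, lapply(polygon, as.numeric))
  }
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  if (ncol(polygon) != 2L) abort("polygon must have two columns: (row, col).")
  polygon
}

# Even-odd (crossing-number) point-in-polygon over an entire pixel grid,
# boundary-inclusive: a pixel center lying exactly on a polygon edge is
# inside. Vectorized over pixels, looped over edges.
polygon_grid_mask <- function(polygon, image_shape, eps = 1e-9) {
  nr <- image_shape[1]; nc <- image_shape[2]
  yy <- rep(0:(nr - 1L), times = nc)   # row coordinate of every pixel center
  xx <- rep(0:(nc - 1L), each = nr)    # col coordinate
  n <- nrow(polygon)
  y1 <- polygon[, 1]; x1 <- polygon[, 2]
  y2 <- polygon[c(2:n, 1L), 1]; x2 <- polygon[c(2:n, 1L), 2]
  crossings <- integer(nr * nc)
  on_edge <- logical(nr * nc)
  for (e in seq_len(n)) {
    ay <- y1[e]; ax <- x1[e]; by <- y2[e]; bx <- x2[e]
    # boundary test: zero cross product and within the edge's bounding box
    cross <- (bx - ax) * (yy - ay) - (by - ay) * (xx - ax)
    seg_len2 <- (bx - ax)^2 + (by - ay)^2
    if (seg_len2 > 0) {
      hit <- abs(cross) <= eps * sqrt(seg_len2) &
        yy >= pmin(ay, by) - eps & yy <= pmax(ay, by) + eps &
        xx >= pmin(ax, bx) - eps & xx <= pmax(ax, bx) + eps
      on_edge <- on_edge | hit
    }
    if (ay == by) next  # horizontal edge: no ray crossings
    inrange <- if (ay < by) (yy >= ay & yy < by) else (yy >= by & yy < ay)
    xint <- ax + (yy - ay) * (bx - ax) / (by - ay)
    crossings <- crossings + as.integer(inrange & xint > xx)
  }
  matrix(crossings %% 2L == 1L | on_edge, nr, nc)
}

#' Rasterize an ROI polygon into a pixel mask
#'
#' A pixel belongs to Omega when its center falls inside the closed polygon
#' under the even-odd rule; centers lying exactly on an edge are included
#' (boundary-inclusive convention). Coordinates are 0-based \code{(row, col)}
#' with pixel centers at integer positions.
#'
#' @param polygon n x 2 matrix (or list of \code{c(row, col)} pairs) of
#'   vertices, at least 3, all within the image bounds; implicitly closed.
#' @param image_shape integer vector \code{c(rows, cols)}.
#' @return a \code{roi_region} (polygon, mask, pixel_count).
#' @examples
#' r <- rasterize_roi(rbind(c(0, 0), c(0, 9), c(4, 9), c(4, 0)), c(10, 12))
#' r$pixel_count  # 50
#' @export
rasterize_roi <- function(polygon, image_shape) {
  polygon <- as_polygon_matrix(polygon)
  if (nrow(polygon) < 3L) abort("polygon needs at least 3 vertices.")
  nr <- image_shape[1]; nc <- image_shape[2]
  if (any(polygon[, 1] < 0 | polygon[, 1] > nr - 1 |
          polygon[, 2] < 0 | polygon[, 2] > nc - 1)) {
    abort("polygon vertices fall outside the image bounds.")
  }
  n <- nrow(polygon)
  area2 <- sum(polygon[, 2] * polygon[c(2:n, 1L), 1] -
               polygon[c(2:n, 1L), 2] * polygon[, 1])
  if (abs(area2) < 1e-12) abort("degenerate (zero-area) polygon.")
  mask <- polygon_grid_mask(polygon, c(nr, nc))
  if (!any(mask)) abort("polygon rasterizes to an empty pixel set.")
  new_roi_region(polygon, mask)
}

#' Crop an image and ROI to the ROI bounding box plus a margin
#'
#' The margin keeps border effects of the wavelet filter bank away from
#' Omega: three undecimated Haar levels reach 2 + 4 + 8 = 14 px, and the
#' default of 56 px is comfortably larger. The crop is clamped at the image
#' borders; Omega membership and |Omega| are preserved, and the polygon is
#' translated into the cropped frame.
#'
#' @param image a \code{\link{us_image}}.
#' @param roi a \code{roi_region} on the same grid.
#' @param margin_px margin in pixels around the ROI bounding box.
#' @return list with elements \code{image} and \code{roi}, plus
#'   \code{offset} = the 0-based \code{(row, col)} of the crop origin in the
#'   original image.
#' @export
crop_to_roi <- function(image, roi, margin_px = 56) {
  image <- as_us_image(image)
  stopifnot(identical(dim(image$pixels), dim(roi$mask)))
  rows <- which(rowSums(roi$mask) > 0)
  cols <- which(colSums(roi$mask) > 0)
  nr <- nrow(roi$mask); nc <- ncol(roi$mask)
  r0 <- as.integer(max(1, min(rows) - margin_px))
  r1 <- as.integer(min(nr, max(rows) + margin_px))
  c0 <- as.integer(max(1, min(cols) - margin_px))
  c1 <- as.integer(min(nc, max(cols) + margin_px))
  px <- image$pixels[r0:r1, c0:c1, drop = FALSE]
  mask <- roi$mask[r0:r1, c0:c1, drop = FALSE]
  poly <- roi$polygon
  poly[, 1] <- poly[, 1] - (r0 - 1L)
  poly[, 2] <- poly[, 2] - (c0 - 1L)
  out_img <- us_image(px, image_id = image$image_id, patient_id = image$patient_id,
                      side = image$side, angle = image$angle, scale = image$scale)
  list(image = out_img, roi = new_roi_region(poly, mask),
       offset = c(r0 - 1L, c0 - 1L))
}
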