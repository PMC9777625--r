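# Small deterministic fixtures and independent oracles used across tests.

tiny_cohort <- function(seed = 7, n = c(PA = 3, EH = 3, C = 3), images = 1,
                        size = c(72, 144), ppm = 8, markers = 0,
                        texture = default_texture_params()) {
  generate_cohort(synthetic_config(
    n_patients = n, images_per_patient = images, image_size = size,
    pixels_per_mm = ppm, roi_length_mm = 12, marker_count = markers,
    texture_params = texture, seed = seed
  ))
}

# Independent point-in-polygon oracle: per-pixel crossing count casting the
# ray upward (the implementation casts rightward), plus an on-segment test.
pip_oracle <- function(poly, shape) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  inside_pt <- function(y, x) {
    cross <- 0L
    for (e in 1:n) {
      ay <- poly[e, 1]; ax <- poly[e, 2]
      by <- poly[nxt[e], 1]; bx <- poly[nxt[e], 2]
      # on-segment?
      d <- (bx - ax) * (y - ay) - (by - ay) * (x - ax)
      if (abs(d) < 1e-9 &&
          x >= min(ax, bx) - 1e-9 && x <= max(ax, bx) + 1e-9 &&
          y >= min(ay, by) - 1e-9 && y <= max(ay, by) + 1e-9) return(TRUE)
      if (ax == bx) next
      inr <- if (ax < bx) (x >= ax && x < bx) else (x >= bx && x < ax)
      if (inr) {
        yint <- ay + (x - ax) * (by - ay) / (bx - ax)
        if (yint > y) cross <- cross + 1L  # ray cast downward in row coords
      }
    }
    cross %% 2L == 1L
  }
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in 0:(shape[1] - 1)) for (c in 0:(shape[2] - 1)) {
    m[r + 1, c + 1] <- inside_pt(r, c)
  }
  m
}

# Exhaustive GLCM oracle: loop over every Omega pixel and count its partner.
glcm_oracle <- function(levels, ng, d, theta, directed = TRUE) {
  off <- switch(as.character(theta),
                "0" = c(-1, 0), "45" = c(-1, 1), "90" = c(0, 1), "135" = c(1, 1)) * d
  nr <- nrow(levels); nc <- ncol(levels)
  counts <- matrix(0, ng, ng)
  for (r in 1:nr) for (c in 1:nc) {
    a <- levels[r, c]
    if (is.na(a)) next
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    b <- levels[r2, c2]
    if (is.na(b)) next
    counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
  }
  if (!directed) counts <- counts + t(counts)
  z <- sum(counts)
  list(P = if (z > 0) counts / z else counts, Z = z)
}

# a quantized_roi built directly from a level matrix (NA outside Omega)
make_q <- function(levels, ng) {
  structure(list(levels = levels, ng = as.integer(ng),
                 bin_edges = seq(0, 1, length.out = ng + 1)),
            class = "quantized_roi")
}

rect_roi <- function(r0, c0, r1, c1, shape) {
  rasterize_roi(rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0)), shape)
}

# Closed-form Welch t-test (statistic, Satterthwaite df, two-sided p)
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}
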