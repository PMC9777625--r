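test_that("quantization spans the ROI range and handles degenerate ROIs", {
  shape <- c(20, 20)
  roi <- rect_roi(2, 2, 9, 9, shape)
  # values linearly spanning [0, 1] inside Omega: all 16 levels occupied
  px <- matrix(0, shape[1], shape[2])
  px[roi$mask] <- seq(0, 1, length.out = roi$pixel_count)
  q <- quantize(us_image(px, scale = "normalized"), roi, ng = 16)
  expect_setequal(unique(q$levels[!is.na(q$levels)]), 0:15)
  expect_equal(max(q$levels, na.rm = TRUE), 15)  # max maps to ng - 1

  const <- quantize(us_image(matrix(0.4, 20, 20), scale = "normalized"), roi)
  expect_true(all(const$levels[!is.na(const$levels)] == 0))

  expect_error(quantize(us_image(px, scale = "normalized"), roi, ng = 1), "ng")
})

test_that("GLCM matches hand-enumerated pair counts and normalizes to 1", {
  lev <- matrix(NA_integer_, 1, 4)
  lev[1, ] <- c(0L, 1L, 0L, 1L)
  q <- make_q(lev, 2)
  g <- compute_glcm(q, 1, 90, directed = TRUE)  # pairs: (0,1), (1,0), (0,1)
  expect_equal(g$P[1, 2], 2 / 3)
  expect_equal(g$P[2, 1], 1 / 3)
  expect_equal(g$Z, 3)
  expect_equal(sum(g$P), 1)

  const_lev <- matrix(0L, 4, 4)
  gc <- compute_glcm(make_q(const_lev, 16), 1, 90)
  expect_equal(gc$P[1, 1], 1)
  expect_equal(sum(gc$P), 1)

  # symmetric mode: P equals its transpose
  set.seed(3)
  lev2 <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  gs <- compute_glcm(make_q(lev2, 4), 2, 45, directed = FALSE)
  expect_identical(gs$P, t(gs$P))

  expect_error(compute_glcm(make_q(lev, 2), 1, 0), "no valid pixel pair")
})

test_that("GLCM equals exhaustive pair enumeration on random masked rasters", {
  set.seed(21)
  for (rep in 1:30) {
    nr <- sample(6:20, 1); nc <- sample(6:20, 1)
    lev <- matrix(sample(0:7, nr * nc, replace = TRUE), nr, nc)
    lev[matrix(runif(nr * nc) < 0.3, nr, nc)] <- NA  # ragged Omega
    q <- make_q(lev, 8)
    for (d in sample(1:5, 2)) for (th in c(0, 45, 90, 135)) {
      oracle <- glcm_oracle(lev, 8, d, th)
      got <- tryCatch(compute_glcm(q, d, th), error = function(e) NULL)
      if (oracle$Z == 0) {
        expect_null(got)
      } else {
        expect_equal(got$P, oracle$P, tolerance = 1e-14)
        expect_equal(got$Z, oracle$Z)
        expect_lt(abs(sum(got$P) - 1), 1e-12)
      }
    }
  }
})

test_that("Haralick measures match closed forms on degenerate matrices", {
  # constant ROI: all mass at (0, 0)
  Pc <- matrix(0, 16, 16); Pc[1, 1] <- 1
  hc <- haralick_measures(Pc)
  expect_equal(unname(hc[c("a1", "a3", "a6", "a7")]), c(0, 0, 0, 0))
  expect_equal(unname(hc[c("a4", "a5")]), c(1, 1))
  expect_equal(unname(hc[["a2"]]), 0)  # flagged zero-variance correlation
  expect_true(attr(hc, "zero_variance"))

  # two-entry matrix: mass 1/2 at (0,1) and (1,0)
  P2 <- matrix(0, 16, 16); P2[1, 2] <- 0.5; P2[2, 1] <- 0.5
  h2 <- haralick_measures(P2)
  expect_equal(unname(h2[["a1"]]), 1)    # inverse difference moment
  expect_equal(unname(h2[["a2"]]), -1)   # perfect anti-correlation
  expect_equal(unname(h2[["a3"]]), 1)    # contrast
  expect_equal(unname(h2[["a5"]]), 0.5)  # energy
  expect_equal(unname(h2[["a6"]]), 1)    # dissimilarity
  expect_equal(unname(h2[["a7"]]), log(2))
})

test_that("Haralick bounds hold on random normalized matrices", {
  set.seed(8)
  for (i in 1:50) {
    P <- matrix(rexp(64), 8, 8); P <- P / sum(P)
    h <- haralick_measures(P)
    expect_gt(h[["a4"]], 0); expect_lte(h[["a4"]], 1)
    expect_gt(h[["a5"]], 0); expect_lte(h[["a5"]], 1)
    expect_gte(h[["a1"]], 0); expect_gte(h[["a3"]], 0)
    expect_gte(h[["a6"]], 0); expect_gte(h[["a7"]], 0)
    expect_lte(abs(h[["a2"]]), 1 + 1e-9)
  }
})

test_that("haralick_all is the per-configuration composition, with imputation", {
  set.seed(4)
  lev <- matrix(sample(0:15, 16 * 16, replace = TRUE), 16, 16)
  q <- make_q(lev, 16)
  all140 <- haralick_all(q)
  expect_length(all140, 140)
  expect_true(all(is.finite(all140)))
  for (pick in list(c(1, 0), c(3, 90), c(5, 135))) {
    g <- compute_glcm(q, pick[1], pick[2])
    expect_equal(
      unname(all140[sprintf("H_d%d_t%d_a%d", pick[1], pick[2], 1:7)]),
      unname(haralick_measures(g)),
      ignore_attr = TRUE
    )
  }

  # 5-row strip: vertical pairs at d = 5 are impossible -> imputed from d = 4
  strip <- rect_roi(2, 2, 6, 40, c(30, 60))
  px <- matrix(runif(1800), 30, 60)
  qs <- quantize(us_image(px, scale = "normalized"), strip)
  expect_warning(hs <- haralick_all(qs), "imputed")
  expect_equal(unname(hs[sprintf("H_d5_t0_a%d", 1:7)]),
               unname(hs[sprintf("H_d4_t0_a%d", 1:7)]))

  # one-row strip: no vertical pair at any displacement
  q1 <- make_q(matrix(sample(0:7, 40, replace = TRUE), 1, 40), 8)
  expect_error(haralick_all(q1), "no pixel pair")
})

test_that("symmetric-mode features are equivariant under 90-degree rotation", {
  set.seed(19)
  lev <- matrix(sample(0:7, 256, replace = TRUE), 16, 16)
  lev[matrix(runif(256) < 0.2, 16, 16)] <- NA
  rot <- t(lev)[ncol(lev):1, ]  # counter-clockwise quarter turn
  f0 <- haralick_all(make_q(lev, 8), directed = FALSE)
  f1 <- haralick_all(make_q(rot, 8), directed = FALSE)
  # direction map under CCW rotation (symmetric counting): 0<->90, 45<->135
  swap <- c("0" = 90, "45" = 135, "90" = 0, "135" = 45)
  for (d in 1:5) for (th in c(0, 45, 90, 135)) {
    expect_equal(
      unname(f1[sprintf("H_d%d_t%d_a%d", d, swap[[as.character(th)]], 1:7)]),
      unname(f0[sprintf("H_d%d_t%d_a%d", d, th, 1:7)]),
      tolerance = 1e-12,
      label = sprintf("d=%d theta=%d", d, th)
    )
  }
})
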