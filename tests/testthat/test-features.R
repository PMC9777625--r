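test_that("first-order statistics use the population divisor", {
  shape <- c(16, 16)
  roi <- rect_roi(2, 2, 5, 5, shape)  # 16 pixels
  const <- matrix(0.3, 16, 16)
  expect_equal(first_order_stats(us_image(const, scale = "normalized"), roi),
               c(mu = 0.3, sigma = 0))

  # half zeros, half ones in Omega: mu = sigma = 1/2 with divisor |Omega|
  px <- matrix(0, 16, 16)
  px[roi$mask] <- rep(c(0, 1), 8)
  expect_equal(first_order_stats(us_image(px, scale = "normalized"), roi),
               c(mu = 0.5, sigma = 0.5))

  single <- rasterize_roi(rbind(c(3, 3), c(3, 3.4), c(3.4, 3.4)), shape)
  expect_equal(single$pixel_count, 1)
  px2 <- matrix(0.8, 16, 16)
  expect_equal(first_order_stats(us_image(px2, scale = "normalized"), single),
               c(mu = 0.8, sigma = 0))
})

test_that("the feature vector has the canonical 152-name layout and is deterministic", {
  nm <- feature_names()
  expect_length(nm, 152)
  expect_equal(nm[1:2], c("mu", "sigma"))
  expect_equal(sum(grepl("^H_", nm)), 140)
  expect_equal(sum(grepl("^W", nm)), 10)
  expect_equal(nm[3:9], sprintf("H_d1_t0_a%d", 1:7))
  expect_equal(tail(nm, 10), c("W0", sprintf("W_%d_%d", rep(1:3, each = 3), 1:3)))

  coh <- tiny_cohort(seed = 3, n = c(PA = 1, EH = 0, C = 0))
  img <- normalize_intensity(coh$images$image[[1]])
  roi <- coh$images$roi[[1]]
  fv <- extract_feature_vector(img, roi)
  expect_identical(names(fv), nm)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_feature_vector(img, roi))

  # changing ng changes values, never the inventory
  fv8 <- extract_feature_vector(img, roi, texture_params(ng = 8))
  expect_length(fv8, 152)
  expect_false(identical(fv, fv8))
})

test_that("Haralick features are invariant to intensity shifts of the image", {
  coh <- tiny_cohort(seed = 23, n = c(PA = 0, EH = 1, C = 0))
  img <- normalize_intensity(coh$images$image[[1]])
  roi <- coh$images$roi[[1]]
  # keep the shifted image inside the declared range via a plain matrix
  fv1 <- extract_feature_vector(us_image(img$pixels * 200, scale = "raw"), roi)
  fv2 <- extract_feature_vector(us_image(img$pixels * 200 + 30, scale = "raw"), roi)
  h <- grepl("^H_", names(fv1))
  expect_equal(fv1[h], fv2[h], tolerance = 1e-12)
  expect_equal(fv2[["mu"]] - fv1[["mu"]], 30, tolerance = 1e-9)
})

test_that("feature tables have one row per image and round-trip through CSV", {
  coh <- tiny_cohort(seed = 17, n = c(PA = 2, EH = 2, C = 2), images = 2)
  ft <- feature_table(coh)
  expect_equal(dim(ft), c(12, 155))
  expect_identical(names(ft)[1:3], c("image_id", "patient_id", "group_label"))
  expect_identical(names(ft)[-(1:3)], feature_names())

  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-15)

  # empty cohort: header-only table
  empty <- coh
  empty$images <- coh$images[0, ]
  ft0 <- feature_table(empty)
  expect_equal(nrow(ft0), 0)
  expect_equal(ncol(ft0), 155)

  # a missing ROI is reported by image id
  broken <- coh
  broken$images$roi[3] <- list(NULL)
  expect_error(feature_table(broken), broken$images$image_id[3], fixed = TRUE)
})

test_that("all features are invariant to whole-pixel translations", {
  set.seed(29)
  nr <- 96; nc <- 160
  px <- matrix(runif(nr * nc), nr, nc)
  roi <- rect_roi(40, 30, 60, 120, c(nr, nc))  # ample margin on every side
  fv0 <- extract_feature_vector(us_image(px, scale = "normalized"), roi)

  # translate image content and polygon together by (+3, +5)
  shifted <- matrix(0.5, nr, nc)
  shifted[4:nr, 6:nc] <- px[1:(nr - 3), 1:(nc - 5)]
  poly <- roi$polygon
  poly[, 1] <- poly[, 1] + 3; poly[, 2] <- poly[, 2] + 5
  roi_sh <- rasterize_roi(poly, c(nr, nc))
  fv1 <- extract_feature_vector(us_image(shifted, scale = "normalized"), roi_sh)
  expect_equal(fv1, fv0, tolerance = 1e-12)
})
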