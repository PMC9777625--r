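test_that("cohort generation is deterministic and honors configured sizes", {
  cfg <- synthetic_config(n_patients = c(PA = 2, EH = 3, C = 2),
                          images_per_patient = 2, image_size = c(72, 144),
                          pixels_per_mm = 8, marker_count = 2, seed = 31)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$clinical), 7)
  expect_equal(nrow(coh$images), 14)
  expect_equal(unname(table(coh$clinical$group_label)[c("PA", "EH", "C")]),
               c(2, 3, 2), ignore_attr = TRUE)

  coh2 <- generate_cohort(cfg)
  expect_identical(
    lapply(coh$images$image, function(i) i$pixels),
    lapply(coh2$images$image, function(i) i$pixels)
  )
  expect_identical(coh$clinical, coh2$clinical)
  expect_identical(lapply(coh$images$roi, function(r) r$polygon),
                   lapply(coh2$images$roi, function(r) r$polygon))

  minimal <- generate_cohort(synthetic_config(
    n_patients = c(PA = 1, EH = 1, C = 0), images_per_patient = 1,
    image_size = c(72, 144), pixels_per_mm = 8, seed = 1))
  expect_equal(nrow(minimal$clinical), 2)
  expect_equal(nrow(minimal$images), 2)

  expect_error(synthetic_config(n_patients = c(PA = -1, EH = 1, C = 1)),
               "group sizes")
})

test_that("generated ROIs sit inside the image, are thick and long enough", {
  coh <- tiny_cohort(seed = 5, n = c(PA = 2, EH = 2, C = 2), ppm = 10,
                     size = c(96, 160))
  for (roi in coh$images$roi) {
    expect_gte(min(roi$polygon), 0)
    expect_lt(max(roi$polygon[, 1]), 96)
    expect_lt(max(roi$polygon[, 2]), 160)
    thickness <- max(roi$polygon[, 1]) - min(roi$polygon[, 1]) + 1
    len <- max(roi$polygon[, 2]) - min(roi$polygon[, 2]) + 1
    expect_gte(thickness, 6)
    expect_gte(len, 10 * 10)  # >= 10 mm at 10 px/mm
    expect_equal(roi$pixel_count, thickness * len)
  }
})

test_that("noiseless wall image is constant along rows inside the ROI", {
  p <- group_texture_params("C", mean_level = 120, speckle_contrast = 0,
                            correlation_length_px = 2)
  sw <- synth_wall_image(p, size = c(96, 160), pixels_per_mm = 8, seed = 3)
  px <- sw$image$pixels
  rows <- which(rowSums(sw$roi$mask) > 0)
  for (r in rows) {
    vals <- px[r, sw$roi$mask[r, ]]
    expect_equal(length(unique(vals)), 1)
  }
  expect_equal(unique(px[sw$roi$mask]), 120)
})

test_that("shorter speckle correlation raises GLCM contrast at d = 1", {
  p_short <- group_texture_params("PA", 140, 0.4, correlation_length_px = 1)
  p_long  <- group_texture_params("EH", 140, 0.4, correlation_length_px = 4)
  contrast_of <- function(p, seed) {
    sw <- synth_wall_image(p, size = c(96, 160), pixels_per_mm = 8, seed = seed)
    q <- quantize(normalize_intensity(sw$image), sw$roi)
    mean(vapply(c(0, 45, 90, 135),
                function(th) haralick_measures(compute_glcm(q, 1, th))[["a3"]],
                numeric(1)))
  }
  short_vals <- vapply(1:20, function(s) contrast_of(p_short, s), numeric(1))
  long_vals <- vapply(1:20, function(s) contrast_of(p_long, 100 + s), numeric(1))
  expect_gt(mean(short_vals), mean(long_vals))
})

test_that("planted markers are saturated, counted and disjoint", {
  p <- default_texture_params()$C
  sw <- synth_wall_image(p, size = c(96, 160), pixels_per_mm = 8, seed = 9)
  pm0 <- plant_markers(sw$image, 0, seed = 1)
  expect_identical(pm0$image$pixels, sw$image$pixels)
  expect_false(any(pm0$marker_mask))

  pm5 <- plant_markers(sw$image, 5, seed = 1)
  comp <- carotexture:::label_components(pm5$marker_mask)
  expect_equal(max(comp), 5)
  expect_true(all(pm5$image$pixels[pm5$marker_mask] == 255))
})

test_that("clinical records follow the configured group distributions", {
  # controls: humoral aldosterone block unavailable
  rec_c <- generate_clinical("C", seed = 2)
  expect_true(is.na(rec_c$aldosterone))
  expect_true(is.na(rec_c$renin))
  expect_true(is.na(rec_c$arr))
  rec_pa <- generate_clinical("PA", seed = 2)
  expect_false(is.na(rec_pa$aldosterone))
  expect_error(generate_clinical("XX"), "unknown group")

  # zero-spread params reproduce the configured locations exactly
  params <- default_clinical_params()
  params$pa_s[params$dist == "normal"] <- 0
  params$pa_s[params$dist == "lognormal"] <- 0
  params$pa_m[params$dist == "binary"] <- 1
  rec <- generate_clinical("PA", params, seed = 4)
  expect_equal(rec$cca_imt, 0.987)
  expect_equal(rec$age, 57)
  expect_equal(rec$sex, 1)
  expect_equal(rec$aldosterone, exp(params$pa_m[params$covariate == "aldosterone"]))

  # Monte-Carlo location check of the Gaussian sampler
  set.seed(11)
  draws <- replicate(10000, generate_clinical("PA")$cca_imt)
  expect_lt(abs(mean(draws) - 0.987), 0.01)
})
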