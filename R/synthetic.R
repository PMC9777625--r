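#' Per-group texture parameters of the synthetic wall generator
#'
#' Describes the speckle process planted for one study group: the mean
#' intensity of the intima-media strip, the multiplicative speckle contrast
#' (SD/mean of the log-normal speckle field), the isotropic correlation
#' length of the speckle, and the range of wall (ROI strip) thicknesses.
#'
#' @param group_label "PA", "EH" or "C".
#' @param mean_level mean strip intensity on the 0–255 scale.
#' @param speckle_contrast SD/mean of the multiplicative speckle, > 0
#'   (0 gives a noiseless layered image).
#' @param correlation_length_px Gaussian smoothing scale of the speckle
#'   field in pixels, > 0.
#' @param wall_thickness_px integer range \code{c(min, max)} of strip
#'   thickness in pixels; the minimum must be at least 6 (the thinnest
#'   walls seen in practice are 6–8 px).
#' @param patient_jitter named numeric vector of log-normal SDs
#'   (\code{mean_level}, \code{speckle_contrast},
#'   \code{correlation_length}): each patient's texture parameters are the
#'   group values times independent log-normal factors, modelling
#'   between-patient heterogeneity. Set to zeros for a homogeneous group.
#' @return a list of class \code{group_texture_params}.
#' @export
group_texture_params <- function(group_label, mean_level,
                                 speckle_contrast, correlation_length_px,
                                 wall_thickness_px = c(8L, 14L),
                                 patient_jitter = c(mean_level = 0.05,
                                                    speckle_contrast = 0.10,
                                                    correlation_length = 0.10)) {
  if (!group_label %in% c("PA", "EH", "C")) abort("group_label must be PA, EH or C.")
  if (speckle_contrast < 0) abort("speckle_contrast must be >= 0.")
  if (correlation_length_px <= 0) abort("correlation_length_px must be > 0.")
  wall_thickness_px <- as.integer(wall_thickness_px)
  if (wall_thickness_px[1] < 6L) abort("wall_thickness_px minimum must be >= 6.")
  if (wall_thickness_px[2] < wall_thickness_px[1]) abort("invalid wall_thickness_px range.")
  if (any(patient_jitter < 0)) abort("patient_jitter SDs must be >= 0.")
  structure(
    list(group_label = group_label, mean_level = mean_level,
         speckle_contrast = speckle_contrast,
         correlation_length_px = correlation_length_px,
         wall_thickness_px = wall_thickness_px,
         patient_jitter = patient_jitter),
    class = "group_texture_params"
  )
}

# one patient's realization of the group texture process: multiplicative
# log-normal jitter on the three speckle parameters (draws from the
# current RNG stream)
patient_texture_params <- function(tp) {
  j <- tp$patient_jitter
  tp$mean_level <- min(250, tp$mean_level * exp(rnorm(1, 0, j[[1]])))
  tp$speckle_contrast <- tp$speckle_contrast * exp(rnorm(1, 0, j[[2]]))
  tp$correlation_length_px <- tp$correlation_length_px * exp(rnorm(1, 0, j[[3]]))
  tp
}

#' Default per-group texture parameters
#'
#' The planted group separation: hypertensives (PA, EH) share a brighter,
#' higher-contrast, shorter-range speckle than controls — a strong
#' hypertensive-vs-control contrast — while PA and EH differ only
#' marginally from each other, so that no single feature separates them but
#' a classifier working on all features retains a weak signal. Effect sizes
#' are a design choice of the generator (no quantitative description of the
#' real texture differences is available).
#'
#' @return named list of \code{\link{group_texture_params}} for PA, EH, C.
#' @export
default_texture_params <- function() {
  list(
    PA = group_texture_params("PA", mean_level = 143, speckle_contrast = 0.48,
                              correlation_length_px = 1.25),
    EH = group_texture_params("EH", mean_level = 140, speckle_contrast = 0.45,
                              correlation_length_px = 1.35),
    C  = group_texture_params("C",  mean_level = 120, speckle_contrast = 0.30,
                              correlation_length_px = 2.5)
  )
}

#' Synthetic cohort configuration
#'
#' @param n_patients named integer vector \code{c(PA=, EH=, C=)}; defaults
#'   33/52/33 (the study design: 118 subjects).
#' @param images_per_patient images per patient (default 4: two insonation
#'   angles on each side).
#' @param image_size \code{c(rows, cols)} in pixels.
#' @param pixels_per_mm spatial scale (default 10).
#' @param roi_length_mm ROI strip length in mm, at least 10 (default 12).
#' @param marker_count bright caliper dots planted per image.
#' @param texture_params named list of \code{\link{group_texture_params}}.
#' @param clinical_params covariate table, see
#'   \code{\link{default_clinical_params}}.
#' @param seed integer master seed; the whole cohort is a deterministic
#'   function of the config.
#' @return a list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_patients = c(PA = 33L, EH = 52L, C = 33L),
                             images_per_patient = 4L,
                             image_size = c(128L, 192L),
                             pixels_per_mm = 10,
                             roi_length_mm = 12,
                             marker_count = 3L,
                             texture_params = default_texture_params(),
                             clinical_params = default_clinical_params(),
                             seed = 1L) {
  n_patients <- n_patients[c("PA", "EH", "C")]
  names(n_patients) <- c("PA", "EH", "C")
  n_patients[is.na(n_patients)] <- 0L
  if (any(n_patients < 0) || sum(n_patients) < 1) {
    abort("invalid group sizes: need nonnegative counts with at least one patient.")
  }
  if (images_per_patient < 1L) abort("images_per_patient must be >= 1.")
  if (roi_length_mm < 10) abort("roi_length_mm must be >= 10 (minimum polygon length).")
  roi_len_px <- round(roi_length_mm * pixels_per_mm)
  if (roi_len_px + 16 > image_size[2]) {
    abort(sprintf("image width %d cannot contain a %d-px ROI strip.",
                  image_size[2], roi_len_px))
  }
  structure(
    list(n_patients = as.integer(n_patients),
         images_per_patient = as.integer(images_per_patient),
         image_size = as.integer(image_size),
         pixels_per_mm = pixels_per_mm, roi_length_mm = roi_length_mm,
         marker_count = as.integer(marker_count),
         texture_params = texture_params, clinical_params = clinical_params,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Synthesize one speckled far-wall image with its ROI polygon
#'
#' The image is a layered far-wall profile — tissue, dark lumen band, the
#' intima-media strip at \code{mean_level}, a bright adventitia band, tissue
#' — multiplied by a correlated log-normal speckle field with SD/mean equal
#' to \code{speckle_contrast} (white Gaussian log-field smoothed at
#' \code{correlation_length_px} and re-standardized), clipped to 0–255 and
#' rounded to 8-bit codes. The ROI polygon is the rectangle tracing the
#' intima-media strip; its thickness is drawn from
#' \code{wall_thickness_px}.
#'
#' @param params a \code{\link{group_texture_params}}.
#' @param size \code{c(rows, cols)}.
#' @param pixels_per_mm spatial scale.
#' @param roi_length_mm ROI length in mm (>= 10).
#' @param seed optional integer seed (NULL: use the current RNG stream).
#' @return list with \code{image} (a \code{\link{us_image}}) and
#'   \code{roi} (a \code{roi_region}).
#' @export
synth_wall_image <- function(params, size = c(128L, 192L), pixels_per_mm = 10,
                             roi_length_mm = 12, seed = NULL) {
  with_seed(seed, {
    nr <- size[1]; nc <- size[2]
    roi_len <- round(roi_length_mm * pixels_per_mm)
    if (roi_len + 16 > nc) abort("ROI strip does not fit in the image width.")
    thick <- sample(params$wall_thickness_px[1]:params$wall_thickness_px[2], 1L)
    wall_top <- sample(floor(nr * 0.50):floor(nr * 0.60), 1L)
    adv_h <- 6L
    if (wall_top + thick + adv_h + 4L > nr) abort("wall strip does not fit vertically.")
    lumen_h <- floor(nr * 0.25)
    lumen_top <- max(1L, wall_top - lumen_h)

    base <- matrix(90, nr, nc)                            # surrounding tissue
    base[lumen_top:(wall_top - 1L), ] <- 25               # lumen (dark)
    base[wall_top:(wall_top + thick - 1L), ] <- params$mean_level
    base[(wall_top + thick):(wall_top + thick + adv_h - 1L), ] <- 225  # adventitia

    px <- base
    if (params$speckle_contrast > 0) {
      g <- matrix(rnorm(nr * nc), nr, nc)
      g <- gaussian_blur(g, params$correlation_length_px)
      g <- g / sqrt(gaussian_blur_var_factor(params$correlation_length_px))
      s_ln <- sqrt(log(1 + params$speckle_contrast^2))
      px <- base * exp(s_ln * g - s_ln^2 / 2)
    }
    px <- round(pmin(pmax(px, 0), 255))
    dim(px) <- c(nr, nc)

    x0 <- sample(4:(nc - roi_len - 4L), 1L)
    poly <- rbind(c(wall_top - 1L, x0 - 1L),
                  c(wall_top - 1L, x0 + roi_len - 2L),
                  c(wall_top + thick - 2L, x0 + roi_len - 2L),
                  c(wall_top + thick - 2L, x0 - 1L))  # 0-based pixel centers
    list(image = us_image(px, scale = "raw"),
         roi = rasterize_roi(poly, c(nr, nc)))
  })
}

#' Plant bright caliper-dot markers
#'
#' Adds \code{n} near-saturated circular dots (radius 2–4 px) at random
#' non-overlapping positions and returns the ground-truth marker mask,
#' for exercising \code{\link{detect_and_inpaint_markers}}.
#'
#' @param image a \code{\link{us_image}} (raw scale).
#' @param n number of dots, >= 0.
#' @param seed optional integer seed.
#' @return list with \code{image} and logical \code{marker_mask}.
#' @export
plant_markers <- function(image, n, seed = NULL) {
  image <- as_us_image(image)
  with_seed(seed, {
    px <- image$pixels
    nr <- nrow(px); nc <- ncol(px)
    mask <- matrix(FALSE, nr, nc)
    if (n > 0) {
      centers <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(centers) < n && tries < 1000L) {
        tries <- tries + 1L
        r <- sample(6:(nr - 5L), 1L); c <- sample(6:(nc - 5L), 1L)
        if (nrow(centers) == 0 ||
            min((centers[, 1] - r)^2 + (centers[, 2] - c)^2) > 12^2) {
          centers <- rbind(centers, c(r, c))
        }
      }
      if (nrow(centers) < n) abort("could not place the requested marker count.")
      for (i in seq_len(n)) {
        rad <- sample(2:4, 1L)
        rr <- pmax(1L, centers[i, 1] - rad):pmin(nr, centers[i, 1] + rad)
        cc <- pmax(1L, centers[i, 2] - rad):pmin(nc, centers[i, 2] + rad)
        d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+")
        disc <- d2 <= rad^2
        sub <- px[rr, cc]; sub[disc] <- 255
        px[rr, cc] <- sub
        msub <- mask[rr, cc]; msub[disc] <- TRUE
        mask[rr, cc] <- msub
      }
    }
    out <- us_image(px, image_id = image$image_id, patient_id = image$patient_id,
                    side = image$side, angle = image$angle, scale = "raw")
    list(image = out, marker_mask = mask)
  })
}

#' Default clinical covariate parameters by group
#'
#' Group means and SDs of the clinical table: Gaussian covariates
#' (mean, sd), Bernoulli covariates (p = prevalence), and log-normal
#' covariates (meanlog = log median, sdlog = IQR on the log scale / 1.349)
#' for the skewed humoral markers. Aldosterone, renin and ARR are not
#' measured in controls (NA).
#'
#' @return tibble with columns \code{covariate}, \code{dist}, and per-group
#'   location/scale columns \code{pa_m, pa_s, eh_m, eh_s, c_m, c_s}.
#' @export
default_clinical_params <- function() {
  ln <- function(med, q1, q3) c(log(med), (log(q3) - log(q1)) / 1.349)
  al_pa <- ln(38.9, 27.4, 64.9); al_eh <- ln(15.7, 9.2, 23.1)
  re_pa <- ln(0.36, 0.25, 0.56); re_eh <- ln(0.66, 0.37, 1.68)
  ar_pa <- ln(103, 69, 157);     ar_eh <- ln(17, 8, 41)
  tibble::tribble(
    ~covariate,    ~dist,       ~pa_m,    ~pa_s,    ~eh_m,    ~eh_s,    ~c_m,  ~c_s,
    "age",         "normal",    57,       8,        55,       7,        54,    8,
    "sex",         "binary",    0.39,     NA,       0.38,     NA,       0.48,  NA,
    "bmi",         "normal",    29.0,     3.9,      28.4,     4.6,      26.6,  4.2,
    "sbp",         "normal",    164,      23,       170,      30,       125,   15,
    "dbp",         "normal",    97,       14,       99,       17,       78,    9,
    "cholesterol", "normal",    4.98,     1.05,     5.28,     1.00,     5.59,  0.97,
    "ldl",         "normal",    2.99,     0.87,     3.06,     0.77,     3.19,  0.84,
    "hdl",         "normal",    1.30,     0.34,     1.38,     0.33,     1.61,  0.40,
    "triglycerides", "normal",  1.54,     0.54,     1.85,     0.97,     1.73,  1.02,
    "glucose",     "normal",    4.9,      0.5,      5.2,      0.9,      5.0,   0.6,
    "smoking",     "binary",    0.33,     NA,       0.38,     NA,       0.24,  NA,
    "cca_imt",     "normal",    0.987,    0.152,    0.892,    0.155,    0.812, 0.126,
    "cb_imt",      "normal",    1.157,    0.243,    1.131,    0.275,    0.994, 0.203,
    "imt",         "normal",    1.066,    0.162,    0.974,    0.196,    0.884, 0.141,
    "aldosterone", "lognormal", al_pa[1], al_pa[2], al_eh[1], al_eh[2], NA,    NA,
    "renin",       "lognormal", re_pa[1], re_pa[2], re_eh[1], re_eh[2], NA,    NA,
    "arr",         "lognormal", ar_pa[1], ar_pa[2], ar_eh[1], ar_eh[2], NA,    NA
  )
}

#' Draw one clinical record
#'
#' Covariates are sampled independently per the group column of
#' \code{clinical_params}: Gaussian draws truncated at 0 for inherently
#' nonnegative quantities, Bernoulli for sex (female = 1) and smoking,
#' log-normal for the skewed humoral markers. Controls get NA for
#' aldosterone, renin and ARR (not measured in normotensives).
#'
#' @param group_label "PA", "EH" or "C".
#' @param clinical_params see \code{\link{default_clinical_params}}.
#' @param seed optional integer seed.
#' @return one-row tibble with one column per covariate.
#' @export
generate_clinical <- function(group_label, clinical_params = default_clinical_params(),
                              seed = NULL) {
  if (!group_label %in% c("PA", "EH", "C")) {
    abort(sprintf("unknown group '%s'.", group_label))
  }
  pre <- switch(group_label, PA = "pa", EH = "eh", C = "c")
  m <- clinical_params[[paste0(pre, "_m")]]
  s <- clinical_params[[paste0(pre, "_s")]]
  with_seed(seed, {
    vals <- vapply(seq_len(nrow(clinical_params)), function(i) {
      if (is.na(m[i])) return(NA_real_)
      switch(clinical_params$dist[i],
        normal    = pmax(0, rnorm(1, m[i], s[i])),
        binary    = as.numeric(runif(1) < m[i]),
        lognormal = rlnorm(1, m[i], s[i]),
        abort(sprintf("unknown distribution '%s'.", clinical_params$dist[i]))
      )
    }, numeric(1))
    as_tibble(as.list(setNames(vals, clinical_params$covariate)))
  })
}

#' Generate a full synthetic cohort
#'
#' Deterministic in the config seed: patients per group exactly as
#' configured, \code{images_per_patient} speckled wall images per patient
#' (cycling through the two sides and two insonation angles), one ROI
#' polygon per image, planted caliper markers with their ground-truth
#' masks, and one clinical record per patient.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return object of class \code{carotid_cohort}: \code{images} (tibble with
#'   list-columns \code{image}, \code{roi}, \code{marker_mask}),
#'   \code{clinical} (tibble, one row per patient), \code{config}.
#' @examples
#' coh <- generate_cohort(synthetic_config(
#'   n_patients = c(PA = 2, EH = 2, C = 2), images_per_patient = 1,
#'   image_size = c(72, 144), pixels_per_mm = 8, roi_length_mm = 12, seed = 7))
#' nrow(coh$clinical)
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  views <- list(c("R", 90), c("R", 150), c("L", 210), c("L", 270))
  with_seed(config$seed, {
    img_rows <- list(); clin_rows <- list()
    for (grp in c("PA", "EH", "C")) {
      n <- config$n_patients[[match(grp, c("PA", "EH", "C"))]]
      if (n == 0L) next
      tp <- config$texture_params[[grp]]
      for (p in seq_len(n)) {
        pid <- sprintf("%s%03d", grp, p)
        clin_rows[[pid]] <- bind_cols(
          tibble(patient_id = pid, group_label = grp),
          generate_clinical(grp, config$clinical_params)
        )
        tp_p <- patient_texture_params(tp)
        for (k in seq_len(config$images_per_patient)) {
          v <- views[[((k - 1L) %% 4L) + 1L]]
          sw <- synth_wall_image(tp_p, size = config$image_size,
                                 pixels_per_mm = config$pixels_per_mm,
                                 roi_length_mm = config$roi_length_mm)
          pm <- plant_markers(sw$image, config$marker_count)
          iid <- sprintf("%s_%s%s_%d", pid, v[[1]], v[[2]], k)
          im <- pm$image
          im$image_id <- iid; im$patient_id <- pid
          im$side <- v[[1]]; im$angle <- as.numeric(v[[2]])
          img_rows[[iid]] <- tibble(
            image_id = iid, patient_id = pid, group_label = grp,
            side = v[[1]], angle = as.numeric(v[[2]]),
            image = list(im), roi = list(sw$roi), marker_mask = list(pm$marker_mask)
          )
        }
      }
    }
    structure(
      list(images = bind_rows(img_rows), clinical = bind_rows(clin_rows),
           config = config),
      class = "carotid_cohort"
    )
  })
}

#' @export
print.carotid_cohort <- function(x, ...) {
  cat(sprintf("<carotid_cohort> %d patients (%s), %d images\n",
              nrow(x$clinical),
              paste(sprintf("%s=%d", c("PA", "EH", "C"),
                            tabulate(factor(x$clinical$group_label,
                                            c("PA", "EH", "C")), 3)),
                    collapse = " "),
              nrow(x$images)))
  invisible(x)
}

#' Write a cohort to disk / read it back
#'
#' Layout: \code{images/*.png} (8-bit grayscale), \code{rois/*.json}
#' (\code{{"image": name, "polygon": [[row, col], ...]}}, 0-based
#' pixel-center coordinates), \code{clinical.csv} (one row per patient,
#' missing values empty), \code{labels.csv}, \code{manifest.json}.
#'
#' @param cohort a \code{carotid_cohort}.
#' @param dir output directory (created if needed).
#' @return \code{write_cohort}: \code{dir}, invisibly; \code{read_cohort}:
#'   a \code{carotid_cohort} (marker masks are not persisted).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "rois"), showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$images))) {
    iid <- cohort$images$image_id[i]
    write_image(cohort$images$image[[i]], file.path(dir, "images", paste0(iid, ".png")))
    roi <- cohort$images$roi[[i]]
    jsonlite::write_json(
      list(image = paste0(iid, ".png"),
           polygon = unname(apply(roi$polygon, 1, as.numeric, simplify = FALSE))),
      file.path(dir, "rois", paste0(iid, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"), na = "")
  readr::write_csv(
    cohort$images |> distinct(.data$patient_id, .data$group_label),
    file.path(dir, "labels.csv")
  )
  manifest <- list(
    package = "carotexture",
    version = as.character(utils::packageVersion("carotexture")),
    n_patients = nrow(cohort$clinical), n_images = nrow(cohort$images),
    seed = cohort$config$seed %||% NA
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  labels <- readr::read_csv(file.path(dir, "labels.csv"), show_col_types = FALSE)
  clinical <- readr::read_csv(file.path(dir, "clinical.csv"), show_col_types = FALSE)
  img_files <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$"))
  rows <- lapply(img_files, function(f) {
    iid <- sub("\\.png$", "", f)
    pid <- sub("_[RL][0-9]+_[0-9]+$", "", iid)
    lab <- labels$group_label[match(pid, labels$patient_id)]
    im <- read_image(file.path(dir, "images", f), image_id = iid, patient_id = pid)
    roi_path <- file.path(dir, "rois", paste0(iid, ".json"))
    roi <- NULL
    if (file.exists(roi_path)) {
      rj <- jsonlite::read_json(roi_path, simplifyVector = TRUE)
      roi <- rasterize_roi(rj$polygon, dim(im$pixels))
    }
    tibble(image_id = iid, patient_id = pid, group_label = lab,
           side = NA_character_, angle = NA_real_,
           image = list(im), roi = list(roi), marker_mask = list(NULL))
  })
  structure(list(images = bind_rows(rows), clinical = clinical, config = NULL),
            class = "carotid_cohort")
}
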