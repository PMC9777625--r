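#' Pipeline run configuration
#'
#' Serializable bundle of every stage's parameters. The cohort is either
#' generated (\code{cohort} = a \code{\link{synthetic_config}}) or loaded
#' (\code{cohort_dir} = an on-disk cohort as written by
#' \code{\link{write_cohort}}).
#'
#' @param cohort a \code{\link{synthetic_config}}, used when
#'   \code{cohort_dir} is NULL.
#' @param cohort_dir optional path of an existing cohort.
#' @param p_low,p_high normalization percentiles.
#' @param inpaint run caliper-dot detection/inpainting.
#' @param texture a \code{\link{texture_params}}.
#' @param alpha screening significance level.
#' @param stat_unit "image" or "patient" screening unit.
#' @param subsets classifier feature subsets to evaluate.
#' @param model \code{\link{boost_params}}.
#' @param aggregation "mean" or "vote".
#' @param seed classifier seed.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(cohort = synthetic_config(), cohort_dir = NULL,
                       p_low = 1, p_high = 99, inpaint = TRUE,
                       texture = texture_params(), alpha = 0.05,
                       stat_unit = "image",
                       subsets = c("clinical", "clinical_imt", "texture", "aldo"),
                       model = boost_params(), aggregation = "mean", seed = 1L) {
  structure(
    list(cohort = cohort, cohort_dir = cohort_dir,
         p_low = p_low, p_high = p_high, inpaint = inpaint,
         texture = texture, alpha = alpha, stat_unit = stat_unit,
         subsets = subsets, model = model, aggregation = aggregation,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

stage_log <- function(log, name, t0, note = "") {
  dur <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  message(sprintf("[carotexture] %-12s %6.1fs %s", name, dur, note))
  c(log, setNames(list(list(seconds = dur, note = note)), name))
}

#' Run the full pipeline
#'
#' simulate (or load) -> preprocess -> extract -> screen -> classify ->
#' report, writing all artifacts into \code{out_dir}: the feature CSV,
#' screening CSVs and markdown tables, per-task ROC CSVs and plots, the
#' accuracy table, and a manifest recording the exact config, package
#' version and per-stage durations. Re-running with the same config
#' reproduces byte-identical CSV outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed).
#' @param write_cohort_dir also persist the generated cohort under
#'   \code{out_dir/cohort} (off by default; images are bulky).
#' @return invisibly, a list with the in-memory results: \code{cohort},
#'   \code{features}, \code{stats}, \code{loo} (list of
#'   \code{carotid_loo}), \code{accuracy}, \code{manifest}.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         write_cohort_dir = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(); warnings_seen <- character()
  withCallingHandlers({
    t0 <- Sys.time()
    cohort <- if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
              else generate_cohort(config$cohort)
    log <- stage_log(log, "cohort", t0, sprintf("%d images", nrow(cohort$images)))
    if (write_cohort_dir) write_cohort(cohort, file.path(out_dir, "cohort"))

    t0 <- Sys.time()
    features <- feature_table(cohort, params = config$texture,
                              normalize = TRUE, inpaint = config$inpaint)
    write_feature_table(features, file.path(out_dir, "features.csv"))
    log <- stage_log(log, "extract", t0, sprintf("%d x %d", nrow(features), ncol(features)))

    t0 <- Sys.time()
    stats_res <- bind_rows(
      feature_significance(features, "PA_vs_EH", alpha = config$alpha,
                           unit = config$stat_unit),
      feature_significance(features, "HTN_vs_C", alpha = config$alpha,
                           unit = config$stat_unit)
    )
    clin_num <- cohort$clinical |> select(-any_of("patient_id"))
    clin_res <- bind_rows(
      feature_significance(clin_num, "PA_vs_EH", alpha = config$alpha),
      feature_significance(clin_num |>
                             select(-any_of(c("aldosterone", "renin", "arr"))),
                           "HTN_vs_C", alpha = config$alpha)
    )
    readr::write_csv(stats_res, file.path(out_dir, "stats_texture.csv"))
    readr::write_csv(clin_res, file.path(out_dir, "stats_clinical.csv"))
    significance_report(stats_res, alpha = config$alpha,
                        path = file.path(out_dir, "stats_texture.md"))
    significance_report(clin_res, alpha = config$alpha,
                        path = file.path(out_dir, "stats_clinical.md"))
    log <- stage_log(log, "screen", t0,
                     sprintf("%d texture features significant (HTN vs C)",
                             count_significant(stats_res |>
                                                 filter(.data$comparison == "HTN_vs_C"),
                                               config$alpha)))

    t0 <- Sys.time()
    combos <- expand.grid(subset = config$subsets,
                          task = c("PA_vs_EH", "HTN_vs_C"),
                          stringsAsFactors = FALSE)
    combos <- combos[!(combos$subset == "aldo" & combos$task == "HTN_vs_C"), ]
    loo <- purrr::pmap(combos, function(subset, task) {
      loo_evaluate(features, cohort$clinical, task = task, feature_set = subset,
                   model = config$model, aggregation = config$aggregation,
                   seed = config$seed, params = config$texture)
    })
    acc <- accuracy_table(loo, subsets = config$subsets,
                          path = file.path(out_dir, "accuracy.csv"))
    accuracy_table(loo, subsets = config$subsets,
                   path = file.path(out_dir, "accuracy.md"))
    for (r in loo) {
      stem <- sprintf("roc_%s_%s", r$task, paste(r$feature_set, collapse = "-"))
      readr::write_csv(r$roc, file.path(out_dir, paste0(stem, ".csv")))
      if (identical(r$feature_set, "texture")) {
        ggsave(file.path(out_dir, paste0(stem, ".png")), autoplot(r),
               width = 4.5, height = 4.5, dpi = 120)
      }
    }
    log <- stage_log(log, "classify", t0, sprintf("%d task/subset runs", nrow(combos)))
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  manifest <- list(
    package = "carotexture",
    version = as.character(utils::packageVersion("carotexture")),
    config = unclass_config(config),
    stages = log,
    n_warnings = length(warnings_seen)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report <- c(
    "# carotexture run report", "",
    sprintf("Cohort: %d patients, %d images.",
            nrow(cohort$clinical), nrow(cohort$images)),
    sprintf("Warnings during run: %d.", length(warnings_seen)), "",
    "## Per-patient leave-one-out accuracy", "",
    readLines(file.path(out_dir, "accuracy.md")), "",
    "## Texture feature screening (blank = not significant)", "",
    head(readLines(file.path(out_dir, "stats_texture.md")), 22)
  )
  writeLines(report, file.path(out_dir, "report.md"))
  invisible(list(cohort = cohort, features = features,
                 stats = list(texture = stats_res, clinical = clin_res),
                 loo = loo, accuracy = acc, manifest = manifest))
}

unclass_config <- function(config) {
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(config)
}

#' Rebuild a run config from a pipeline manifest
#'
#' Inverse of the manifest serialization for synthetic-cohort runs, so a
#' finished run can be reproduced exactly from its \code{manifest.json}.
#'
#' @param path path to a manifest.json written by \code{\link{run_pipeline}}.
#' @return a \code{\link{run_config}}.
#' @export
config_from_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- j$config
  tp <- purrr::imap(cfg$cohort$texture_params, function(p, g) {
    group_texture_params(g, p$mean_level, p$speckle_contrast,
                         p$correlation_length_px,
                         unlist(p$wall_thickness_px))
  })
  coh <- synthetic_config(
    n_patients = setNames(unlist(cfg$cohort$n_patients), c("PA", "EH", "C")),
    images_per_patient = cfg$cohort$images_per_patient,
    image_size = unlist(cfg$cohort$image_size),
    pixels_per_mm = cfg$cohort$pixels_per_mm,
    roi_length_mm = cfg$cohort$roi_length_mm,
    marker_count = cfg$cohort$marker_count,
    texture_params = tp,
    clinical_params = as_tibble(cfg$cohort$clinical_params),
    seed = cfg$cohort$seed
  )
  tex <- cfg$texture
  run_config(
    cohort = coh,
    cohort_dir = if (length(cfg$cohort_dir)) cfg$cohort_dir else NULL,
    p_low = cfg$p_low, p_high = cfg$p_high, inpaint = cfg$inpaint,
    texture = texture_params(tex$ng, unlist(tex$d_set), unlist(tex$theta_set),
                             tex$glcm_mode, tex$quant_range,
                             tex$wavelet_levels, tex$wavelet_boundary),
    alpha = cfg$alpha, stat_unit = cfg$stat_unit,
    subsets = unlist(cfg$subsets),
    model = do.call(boost_params,
                    cfg$model[c("nrounds", "max_depth", "learning_rate",
                                "min_child_weight")]),
    aggregation = cfg$aggregation, seed = cfg$seed
  )
}

#' Validate an on-disk cohort directory
#'
#' Report-only checks: every image has an ROI file, every ROI has at least
#' 3 vertices and rasterizes to a non-empty mask, and the clinical table
#' covers every labelled patient.
#'
#' @param cohort_dir cohort directory (layout of \code{\link{write_cohort}}).
#' @return tibble of violations (zero rows when the cohort is intact), with
#'   columns \code{check}, \code{item}, \code{message}.
#' @export
validate_inputs <- function(cohort_dir) {
  if (!dir.exists(cohort_dir)) abort(sprintf("no such directory: %s", cohort_dir))
  bad <- list()
  imgs <- list.files(file.path(cohort_dir, "images"), pattern = "\\.png$")
  for (f in imgs) {
    iid <- sub("\\.png$", "", f)
    rp <- file.path(cohort_dir, "rois", paste0(iid, ".json"))
    if (!file.exists(rp)) {
      bad[[length(bad) + 1L]] <- tibble(check = "roi_present", item = iid,
                                        message = sprintf("no ROI file for image %s", iid))
      next
    }
    rj <- jsonlite::read_json(rp, simplifyVector = TRUE)
    poly <- rj$polygon
    if (is.null(dim(poly)) || nrow(poly) < 3L) {
      bad[[length(bad) + 1L]] <- tibble(check = "roi_degenerate", item = iid,
                                        message = sprintf("ROI of %s has < 3 vertices", iid))
      next
    }
    im <- read_image(file.path(cohort_dir, "images", f))
    ras <- tryCatch(rasterize_roi(poly, dim(im$pixels)), error = function(e) NULL)
    if (is.null(ras) || ras$pixel_count < 1L) {
      bad[[length(bad) + 1L]] <- tibble(check = "roi_empty", item = iid,
                                        message = sprintf("ROI of %s rasterizes empty", iid))
    }
  }
  lab_path <- file.path(cohort_dir, "labels.csv")
  clin_path <- file.path(cohort_dir, "clinical.csv")
  if (file.exists(lab_path) && file.exists(clin_path)) {
    labels <- readr::read_csv(lab_path, show_col_types = FALSE)
    clinical <- readr::read_csv(clin_path, show_col_types = FALSE)
    uncovered <- setdiff(labels$patient_id, clinical$patient_id)
    for (p in uncovered) {
      bad[[length(bad) + 1L]] <- tibble(check = "clinical_coverage", item = p,
                                        message = sprintf("no clinical row for patient %s", p))
    }
  } else {
    bad[[length(bad) + 1L]] <- tibble(check = "tables_present", item = cohort_dir,
                                      message = "labels.csv or clinical.csv missing")
  }
  if (length(bad)) bind_rows(bad)
  else tibble(check = character(), item = character(), message = character())
}
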