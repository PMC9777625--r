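#' Feature subsets for classification
#'
#' The four subsets evaluated against each task:
#' \itemize{
#'   \item \code{clinical}: age, sex, systolic/diastolic BP, glucose,
#'     cholesterol, HDL, LDL, smoking, triglycerides;
#'   \item \code{clinical_imt}: clinical plus CCA-IMT, CB-IMT and combined
#'     IMT;
#'   \item \code{texture}: the 152 texture features;
#'   \item \code{aldo}: plasma aldosterone, plasma renin activity and the
#'     aldosterone-to-renin ratio — the diagnostic gold standard, defined
#'     only for the PA-vs-EH task (controls are not assayed).
#' }
#'
#' @param feature_set one of the names above, or an explicit character
#'   vector of column names.
#' @param params \code{\link{texture_params}} used to enumerate texture
#'   columns.
#' @return character vector of column names.
#' @export
feature_subset_columns <- function(feature_set, params = texture_params()) {
  if (length(feature_set) > 1L || !feature_set %in%
        c("clinical", "clinical_imt", "texture", "aldo")) {
    return(feature_set)
  }
  clin <- c("age", "sex", "sbp", "dbp", "glucose", "cholesterol",
            "hdl", "ldl", "smoking", "triglycerides")
  switch(feature_set,
    clinical = clin,
    clinical_imt = c(clin, "cca_imt", "cb_imt", "imt"),
    texture = feature_names(params),
    aldo = c("aldosterone", "renin", "arr")
  )
}

task_labels <- function(task) {
  switch(task,
    PA_vs_EH = list(positive = "PA", negative = "EH"),
    HTN_vs_C = list(positive = c("PA", "EH"), negative = "C"),
    abort("task must be 'PA_vs_EH' or 'HTN_vs_C'.")
  )
}

#' Gradient-boosting hyperparameters
#'
#' Recorded explicitly so a run is fully reproducible; values are ordinary
#' small-data defaults, not tuned.
#'
#' @param nrounds boosting rounds.
#' @param max_depth tree depth.
#' @param learning_rate shrinkage.
#' @param min_child_weight minimum hessian sum per leaf. The default of 0
#'   (not xgboost's 1) matters here: unit-patient weighting divides every
#'   row weight by the patient's image count, which scales the hessian sums
#'   down and would otherwise forbid splits in small cohorts.
#' @param ... further \code{xgboost} params (all deterministic defaults:
#'   no row/column subsampling, single thread).
#' @return named list.
#' @export
boost_params <- function(nrounds = 50, max_depth = 3, learning_rate = 0.3,
                         min_child_weight = 0, ...) {
  list(nrounds = nrounds, max_depth = max_depth, learning_rate = learning_rate,
       min_child_weight = min_child_weight,
       subsample = 1, colsample_bytree = 1, nthread = 1, ...)
}

# Rows + 0/1 labels for one task/feature-set combination. Texture rows are
# per image; clinical subsets have one row per patient (aggregation is then
# a no-op).
assemble_task_data <- function(features, clinical, task, feature_set,
                               params = texture_params()) {
  lab <- task_labels(task)
  cols <- feature_subset_columns(feature_set, params)
  if (identical(sort(cols), sort(c("aldosterone", "renin", "arr"))) &&
      task == "HTN_vs_C") {
    abort("the 'aldo' subset is undefined for HTN_vs_C: controls lack these assays.")
  }
  src <- if (all(cols %in% names(features))) {
    features
  } else if (!is.null(clinical) && all(cols %in% names(clinical))) {
    clinical
  } else {
    abort(sprintf("feature column(s) not found: %s",
                  paste(setdiff(cols, c(names(features), names(clinical))),
                        collapse = ", ")))
  }
  src |>
    filter(.data$group_label %in% c(lab$positive, lab$negative)) |>
    mutate(label = as.numeric(.data$group_label %in% lab$positive)) |>
    select("patient_id", "group_label", "label", all_of(cols))
}

#' Aggregate per-image probabilities into a patient-level prediction
#'
#' Mean aggregation (default): the patient probability is the arithmetic
#' mean of the image probabilities and the label is positive iff it exceeds
#' 0.5; an exact tie goes to the negative class. Vote aggregation binarizes
#' each image at 0.5 first and takes the majority, ties again negative.
#'
#' @param image_probs numeric vector of per-image positive-class
#'   probabilities, length >= 1.
#' @param mode "mean" or "vote".
#' @return list with \code{probability} and logical \code{positive}.
#' @export
aggregate_patient <- function(image_probs, mode = c("mean", "vote")) {
  mode <- match.arg(mode)
  if (!length(image_probs)) abort("no image probabilities to aggregate.")
  if (mode == "mean") {
    p <- mean(image_probs)
    list(probability = p, positive = p > 0.5)
  } else {
    votes <- mean(image_probs > 0.5)
    list(probability = votes, positive = votes > 0.5)
  }
}

#' ROC curve and AUC from patient-level scores
#'
#' Sweeps the decision threshold across the aggregated patient
#' probabilities (ties cross simultaneously) and integrates by the
#' trapezoidal rule.
#'
#' @param probability numeric scores.
#' @param truth logical (or 0/1) true positive-class indicator.
#' @return list with \code{roc} (tibble of threshold, fpr, tpr, from (0,0)
#'   to (1,1)) and \code{auc}.
#' @export
roc_curve <- function(probability, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) abort("ROC needs both classes present.")
  th <- sort(unique(probability), decreasing = TRUE)
  pts <- tibble(
    threshold = c(Inf, th),
    fpr = c(0, vapply(th, function(t) mean(probability[!truth] >= t), numeric(1))),
    tpr = c(0, vapply(th, function(t) mean(probability[truth] >= t), numeric(1)))
  )
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  list(roc = pts, auc = auc)
}

#' Patient-level leave-one-out evaluation with gradient-boosted trees
#'
#' For each patient in turn, trains an XGBoost classifier on all rows of
#' all other patients — each training row weighted by 1 / (number of rows
#' of its patient), so every patient carries unit total weight — predicts
#' the held-out patient's rows, and aggregates them into one patient-level
#' probability and label. The held-out patient's rows never enter the
#' training fold. Accuracy and the ROC/AUC are computed over patients.
#'
#' @param features per-image feature table (\code{\link{feature_table}}).
#' @param clinical per-patient clinical table with \code{patient_id},
#'   \code{group_label} and covariate columns; may be NULL for texture-only
#'   runs.
#' @param task "PA_vs_EH" or "HTN_vs_C".
#' @param feature_set see \code{\link{feature_subset_columns}}.
#' @param model \code{\link{boost_params}}.
#' @param aggregation "mean" or "vote", see \code{\link{aggregate_patient}}.
#' @param seed integer seed (deterministic result for a fixed seed/config).
#' @param keep_folds store per-fold training patient ids and weights (for
#'   leakage/weight audits).
#' @param params \code{\link{texture_params}} naming the texture columns.
#' @return object of class \code{carotid_loo}: \code{patients} (tibble:
#'   patient_id, truth, probability, predicted), \code{accuracy},
#'   \code{roc}, \code{auc}, \code{task}, \code{feature_set}, \code{config},
#'   \code{config_hash}, and optionally \code{folds}.
#' @export
loo_evaluate <- function(features, clinical = NULL,
                         task = c("PA_vs_EH", "HTN_vs_C"),
                         feature_set = "texture",
                         model = boost_params(),
                         aggregation = c("mean", "vote"),
                         seed = 1L, keep_folds = FALSE,
                         params = texture_params()) {
  task <- match.arg(task)
  aggregation <- match.arg(aggregation)
  dat <- assemble_task_data(features, clinical, task, feature_set, params)
  cols <- setdiff(names(dat), c("patient_id", "group_label", "label"))
  pats <- dat |> distinct(.data$patient_id, .data$label)
  if (length(unique(pats$label)) < 2L || any(table(pats$label) < 2L)) {
    abort("need at least 2 patients in each class.")
  }
  X <- as.matrix(dat[cols])
  storage.mode(X) <- "double"
  xgbp <- do.call(xgboost::xgb.params, c(
    list(objective = "binary:logistic"),
    model[setdiff(names(model), "nrounds")]
  ))
  n_img <- table(dat$patient_id)
  w_all <- as.numeric(1 / n_img[dat$patient_id])
  folds <- list()
  res <- with_seed(seed, {
    purrr::map(pats$patient_id, function(pid) {
      tr <- dat$patient_id != pid
      if (length(unique(dat$label[tr])) < 2L) {
        abort(sprintf("a class is absent from the training fold for patient %s.", pid))
      }
      dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE],
                                     label = dat$label[tr],
                                     weight = w_all[tr], nthread = 1)
      fit <- xgboost::xgb.train(xgbp, dtrain, nrounds = model$nrounds, verbose = 0)
      probs <- predict(fit, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], nthread = 1))
      agg <- aggregate_patient(probs, aggregation)
      if (keep_folds) {
        folds[[pid]] <<- list(train_patients = unique(dat$patient_id[tr]),
                              weights = w_all[tr])
      }
      tibble(patient_id = pid, truth = dat$label[!tr][1],
             probability = agg$probability,
             predicted = as.numeric(agg$positive))
    }) |> bind_rows()
  })
  rc <- roc_curve(res$probability, res$truth == 1)
  config <- list(task = task, feature_set = feature_set, model = model,
                 aggregation = aggregation, seed = seed)
  structure(
    list(patients = res, accuracy = mean(res$predicted == res$truth),
         roc = rc$roc, auc = rc$auc, task = task, feature_set = feature_set,
         config = config, config_hash = rlang::hash(list(config, res)),
         folds = if (keep_folds) folds else NULL),
    class = "carotid_loo"
  )
}

#' @export
print.carotid_loo <- function(x, ...) {
  cat(sprintf("<carotid_loo> %s / %s: accuracy %.3f, AUC %.3f over %d patients\n",
              x$task, paste(x$feature_set, collapse = ","),
              x$accuracy, x$auc, nrow(x$patients)))
  invisible(x)
}

#' Accuracy table across feature subsets and tasks
#'
#' Rows are feature subsets, columns the two tasks; the aldo x HTN_vs_C
#' cell is structurally "NA" (controls are not assayed). Missing subsets
#' are omitted with a warning.
#'
#' @param results list of \code{carotid_loo} objects.
#' @param subsets row order (default the four standard subsets).
#' @param path optional CSV or markdown output file.
#' @return tibble with columns \code{feature_set}, \code{PA_vs_EH},
#'   \code{HTN_vs_C} (accuracy as character, "NA" where undefined).
#' @export
accuracy_table <- function(results,
                           subsets = c("clinical", "clinical_imt", "texture", "aldo"),
                           path = NULL) {
  got <- tibble(
    feature_set = map_chr(results, function(r) paste(r$feature_set, collapse = ",")),
    task = map_chr(results, "task"),
    accuracy = map_dbl(results, "accuracy")
  )
  rows <- purrr::map(subsets, function(s) {
    cells <- purrr::map_chr(c("PA_vs_EH", "HTN_vs_C"), function(tk) {
      if (s == "aldo" && tk == "HTN_vs_C") return("NA")
      hit <- got |> filter(.data$feature_set == s, .data$task == tk)
      if (nrow(hit) == 0L) NA_character_ else sprintf("%.2f", hit$accuracy[1])
    })
    tibble(feature_set = s, PA_vs_EH = cells[1], HTN_vs_C = cells[2])
  }) |> bind_rows()
  missing <- rows |> filter(is.na(.data$PA_vs_EH) & is.na(.data$HTN_vs_C))
  if (nrow(missing)) {
    warn(sprintf("no results for subset(s): %s; row(s) omitted.",
                 paste(missing$feature_set, collapse = ", ")))
    rows <- rows |> filter(!(is.na(.data$PA_vs_EH) & is.na(.data$HTN_vs_C)))
  }
  if (!is.null(path)) {
    if (grepl("\\.csv$", path)) readr::write_csv(rows, path)
    else {
      hdr <- "| Feature set | PA vs EH | PA+EH vs C |"
      sep <- "|---|---|---|"
      body <- apply(rows, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
      writeLines(c(hdr, sep, body), path)
    }
    return(invisible(rows))
  }
  rows
}
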