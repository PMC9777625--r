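# A small feature table with a planted class difference, built directly
# (no images) to keep classifier tests fast and focused.
toy_features <- function(n_per_class = 8, images = 2, delta = 0, seed = 1,
                         task_groups = c("PA", "EH")) {
  set.seed(seed)
  pats <- tibble::tibble(
    patient_id = sprintf("%s%02d", rep(task_groups, each = n_per_class),
                         seq_len(2 * n_per_class)),
    group_label = rep(task_groups, each = n_per_class)
  )
  rows <- pats[rep(seq_len(nrow(pats)), each = images), ]
  rows$image_id <- sprintf("%s_i%d", rows$patient_id, seq_len(images))
  shift <- ifelse(rows$group_label == task_groups[1], delta, 0)
  rows$x1 <- rnorm(nrow(rows)) + shift
  rows$x2 <- rnorm(nrow(rows)) + shift / 2
  rows$x3 <- rnorm(nrow(rows))
  dplyr::select(rows, image_id, patient_id, group_label, x1, x2, x3)
}

test_that("patient aggregation averages probabilities with ties to negative", {
  agg <- aggregate_patient(c(0.9, 0.8, 0.1))
  expect_equal(agg$probability, 0.6)
  expect_true(agg$positive)
  tie <- aggregate_patient(c(0.5, 0.5))
  expect_equal(tie$probability, 0.5)
  expect_false(tie$positive)
  single <- aggregate_patient(0.3)
  expect_equal(single$probability, 0.3)
  expect_false(single$positive)
  expect_error(aggregate_patient(numeric(0)), "no image probabilities")
  # vote mode: majority of binarized predictions
  vote <- aggregate_patient(c(0.9, 0.6, 0.1), mode = "vote")
  expect_true(vote$positive)
})

test_that("the ROC sweep matches exhaustive threshold enumeration and pROC", {
  hand <- roc_curve(c(0.9, 0.6, 0.7, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(hand$auc, 0.75)
  expect_equal(hand$roc$fpr[1], 0)
  expect_equal(tail(hand$roc$tpr, 1), 1)

  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  flat <- roc_curve(rep(0.4, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(flat$auc, 0.5)

  set.seed(44)
  for (i in 1:10) {
    probs <- round(runif(30), 2)  # ties on purpose
    truth <- runif(30) < 0.5
    if (!any(truth) || all(truth)) next
    mine <- roc_curve(probs, truth)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(truth, probs, quiet = TRUE,
                                          direction = "<")))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
  expect_error(roc_curve(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
})

test_that("a label-equal feature yields perfect accuracy; monotone ROC", {
  ft <- toy_features(n_per_class = 5, images = 2, delta = 0, seed = 2)
  ft$x1 <- as.numeric(ft$group_label == "PA")  # leak the label on purpose
  r <- loo_evaluate(ft, NULL, task = "PA_vs_EH", feature_set = c("x1"),
                    model = boost_params(nrounds = 10), seed = 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$auc, 1)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
})

test_that("LOO folds never contain the held-out patient and weights are unit per patient", {
  ft <- toy_features(n_per_class = 4, images = 3, delta = 1, seed = 3)
  r <- loo_evaluate(ft, NULL, task = "PA_vs_EH", feature_set = c("x1", "x2", "x3"),
                    model = boost_params(nrounds = 10), seed = 1, keep_folds = TRUE)
  expect_equal(nrow(r$patients), 8)
  for (pid in names(r$folds)) {
    fold <- r$folds[[pid]]
    expect_false(pid %in% fold$train_patients)
    expect_equal(sum(fold$weights), length(fold$train_patients))
  }
})

test_that("LOO results are deterministic in seed and config", {
  ft <- toy_features(n_per_class = 4, images = 2, delta = 2, seed = 5)
  r1 <- loo_evaluate(ft, NULL, task = "PA_vs_EH", feature_set = c("x1", "x2"),
                     model = boost_params(nrounds = 15), seed = 9)
  r2 <- loo_evaluate(ft, NULL, task = "PA_vs_EH", feature_set = c("x1", "x2"),
                     model = boost_params(nrounds = 15), seed = 9)
  expect_identical(r1$config_hash, r2$config_hash)
  expect_equal(r1$patients, r2$patients)
})

test_that("task and subset plumbing enforce the aldo restriction", {
  ft <- toy_features()
  clin <- tibble::tibble(
    patient_id = unique(ft$patient_id),
    group_label = rep(c("PA", "EH"), each = 8),
    aldosterone = rnorm(16, 30), renin = rnorm(16, 1), arr = rnorm(16, 50)
  )
  expect_error(
    loo_evaluate(ft, clin, task = "HTN_vs_C", feature_set = "aldo"),
    "undefined for HTN_vs_C"
  )
  expect_error(
    loo_evaluate(ft, NULL, task = "PA_vs_EH", feature_set = "nope"),
    "not found"
  )
  cols <- feature_subset_columns("clinical_imt")
  expect_true(all(c("cca_imt", "cb_imt", "imt") %in% cols))
  expect_length(feature_subset_columns("texture"), 152)
})

test_that("tidy, glance and the accuracy table summarize LOO results", {
  ft <- toy_features(n_per_class = 4, images = 2, delta = 3, seed = 8)
  r <- loo_evaluate(ft, NULL, task = "PA_vs_EH", feature_set = c("x1", "x2"),
                    model = boost_params(nrounds = 10), seed = 1)
  td <- tidy(r)
  expect_equal(nrow(td), 8)
  expect_true(all(c("patient_id", "truth", "probability", "predicted") %in% names(td)))
  gl <- glance(r)
  expect_equal(gl$accuracy, r$accuracy)

  r$feature_set <- "texture"  # present it as the texture subset row
  expect_warning(tab <- accuracy_table(list(r)), "no results for subset")
  expect_equal(tab$feature_set, c("texture", "aldo"))
  expect_equal(tab$HTN_vs_C[tab$feature_set == "aldo"], "NA")
  expect_equal(as.numeric(tab$PA_vs_EH[tab$feature_set == "texture"]),
               round(r$accuracy, 2))

  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
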