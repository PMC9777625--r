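comparison_groups <- function(comparison) {
  switch(comparison,
    PA_vs_EH = list(g1 = "PA", g2 = "EH"),
    HTN_vs_C = list(g1 = c("PA", "EH"), g2 = "C"),
    abort("comparison must be 'PA_vs_EH' or 'HTN_vs_C'.")
  )
}

#' Per-feature two-group significance screening
#'
#' For every numeric feature column, compares the two groups of the chosen
#' contrast with three two-sided tests: Welch's unequal-variance t-test, the
#' two-sample Kolmogorov–Smirnov test, and the Mann–Whitney–Wilcoxon
#' rank-sum test. A feature counts as significant only when all three
#' p-values fall below \code{alpha}. No multiple-testing correction gates
#' significance; a Benjamini–Hochberg column on the Welch p-values is
#' emitted as supplementary output.
#'
#' @param table tibble with a \code{group_label} column ("PA"/"EH"/"C"),
#'   optional \code{image_id}/\code{patient_id}, and numeric feature
#'   columns (e.g. from \code{\link{feature_table}}, or a clinical table).
#' @param comparison "PA_vs_EH" or "HTN_vs_C" (PA+EH pooled vs controls).
#' @param alpha significance level (default 0.05).
#' @param unit "image" (default; one observation per row) or "patient"
#'   (per-patient feature means, requires \code{patient_id}).
#' @param exact passed to \code{wilcox.test}/\code{ks.test}: NULL (default)
#'   uses the exact distribution for small untied samples and the
#'   tie-corrected normal approximation otherwise.
#' @return tibble with one row per feature: \code{feature},
#'   \code{comparison}, \code{p_welch}, \code{p_ks}, \code{p_mw},
#'   \code{p_welch_bh}, \code{significant_all}, \code{degenerate}.
#' @export
feature_significance <- function(table, comparison = c("PA_vs_EH", "HTN_vs_C"),
                                 alpha = 0.05, unit = c("image", "patient"),
                                 exact = NULL) {
  comparison <- match.arg(comparison)
  unit <- match.arg(unit)
  grp <- comparison_groups(comparison)
  meta <- intersect(c("image_id", "patient_id", "group_label", "side", "angle"),
                    names(table))
  feats <- setdiff(names(table), meta)
  feats <- feats[vapply(table[feats], is.numeric, logical(1))]
  if (!length(feats)) abort("no numeric feature columns found.")
  if (unit == "patient") {
    table <- table |>
      group_by(.data$patient_id, .data$group_label) |>
      summarise(across(all_of(feats), mean), .groups = "drop")
  }
  x_tab <- table |> filter(.data$group_label %in% grp$g1)
  y_tab <- table |> filter(.data$group_label %in% grp$g2)
  if (nrow(x_tab) == 0L || nrow(y_tab) == 0L) {
    abort(sprintf("a group of comparison %s is empty.", comparison))
  }
  res <- purrr::map(feats, function(f) {
    x <- x_tab[[f]]; y <- y_tab[[f]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    degenerate <- length(unique(c(x, y))) < 2L
    if (degenerate) {
      # both samples one identical constant: no evidence of any difference
      pw <- 1; pk <- 1; pm <- 1
    } else {
      pw <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
      pk <- suppressWarnings(stats::ks.test(x, y, exact = exact)$p.value)
      pm <- suppressWarnings(stats::wilcox.test(x, y, exact = exact)$p.value)
      if (is.na(pm)) pm <- 1
    }
    tibble(feature = f, comparison = comparison,
           p_welch = pw, p_ks = pk, p_mw = pm, degenerate = degenerate)
  }) |> bind_rows()
  res |>
    mutate(p_welch_bh = p.adjust(.data$p_welch, "BH"),
           significant_all = pmax(.data$p_welch, .data$p_ks, .data$p_mw) < alpha) |>
    select("feature", "comparison", "p_welch", "p_ks", "p_mw",
           "p_welch_bh", "significant_all", "degenerate")
}

#' Count features significant by all three tests
#'
#' @param results output of \code{\link{feature_significance}}.
#' @param alpha significance level; the count is recomputed from the stored
#'   p-values at this level.
#' @return integer count.
#' @export
count_significant <- function(results, alpha = 0.05) {
  if (nrow(results) == 0L) abort("empty results.")
  sum(pmax(results$p_welch, results$p_ks, results$p_mw) < alpha)
}

format_p <- function(p, alpha) {
  ifelse(p >= alpha, "", ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' Render a significance table
#'
#' One row per feature with the three test p-values per comparison, sorted
#' ascending by the Welch p-value; cells of non-significant tests are left
#' blank (the paper-table convention). Pass results for one or both
#' comparisons (rows are matched by feature), optionally prepending a
#' clinical-covariate block.
#'
#' @param results output of \code{\link{feature_significance}} (one or more
#'   comparisons row-bound).
#' @param clinical_results optional additional block, same format.
#' @param alpha blanking threshold.
#' @param path optional file; writes CSV (\code{.csv}) or
#'   GitHub-markdown (anything else).
#' @return a tibble of formatted cells, invisibly when written to a file.
#' @export
significance_report <- function(results, clinical_results = NULL,
                                alpha = 0.05, path = NULL) {
  all_res <- bind_rows(clinical_results, results)
  wide <- all_res |>
    mutate(across(c("p_welch", "p_ks", "p_mw"), ~ format_p(.x, alpha))) |>
    select("feature", "comparison", "p_welch", "p_ks", "p_mw") |>
    tidyr::pivot_wider(names_from = "comparison",
                       values_from = c("p_welch", "p_ks", "p_mw"),
                       names_glue = "{comparison}_{.value}")
  ord <- all_res |>
    group_by(.data$feature) |>
    summarise(p = min(.data$p_welch), .groups = "drop")
  wide <- wide |>
    left_join(ord, by = "feature") |>
    arrange(.data$p) |>
    select(-"p")
  if (!is.null(path)) {
    if (grepl("\\.csv$", path)) {
      readr::write_csv(wide, path)
    } else {
      hdr <- paste0("| ", paste(names(wide), collapse = " | "), " |")
      sep <- paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|")
      body <- apply(wide, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
      writeLines(c(hdr, sep, body), path)
    }
    return(invisible(wide))
  }
  wide
}
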