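#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a leave-one-out result
#'
#' One row per patient: identifier, true class (0/1), aggregated
#' probability and predicted class.
#'
#' @param x a \code{carotid_loo} from \code{\link{loo_evaluate}}.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.carotid_loo <- function(x, ...) {
  x$patients |>
    mutate(task = x$task, feature_set = paste(x$feature_set, collapse = ","),
           .before = 1)
}

#' One-row summary of a leave-one-out result
#'
#' @param x a \code{carotid_loo}.
#' @param ... unused.
#' @return tibble with task, feature set, n_patients, accuracy, AUC.
#' @export
glance.carotid_loo <- function(x, ...) {
  tibble(task = x$task, feature_set = paste(x$feature_set, collapse = ","),
         n_patients = nrow(x$patients), accuracy = x$accuracy, auc = x$auc)
}

#' ROC curve plot of a leave-one-out result
#'
#' @param object a \code{carotid_loo}.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.carotid_loo <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step(linewidth = 0.8, colour = "#2166ac") +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("%s — %s", object$task,
                         paste(object$feature_set, collapse = ",")),
         subtitle = sprintf("accuracy %.2f, AUC %.2f over %d patients",
                            object$accuracy, object$auc, nrow(object$patients))) +
    theme_minimal()
  }

#' Plot an ultrasound image, optionally with its ROI polygon
#'
#' @param object a \code{\link{us_image}}.
#' @param roi optional \code{roi_region} to overlay.
#' @param ... unused.
#' @return a ggplot (grayscale raster, row 0 on top).
#' @export
autoplot.us_image <- function(object, roi = NULL, ...) {
  px <- object$pixels
  df <- tibble(
    row = rep(0:(nrow(px) - 1L), times = ncol(px)),
    col = rep(0:(ncol(px) - 1L), each = nrow(px)),
    intensity = as.vector(px)
  )
  p <- ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", guide = "none") +
    scale_y_reverse() +
    coord_equal() +
    labs(x = NULL, y = NULL, title = object$image_id) +
    theme_void()
  if (!is.null(roi)) {
    poly <- as.data.frame(roi$polygon)
    names(poly) <- c("row", "col")
    poly <- rbind(poly, poly[1, ])
    p <- p + geom_path(data = poly, aes(x = .data$col, y = .data$row),
                       inherit.aes = FALSE, colour = "yellow", linewidth = 0.6)
  }
  p
}
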