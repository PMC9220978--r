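#' Plot a leaderboard of test AUROCs
#'
#' @param object An `omics_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.omics_experiment <- function(object, ...) {
  lb <- object$leaderboard
  ggplot2::ggplot(lb, ggplot2::aes(x = .data$classifier, y = .data$auroc,
                                   fill = .data$selector)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "classifier", y = "test AUROC", fill = "selector") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' ROC curve of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the AUROC in the title.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- roc_points(object$scores, object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}

#' ROC curve point list
#'
#' Thresholds descend through the distinct scores; one (FPR, TPR) point per
#' threshold plus the (0, 0) origin.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @return A tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)
  n1 <- max(sum(y == 1), 1L); n0 <- max(sum(y == 0), 1L)
  tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n0),
    tpr = c(0, tp[last] / n1)
  )
}

#' Top-n feature importance plot
#'
#' The interpretability view: model-native importances of the winning model,
#' with the feature names exposing parameter, frequency band and lesion area.
#'
#' @param model A `trained_model` (or an `omics_experiment`, whose winner is
#'   used).
#' @param top_n Number of features to show.
#' @return A ggplot.
#' @export
plot_importance <- function(model, top_n = 10L) {
  if (inherits(model, "omics_experiment")) model <- model$winner
  imp <- model$importance
  imp <- imp[!is.na(imp$importance), , drop = FALSE]
  imp <- utils::head(imp[order(-imp$importance), ], top_n)
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of conventional single-index AUROCs
#'
#' @param grid Result of [conventional_auc_grid()].
#' @return A ggplot tile map (5 indexes x 3 subregions).
#' @export
plot_conventional_heatmap <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$roi, y = .data$index,
                                     fill = .data$auroc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$auroc))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0.5, 1)) +
    ggplot2::labs(x = "subregion", y = "index", fill = "AUROC") +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a parameter map
#'
#' @param object A `parameter_map`.
#' @param slice Axial (z) slice index; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.parameter_map <- function(object, slice = NULL, ...) {
  d <- dim(object$values)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(object$values[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s @ %s (z = %d)", variant_label(object$variant),
                      object$band$name, slice),
      fill = "value"
    ) +
    ggplot2::theme_minimal()
}
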