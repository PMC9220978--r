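#' Tidy a trained model into its importance ranking
#'
#' @param x A `trained_model`.
#' @param ... Unused.
#' @return A tibble with `feature`, `importance`, sorted decreasing, plus the
#'   parsed feature components (`base`, `band`, `roi`).
#' @export
tidy.trained_model <- function(x, ...) {
  imp <- x$importance
  parsed <- lapply(imp$feature, parse_feature_name)
  dplyr::mutate(
    imp,
    base = vapply(parsed, `[[`, character(1), "base"),
    band = vapply(parsed, `[[`, character(1), "band"),
    roi = vapply(parsed, `[[`, character(1), "roi")
  )
}

#' One-row summary of a trained model
#' @param x A `trained_model`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.trained_model <- function(x, ...) {
  tibble::tibble(
    selector = x$config$selector,
    classifier = x$config$classifier,
    n_selected = length(x$selected_features),
    cv_f1 = max(x$cv_results$mean_f1)
  )
}

#' Tidy an evaluation report into a metric table
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with `metric` and `value`.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    metric = c("auroc", "auprc", "acc", "sen", "spe", "f1"),
    value = c(x$auroc, x$auprc, x$acc, x$sen, x$spe, x$f1)
  )
}

#' One-row summary of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble of the six metrics.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, auprc = x$auprc, acc = x$acc,
                 sen = x$sen, spe = x$spe, f1 = x$f1)
}

#' Tidy an experiment into its leaderboard
#' @param x An `omics_experiment`.
#' @param ... Unused.
#' @return The leaderboard tibble.
#' @export
tidy.omics_experiment <- function(x, ...) x$leaderboard

#' One-row summary of an experiment (the winning model)
#' @param x An `omics_experiment`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.omics_experiment <- function(x, ...) x$leaderboard[1, ]

#' Tidy a DeLong test result
#' @param x A `delong_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.delong_result <- function(x, ...) {
  tibble::tibble(auc_a = x$auc_a, auc_b = x$auc_b, z = x$z, p = x$p)
}
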