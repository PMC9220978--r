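#' DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two score vectors measured on the same subjects
#' using structural components: per-positive placements V10 and per-negative
#' placements V01 (midrank convention: ties count 1/2), their empirical
#' covariance across the two models, and the normal approximation
#' `z = (auc_a - auc_b) / sqrt(var)`. The p value is two-sided; swapping the
#' inputs negates z and preserves p.
#'
#' @param scores_a,scores_b Numeric score vectors on the same subjects.
#' @param labels Binary labels (0/1), both classes present.
#' @return A `delong_result` list: `auc_a`, `auc_b`, `z`, `p`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must have equal length")
  }
  pos <- labels == 1
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) stop("both classes must be present")
  comp <- function(scores) {
    x <- scores[pos]; y <- scores[!pos]
    psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  a <- comp(scores_a)
  b <- comp(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- a$auc - b$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      z <- 0; p <- 1
    } else {
      stop("degenerate zero variance with unequal AUCs; DeLong z is undefined")
    }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(auc_a = a$auc, auc_b = b$auc, z = z, p = p, var_diff = var_diff),
    class = "delong_result"
  )
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf(
    "<delong_result> AUC %.3f vs %.3f, z = %.3f, p = %.4g\n",
    x$auc_a, x$auc_b, x$z, x$p
  ))
  invisible(x)
}

conventional_variant_labels <- function() {
  c(alff = "alff_s_nogsr", falff = "falff_s_nogsr", reho = "reho_ns_nogsr",
    he = "he_s_nogsr", tsa = "tsa_s_nogsr")
}

#' Conventional single-index AUROC grid
#'
#' The conventional strategy: each of the five base parameters, in the broad
#' 0.01-0.1 Hz band without global regression, summarized per subregion, is
#' used directly as a classification score. Each index is oriented so its
#' AUROC is >= 0.5 (the direction is reported), giving the 5 x 3 heatmap of
#' single-index discriminative power.
#'
#' @param table Feature table with a `label` column containing the broad-band
#'   features.
#' @param broad_band_name Name of the broad band (default `"0.01-0.10"`).
#' @return A tibble with columns `index`, `roi`, `feature`, `auroc`,
#'   `direction` (+1/-1), sorted in index-major order; the best cell is in
#'   attribute `best`.
#' @export
conventional_auc_grid <- function(table, broad_band_name = "0.01-0.10") {
  if (!"label" %in% names(table)) stop("feature table has no 'label' column")
  if (length(unique(table$label)) < 2L) stop("endpoint has a single class")
  labs <- conventional_variant_labels()
  rows <- list()
  for (i in seq_along(labs)) {
    for (r in roi_names()) {
      feat <- paste(labs[i], broad_band_name, r, sep = "_")
      if (!feat %in% names(table)) stop("feature '", feat, "' not in table")
      x <- table[[feat]]
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      a <- auroc(x, table$label)
      dir <- if (!is.na(a) && a < 0.5) -1L else 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        index = names(labs)[i], roi = r, feature = feat,
        auroc = if (dir < 0) 1 - a else a, direction = dir
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  best <- out[which.max(out$auroc), ]
  attr(out, "best") <- best
  out
}

#' DeLong comparisons of the best conventional cell against the rest
#'
#' Pairs the best (index, ROI) cell with every other cell on the same
#' subjects and reports the raw two-sided DeLong p values next to the
#' Bonferroni-adjusted threshold for the 14 comparisons.
#'
#' @param table Feature table with `label`.
#' @param grid Result of [conventional_auc_grid()] (recomputed if missing).
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble of comparisons with attribute `bonferroni_threshold`.
#' @export
conventional_comparisons <- function(table, grid = NULL, alpha = 0.05) {
  if (is.null(grid)) grid <- conventional_auc_grid(table)
  best <- attr(grid, "best")
  oriented <- function(row) {
    x <- table[[row$feature]]
    x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    as.numeric(row$direction) * x
  }
  sa <- oriented(best)
  others <- grid[grid$feature != best$feature, ]
  rows <- lapply(seq_len(nrow(others)), function(i) {
    dl <- delong_test(sa, oriented(others[i, ]), table$label)
    tibble::tibble(
      best_index = best$index, best_roi = best$roi,
      index = others$index[i], roi = others$roi[i],
      auc_best = dl$auc_a, auc_other = dl$auc_b, z = dl$z, p = dl$p
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "bonferroni_threshold") <- alpha / nrow(out)
  out
}
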