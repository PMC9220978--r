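#' Stratified train/test split
#'
#' Splits a feature table into training and testing sets stratified by
#' `label`. The training size is `round(train_fraction * n)` overall, with
#' per-class counts allocated by largest remainder, so 176 subjects at 0.7
#' give 123 training and 53 testing subjects.
#'
#' @param table Feature table with a `label` column.
#' @param train_fraction Fraction of subjects in the training set (0, 1).
#' @param seed Integer seed; the split is seed-deterministic.
#' @return A list with tibbles `train` and `test`.
#' @export
split_dataset <- function(table, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!"label" %in% names(table)) stop("feature table has no 'label' column")
  y <- table$label
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("both classes must be present to split")
  n <- nrow(table)
  n_train <- round(train_fraction * n)
  cls_n <- vapply(classes, function(cl) sum(y == cl), integer(1))
  exact <- train_fraction * cls_n
  base <- floor(exact)
  rem <- n_train - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  } else if (rem < 0) {
    cut <- order(exact - base, decreasing = FALSE)[seq_len(-rem)]
    base[cut] <- base[cut] - 1L
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train_idx <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(y == classes[i])
    if (base[i] < 1L || base[i] >= length(idx)) {
      stop("class ", classes[i], " would be absent from one side of the split")
    }
    train_idx <- c(train_idx, sample(idx, base[i]))
  }
  train_idx <- sort(train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[-train_idx, , drop = FALSE])
}

# Spearman correlation that tolerates constant columns (returns 0, not NA)
safe_spearman <- function(x, y = NULL) {
  r <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  r[is.na(r)] <- 0
  r
}

#' Greedy Spearman redundancy filter
#'
#' Features are visited in decreasing |Spearman correlation with the label|
#' (ties by column order); a feature is dropped when its |Spearman rho| with
#' any already-retained feature exceeds `threshold`. No retained pair exceeds
#' the threshold, and of any redundant group the member most correlated with
#' the endpoint survives. Constant features get label-correlation 0.
#'
#' @param train Training feature table with a `label` column.
#' @param threshold Absolute rank-correlation threshold (default 0.9).
#' @return Character vector of retained feature names (in visit order).
#' @export
spearman_redundancy_filter <- function(train, threshold = 0.9) {
  feats <- feature_columns(train)
  if (length(feats) < 2L) return(feats)
  x <- as.matrix(train[, feats, drop = FALSE])
  x <- impute_median(x, colMedians(x))  # rank correlations need complete columns
  lab_cor <- abs(as.vector(safe_spearman(x, train$label)))
  ord <- order(-lab_cor)  # stable: ties keep column order
  rho <- abs(safe_spearman(x))
  retained <- integer(0)
  for (j in ord) {
    if (length(retained) == 0L || all(rho[j, retained] <= threshold)) {
      retained <- c(retained, j)
    }
  }
  feats[retained]
}

colMedians <- function(x) apply(x, 2, stats::median, na.rm = TRUE)

impute_median <- function(x, med) {
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

# one-way ANOVA F statistic per column for a binary grouping
f_statistic <- function(x, y) {
  y <- as.integer(y)
  n <- nrow(x)
  g1 <- y == 1L
  n1 <- sum(g1); n0 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m0 <- colMeans(x[!g1, , drop = FALSE])
  gm <- colMeans(x)
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ssw <- colSums(sweep(x[g1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(x[!g1, , drop = FALSE], 2, m0)^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw == 0 & ssb == 0] <- 0
  f[ssw == 0 & ssb > 0] <- Inf
  f
}

#' Select features on a training set
#'
#' Three methods: `"f_test"` ranks features by the one-way ANOVA F statistic
#' between classes and keeps the top `k`; `"l1_linear"` keeps the features
#' with non-zero coefficients of an L1-penalized logistic model at penalty
#' strength `C` (lambda = 1/(n C)); `"tree"` keeps features whose
#' impurity-based random-forest importance exceeds the mean importance.
#'
#' @param train Training feature table with labels (fit on training data
#'   only).
#' @param method `"f_test"`, `"l1_linear"` or `"tree"`.
#' @param k Number of features kept by `f_test` (clipped with a warning).
#' @param C L1 penalty strength for `l1_linear`.
#' @param num_trees,seed Random-forest settings for `tree`.
#' @return Character vector of selected feature names.
#' @export
select_features <- function(train, method = c("f_test", "l1_linear", "tree"),
                            k = 30L, C = 1, num_trees = 300L, seed = 1L) {
  method <- match.arg(method)
  feats <- feature_columns(train)
  x <- as.matrix(train[, feats, drop = FALSE])
  x <- impute_median(x, colMedians(x))
  y <- train$label
  switch(method,
    f_test = {
      if (k > length(feats)) {
        warning("k = ", k, " exceeds the ", length(feats),
                " available features; clipping")
        k <- length(feats)
      }
      f <- f_statistic(x, y)
      feats[order(-f)[seq_len(k)]]
    },
    l1_linear = {
      xs <- scale_fit_apply(x)
      fit <- suppressWarnings(  # glmnet small-class note in tiny CV folds
        glmnet::glmnet(xs, factor(y), family = "binomial", alpha = 1,
                       lambda = 1 / (nrow(x) * C), standardize = FALSE)
      )
      beta <- as.vector(fit$beta)
      sel <- feats[beta != 0]
      if (length(sel) == 0L) {
        stop("the L1 penalty at C = ", C,
             " shrank every coefficient to zero; increase C")
      }
      sel
    },
    tree = {
      fit <- ranger::ranger(
        x = x, y = factor(y), num.trees = num_trees, importance = "impurity",
        seed = seed, num.threads = 1
      )
      imp <- fit$variable.importance
      feats[imp > mean(imp)]
    }
  )
}

scale_fit <- function(x) {
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  list(center = ctr, scale = sds)
}

scale_apply <- function(x, sc) sweep(sweep(x, 2, sc$center), 2, sc$scale, "/")

scale_fit_apply <- function(x) scale_apply(x, scale_fit(x))

#' Default hyperparameter grids
#'
#' Small standard grids: `C` in 10^(-2..2) for the linear models and the SVM
#' (the SVM adds RBF `gamma` in scale, 0.01, 0.001, where "scale" means
#' 1/(p Var(x))); the random forest searches trees in 100/300/500 and depth
#' in 3/5/unlimited.
#'
#' @param classifier One of `"lr"`, `"svm"`, `"rf"`, `"linear_svc"`.
#' @return A tibble, one row per grid point.
#' @export
default_grid <- function(classifier = c("lr", "svm", "rf", "linear_svc")) {
  classifier <- match.arg(classifier)
  cs <- c(0.01, 0.1, 1, 10, 100)
  switch(classifier,
    lr = tibble::tibble(C = cs),
    linear_svc = tibble::tibble(C = cs),
    svm = tidyr::expand_grid(C = cs, gamma = c("scale", "0.01", "0.001")),
    rf = tidyr::expand_grid(num_trees = c(100L, 300L, 500L),
                            max_depth = c(3L, 5L, 0L))
  )
}

classifier_names <- function() c("lr", "svm", "rf", "linear_svc")
selector_names <- function() c("f_test", "l1_linear", "tree")

needs_scaling <- function(classifier) classifier %in% c("lr", "svm", "linear_svc")

resolve_gamma <- function(gamma, x) {
  if (identical(gamma, "scale")) 1 / (ncol(x) * mean(apply(x, 2, stats::var)))
  else as.numeric(gamma)
}

# fit one classifier; returns a closure-free object usable by predict_scores
fit_classifier <- function(x, y, classifier, params, seed = 1L) {
  y <- as.integer(y)
  obj <- list(classifier = classifier, params = params, features = colnames(x))
  if (classifier == "lr") {
    xx <- if (ncol(x) == 1L) cbind(x, .pad = 0) else x
    fit <- suppressWarnings(  # glmnet small-class note in tiny CV folds
      glmnet::glmnet(xx, factor(y), family = "binomial", alpha = 0,
                     lambda = 1 / (nrow(x) * params$C), standardize = FALSE)
    )
    obj$fit <- fit
    obj$padded <- ncol(x) == 1L
  } else if (classifier %in% c("svm", "linear_svc")) {
    kernel <- if (classifier == "svm") "radial" else "linear"
    gamma <- if (classifier == "svm") resolve_gamma(params$gamma, x) else 1 / ncol(x)
    fit <- e1071::svm(x = x, y = factor(y, levels = c(0, 1)), kernel = kernel,
                      cost = params$C, gamma = gamma, scale = FALSE)
    dv <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")
    obj$fit <- fit
    # e1071 labels the decision column "a/b": positive values vote for class a
    obj$flip <- !startsWith(colnames(dv)[1], "1")
  } else if (classifier == "rf") {
    depth <- params$max_depth
    fit <- ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$num_trees,
      max.depth = if (depth == 0L) NULL else depth,
      importance = "impurity", seed = seed, num.threads = 1
    )
    obj$fit <- fit
  } else {
    stop("unknown classifier '", classifier, "'; valid names: ",
         paste(classifier_names(), collapse = ", "))
  }
  obj
}

predict_scores <- function(obj, x) {
  if (obj$classifier == "lr") {
    xx <- if (isTRUE(obj$padded)) cbind(x, .pad = 0) else x
    as.vector(stats::predict(obj$fit, xx, type = "response"))
  } else if (obj$classifier %in% c("svm", "linear_svc")) {
    dv <- attr(stats::predict(obj$fit, x, decision.values = TRUE),
               "decision.values")[, 1]
    if (obj$flip) dv <- -dv
    stats::plogis(dv)
  } else {
    stats::predict(obj$fit, data = as.data.frame(x))$predictions[, "1"]
  }
}

# model-agnostic permutation importance (training-set AUROC drop), used for
# kernel models that expose no native coefficients
permutation_importance <- function(obj, x, y, n_perm = 10L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  base <- auroc(predict_scores(obj, x), y)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    drop <- vapply(seq_len(n_perm), function(b) {
      xp <- x
      xp[, j] <- sample(xp[, j])
      base - auroc(predict_scores(obj, xp), y)
    }, numeric(1))
    mean(drop)
  }, numeric(1))
  tibble::tibble(feature = colnames(x), importance = pmax(imp, 0))
}

classifier_importance <- function(obj) {
  if (obj$classifier == "rf") {
    imp <- obj$fit$variable.importance
    tibble::tibble(feature = names(imp), importance = unname(imp))
  } else if (obj$classifier == "lr") {
    beta <- as.vector(obj$fit$beta)
    nm <- rownames(obj$fit$beta)
    keep <- nm != ".pad"
    tibble::tibble(feature = nm[keep], importance = abs(beta[keep]))
  } else if (obj$classifier == "linear_svc") {
    w <- as.vector(t(obj$fit$coefs) %*% obj$fit$SV)
    if (obj$flip) w <- -w
    tibble::tibble(feature = obj$features, importance = abs(w))
  } else {
    tibble::tibble(feature = obj$features, importance = NA_real_)
  }
}

#' Model configuration
#'
#' One (feature selector, classifier, hyperparameter grid) combination with
#' its cross-validation settings.
#'
#' @param selector `"f_test"`, `"l1_linear"` or `"tree"`.
#' @param classifier `"lr"`, `"svm"`, `"rf"` or `"linear_svc"`.
#' @param grid Tibble of hyperparameter points; default [default_grid()].
#' @param selector_params List of selector settings (`k`, `C`, `num_trees`).
#' @param cv_folds Cross-validation folds (>= 2; default 5).
#' @param redundancy_threshold Spearman redundancy threshold (default 0.9).
#' @return A `model_config` object.
#' @export
model_config <- function(selector = "f_test", classifier = "lr",
                         grid = default_grid(classifier),
                         selector_params = list(k = 30L, C = 1, num_trees = 300L),
                         cv_folds = 5L, redundancy_threshold = 0.9) {
  selector <- match.arg(selector, selector_names())
  classifier <- match.arg(classifier, classifier_names())
  if (nrow(grid) == 0L) stop("hyperparameter grid is empty")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  structure(
    list(selector = selector, classifier = classifier, grid = grid,
         selector_params = selector_params, cv_folds = as.integer(cv_folds),
         redundancy_threshold = redundancy_threshold),
    class = "model_config"
  )
}

stratified_folds <- function(y, k, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

f1_score <- function(pred, y) {
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# train-only preprocessing chain: impute -> redundancy filter -> select -> scale
fit_pipeline <- function(train, config, seed) {
  feats <- feature_columns(train)
  x <- as.matrix(train[, feats, drop = FALSE])
  med <- colMedians(x)
  ximp <- impute_median(x, med)
  timp <- train
  timp[feats] <- as.data.frame(ximp)
  retained <- spearman_redundancy_filter(timp, config$redundancy_threshold)
  sp <- config$selector_params
  selected <- select_features(
    timp[, c("label", retained)], method = config$selector,
    k = sp$k %||% 30L, C = sp$C %||% 1, num_trees = sp$num_trees %||% 300L,
    seed = seed
  )
  xsel <- ximp[, selected, drop = FALSE]
  sc <- if (needs_scaling(config$classifier)) scale_fit(xsel) else NULL
  list(medians = med, retained = retained, selected = selected, scaling = sc)
}

apply_pipeline <- function(pipe, table, classifier) {
  feats <- feature_columns(table)
  x <- as.matrix(table[, feats, drop = FALSE])
  x <- impute_median(x, pipe$medians[feats])
  x <- x[, pipe$selected, drop = FALSE]
  if (!is.null(pipe$scaling)) x <- scale_apply(x, pipe$scaling)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exhaustive grid search with stratified cross-validated F1
#'
#' For every grid point, the mean F1 score (at the 0.5 score threshold) over
#' `cv_folds` stratified folds is computed; imputation, the redundancy
#' filter, feature selection and scaling are refit inside each fold on the
#' training part only. The best point (ties broken by first-in-grid order) is
#' refit on the full training set.
#'
#' @param train Training feature table with a `label` column.
#' @param config A [model_config].
#' @param seed Integer seed for fold assignment and tree fitting.
#' @return A `trained_model` with the fitted pipeline, classifier, selected
#'   features, per-point CV results and importance ranking.
#' @export
grid_search_cv <- function(train, config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  y <- train$label
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  fold <- stratified_folds(y, config$cv_folds, seed)
  for (f in seq_len(config$cv_folds)) {
    if (length(unique(y[fold != f])) < 2L || length(unique(y[fold == f])) < 2L) {
      stop("fold ", f, " lacks both classes; use fewer folds")
    }
  }
  grid <- config$grid
  cv_f1 <- matrix(NA_real_, nrow(grid), config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- train[fold != f, , drop = FALSE]
    va <- train[fold == f, , drop = FALSE]
    pipe <- fit_pipeline(tr, config, seed)
    xtr <- apply_pipeline(pipe, tr, config$classifier)
    xva <- apply_pipeline(pipe, va, config$classifier)
    for (g in seq_len(nrow(grid))) {
      fit <- fit_classifier(xtr, tr$label, config$classifier,
                            as.list(grid[g, ]), seed = seed)
      scores <- predict_scores(fit, xva)
      cv_f1[g, f] <- f1_score(as.integer(scores >= 0.5), va$label)
    }
  }
  mean_f1 <- rowMeans(cv_f1)
  best <- which.max(mean_f1)  # first max = first-in-grid tie-break
  pipe <- fit_pipeline(train, config, seed)
  xtr <- apply_pipeline(pipe, train, config$classifier)
  fit <- fit_classifier(xtr, train$label, config$classifier,
                        as.list(grid[best, ]), seed = seed)
  imp <- classifier_importance(fit)
  if (all(is.na(imp$importance))) {
    # RBF kernels have no native coefficients: fall back to permutation
    # importance measured on the training set
    imp <- permutation_importance(fit, xtr, train$label, seed = seed)
  }
  imp <- imp[order(-imp$importance), ]
  structure(
    list(config = config, pipeline = pipe, fit = fit,
         best_params = as.list(grid[best, ]),
         cv_results = dplyr::mutate(grid, mean_f1 = mean_f1),
         selected_features = pipe$selected,
         importance = imp, seed = seed),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> %s + %s, %d features, best CV F1 = %.3f\n",
    x$config$selector, x$config$classifier, length(x$selected_features),
    max(x$cv_results$mean_f1)
  ))
  invisible(x)
}

#' Predict scores for new subjects
#' @param object A `trained_model`.
#' @param newdata Feature table.
#' @param ... Unused.
#' @return Numeric scores in \[0, 1\].
#' @export
predict.trained_model <- function(object, newdata, ...) {
  x <- apply_pipeline(object$pipeline, newdata, object$config$classifier)
  predict_scores(object$fit, x)
}

#' AUROC by the Mann-Whitney rank identity
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1).
#' @return AUROC in \[0, 1\]; `NA` when a class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integration)
#'
#' Average-precision form: thresholds descend through the distinct scores and
#' each recall increment is weighted by the precision at that threshold (no
#' trapezoidal interpolation).
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\]; `NA` when no positives are present.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0) return(NA_real_)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)  # threshold at each distinct score
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate a trained model on a held-out test set
#'
#' AUROC by the rank identity, AUPRC by step integration, and accuracy,
#' sensitivity, specificity and F1 at the 0.5 score threshold. With a
#' single-class test set the AUROC is reported missing and the threshold
#' metrics are still computed.
#'
#' @param model A `trained_model`.
#' @param test Test feature table (disjoint from training).
#' @return An `eval_report` list with the six metrics, the scores, the
#'   selected features, and the importance ranking.
#' @export
evaluate <- function(model, test) {
  scores <- stats::predict(model, test)
  y <- as.integer(test$label)
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(
    list(
      auroc = auroc(scores, y),
      auprc = auprc(scores, y),
      acc = (tp + tn) / length(y),
      sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      f1 = f1_score(pred, y),
      scores = scores, labels = y,
      selected_features = model$selected_features,
      importance = model$importance
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> AUROC %.3f  AUPRC %.3f  ACC %.3f  SEN %.3f  SPE %.3f  F1 %.3f\n",
    x$auroc, x$auprc, x$acc, x$sen, x$spe, x$f1
  ))
  invisible(x)
}

#' Run the full benchmarking experiment
#'
#' Splits the table 7:3 (stratified), then runs every selector x classifier
#' combination through [grid_search_cv()] and [evaluate()]. The winning model
#' has the top test AUROC, ties broken by AUPRC then leaderboard order. The
#' importance ranking is model-native (impurity for forests, |coefficients|
#' for linear models).
#'
#' @param table Feature table with `label`.
#' @param selectors Subset of selectors to run.
#' @param classifiers Subset of classifiers to run.
#' @param grids Optional named list of hyperparameter grids per classifier.
#' @param selector_params Passed to each [model_config()].
#' @param train_fraction,cv_folds,redundancy_threshold Experiment settings.
#' @param seed Integer seed driving the split, folds and forests.
#' @return An `omics_experiment` with `leaderboard` (tibble), `winner`
#'   (`trained_model`), `winner_report` (`eval_report`), and the split.
#' @export
run_omics_experiment <- function(table,
                                 selectors = selector_names(),
                                 classifiers = classifier_names(),
                                 grids = NULL,
                                 selector_params = list(k = 30L, C = 1,
                                                        num_trees = 300L),
                                 train_fraction = 0.7, cv_folds = 5L,
                                 redundancy_threshold = 0.9, seed = 1L) {
  selectors <- match.arg(selectors, selector_names(), several.ok = TRUE)
  bad <- setdiff(classifiers, classifier_names())
  if (length(bad)) {
    stop("unknown classifier '", bad[1], "'; valid names: ",
         paste(classifier_names(), collapse = ", "))
  }
  split <- split_dataset(table, train_fraction, seed)
  rows <- list()
  best <- NULL
  for (sel in selectors) {
    for (clf in classifiers) {
      grid <- if (!is.null(grids) && !is.null(grids[[clf]])) grids[[clf]] else default_grid(clf)
      cfg <- model_config(sel, clf, grid = grid,
                          selector_params = selector_params,
                          cv_folds = cv_folds,
                          redundancy_threshold = redundancy_threshold)
      model <- grid_search_cv(split$train, cfg, seed = seed)
      rep <- evaluate(model, split$test)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        selector = sel, classifier = clf,
        n_selected = length(model$selected_features),
        cv_f1 = max(model$cv_results$mean_f1),
        auroc = rep$auroc, auprc = rep$auprc, acc = rep$acc,
        sen = rep$sen, spe = rep$spe, f1 = rep$f1
      )
      cand <- list(model = model, report = rep,
                   key = c(rep$auroc, rep$auprc))
      if (is.null(best) ||
          isTRUE(cand$key[1] > best$key[1]) ||
          (isTRUE(cand$key[1] == best$key[1]) && isTRUE(cand$key[2] > best$key[2]))) {
        best <- cand
      }
    }
  }
  leaderboard <- dplyr::bind_rows(rows)
  leaderboard <- dplyr::arrange(leaderboard, dplyr::desc(.data$auroc),
                                dplyr::desc(.data$auprc))
  structure(
    list(leaderboard = leaderboard, winner = best$model,
         winner_report = best$report, split = split, seed = seed),
    class = "omics_experiment"
  )
}

#' @export
print.omics_experiment <- function(x, ...) {
  cat("<omics_experiment> winner:", x$leaderboard$selector[1], "+",
      x$leaderboard$classifier[1],
      sprintf("(test AUROC %.3f, AUPRC %.3f)\n",
              x$leaderboard$auroc[1], x$leaderboard$auprc[1]))
  print(x$leaderboard, n = 6)
  invisible(x)
}
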