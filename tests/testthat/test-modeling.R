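test_that("the stratified split reproduces the 123/53 partition of 176 subjects", {
  tab <- random_feature_table(176, feature_names()[1:5], seed = 50,
                              balance = 63 / 176)  # low-grade fraction
  sp <- split_dataset(tab, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 123L)
  expect_equal(nrow(sp$test), 53L)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0L)
  # stratification: class fractions preserved to rounding
  expect_equal(sum(sp$train$label), round(0.7 * sum(tab$label)), tolerance = 1)
  # determinism
  sp2 <- split_dataset(tab, 0.7, seed = 1)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  sp3 <- split_dataset(tab, 0.7, seed = 2)
  expect_false(identical(sp$train$subject_id, sp3$train$subject_id))
})

test_that("small balanced splits keep both classes on both sides", {
  tab <- random_feature_table(10, feature_names()[1:3], seed = 51, balance = 0.5)
  sp <- split_dataset(tab, 0.7, seed = 3)
  expect_equal(nrow(sp$train), 7L)
  expect_setequal(unique(sp$train$label), c(0, 1))
  expect_setequal(unique(sp$test$label), c(0, 1))
  tab$label <- 1L
  expect_error(split_dataset(tab, 0.7), "classes")
})

test_that("the greedy Spearman filter keeps the more label-correlated of identical twins", {
  set.seed(52)
  n <- 60
  lab <- rep(0:1, each = n / 2)
  strong <- rnorm(n) + 1.5 * lab
  tab <- tibble::tibble(
    subject_id = as.character(1:n), label = lab,
    weak_copy = strong + rnorm(n, sd = 1e-6),  # near-identical, same info
    strong = strong,
    indep = rnorm(n)
  )
  kept <- spearman_redundancy_filter(tab, threshold = 0.9)
  expect_true("indep" %in% kept)
  expect_equal(sum(c("strong", "weak_copy") %in% kept), 1L)
  # mutually independent features all survive
  tab2 <- random_feature_table(80, feature_names()[1:6], seed = 53)
  expect_length(spearman_redundancy_filter(tab2, 0.9), 6L)
  # constant features never crash
  tab2$const <- 1
  expect_silent(spearman_redundancy_filter(tab2, 0.9))
})

test_that("the greedy filter matches a hand-evaluated pass on a known correlation graph", {
  # five features built so that (f1,f2) and (f1,f3) are redundant pairs while
  # f4, f5 are independent; f1 is the most label-correlated
  set.seed(54)
  n <- 400
  lab <- rep(0:1, each = n / 2)
  base <- rnorm(n)
  f1 <- base + 1.0 * lab
  f2 <- f1 + rnorm(n, sd = 0.05)
  f3 <- -f1 + rnorm(n, sd = 0.05)
  f4 <- rnorm(n) + 0.3 * lab
  f5 <- rnorm(n)
  tab <- tibble::tibble(subject_id = as.character(1:n), label = lab,
                        f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5)
  # independent re-implementation of the stated greedy definition
  x <- as.matrix(tab[, c("f1", "f2", "f3", "f4", "f5")])
  labcor <- abs(apply(x, 2, function(col) cor(col, lab, method = "spearman")))
  ord <- order(-labcor)
  rho <- abs(cor(x, method = "spearman"))
  kept_oracle <- integer(0)
  for (j in ord) {
    if (!length(kept_oracle) || all(rho[j, kept_oracle] <= 0.9)) {
      kept_oracle <- c(kept_oracle, j)
    }
  }
  expect_setequal(spearman_redundancy_filter(tab, 0.9),
                  colnames(x)[kept_oracle])
})

test_that("f_test ranks a strongly shifted feature first in almost every cohort", {
  hits <- 0L
  for (i in 1:100) {
    tab <- random_feature_table(40, feature_names()[1:20], seed = 1000 + i)
    planted <- names(tab)[3]
    tab[[planted]] <- tab[[planted]] + 2 * tab$label
    top <- select_features(tab, "f_test", k = 1)
    hits <- hits + (top == planted)
  }
  expect_gte(hits, 95L)
})

test_that("selector edge cases behave as documented", {
  tab <- random_feature_table(40, feature_names()[1:10], seed = 55)
  tab[[3]] <- tab[[3]] + 2 * tab$label
  expect_error(select_features(tab, "l1_linear", C = 1e-6), "increase C")
  expect_setequal(select_features(tab, "f_test", k = 10), feature_names()[1:10])
  expect_warning(sel <- select_features(tab, "f_test", k = 99), "clipping")
  expect_length(sel, 10L)
  sel_tree <- select_features(tab, "tree", seed = 2)
  expect_true(length(sel_tree) >= 1 && length(sel_tree) < 10)
})

test_that("a one-point grid equals a direct fit and separable data reach CV F1 of 1", {
  tab <- random_feature_table(40, feature_names()[1:8], seed = 56)
  tab[[3]] <- tab[[3]] + 10 * tab$label  # separable
  cfg <- model_config("f_test", "lr", grid = tibble::tibble(C = 1),
                      selector_params = list(k = 4))
  m <- grid_search_cv(tab, cfg, seed = 9)
  expect_equal(nrow(m$cv_results), 1L)
  expect_equal(max(m$cv_results$mean_f1), 1)
  # direct fit on the same pipeline output gives identical test scores
  pipe <- boldomics:::fit_pipeline(tab, cfg, seed = 9)
  x <- boldomics:::apply_pipeline(pipe, tab, "lr")
  direct <- boldomics:::fit_classifier(x, tab$label, "lr", list(C = 1), seed = 9)
  expect_equal(stats::predict(m, tab), boldomics:::predict_scores(direct, x),
               tolerance = 1e-10)
})

test_that("grid search prefers an informative point over one regularized to chance", {
  tab <- random_feature_table(60, feature_names()[1:8], seed = 57)
  tab[[3]] <- tab[[3]] + 3 * tab$label
  cfg <- model_config("f_test", "lr", grid = tibble::tibble(C = c(1e-9, 1)),
                      selector_params = list(k = 4))
  m <- grid_search_cv(tab, cfg, seed = 10)
  expect_equal(m$best_params$C, 1)
})

test_that("folds that lose a class are rejected with guidance", {
  tab <- random_feature_table(12, feature_names()[1:4], seed = 58, balance = 1 / 3)
  cfg <- model_config("f_test", "lr", cv_folds = 5L,
                      selector_params = list(k = 2))
  expect_error(grid_search_cv(tab, cfg, seed = 1), "folds")
})

test_that("evaluation metrics follow their definitions", {
  # perfect scores
  rep0 <- list(scores = c(0, 0, 1, 1))
  y <- c(0, 0, 1, 1)
  expect_equal(auroc(rep0$scores, y), 1)
  expect_equal(auprc(rep0$scores, y), 1)
  # the 4-sample worked example, against exhaustive pair counting
  s4 <- c(.1, .4, .35, .8)
  expect_equal(auroc(s4, y), 0.75)
  expect_equal(auroc(s4, y), oracle_auc_pairs(s4, y))
  # label-independent scores are at chance
  set.seed(59)
  s <- runif(2000); yy <- rbinom(2000, 1, 0.5)
  expect_equal(auroc(s, yy), 0.5, tolerance = 0.03)
})

test_that("the rank-formula AUROC equals pair counting on many small inputs with ties", {
  set.seed(60)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    expect_equal(auroc(s, y), oracle_auc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("AUPRC performs step integration over distinct thresholds", {
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.1)
  # thresholds .9, .8, .7, .1 -> recall steps 1/2 @P=1, 0, 1/2 @P=2/3, 0
  expect_equal(auprc(s, y), 0.5 * 1 + 0.5 * (2 / 3))
  # tied scores collapse into one threshold
  expect_equal(auprc(c(.5, .5, .5, .5), y), 0.5)
})

test_that("evaluate reports the threshold metrics and handles one-class tests", {
  tab <- random_feature_table(60, feature_names()[1:6], seed = 61)
  tab[[3]] <- tab[[3]] + 5 * tab$label
  sp <- split_dataset(tab, 0.7, seed = 4)
  cfg <- model_config("f_test", "lr", grid = tibble::tibble(C = 1),
                      selector_params = list(k = 3))
  m <- grid_search_cv(sp$train, cfg, seed = 4)
  rep <- evaluate(m, sp$test)
  expect_true(all(unlist(rep[c("auroc", "auprc", "acc", "sen", "spe", "f1")]) >= 0))
  # sen/spe consistent with the confusion matrix at 0.5
  pred <- as.integer(rep$scores >= 0.5)
  expect_equal(rep$sen, sum(pred == 1 & rep$labels == 1) / sum(rep$labels == 1))
  expect_equal(rep$spe, sum(pred == 0 & rep$labels == 0) / sum(rep$labels == 0))
  one_class <- sp$test[sp$test$label == 1, ]
  rep1 <- evaluate(m, one_class)
  expect_true(is.na(rep1$auroc))
  expect_false(is.na(rep1$acc))
})

test_that("no training statistic leaks from the test set", {
  tab <- random_feature_table(60, feature_names()[1:12], seed = 62)
  tab[[4]] <- tab[[4]] + 2 * tab$label
  sp <- split_dataset(tab, 0.7, seed = 11)
  cfg <- model_config("f_test", "lr", selector_params = list(k = 5))
  m1 <- grid_search_cv(sp$train, cfg, seed = 11)
  # corrupt the held-out rows wholesale; the fitted pipeline must not notice
  corrupted <- sp$test
  corrupted[, -(1:2)] <- corrupted[, -(1:2)] * 100 + 7
  m2 <- grid_search_cv(sp$train, cfg, seed = 11)
  expect_identical(m1$selected_features, m2$selected_features)
  expect_identical(m1$pipeline$medians, m2$pipeline$medians)
  expect_equal(stats::predict(m1, sp$train), stats::predict(m2, sp$train))
})

test_that("the experiment loop is seed-reproducible and rejects unknown classifiers", {
  tab <- random_feature_table(50, feature_names()[1:15], seed = 63)
  tab[[3]] <- tab[[3]] + 2.5 * tab$label
  e1 <- run_omics_experiment(tab, selectors = "f_test",
                             classifiers = c("lr", "rf"),
                             selector_params = list(k = 5), seed = 21)
  e2 <- run_omics_experiment(tab, selectors = "f_test",
                             classifiers = c("lr", "rf"),
                             selector_params = list(k = 5), seed = 21)
  expect_equal(e1$leaderboard, e2$leaderboard)
  expect_error(
    run_omics_experiment(tab, classifiers = "boost"),
    "lr, svm, rf, linear_svc"
  )
})

test_that("tidiers expose leaderboards, metrics and parsed importances", {
  tab <- random_feature_table(50, feature_names()[1:15], seed = 64)
  tab[[3]] <- tab[[3]] + 3 * tab$label
  e <- run_omics_experiment(tab, selectors = "f_test", classifiers = "rf",
                            grids = list(rf = tibble::tibble(num_trees = 100L,
                                                             max_depth = 3L)),
                            selector_params = list(k = 5), seed = 22)
  expect_s3_class(tidy(e), "tbl_df")
  expect_equal(nrow(glance(e)), 1L)
  ti <- tidy(e$winner)
  expect_true(all(c("feature", "importance", "base", "band", "roi") %in% names(ti)))
  gl <- glance(e$winner_report)
  expect_true(all(gl >= 0 & gl <= 1, na.rm = TRUE))
  expect_equal(tidy(e$winner_report)$metric,
               c("auroc", "auprc", "acc", "sen", "spe", "f1"))
})
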