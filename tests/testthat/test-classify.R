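test_that("MCC matches the closed formula and its zero conventions", {
  expect_equal(compute_mcc(10, 0, 10, 0), 1.0)
  expect_equal(compute_mcc(5, 5, 5, 5), 0.0)
  expect_equal(compute_mcc(0, 0, 10, 10), 0.0)  # empty predicted-positive
  tp <- 38; fp <- 1; tn <- 47; fn <- 2
  expect_equal(compute_mcc(tp, fp, tn, fn),
               (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
})

test_that("evaluation report: rates, weighting, pooled confusion", {
  truth <- rep(c("TD", "ASD"), c(10, 14))
  pred <- truth
  pred[1] <- "ASD"          # one TD subject misclassified
  pred[c(11, 12)] <- "TD"   # two ASD subjects misclassified
  set.seed(51)
  score <- ifelse(truth == "ASD", 0.8, 0.2) + rnorm(24, 0, 0.05)
  rep <- evaluation_report(truth, pred, score)
  expect_equal(sum(attr(rep, "confusion")), 24)
  td <- rep[rep$class == "TD", ]
  expect_equal(td$tp_rate, 9 / 10)
  expect_equal(td$fp_rate, 2 / 14)
  w <- rep[rep$class == "Weighted Avg.", ]
  expect_equal(w$recall,
               (10 * rep$recall[rep$class == "TD"] +
                  14 * rep$recall[rep$class == "ASD"]) / 24)
  expect_equal(attr(rep, "accuracy"), 21 / 24)
  # balanced classes with equal per-class values: weighted equals per-class
  rep2 <- evaluation_report(rep(c("TD", "ASD"), 8),
                            rep(c("TD", "ASD"), 8),
                            rep(c(0.1, 0.9), 8))
  expect_equal(rep2$f_measure, rep(1, 3))
})

test_that("trapezoid ROC area agrees with an independent implementation", {
  set.seed(52)
  truth <- sample(c("TD", "ASD"), 60, replace = TRUE)
  score <- ifelse(truth == "ASD", 0.6, 0.4) + rnorm(60, 0, 0.2)
  ours <- qeegnl:::roc_area_trapezoid(truth, score, "ASD")
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score, levels = c("TD", "ASD"),
    direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("the suite is deterministic and bookkeeps subsets x models", {
  ft <- synth_feature_table(10, informative = c("TE_C5", "RE_C1"),
                            shift = 3, seed = 53)
  subs <- list(a = c("TE_C5", "RE_C1", "LZC_C3"), b = c("TE_C5", "RE_C1"),
               c = c("RE_C2", "RE_C3"), d = c("TE_C5"))
  reps <- run_suite(ft, subsets = subs, folds = 5, seed = 9,
                    models = c("random_forest", "pruned_tree", "rep_tree",
                               "svm", "mlp"))
  expect_length(reps, 20)  # 4 subsets x 5 models
  for (r in reps) {
    preds <- attr(r, "predictions")
    expect_equal(nrow(preds), nrow(ft))       # pooled folds cover everyone
    expect_equal(sum(attr(r, "confusion")), nrow(ft))
  }
  reps2 <- run_suite(ft, subsets = subs["a"], folds = 5, seed = 9,
                     models = c("random_forest", "mlp"))
  expect_identical(attr(reps2[["random_forest.a"]], "predictions"),
                   attr(reps[["random_forest.a"]], "predictions"))
  expect_error(run_suite(ft, folds = 11), "folds")
})

test_that("separable data is classified perfectly by trees and SVM", {
  ft <- synth_feature_table(15, informative = "LZC_C15", shift = 8,
                            seed = 54)
  subs <- list(sep = c("LZC_C15", "RE_C1"))
  reps <- run_suite(ft, subsets = subs, folds = 10, seed = 2,
                    models = c("pruned_tree", "svm"))
  expect_equal(attr(reps[["pruned_tree.sep"]], "accuracy"), 1.0)
  expect_equal(attr(reps[["svm.sep"]], "accuracy"), 1.0)
})

test_that("tree rules expose root-to-leaf thresholds", {
  # depth-1 stump on a single planted feature
  ft <- synth_feature_table(15, informative = "LZC_C15", shift = 8,
                            seed = 55)
  tree <- fit_decision_tree(ft, seed = 1)
  rules <- extract_tree_rules(tree)
  expect_length(rules, sum(tree$frame$var == "<leaf>"))
  expect_true(all(vapply(rules, function(r) all(r$path$feature == "LZC_C15"),
                         TRUE)))
  expect_equal(sum(vapply(rules, `[[`, 0, "support")), nrow(ft))

  # planted two-feature AND structure: thresholds recovered near 0
  set.seed(56)
  n <- 120
  tab <- synth_feature_table(n / 2, seed = 56)
  tab$group <- ifelse(tab$RE_C1 > 0 & tab$TE_C5 > 0, "ASD", "TD")
  tree2 <- fit_decision_tree(tab, seed = 1)
  rules2 <- extract_tree_rules(tree2)
  feats <- unique(unlist(lapply(rules2, function(r) r$path$feature)))
  expect_setequal(feats, c("RE_C1", "TE_C5"))
  thr <- unlist(lapply(rules2, function(r) r$path$threshold))
  expect_lt(max(abs(thr)), 0.5)

  expect_error(extract_tree_rules(lm(mpg ~ wt, mtcars)), "tree")
})
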