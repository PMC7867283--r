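test_that("stratified split keeps class proportions and is seeded", {
  lab <- toy_labeled(5, 5)
  sp <- stratified_split(lab, 0.8, seed = 3)
  expect_identical(table(sp$train$label)[["active"]], 4L)
  expect_identical(table(sp$train$label)[["inactive"]], 4L)
  expect_identical(nrow(sp$test), 2L)
  expect_setequal(c(sp$train$compound_id, sp$test$compound_id), lab$compound_id)
  expect_length(intersect(sp$train$compound_id, sp$test$compound_id), 0)

  sp2 <- stratified_split(lab, 0.8, seed = 3)
  expect_identical(sp$test$compound_id, sp2$test$compound_id)

  big <- toy_labeled(91, 75)
  spb <- stratified_split(big, 0.8, seed = 1)
  expect_identical(table(spb$test$label)[["active"]], 18L)
  expect_identical(table(spb$test$label)[["inactive"]], 15L)

  single <- lab[lab$label == "active", ]
  expect_error(stratified_split(single, 0.8, seed = 1), "both classes")
  expect_error(stratified_split(lab, 0.95, seed = 1), "empty")
})

test_that("forest training is reproducible and separates strong signal", {
  lab <- toy_labeled(40, 40)
  m <- toy_descriptors(lab, shift = 3)
  f1 <- train_forest(m, lab$label, n_trees = 100, seed = 9)
  f2 <- train_forest(m, lab$label, n_trees = 100, seed = 9)
  expect_equal(predict_activity(f1, m), predict_activity(f2, m))

  train_report <- evaluate_classifier(f1, m, lab$label)
  expect_equal(train_report$accuracy, 1.0)

  expect_error(train_forest(m, lab$label[-1]), "misaligned")
  expect_error(train_forest(m, lab$label, n_trees = 0), "positive")
})

test_that("constant descriptor columns are dropped with a warning", {
  lab <- toy_labeled(10, 10)
  m <- cbind(toy_descriptors(lab, shift = 2), flat = rep(1, 20))
  expect_warning(model <- train_forest(m, lab$label, n_trees = 50, seed = 1),
                 "flat")
  expect_false("flat" %in% model$features)
  # prediction works on data still carrying the constant column
  expect_length(predict_activity(model, m), 20)
})

test_that("Matthews correlation matches hand-computed confusion matrices", {
  expect_equal(round(matthews_cc(tp = 76, fp = 24, tn = 76, fn = 24), 2), 0.52)
  expect_equal(round(matthews_cc(tp = 76, fp = 29, tn = 71, fn = 24), 2), 0.47)
  expect_equal(matthews_cc(tp = 10, fp = 0, tn = 10, fn = 0), 1.0)
  expect_equal(matthews_cc(tp = 0, fp = 10, tn = 0, fn = 10), -1.0)
  expect_equal(matthews_cc(tp = 5, fp = 5, tn = 0, fn = 0), 0) # zero marginal
  expect_error(matthews_cc(0, 0, 0, 0), "zero")
  expect_error(matthews_cc(-1, 2, 3, 4), "non-negative")
})

test_that("evaluation handles perfect and degenerate probability vectors", {
  lab <- factor(rep(c("active", "inactive"), each = 4),
                levels = c("inactive", "active"))
  perfect <- performance_report(
    confusion_counts(lab, c(rep(1, 4), rep(0, 4))),
    auc = compute_roc(c(rep(1, 4), rep(0, 4)), lab)$auc)
  for (metric in c("sensitivity", "specificity", "accuracy", "ppv", "npv",
                   "mcc", "auc")) {
    expect_equal(perfect[[metric]], 1.0)
  }

  flat <- performance_report(confusion_counts(lab, rep(0.5, 8)))
  expect_equal(flat$mcc, 0)
  expect_true(min(flat$sensitivity, flat$specificity) <= 0.5)
})

test_that("ROC pair counting matches brute force and the trapezoid", {
  lab4 <- factor(c("active", "active", "inactive", "inactive"),
                 levels = c("inactive", "active"))
  roc <- compute_roc(c(0.9, 0.6, 0.6, 0.2), lab4)
  expect_equal(roc$auc, 0.875)

  expect_equal(compute_roc(c(4, 3, 2, 1), lab4)$auc, 1.0)
  expect_equal(compute_roc(c(1, 2, 3, 4), lab4)$auc, 0.0)

  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:15, 1)
    labels <- factor(sample(c("active", "inactive"), n, replace = TRUE),
                     levels = c("inactive", "active"))
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # forces ties
    r <- compute_roc(scores, labels)
    expect_equal(r$auc, pairwise_auc(scores, labels), tolerance = 1e-12)
    expect_equal(r$auc, trapezoid_auc(r$curve), tolerance = 1e-9)
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  }

  expect_error(compute_roc(1:3, factor(rep("active", 3),
                                       levels = c("inactive", "active"))),
               "both classes")
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- factor(sample(c("active", "inactive"), 60, replace = TRUE),
                   levels = c("inactive", "active"))
  scores <- rnorm(60) + (labels == "active")
  ours <- compute_roc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("inactive", "active"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("pooled cross-validation is deterministic and scores once", {
  lab <- toy_labeled(25, 25)
  m <- toy_descriptors(lab, shift = 3)
  r1 <- cross_validate(m, lab$label, k = 5, n_trees = 100, seed = 4)
  r2 <- cross_validate(m, lab$label, k = 5, n_trees = 100, seed = 4)
  expect_equal(attr(r1, "oof_prob"), attr(r2, "oof_prob"))
  expect_equal(r1$accuracy, r2$accuracy)
  expect_gt(r1$accuracy, 0.9)
  total <- with(r1$counts, tp + fp + tn + fn)
  expect_identical(total, nrow(m)) # pooled: every compound scored exactly once

  expect_error(cross_validate(m, lab$label, k = 1), "k must be")
  expect_error(cross_validate(m, lab$label, k = 26), "exceeds")
})
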