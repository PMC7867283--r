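# Random-forest QSAR classification: stratified partitioning, training,
# evaluation, and pooled cross-validation. The forest itself is fit with
# the randomForest package; everything around it (splits, metrics, pooling)
# is defined here so the conventions are explicit and testable.

#' Stratified train/test partition
#'
#' Splits a labelled library into training and test sets preserving the
#' class proportions. The per-class test size is `round((1 - train_fraction)
#' * class size)` with banker's rounding (round-half-even); membership is
#' decided by a seeded per-class shuffle, so identical seeds give identical
#' partitions.
#'
#' @param labeled Labelled library tibble from [label_activity()] (needs
#'   `compound_id` and `label`).
#' @param train_fraction Fraction assigned to training, in (0, 1). Default 0.8.
#' @param seed Integer seed for the shuffle.
#' @return List with tibbles `train` and `test`; their union is the input and
#'   their intersection empty.
#' @export
stratified_split <- function(labeled, train_fraction = 0.8, seed = 1) {
  stopifnot_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  labels <- as_class_labels(labeled$label)
  sizes <- table(labels)
  if (any(sizes == 0)) {
    stop("both classes must be present for a stratified split", call. = FALSE)
  }
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in CLASS_LEVELS) {
    idx <- which(labels == cl)
    n_test <- round((1 - train_fraction) * length(idx))
    if (n_test < 1 || n_test >= length(idx)) {
      stop("split leaves class '", cl, "' empty in the test or training set",
           call. = FALSE)
    }
    shuffled <- idx[sample.int(length(idx))]
    test_idx <- c(test_idx, shuffled[seq_len(n_test)])
  }
  test_idx <- sort(test_idx)
  list(
    train = labeled[-test_idx, , drop = FALSE],
    test = labeled[test_idx, , drop = FALSE]
  )
}

#' Train the random-forest activity classifier
#'
#' Fits a classification random forest (250 trees by default, single seed)
#' on a descriptor matrix. Constant descriptor columns are dropped with a
#' warning before training; the retained feature set is stored so that
#' prediction subsets new data identically. Identical inputs and seed give
#' identical probability outputs.
#'
#' @param descriptors Descriptor matrix ([as_descriptor_matrix()]) whose rows
#'   align with `labels`.
#' @param labels Class per row (`"active"`/`"inactive"`).
#' @param n_trees Number of trees, default 250.
#' @param seed Integer seed.
#' @return An object of class `activity_forest` wrapping the fitted forest,
#'   the retained feature names, and the training metadata.
#' @export
train_forest <- function(descriptors, labels, n_trees = 250, seed = 1) {
  m <- as_descriptor_matrix(descriptors)
  labels <- as_class_labels(labels)
  if (nrow(m) == 0L) stop("empty descriptor matrix", call. = FALSE)
  if (nrow(m) != length(labels)) {
    stop("descriptor rows and labels are misaligned (", nrow(m), " rows vs ",
         length(labels), " labels)", call. = FALSE)
  }
  if (!is.numeric(n_trees) || length(n_trees) != 1L || n_trees < 1) {
    stop("n_trees must be a positive integer", call. = FALSE)
  }
  constant <- attr(m, "constant")
  if (any(constant)) {
    warning("dropping constant descriptor column(s): ",
            paste(colnames(m)[constant], collapse = ", "), call. = FALSE)
    m <- m[, !constant, drop = FALSE]
    if (ncol(m) == 0L) stop("all descriptor columns are constant", call. = FALSE)
  }
  set.seed(seed)
  forest <- randomForest::randomForest(x = m, y = labels, ntree = n_trees)
  structure(
    list(forest = forest, features = colnames(m), n_trees = n_trees,
         seed = seed, classes = CLASS_LEVELS),
    class = "activity_forest"
  )
}

#' @export
print.activity_forest <- function(x, ...) {
  cat(sprintf("Random-forest activity classifier: %d trees, %d descriptors, seed %d\n",
              x$n_trees, length(x$features), x$seed))
  invisible(x)
}

#' Predict the active-class probability
#'
#' Returns the model's per-compound probability of the active class
#' (the P_Activity entering the consensus probability).
#'
#' @param model An `activity_forest`.
#' @param descriptors Descriptor matrix for the query compounds; must contain
#'   every feature the model was trained on.
#' @return Named numeric vector of probabilities in \[0, 1\].
#' @export
predict_activity <- function(model, descriptors) {
  m <- as_descriptor_matrix(descriptors)
  missing <- setdiff(model$features, colnames(m))
  if (length(missing)) {
    stop("query descriptors are missing feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- m[, model$features, drop = FALSE]
  prob <- predict(model$forest, newdata = m, type = "prob")[, "active"]
  stats::setNames(as.numeric(prob), rownames(m))
}

#' Variable importance of the trained forest
#'
#' Exposes the forest's mean-decrease-in-Gini importance ranking. No claim
#' is made that any particular importance measure reproduces a specific
#' published descriptor list.
#'
#' @param model An `activity_forest`.
#' @param n Number of top descriptors to return; default all.
#' @return Tibble with `descriptor` and `importance`, sorted decreasing.
#' @export
forest_importance <- function(model, n = Inf) {
  imp <- randomForest::importance(model$forest)
  out <- tibble(descriptor = rownames(imp), importance = as.numeric(imp[, 1]))
  out <- out[order(-out$importance, out$descriptor), ]
  utils::head(out, n)
}

#' Evaluate a classifier on a test set
#'
#' Thresholds the predicted active-class probability at `cutoff`, computes
#' the confusion counts, the six rates, and the ROC AUC of the probability
#' ranking.
#'
#' @param model An `activity_forest`.
#' @param descriptors Test descriptor matrix.
#' @param labels True classes for the test rows.
#' @param cutoff Probability cutoff, default 0.5.
#' @return A `performance_report`.
#' @export
evaluate_classifier <- function(model, descriptors, labels, cutoff = 0.5) {
  labels <- as_class_labels(labels)
  if (length(labels) == 0L) stop("empty test set", call. = FALSE)
  prob <- predict_activity(model, descriptors)
  if (length(prob) != length(labels)) {
    stop("test rows and labels are misaligned", call. = FALSE)
  }
  score_performance(labels, prob, cutoff)
}

# Counts + rates + AUC from probabilities; AUC only when both classes present.
score_performance <- function(labels, prob, cutoff = 0.5) {
  counts <- confusion_counts(labels, prob, cutoff)
  auc <- if (length(unique(labels)) == 2L) compute_roc(prob, labels)$auc else NA_real_
  performance_report(counts, auc = auc)
}

#' Stratified k-fold cross-validation
#'
#' Assigns stratified folds (each fold contains both classes), refits the
#' forest on each training complement, and pools the out-of-fold
#' probabilities into a single confusion matrix that is scored once —
#' one value per metric, not per-fold averages. Deterministic under `seed`.
#'
#' @param descriptors Descriptor matrix, rows aligned with `labels`.
#' @param labels Class per row.
#' @param k Number of folds, default 10; must not exceed the smaller class.
#' @param n_trees Trees per fold model, default 250.
#' @param seed Integer seed (drives fold assignment and per-fold fits).
#' @param cutoff Probability cutoff, default 0.5.
#' @return A `performance_report` for the pooled out-of-fold predictions,
#'   with the per-compound probabilities in attribute `"oof_prob"`.
#' @export
cross_validate <- function(descriptors, labels, k = 10, n_trees = 250,
                           seed = 1, cutoff = 0.5) {
  m <- as_descriptor_matrix(descriptors)
  labels <- as_class_labels(labels)
  if (nrow(m) != length(labels)) {
    stop("descriptor rows and labels are misaligned", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop("k must be an integer >= 2", call. = FALSE)
  }
  smallest <- min(table(labels))
  if (k > smallest) {
    stop("k = ", k, " exceeds the smaller class size (", smallest, ")",
         call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in CLASS_LEVELS) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  oof <- rep(NA_real_, length(labels))
  for (f in seq_len(k)) {
    hold <- fold == f
    model <- train_forest(m[!hold, , drop = FALSE], labels[!hold],
                          n_trees = n_trees, seed = seed + f)
    oof[hold] <- predict_activity(model, m[hold, , drop = FALSE])
  }
  report <- score_performance(labels, oof, cutoff)
  attr(report, "oof_prob") <- stats::setNames(oof, rownames(m))
  report
}
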