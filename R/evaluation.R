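# Evaluation harness: repeated stratified train/test splits, repeated
# stratified k-fold cross-validation, pooled confusion matrices, class-wise
# precision and recall. Splits are stratified so every class is represented
# in each training dictionary (a requirement of the SRC classifier).

#' Confusion matrix and class-wise precision/recall
#'
#' @param true_labels,predicted_labels integer vectors in `1..C`.
#' @param C number of classes.
#' @return list with `confusion` (C x C integer matrix, rows = true,
#'   columns = predicted), `recall` (`confusion[c,c] / row sum`), and
#'   `precision` (`confusion[c,c] / column sum`; 0 when the column sum is 0).
#' @export
confusion_and_classwise <- function(true_labels, predicted_labels, C) {
  stopifnot(length(true_labels) == length(predicted_labels))
  f <- factor(true_labels, levels = seq_len(C))
  g <- factor(predicted_labels, levels = seq_len(C))
  conf <- unclass(table(f, g, dnn = c("true", "predicted")))
  rs <- rowSums(conf); cs <- colSums(conf)
  recall <- ifelse(rs > 0, diag(conf) / rs, 0)
  precision <- ifelse(cs > 0, diag(conf) / cs, 0)
  list(confusion = conf, recall = unname(recall), precision = unname(precision))
}

# stratified train indices: per class, round(train_frac * n_c) samples,
# clamped to [1, n_c - 1] so both sides stay populated
stratified_split <- function(labels, train_frac) {
  idx <- integer(0)
  for (c in sort(unique(labels))) {
    pool <- which(labels == c)
    n_c <- length(pool)
    n_tr <- min(max(round(train_frac * n_c), 1L), n_c - 1L)
    idx <- c(idx, sample(pool, n_tr))
  }
  sort(idx)
}

# stratified fold assignment in 1..k, shuffled within class
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (c in sort(unique(labels))) {
    pool <- sample(which(labels == c))
    fold[pool] <- rep_len(seq_len(k), length(pool))
  }
  fold
}

new_eval_report <- function(acc_per_repeat, confusion, scheme, n_repeats, seed) {
  C <- nrow(confusion)
  cw <- list(recall = ifelse(rowSums(confusion) > 0, diag(confusion) / rowSums(confusion), 0),
             precision = ifelse(colSums(confusion) > 0, diag(confusion) / colSums(confusion), 0))
  structure(list(
    accuracy = mean(acc_per_repeat),
    accuracy_se = if (length(acc_per_repeat) > 1)
      stats::sd(acc_per_repeat) / sqrt(length(acc_per_repeat)) else 0,
    accuracy_per_repeat = acc_per_repeat,
    confusion = confusion,
    recall_per_class = unname(cw$recall),
    precision_per_class = unname(cw$precision),
    n_repeats = n_repeats, scheme = scheme, seed = seed),
    class = "eval_report")
}

#' Repeated stratified train/test-split evaluation
#'
#' Performs `n_repeats` stratified random splits (default 85% train),
#' training a fresh classifier on each and scoring it on the held-out part.
#' Accuracy is averaged over repeats with its standard error; the confusion
#' matrix pools all test predictions.
#'
#' @param x feature matrix, p features x n samples (columns are samples).
#' @param labels integer labels in `1..C`.
#' @param classifier_factory `function(x_train, labels_train)` returning a
#'   prediction function `function(x_test) -> integer labels`.
#' @param train_frac training fraction (default 0.85).
#' @param n_repeats number of random splits.
#' @param seed RNG seed (the whole evaluation is deterministic per seed).
#' @return an object of class `"eval_report"`.
#' @export
repeated_split_eval <- function(x, labels, classifier_factory,
                                train_frac = 0.85, n_repeats = 100L,
                                seed = 1L) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  C <- max(labels)
  if (min(table(labels)) < 2)
    stop("every class needs at least 2 samples to split into train and test")
  set.seed(seed)
  acc <- numeric(n_repeats)
  conf <- matrix(0L, C, C, dimnames = list(true = seq_len(C), predicted = seq_len(C)))
  for (r in seq_len(n_repeats)) {
    tr <- stratified_split(labels, train_frac)
    te <- setdiff(seq_along(labels), tr)
    predictor <- classifier_factory(x[, tr, drop = FALSE], labels[tr])
    pred <- as.integer(predictor(x[, te, drop = FALSE]))
    acc[r] <- mean(pred == labels[te])
    conf <- conf + confusion_and_classwise(labels[te], pred, C)$confusion
  }
  new_eval_report(acc, conf, sprintf("repeated %d-%d split", round(train_frac * 100),
                                     round((1 - train_frac) * 100)),
                  n_repeats, seed)
}

#' Repeated stratified k-fold cross-validation
#'
#' Folds are stratified by class and re-shuffled on every repeat; each
#' repeat's accuracy pools its k held-out folds, and the confusion matrix
#' pools everything.
#'
#' @inheritParams repeated_split_eval
#' @param k number of folds (default 10).
#' @param n_repeats number of shuffles (default 10).
#' @return an object of class `"eval_report"`.
#' @export
repeated_kfold_eval <- function(x, labels, classifier_factory, k = 10L,
                                n_repeats = 10L, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  C <- max(labels)
  if (k < 2) stop("'k' must be at least 2")
  if (min(table(labels)) < 2)
    stop("every class needs at least 2 samples for cross-validation")
  set.seed(seed)
  acc <- numeric(n_repeats)
  conf <- matrix(0L, C, C, dimnames = list(true = seq_len(C), predicted = seq_len(C)))
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(labels, k)
    correct <- 0L; total <- 0L
    for (f in seq_len(k)) {
      te <- which(fold == f)
      if (length(te) == 0L) next
      tr <- which(fold != f)
      predictor <- classifier_factory(x[, tr, drop = FALSE], labels[tr])
      pred <- as.integer(predictor(x[, te, drop = FALSE]))
      correct <- correct + sum(pred == labels[te])
      total <- total + length(te)
      conf <- conf + confusion_and_classwise(labels[te], pred, C)$confusion
    }
    acc[r] <- correct / total
  }
  new_eval_report(acc, conf, sprintf("repeated %d-fold CV", k), n_repeats, seed)
}

#' Classifier factory for the SRC model
#'
#' Convenience adaptor plugging [src_model()] into the evaluation harness.
#'
#' @param ... arguments forwarded to [src_model()] (variant, lambda, k, rho,
#'   control, ...).
#' @return a `classifier_factory` function.
#' @export
src_factory <- function(...) {
  args <- list(...)
  function(x_train, labels_train) {
    model <- do.call(src_model, c(list(x = x_train, labels = labels_train), args))
    function(x_test) predict(model, x_test)$class
  }
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation:", x$scheme, "(", x$n_repeats, "repeats, seed", x$seed, ")\n")
  cat(sprintf("  accuracy: %.4f (SE %.4f)\n", x$accuracy, x$accuracy_se))
  cat("  confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  cat("  recall:   ", paste(sprintf("%.3f", x$recall_per_class), collapse = " "), "\n")
  cat("  precision:", paste(sprintf("%.3f", x$precision_per_class), collapse = " "), "\n")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes a JSON document with the accuracy, standard error, per-repeat
#' accuracies, class-wise precision/recall and scheme metadata, plus a
#' tab-separated confusion-matrix file alongside (same path with a
#' `_confusion.tsv` suffix).
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  payload <- unclass(report)
  payload$confusion <- unname(as.matrix(report$confusion))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  conf_path <- sub("\\.json$", "", path)
  conf_path <- paste0(conf_path, "_confusion.tsv")
  utils::write.table(as.matrix(report$confusion), conf_path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
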