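# Individual-level classification: radial-kernel SVM on a single scalar
# feature under stratified K-fold cross-validation, reporting pooled
# out-of-fold accuracy, sensitivity and specificity with the AD group as the
# positive class.

#' Stratified K-fold SVM classification of a scalar feature
#'
#' Splits subjects into `k` folds preserving class proportions (so a small
#' control group is never absent from a fold's training set), trains one
#' radial-basis SVM (`cost = 1`, features standardised on the training folds)
#' per fold, and pools the out-of-fold predictions into a single confusion
#' matrix. Sensitivity is the true-positive rate of the `positive` class;
#' specificity the true-negative rate; swapping the positive-class convention
#' swaps the two exactly.
#'
#' @param data Data frame with one row per subject.
#' @param feature Name of the numeric feature column (default `"value"`).
#' @param label Name of the class-label column (two classes).
#' @param positive Label treated as positive (default `"AD"`).
#' @param k Number of folds (default 10; at least 2, at most the number of
#'   subjects).
#' @param seed Integer seed for the fold shuffle; identical inputs and seed
#'   give identical reports.
#' @return An `svm_cv_report`: list with `k`, `seed`, `positive`,
#'   `confusion` (tp, fn, tn, fp), `accuracy`, `sensitivity`, `specificity`
#'   (percent) and `folds` (per-fold confusion counts).
#' @export
#' @examples
#' d <- data.frame(
#'   value = c(rnorm(20), rnorm(20, mean = 6)),
#'   label = rep(c("healthy", "AD"), each = 20)
#' )
#' glance(kfold_svm(d, k = 5, seed = 1))
kfold_svm <- function(data, feature = "value", label = "label",
                      positive = "AD", k = 10, seed = 1L) {
  stopifnot(is.data.frame(data))
  values <- data[[feature]]
  labels <- as.character(data[[label]])
  if (is.null(values) || is.null(labels)) {
    stop_eeg("`data` must contain columns '", feature, "' and '", label, "'")
  }
  if (!all(is.finite(values))) stop_eeg("feature values must be finite")
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    stop_eeg("need exactly 2 classes, got ", length(classes))
  }
  if (!positive %in% classes) {
    stop_eeg("positive class '", positive, "' not among labels")
  }
  n <- length(values)
  if (k < 2 || k > n) stop_eeg("`k` must be between 2 and the subject count")
  fold <- integer(n)
  with_local_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  y <- factor(labels, levels = c(positive, setdiff(classes, positive)))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(unique(labels[train])) < 2) {
      stop_eeg("fold ", f, " leaves a single-class training set; lower `k`")
    }
    fit <- e1071::svm(
      x = matrix(values[train], ncol = 1), y = y[train],
      kernel = "radial", cost = 1, scale = sd(values[train]) > 0
    )
    pred <- stats::predict(fit, matrix(values[test], ncol = 1))
    actual_pos <- labels[test] == positive
    pred_pos <- as.character(pred) == positive
    folds[[f]] <- tibble::tibble(
      fold = f, n = length(test),
      tp = sum(actual_pos & pred_pos), fn = sum(actual_pos & !pred_pos),
      tn = sum(!actual_pos & !pred_pos), fp = sum(!actual_pos & pred_pos)
    )
  }
  folds <- dplyr::bind_rows(folds)
  conf <- c(
    tp = sum(folds$tp), fn = sum(folds$fn),
    tn = sum(folds$tn), fp = sum(folds$fp)
  )
  structure(
    list(
      k = as.integer(k), seed = as.integer(seed), positive = positive,
      confusion = conf,
      accuracy = 100 * (conf[["tp"]] + conf[["tn"]]) / n,
      sensitivity = 100 * conf[["tp"]] / (conf[["tp"]] + conf[["fn"]]),
      specificity = 100 * conf[["tn"]] / (conf[["tn"]] + conf[["fp"]]),
      folds = folds
    ),
    class = "svm_cv_report"
  )
}

#' @export
print.svm_cv_report <- function(x, ...) {
  cat(
    "<svm_cv_report> K =", x$k, " positive =", x$positive, "\n",
    " Acc =", sprintf("%.1f%%", x$accuracy),
    " Sen =", sprintf("%.1f%%", x$sensitivity),
    " Spe =", sprintf("%.1f%%", x$specificity), "\n"
  )
  invisible(x)
}

#' @rdname kfold_svm
#' @param x An `svm_cv_report`.
#' @param ... Unused.
#' @method tidy svm_cv_report
#' @export
tidy.svm_cv_report <- function(x, ...) x$folds

#' @rdname kfold_svm
#' @method glance svm_cv_report
#' @export
glance.svm_cv_report <- function(x, ...) {
  tibble::tibble(
    k = x$k, seed = x$seed, positive = x$positive,
    accuracy = x$accuracy, sensitivity = x$sensitivity,
    specificity = x$specificity,
    tp = x$confusion[["tp"]], fn = x$confusion[["fn"]],
    tn = x$confusion[["tn"]], fp = x$confusion[["fp"]]
  )
}
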