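#' Stratified train/validation/test split
#'
#' Partitions sample indices into three disjoint, exhaustive sets. Subset
#' totals follow the largest-remainder rounding of `fractions * n` (ties
#' toward train, then validation); the per-class allocation is the rounding
#' of the exact class-by-subset quota matrix to those row and column
#' totals, so every class lands within one sample of its target proportion
#' in every subset.
#'
#' @param labels Class label per sample (factor or vector).
#' @param fractions Length-3 positive vector `(train, val, test)` summing
#'   to 1. The default 0.70/0.15/0.15 yields the 148/32/32 subset sizes on
#'   a 212-subject cohort.
#' @param seed Seed for the within-class shuffles.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(labels, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  labels <- as.factor(labels)
  if (any(table(labels) < 3L)) {
    stop("ostvol_stratify_error: every class needs at least 3 samples",
         call. = FALSE)
  }
  n <- length(labels)
  n_class <- table(labels)
  # global subset totals by largest remainder
  base_tot <- floor(fractions * n)
  rem_tot <- fractions * n - base_tot
  extra <- order(rem_tot, decreasing = TRUE)[seq_len(n - sum(base_tot))]
  targets <- base_tot
  targets[extra] <- targets[extra] + 1L
  # round the class x subset quota matrix to the row/column totals:
  # floor everything, then hand out the remaining units in decreasing
  # order of fractional part, never exceeding a row or column need
  quota <- outer(as.vector(n_class), fractions)
  alloc <- floor(quota)
  frac <- quota - alloc
  row_need <- as.vector(n_class) - rowSums(alloc)
  col_need <- targets - colSums(alloc)
  ord <- order(frac, decreasing = TRUE)
  for (pass in 1:2) {   # second pass ignores fractional order (repair)
    for (cell in ord) {
      r <- (cell - 1L) %% nrow(alloc) + 1L
      s <- (cell - 1L) %/% nrow(alloc) + 1L
      if (row_need[r] > 0L && col_need[s] > 0L &&
          (pass == 2L || frac[cell] > 0)) {
        alloc[r, s] <- alloc[r, s] + 1L
        row_need[r] <- row_need[r] - 1L
        col_need[s] <- col_need[s] - 1L
      }
    }
    if (all(row_need == 0L)) break
  }
  set.seed(seed)
  out <- list(train = integer(), val = integer(), test = integer())
  for (ci in seq_along(levels(labels))) {
    idx <- sample(which(labels == levels(labels)[ci]))
    cuts <- cumsum(alloc[ci, ])
    out$train <- c(out$train, idx[seq_len(alloc[ci, 1L])])
    out$val <- c(out$val, idx[seq.int(cuts[1L] + 1L, length.out = alloc[ci, 2L])])
    out$test <- c(out$test, idx[seq.int(cuts[2L] + 1L, length.out = alloc[ci, 3L])])
  }
  lapply(out, sort)
}

#' k-fold cross-validation indices
#'
#' @param n Number of samples.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Shuffle seed.
#' @return List of `k` elements, each `list(train, heldout)`; held-out sets
#'   are disjoint, exhaustive, and differ in size by at most one.
#' @export
kfold_indices <- function(n, k, seed = 1L) {
  if (k < 2L || k > n) {
    stop("ostvol_kfold_error: k must satisfy 2 <= k <= n", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample.int(n)
  # round-robin fold assignment over the permuted order: sizes differ by <= 1
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), heldout = which(fold == f))
  })
}

#' Classification accuracy
#'
#' @param truth True labels.
#' @param predicted Predicted labels, same length.
#' @return Fraction correct.
#' @export
accuracy <- function(truth, predicted) {
  if (length(truth) == 0L || length(truth) != length(predicted)) {
    stop("ostvol_length_error: non-empty equal-length label vectors required",
         call. = FALSE)
  }
  mean(as.character(truth) == as.character(predicted))
}

#' Pooled overall accuracy across disjoint subsets
#'
#' The reporting convention behind the published "overall accuracy": total
#' correct across the training, validation and test subsets divided by the
#' total evaluated, i.e. the subset-size-weighted mean of subset accuracies.
#'
#' @param correct Integer vector of correct counts per subset.
#' @param n Integer vector of subset sizes.
#' @return Pooled fraction correct.
#' @export
#' @examples
#' pooled_overall(c(99, 21, 18), c(148, 32, 32))  # 138/212
pooled_overall <- function(correct, n) {
  if (length(correct) != length(n) || sum(n) == 0L) {
    stop("ostvol_length_error: matching non-empty subset vectors required",
         call. = FALSE)
  }
  if (any(correct > n) || any(correct < 0)) {
    stop("ostvol_count_error: correct counts must lie in [0, n]", call. = FALSE)
  }
  sum(correct) / sum(n)
}

#' Three-class confusion matrix
#'
#' @param truth,predicted Survival-class labels (factor on the class levels
#'   or integer 1-3).
#' @return 3x3 integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as_class_factor(truth)
  predicted <- as_class_factor(predicted)
  if (anyNA(truth) || anyNA(predicted)) {
    stop("ostvol_class_error: labels must be one of the three survival classes",
         call. = FALSE)
  }
  m <- table(truth = truth, predicted = predicted)
  matrix(as.integer(m), 3L, 3L,
         dimnames = list(truth = levels(truth), predicted = levels(truth)))
}

#' Per-class error decomposition of a confusion matrix
#'
#' @param cm 3x3 confusion matrix from [confusion_matrix].
#' @return Data frame with per-class TP, FN (type II), FP (type I), TN.
#' @export
confusion_errors <- function(cm) {
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- sum(cm) - tp - fn - fp
  data.frame(class = rownames(cm), TP = as.integer(tp), FN = as.integer(fn),
             FP = as.integer(fp), TN = as.integer(tn), row.names = NULL)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores of the positive class (one
#' survival class against the other two), computing true/false positive
#' rates, and integrates by the trapezoidal rule. The result equals the
#' probability a random positive outscores a random negative, with ties
#' counted one half.
#'
#' @param truth Labels (factor or integer 1-3).
#' @param scores Numeric score for the positive class per sample (e.g. the
#'   class column of [nn_forward] probabilities).
#' @param positive The positive class (level name or index).
#' @return List with `points` (data frame of fpr/tpr, threshold) and `auc`.
#' @export
roc_ovr <- function(truth, scores, positive) {
  truth <- as_class_factor(truth)
  if (is.numeric(positive)) positive <- levels(truth)[positive]
  pos <- as.character(truth) == positive
  if (!any(pos) || all(pos)) {
    stop("ostvol_roc_error: need both positive and negative samples",
         call. = FALSE)
  }
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  np <- sum(pos); nn <- sum(!pos)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / nn, 0)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a fitted classifier over a three-way split
#'
#' Builds the full evaluation report: per-subset accuracies, the pooled
#' overall accuracy, the test-set confusion matrix with per-class error
#' counts, and one-vs-rest ROC/AUC per class on the test set.
#'
#' @param model An [ost_net] fit (or any object with a `predict` method
#'   returning classes and, for ROC, probabilities via [nn_forward]).
#' @param x Full feature matrix.
#' @param y Full label factor.
#' @param split Index list from [stratified_split].
#' @return Object of class `ost_eval`.
#' @export
evaluate_model <- function(model, x, y, split) {
  x <- as.matrix(x); y <- as_class_factor(y)
  pred <- predict(model, x)
  subsets <- c("train", "val", "test")
  acc <- vapply(subsets, function(s) accuracy(y[split[[s]]], pred[split[[s]]]), 0)
  correct <- vapply(subsets, function(s) sum(y[split[[s]]] == pred[split[[s]]]), 0L)
  sizes <- vapply(subsets, function(s) length(split[[s]]), 0L)
  cm <- confusion_matrix(y[split$test], pred[split$test])
  probs <- nn_forward(model, x[split$test, , drop = FALSE])
  # a class absent from (or filling) a small test set has no ROC
  roc <- lapply(levels(y), function(cl) {
    tryCatch(roc_ovr(y[split$test], probs[, cl], cl),
             error = function(e) list(points = NULL, auc = NA_real_))
  })
  names(roc) <- levels(y)
  structure(list(accuracy = acc,
                 overall_accuracy = pooled_overall(correct, sizes),
                 subset_sizes = sizes, subset_correct = correct,
                 confusion = cm, errors = confusion_errors(cm),
                 auc = vapply(roc, `[[`, 0, "auc"), roc = roc),
            class = "ost_eval")
}

#' @export
print.ost_eval <- function(x, ...) {
  cat("Survival-class evaluation\n")
  cat(sprintf("  accuracy: train %.1f%% (n=%d)  val %.1f%% (n=%d)  test %.1f%% (n=%d)\n",
              100 * x$accuracy[["train"]], x$subset_sizes[["train"]],
              100 * x$accuracy[["val"]], x$subset_sizes[["val"]],
              100 * x$accuracy[["test"]], x$subset_sizes[["test"]]))
  cat(sprintf("  overall (pooled): %.1f%%\n", 100 * x$overall_accuracy))
  cat("  test confusion matrix (rows = true):\n")
  print(x$confusion)
  cat(sprintf("  one-vs-rest AUC: %s\n",
              paste(sprintf("%s %.3f", names(x$auc), x$auc), collapse = "  ")))
  invisible(x)
}

#' Select the hidden-layer size by k-fold cross-validation
#'
#' Runs k-fold CV on the training subset over a grid of hidden sizes and
#' returns the grid value with the highest mean held-out accuracy (ties
#' toward the smaller size).
#'
#' @param x,y Training features and labels.
#' @param grid Hidden sizes to try (default the published grid).
#' @param k Number of folds.
#' @param seed Seed for fold assignment and fits.
#' @param ... Passed to [ost_net].
#' @return List with `hidden` (selected size) and `cv_accuracy` (named mean
#'   accuracies).
#' @export
select_hidden_size <- function(x, y, grid = c(40L, 50L, 100L, 150L, 200L),
                               k = 5L, seed = 1L, ...) {
  x <- as.matrix(x); y <- as_class_factor(y)
  folds <- kfold_indices(nrow(x), k, seed)
  cv <- vapply(grid, function(h) {
    mean(vapply(folds, function(f) {
      fit <- ost_net(x[f$train, , drop = FALSE], y[f$train], hidden = h,
                     seed = seed, ...)
      accuracy(y[f$heldout], predict(fit, x[f$heldout, , drop = FALSE]))
    }, 0))
  }, 0)
  names(cv) <- as.character(grid)
  list(hidden = grid[which.max(cv)], cv_accuracy = cv)
}
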