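test_that("stratified split partitions indices with near-exact proportions", {
  labels <- rep(c("short", "mid", "long"), each = 30)
  sp <- stratified_split(labels, c(0.7, 0.15, 0.15), seed = 1)
  expect_setequal(c(sp$train, sp$val, sp$test), 1:90)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(length(sp$train), 63)
  expect_true(length(sp$val) %in% 13:14)
  expect_equal(length(sp$val) + length(sp$test), 27)
  # per-class proportions within one sample of the target
  for (cl in unique(labels)) {
    n_cl <- sum(labels[sp$train] == cl)
    expect_lte(abs(n_cl - 0.7 * 30), 1)
  }
  sp2 <- stratified_split(labels, c(0.7, 0.15, 0.15), seed = 1)
  expect_identical(sp, sp2)
  expect_error(stratified_split(c("short", "short", "mid", "mid", "long")),
               "ostvol_stratify_error")
})

test_that("the 212-subject cohort splits 148/32/32 under the default fractions", {
  labels <- rep(c("short", "mid", "long"), c(81, 55, 76))
  sp <- stratified_split(labels, seed = 3)
  expect_equal(length(sp$train), 148)
  expect_equal(length(sp$val), 32)
  expect_equal(length(sp$test), 32)
})

test_that("k-fold indices hold out every sample exactly once with balanced folds", {
  folds <- kfold_indices(10, 5, seed = 2)
  expect_length(folds, 5)
  held <- lapply(folds, `[[`, "heldout")
  expect_true(all(lengths(held) == 2))
  expect_setequal(unlist(held), 1:10)
  folds7 <- kfold_indices(7, 3, seed = 2)
  expect_setequal(lengths(lapply(folds7, `[[`, "heldout")), c(3, 2, 2))
  for (f in folds7) {
    expect_setequal(c(f$train, f$heldout), 1:7)
    expect_length(intersect(f$train, f$heldout), 0)
  }
  expect_error(kfold_indices(5, 6), "ostvol_kfold_error")
  expect_error(kfold_indices(5, 1), "ostvol_kfold_error")
})

test_that("accuracy and pooled overall follow the correct/total arithmetic", {
  expect_equal(accuracy(c(1, 2, 3, 1), c(1, 2, 1, 1)), 0.75)
  expect_equal(accuracy(1:3, 1:3), 1)
  expect_equal(pooled_overall(c(3, 1), c(4, 2)), 4 / 6)
  expect_error(accuracy(integer(), integer()), "ostvol_length_error")
  expect_error(pooled_overall(c(5), c(4)), "ostvol_count_error")

  # pooled overall equals the size-weighted mean of subset accuracies,
  # for random partitions of a fixed prediction set
  set.seed(17)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    truth <- sample(1:3, n, replace = TRUE)
    pred <- sample(1:3, n, replace = TRUE)
    part <- split(seq_len(n), sample(1:3, n, replace = TRUE))
    correct <- vapply(part, function(ix) sum(truth[ix] == pred[ix]), 0L)
    sizes <- lengths(part)
    expect_equal(pooled_overall(correct, sizes), mean(truth == pred))
    expect_equal(pooled_overall(correct, sizes),
                 sum((correct / sizes) * sizes) / sum(sizes))
  }
})

test_that("confusion matrix counts and per-class errors match direct counting", {
  truth <- c(1, 1, 2, 2, 3, 3, 3)
  pred <- c(1, 2, 2, 3, 3, 3, 1)
  cm <- confusion_matrix(truth, pred)
  expect_equal(sum(cm), 7)
  expect_equal(cm["short", "mid"], 1L)
  expect_equal(cm["long", "short"], 1L)
  perfect <- confusion_matrix(c(1, 2, 3, 3), c(1, 2, 3, 3))
  expect_equal(unname(diag(perfect)), c(1L, 1L, 2L))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)

  err <- confusion_errors(cm)
  for (k in 1:3) {
    fn_direct <- sum(truth == k & pred != k)
    fp_direct <- sum(truth != k & pred == k)
    expect_equal(err$FN[k], fn_direct)
    expect_equal(err$FP[k], fp_direct)
    expect_equal(err$TP[k], sum(truth == k & pred == k))
  }
  expect_error(confusion_matrix(c(1, 5), c(1, 1)), "ostvol_class_error")
})

test_that("ROC/AUC equals the pairwise-ranking oracle and handles ties", {
  r <- roc_ovr(c(1, 1, 2, 3), c(0.9, 0.8, 0.2, 0.1), positive = 1)
  expect_equal(r$auc, 1.0)
  expect_equal(roc_ovr(c(1, 2, 1, 3), c(0.5, 0.5, 0.5, 0.5), 1)$auc, 0.5)

  set.seed(23)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    truth <- sample(1:3, n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c(1, 2)
    scores <- round(runif(n), 2)  # rounding provokes ties
    cl <- sample(unique(truth), 1)
    r <- roc_ovr(truth, scores, cl)
    expect_equal(r$auc,
                 pairwise_auc(scores[truth == cl], scores[truth != cl]),
                 tolerance = 1e-12, info = sprintf("case %d", i))
    # negation symmetry
    rn <- roc_ovr(truth, -scores, cl)
    expect_equal(rn$auc, 1 - r$auc, tolerance = 1e-12)
  }
  expect_error(roc_ovr(c(1, 1), c(0.2, 0.4), 1), "ostvol_roc_error")
})

test_that("evaluation report is internally consistent on a synthetic experiment", {
  co <- tiny_cohort(seed = 41, n = c(6L, 6L, 6L))
  ex <- run_experiment(co, "mid_sagittal", "age", hidden = 15, seed = 2,
                       max_epochs = 200)
  ev <- ex$eval
  expect_equal(sum(ev$confusion), length(ex$split$test))
  expect_true(all(ev$accuracy >= 0 & ev$accuracy <= 1))
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_equal(ev$overall_accuracy,
               sum(ev$subset_correct) / sum(ev$subset_sizes))
  # determinism end to end
  ex2 <- run_experiment(co, "mid_sagittal", "age", hidden = 15, seed = 2,
                        max_epochs = 200)
  expect_identical(ex2$eval$confusion, ev$confusion)
  expect_identical(coef(ex2$model), coef(ex$model))
})

test_that("hidden-size selection by cross-validation returns a grid member", {
  co <- tiny_cohort(seed = 43, n = c(6L, 6L, 6L))
  fx <- extract_features(co, "mid_coronal", "age")
  sel <- select_hidden_size(fx$features, fx$classes, grid = c(5L, 10L),
                            k = 3L, seed = 1, max_epochs = 100)
  expect_true(sel$hidden %in% c(5L, 10L))
  expect_length(sel$cv_accuracy, 2L)
  expect_true(all(sel$cv_accuracy >= 0 & sel$cv_accuracy <= 1))
})
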