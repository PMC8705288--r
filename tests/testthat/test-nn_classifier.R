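# build an ost_net with hand-set weights, bypassing training
toy_net <- function(W1, b1, W2, b2, center = NULL, scale = NULL) {
  p <- nrow(W1)
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 center = if (is.null(center)) rep(0, p) else center,
                 scale = if (is.null(scale)) rep(1, p) else scale,
                 levels = c("short", "mid", "long"),
                 hidden = ncol(W1), l2 = 0, loss_trace = NA_real_,
                 config = list()),
            class = "ost_net")
}

test_that("forward pass is a softmax over tanh features, summing to one", {
  # zero weights: perfect symmetry gives uniform probabilities
  z <- toy_net(matrix(0, 2, 2), c(0, 0), matrix(0, 2, 3), c(0, 0, 0))
  expect_equal(unname(nn_forward(z, c(1.5, -2))[1, ]), rep(1 / 3, 3))

  # hand-computed 2-feature, 2-hidden example
  W1 <- matrix(c(0.5, -0.3, 0.2, 0.1), 2, 2)
  b1 <- c(0.1, -0.2)
  W2 <- matrix(c(0.3, -0.1, 0.2, 0.4, -0.2, 0.1), 2, 3)
  b2 <- c(0.05, -0.05, 0)
  x <- c(1.0, 2.0)
  a1 <- tanh(c(0.5 * 1 - 0.3 * 2 + 0.1, 0.2 * 1 + 0.1 * 2 - 0.2))
  z2 <- c(0.3 * a1[1] - 0.1 * a1[2] + 0.05,
          0.2 * a1[1] + 0.4 * a1[2] - 0.05,
          -0.2 * a1[1] + 0.1 * a1[2] + 0)
  expected <- exp(z2) / sum(exp(z2))
  got <- nn_forward(toy_net(W1, b1, W2, b2), x)
  expect_equal(unname(got[1, ]), expected, tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)

  set.seed(99)
  rand <- matrix(rnorm(20), 10, 2)
  expect_equal(rowSums(nn_forward(toy_net(W1, b1, W2, b2), rand)),
               rep(1, 10), tolerance = 1e-12)
  expect_error(nn_forward(toy_net(W1, b1, W2, b2), c(1, 2, 3)),
               "ostvol_dimension_error")
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  x <- matrix(rnorm(24), 8, 3)
  y <- factor(rep(c("short", "mid", "long"), length.out = 8),
              levels = c("short", "mid", "long"))
  model <- ost_net(x, y, hidden = 4, max_epochs = 1, l2 = 1e-3, seed = 2)
  xs <- ostvol:::scale_features(x, model$center, model$scale)
  ymat <- ostvol:::class_indicator(y)
  fg <- ostvol:::nn_loss_grad(model, xs, ymat)
  h <- 1e-5
  for (field in c("W1", "b1", "W2", "b2")) {
    analytic <- fg$grad[[field]]
    for (i in seq_along(model[[field]])) {
      up <- model; up[[field]][i] <- up[[field]][i] + h
      dn <- model; dn[[field]][i] <- dn[[field]][i] - h
      fd <- (ostvol:::nn_loss_grad(up, xs, ymat, grad = FALSE)$loss -
             ostvol:::nn_loss_grad(dn, xs, ymat, grad = FALSE)$loss) / (2 * h)
      expect_equal(as.vector(analytic)[i], fd, tolerance = 1e-6,
                   info = sprintf("%s[%d]", field, i))
    }
  }
})

test_that("training fits separable classes, is deterministic and non-increasing", {
  set.seed(12)
  n <- 30
  x <- rbind(matrix(rnorm(2 * n, mean = -4), n, 2),
             matrix(rnorm(2 * n, mean = 0), n, 2),
             matrix(rnorm(2 * n, mean = 4), n, 2))
  y <- factor(rep(c("short", "mid", "long"), each = n),
              levels = c("short", "mid", "long"))
  fit <- ost_net(x, y, hidden = 10, learning_rate = 0.1, max_epochs = 400,
                 seed = 5)
  expect_gte(accuracy(y, predict(fit, x)), 0.95)

  fit2 <- ost_net(x, y, hidden = 10, learning_rate = 0.1, max_epochs = 400,
                  seed = 5)
  expect_identical(coef(fit), coef(fit2))

  slow <- ost_net(x, y, hidden = 10, learning_rate = 0.01, max_epochs = 100,
                  seed = 5, l2 = 0)
  expect_true(all(diff(slow$loss_trace) <= 1e-10))
})

test_that("training rejects degenerate inputs", {
  x <- matrix(rnorm(12), 6, 2)
  expect_error(ost_net(x, factor(rep(c("short", "mid"), 3),
                                 levels = c("short", "mid", "long"))),
               "ostvol_class_error")
  x[2, 1] <- NA
  expect_error(ost_net(x, factor(rep(c("short", "mid", "long"), 2),
                                 levels = c("short", "mid", "long"))),
               "ostvol_nonfinite_error")
})

test_that("prediction takes the argmax with ties toward the lower class", {
  m <- toy_net(matrix(0, 1, 1), 0, matrix(0, 1, 3), c(0.1, 0.6, 0.3))
  expect_equal(as.character(predict(m, matrix(0, 1, 1))), "mid")
  tie <- toy_net(matrix(0, 1, 1), 0, matrix(0, 1, 3), c(0, 0, 0))
  expect_equal(as.character(predict(tie, matrix(0, 1, 1))), "short")
})

test_that("predictions are invariant to feature rescaling absorbed by the scaler", {
  set.seed(21)
  x <- matrix(rnorm(90), 30, 3) + rep(c(-4, 0, 4), 10)  # separated classes
  y <- factor(rep(c("short", "mid", "long"), 10),
              levels = c("short", "mid", "long"))
  fit1 <- ost_net(x, y, hidden = 6, max_epochs = 150, seed = 9)
  for (i in 1:5) {
    s <- runif(3, 0.1, 1000)
    xr <- sweep(x, 2, s, "*")
    fit2 <- ost_net(xr, y, hidden = 6, max_epochs = 150, seed = 9)
    expect_equal(as.character(predict(fit2, xr)),
                 as.character(predict(fit1, x)))
  }
})

test_that("model serialization round-trips weights and scaler", {
  set.seed(33)
  x <- matrix(rnorm(60), 20, 3)
  colnames(x) <- c("a", "b", "c")
  y <- factor(rep(c("short", "mid", "long"), length.out = 20),
              levels = c("short", "mid", "long"))
  fit <- ost_net(x, y, hidden = 5, max_epochs = 50, seed = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_ost_net(fit, path)
  back <- read_ost_net(path)
  expect_equal(back$W1, fit$W1)
  expect_equal(back$center, unname(fit$center))
  expect_equal(nn_forward(back, x), nn_forward(fit, x), tolerance = 1e-12)
})

test_that("baseline classifier adapters fit and predict through one interface", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("MASS")
  skip_if_not_installed("rpart")
  set.seed(14)
  n <- 20
  x <- rbind(matrix(rnorm(2 * n, -3), n, 2), matrix(rnorm(2 * n, 0), n, 2),
             matrix(rnorm(2 * n, 3), n, 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("short", "mid", "long"), each = n)
  for (method in c("svm", "knn", "naive_bayes", "lda", "tree")) {
    ad <- classifier_adapter(method)
    fit <- ad$fit(x, y)
    pred <- ad$predict(fit, x)
    expect_gte(accuracy(y, pred), 0.8)
  }
})
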