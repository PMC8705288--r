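#' Fit the single-hidden-layer survival-class network
#'
#' From-scratch three-class classifier: one hidden layer with hyperbolic
#' tangent activation, a softmax output layer, mean cross-entropy loss with
#' an optional L2 penalty, trained by full-batch gradient descent. Features
#' are z-scored with training-set statistics stored in the model (voxel
#' counts span ~1e6 while age is ~1e1; unscaled training is numerically
#' degenerate). Training is deterministic under a fixed seed.
#'
#' @param x Numeric matrix, subjects x features.
#' @param y Factor of survival classes (3 levels) or integer classes 1-3.
#' @param hidden Number of hidden nodes (the published grid is 40, 50, 100,
#'   150, 200).
#' @param learning_rate Gradient-descent step size.
#' @param max_epochs Maximum full-batch epochs.
#' @param l2 L2 penalty weight on `W1`/`W2` (biases unpenalized); 0 disables.
#' @param seed Seed for weight initialization.
#' @param x_val,y_val Optional validation set for early stopping.
#' @param patience Early-stopping patience in epochs (validation loss);
#'   only used when a validation set is supplied.
#' @return Object of class `ost_net` with weights `W1`, `b1`, `W2`, `b2`,
#'   the feature scaler, the loss trace and the configuration.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 30, 2)
#' y <- factor(ifelse(x[, 1] > 0.5, "long", ifelse(x[, 1] < -0.5, "short", "mid")),
#'             levels = c("short", "mid", "long"))
#' fit <- ost_net(x, y, hidden = 10, max_epochs = 200)
#' mean(predict(fit, x) == y)
ost_net <- function(x, y, hidden = 50L, learning_rate = 0.05,
                    max_epochs = 500L, l2 = 1e-4, seed = 1L,
                    x_val = NULL, y_val = NULL, patience = 50L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) {
    stop("ostvol_nonfinite_error: features must be finite", call. = FALSE)
  }
  y <- as_class_factor(y)
  if (nlevels(y) != 3L || any(tabulate(y, 3L) == 0L)) {
    stop("ostvol_class_error: all three survival classes must be present in training labels",
         call. = FALSE)
  }
  stopifnot(hidden >= 1, learning_rate > 0, max_epochs >= 1, l2 >= 0)
  p <- ncol(x)
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  sigma[sigma == 0 | !is.finite(sigma)] <- 1
  xs <- scale_features(x, mu, sigma)

  set.seed(seed)
  model <- list(
    W1 = matrix(runif(p * hidden, -1, 1) / sqrt(p), p, hidden),
    b1 = numeric(hidden),
    W2 = matrix(runif(hidden * 3L, -1, 1) / sqrt(hidden), hidden, 3L),
    b2 = numeric(3L),
    center = mu, scale = sigma, levels = levels(y),
    feature_names = colnames(x),
    hidden = as.integer(hidden), l2 = l2
  )
  ymat <- class_indicator(y)

  use_val <- !is.null(x_val)
  if (use_val) {
    yv <- class_indicator(as_class_factor(y_val))
    xv <- scale_features(as.matrix(x_val), mu, sigma)
    best_val <- Inf; best <- model; wait <- 0L
  }
  loss_trace <- numeric(max_epochs)
  val_trace <- if (use_val) numeric(max_epochs) else NULL
  for (epoch in seq_len(max_epochs)) {
    fg <- nn_loss_grad(model, xs, ymat)
    loss_trace[epoch] <- fg$loss
    model$W1 <- model$W1 - learning_rate * fg$grad$W1
    model$b1 <- model$b1 - learning_rate * fg$grad$b1
    model$W2 <- model$W2 - learning_rate * fg$grad$W2
    model$b2 <- model$b2 - learning_rate * fg$grad$b2
    if (use_val) {
      vl <- nn_loss_grad(model, xv, yv, grad = FALSE)$loss
      val_trace[epoch] <- vl
      if (vl < best_val - 1e-9) {
        best_val <- vl; best <- model; wait <- 0L
      } else if ((wait <- wait + 1L) >= patience) {
        model <- best
        loss_trace <- loss_trace[seq_len(epoch)]
        val_trace <- val_trace[seq_len(epoch)]
        break
      }
    }
  }
  dimnames(model$W1) <- dimnames(model$W2) <- NULL
  model$loss_trace <- loss_trace
  model$val_trace <- val_trace
  model$config <- list(hidden = hidden, learning_rate = learning_rate,
                       max_epochs = max_epochs, l2 = l2, seed = seed,
                       patience = if (use_val) patience else NA_integer_)
  class(model) <- "ost_net"
  model
}

as_class_factor <- function(y) {
  if (is.factor(y)) {
    factor(as.character(y), levels = if (nlevels(y) == 3L) levels(y)
                                     else survival_class_levels())
  } else if (is.character(y)) {
    factor(y, levels = survival_class_levels())
  } else {
    factor(survival_class_levels()[as.integer(y)],
           levels = survival_class_levels())
  }
}

scale_features <- function(x, center, scale) {
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

class_indicator <- function(y) {
  ymat <- matrix(0, length(y), 3L)
  ymat[cbind(seq_along(y), as.integer(y))] <- 1
  ymat
}

# row-wise numerically stable softmax
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# loss (mean cross-entropy + L2) and analytic backprop gradients on
# standardized inputs; the central testable primitive of the module
nn_loss_grad <- function(model, xs, ymat, grad = TRUE) {
  n <- nrow(xs)
  z1 <- sweep(xs %*% model$W1, 2, model$b1, "+")
  a1 <- tanh(z1)
  z2 <- sweep(a1 %*% model$W2, 2, model$b2, "+")
  p <- softmax_rows(z2)
  ce <- -sum(ymat * log(pmax(p, 1e-300))) / n
  loss <- ce + model$l2 / 2 * (sum(model$W1^2) + sum(model$W2^2))
  if (!grad) return(list(loss = loss))
  dz2 <- (p - ymat) / n
  dW2 <- crossprod(a1, dz2) + model$l2 * model$W2
  db2 <- colSums(dz2)
  dz1 <- (dz2 %*% t(model$W2)) * (1 - a1^2)
  dW1 <- crossprod(xs, dz1) + model$l2 * model$W1
  db1 <- colSums(dz1)
  list(loss = loss, grad = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Forward pass: class probabilities
#'
#' Evaluates tanh-hidden / softmax-output probabilities for new feature
#' vectors under a fitted model's scaler and weights. Rows sum to 1.
#'
#' @param model An [ost_net] fit.
#' @param x Feature matrix or single vector matching the training features.
#' @return Matrix, subjects x 3 class probabilities (columns named by class).
#' @export
nn_forward <- function(model, x) {
  stopifnot(inherits(model, "ost_net"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$W1)) {
    stop(sprintf("ostvol_dimension_error: model expects %d features, got %d",
                 nrow(model$W1), ncol(x)), call. = FALSE)
  }
  xs <- scale_features(x, model$center, model$scale)
  a1 <- tanh(sweep(xs %*% model$W1, 2, model$b1, "+"))
  p <- softmax_rows(sweep(a1 %*% model$W2, 2, model$b2, "+"))
  colnames(p) <- model$levels
  p
}

#' Predict survival classes
#'
#' @param object An [ost_net] fit.
#' @param newdata Feature matrix.
#' @param type `"class"` for hard labels (argmax, ties broken toward the
#'   lower class index) or `"prob"` for the probability matrix.
#' @param ... Unused.
#' @return Factor of predicted classes, or a probability matrix.
#' @export
predict.ost_net <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- nn_forward(object, newdata)
  if (type == "prob") return(p)
  factor(object$levels[max.col(p, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.ost_net <- function(x, ...) {
  cat(sprintf("Survival-class network: %d -> %d (tanh) -> 3 (softmax)\n",
              nrow(x$W1), x$hidden))
  cat(sprintf("  final training loss %.4f after %d epochs (lr=%g, l2=%g, seed=%d)\n",
              x$loss_trace[length(x$loss_trace)], length(x$loss_trace),
              x$config$learning_rate, x$l2, x$config$seed))
  invisible(x)
}

#' @export
summary.ost_net <- function(object, ...) {
  cat(sprintf("Single-hidden-layer survival classifier (%d features -> %d hidden -> 3 classes)\n",
              nrow(object$W1), object$hidden))
  cat(sprintf("  parameters: %d\n",
              length(object$W1) + length(object$b1) + length(object$W2) + length(object$b2)))
  cat(sprintf("  loss: initial %.4f, final %.4f over %d epochs\n",
              object$loss_trace[1L], object$loss_trace[length(object$loss_trace)],
              length(object$loss_trace)))
  if (!is.null(object$val_trace)) {
    cat(sprintf("  validation loss (early stopping): best %.4f\n",
                min(object$val_trace)))
  }
  invisible(object)
}

#' @export
coef.ost_net <- function(object, ...) {
  object[c("W1", "b1", "W2", "b2")]
}

#' @export
plot.ost_net <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "loss", main = "Training loss", ...)
  if (!is.null(x$val_trace)) {
    graphics::lines(seq_along(x$val_trace), x$val_trace, lty = 2)
    graphics::legend("topright", c("training", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Save / load a fitted network as a plain-text key-value file
#'
#' @param model An [ost_net] fit.
#' @param path Output file.
#' @return `write_ost_net` returns `path` invisibly; `read_ost_net` the
#'   restored model.
#' @export
write_ost_net <- function(model, path) {
  stopifnot(inherits(model, "ost_net"))
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(key, x) {
    writeLines(sprintf("%s %s", key,
                       paste(sprintf("%.17g", as.vector(x)), collapse = " ")),
               con)
  }
  emit("dims", c(nrow(model$W1), model$hidden))
  emit("W1", model$W1); emit("b1", model$b1)
  emit("W2", model$W2); emit("b2", model$b2)
  emit("center", model$center); emit("scale", model$scale)
  emit("l2", model$l2)
  writeLines(paste("levels", paste(model$levels, collapse = " ")), con)
  if (!is.null(model$feature_names)) {
    writeLines(paste("features", paste(model$feature_names, collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_ost_net
#' @export
read_ost_net <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(trimws(lines), "\\s+")
  get <- function(key) {
    hit <- kv[[which(vapply(kv, `[[`, "", 1L) == key)]][-1L]
    hit
  }
  dims <- as.integer(get("dims"))
  model <- list(
    W1 = matrix(as.numeric(get("W1")), dims[1L], dims[2L]),
    b1 = as.numeric(get("b1")),
    W2 = matrix(as.numeric(get("W2")), dims[2L], 3L),
    b2 = as.numeric(get("b2")),
    center = as.numeric(get("center")), scale = as.numeric(get("scale")),
    l2 = as.numeric(get("l2")),
    levels = get("levels"), hidden = dims[2L],
    feature_names = tryCatch(get("features"), error = function(e) NULL),
    loss_trace = NA_real_, config = list()
  )
  class(model) <- "ost_net"
  model
}

#' Baseline classifier adapter
#'
#' Uniform fit/predict interface over the comparison classifier families
#' (support vector machine, k-nearest neighbours, Gaussian naive Bayes,
#' linear discriminant, decision tree), delegating to their established
#' implementations; only the neural network is implemented in this package.
#'
#' @param method One of `"svm"`, `"knn"`, `"naive_bayes"`, `"lda"`,
#'   `"tree"`.
#' @param ... Passed to the underlying fit function.
#' @return List with functions `fit(x, y)` and `predict(fit, x)` returning a
#'   class factor.
#' @export
classifier_adapter <- function(method = c("svm", "knn", "naive_bayes", "lda", "tree"),
                               ...) {
  method <- match.arg(method)
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop(sprintf("ostvol_dependency_error: package '%s' required for method '%s'",
                   pkg, method), call. = FALSE)
    }
  }
  dots <- list(...)
  switch(method,
    svm = {
      need("e1071")
      list(fit = function(x, y) e1071::svm(x, as_class_factor(y), ...),
           predict = function(fit, x) predict(fit, x))
    },
    knn = {
      need("e1071")
      list(fit = function(x, y) list(x = x, y = as_class_factor(y),
                                     k = if (is.null(dots$k)) 5L else dots$k),
           predict = function(fit, x) {
             e1071::gknn(fit$x, fit$y, k = fit$k) |>
               predict(as.matrix(x))
           })
    },
    naive_bayes = {
      need("e1071")
      list(fit = function(x, y) e1071::naiveBayes(as.data.frame(x), as_class_factor(y), ...),
           predict = function(fit, x) predict(fit, as.data.frame(x)))
    },
    lda = {
      need("MASS")
      list(fit = function(x, y) MASS::lda(x, as_class_factor(y), ...),
           predict = function(fit, x) predict(fit, as.matrix(x))$class)
    },
    tree = {
      need("rpart")
      list(fit = function(x, y) {
             df <- as.data.frame(x); df$.y <- as_class_factor(y)
             rpart::rpart(.y ~ ., df, method = "class", ...)
           },
           predict = function(fit, x) {
             predict(fit, as.data.frame(x), type = "class")
           })
    })
}
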