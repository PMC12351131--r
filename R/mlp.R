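#' MLP configuration
#'
#' Hyperparameters of the single-hidden-layer perceptron used to classify
#' statistical cycles. The presets mirror the basic configuration under which
#' the method is intended to run: a hidden layer of 5, 10 or 100 neurons, two
#' output classes, learning rate 0.01, at most 1000 epochs, stopping
#' tolerance 1e-4 on the log loss, ReLU activation and the Adam optimizer
#' (a sigmoid/SGD preset is available via the `activation` and `optimizer`
#' arguments). Training is full-batch, which keeps runs deterministic for a
#' given seed.
#'
#' @param hidden_neurons Hidden-layer width (presets 5, 10, 100).
#' @param learning_rate Positive step size (default 0.01).
#' @param max_epochs Maximum training epochs (default 1000).
#' @param tolerance Stop when the loss has failed to improve by at least this
#'   amount for 10 consecutive epochs (default 1e-4).
#' @param activation Hidden-layer activation.
#' @param optimizer `"adam"` or plain gradient descent `"sgd"`.
#' @param seed Integer seed controlling weight initialization.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden_neurons = 5L, learning_rate = 0.01,
                       max_epochs = 1000L, tolerance = 1e-4,
                       activation = c("relu", "sigmoid"),
                       optimizer = c("adam", "sgd"), seed = 1L) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  stopifnot(hidden_neurons >= 1, learning_rate > 0, max_epochs >= 1,
            tolerance > 0)
  structure(list(hidden_neurons = as.integer(hidden_neurons),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), tolerance = tolerance,
                 activation = activation, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Train the cycle classifier
#'
#' Fits a two-class MLP (one hidden layer, softmax output, log loss) on a
#' feature matrix. Inputs are standardized to zero mean / unit variance using
#' statistics of the training data only; the scaler is stored in the model
#' and applied at prediction time, so no information leaks from evaluation
#' folds. Weights use Glorot-uniform initialization seeded from
#' `cfg$seed`; optimization is full-batch Adam (or SGD) on the cross-entropy.
#'
#' @param x Numeric feature matrix (rows = cycles) or a `cycle_features`
#'   table, in which case the `variance`, `skewness`, `kurtosis` columns (plus
#'   `center` when `use_center = TRUE`) form the inputs.
#' @param y Class labels: factor or character with values `"healthy"` /
#'   `"epilepsy"`. Taken from the table when `x` is a `cycle_features`.
#' @param cfg An [mlp_config()].
#' @param use_center Add the per-cycle center statistic as a fourth input.
#' @return An `mlp_model`: weights, scaler, loss history and config.
#' @export
train_mlp <- function(x, y = NULL, cfg = mlp_config(), use_center = FALSE) {
  if (inherits(x, "cycle_features")) {
    y <- x$label
    x <- feature_matrix(x, use_center)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || !all(is.finite(x))) {
    stop("feature matrix contains non-finite values", call. = FALSE)
  }
  y <- factor(as.character(y), levels = c("healthy", "epilepsy"))
  if (anyNA(y)) stop("labels must be 'healthy' or 'epilepsy'", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  n <- nrow(x); d <- ncol(x); h <- cfg$hidden_neurons
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, `/`)
  yi <- as.integer(y)                       # 1 = healthy, 2 = epilepsy
  t1 <- cbind(yi == 1L, yi == 2L) * 1       # one-hot targets

  params <- with_seed(cfg$seed, list(
    W1 = matrix(stats::runif(d * h, -1, 1) * sqrt(6 / (d + h)), d, h),
    b1 = numeric(h),
    W2 = matrix(stats::runif(h * 2, -1, 1) * sqrt(6 / (h + 2)), h, 2),
    b2 = numeric(2)
  ))
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  act <- if (cfg$activation == "relu") {
    list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1)
  } else {
    list(f = function(z) 1 / (1 + exp(-z)), df = function(z, a) a * (1 - a))
  }

  loss_hist <- numeric(0)
  best <- Inf
  stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    z1 <- sweep(xs %*% params$W1, 2L, params$b1, `+`)
    a1 <- act$f(z1)
    z2 <- sweep(a1 %*% params$W2, 2L, params$b2, `+`)
    zmax <- apply(z2, 1L, max)
    ez <- exp(z2 - zmax)
    p <- ez / rowSums(ez)
    loss <- -mean(log(pmax(p[cbind(seq_len(n), yi)], 1e-15)))
    loss_hist <- c(loss_hist, loss)

    dz2 <- (p - t1) / n
    grads <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(a1, dz2),
      b2 = colSums(dz2)
    )
    da1 <- dz2 %*% t(params$W2)
    dz1 <- da1 * act$df(z1, a1)
    grads$W1 <- crossprod(xs, dz1)
    grads$b1 <- colSums(dz1)

    if (cfg$optimizer == "adam") {
      for (k in names(params)) {
        adam_m[[k]] <- beta1 * adam_m[[k]] + (1 - beta1) * grads[[k]]
        adam_v[[k]] <- beta2 * adam_v[[k]] + (1 - beta2) * grads[[k]]^2
        mhat <- adam_m[[k]] / (1 - beta1^epoch)
        vhat <- adam_v[[k]] / (1 - beta2^epoch)
        params[[k]] <- params[[k]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    } else {
      for (k in names(params)) {
        params[[k]] <- params[[k]] - cfg$learning_rate * grads[[k]]
      }
    }

    # sklearn-style stopping: tol improvement must recur within 10 epochs
    if (loss < best - cfg$tolerance) {
      best <- loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 10L) break
    }
  }

  structure(list(params = params, center = ctr, scale = scl,
                 levels = c("healthy", "epilepsy"), use_center = use_center,
                 cfg = cfg, loss = loss_hist, epochs = length(loss_hist)),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d-%d-2 (%s, %s), %d epochs, final loss %.4g\n",
              nrow(x$params$W1), ncol(x$params$W1), x$cfg$activation,
              x$cfg$optimizer, x$epochs, x$loss[length(x$loss)]))
  invisible(x)
}

#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  if (inherits(newdata, "cycle_features")) {
    newdata <- feature_matrix(newdata, object$use_center)
  }
  x <- as.matrix(newdata)
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, `/`)
  z1 <- sweep(xs %*% object$params$W1, 2L, object$params$b1, `+`)
  a1 <- if (object$cfg$activation == "relu") pmax(z1, 0) else 1 / (1 + exp(-z1))
  z2 <- sweep(a1 %*% object$params$W2, 2L, object$params$b2, `+`)
  ez <- exp(z2 - apply(z2, 1L, max))
  p <- ez / rowSums(ez)
  colnames(p) <- object$levels
  if (type == "prob") {
    return(p)
  }
  factor(object$levels[max.col(p, ties.method = "first")],
         levels = object$levels)
}

# default inputs: the three dispersion/shape moments; the center statistic is
# an optional fourth input
feature_matrix <- function(features, use_center = FALSE) {
  cols <- c(if (use_center) "center", "variance", "skewness", "kurtosis")
  as.matrix(features[, cols, drop = FALSE])
}
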