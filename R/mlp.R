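# Minimal feed-forward network for tabular binary classification: one or
# two 50-unit rectified-linear hidden layers into a 2-unit softmax, trained
# by mini-batch Adam on the categorical cross-entropy. Written directly on
# matrix operations; the networks involved are tiny (3 -> 50 -> 50 -> 2).

#' Multilayer perceptron specification
#'
#' @param input_dim Number of input features.
#' @param hidden_layers 1 or 2 hidden layers.
#' @param hidden_units Units per hidden layer.
#' @param epochs Number of full passes over the training data.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A list of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim = 3L, hidden_layers = 1L, hidden_units = 50L,
                     epochs = 100L, batch_size = 16L, learning_rate = 1e-3,
                     seed = 1L) {
  if (!hidden_layers %in% c(1L, 2L)) stop("`hidden_layers` must be 1 or 2")
  if (!is_count(epochs)) stop("`epochs` must be a positive integer")
  if (!is_count(batch_size) || !is_count(hidden_units) || !is_count(input_dim)) {
    stop("`input_dim`, `hidden_units` and `batch_size` must be positive integers")
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden_layers = as.integer(hidden_layers),
                 hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "mlp_spec")
}

.mlp_init <- function(spec) {
  dims <- c(spec$input_dim,
            rep(spec$hidden_units, spec$hidden_layers), 2L)
  weights <- vector("list", length(dims) - 1)
  for (l in seq_along(weights)) {
    # He initialization for the rectified-linear layers
    weights[[l]] <- list(
      W = matrix(stats::rnorm(dims[l] * dims[l + 1],
                              sd = sqrt(2 / dims[l])),
                 nrow = dims[l]),
      b = rep(0, dims[l + 1])
    )
  }
  weights
}

.mlp_forward <- function(weights, X) {
  L <- length(weights)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L - 1)) {
    z <- acts[[l]] %*% weights[[l]]$W
    z <- sweep(z, 2, weights[[l]]$b, "+")
    acts[[l + 1]] <- pmax(z, 0)
  }
  z <- acts[[L]] %*% weights[[L]]$W
  z <- sweep(z, 2, weights[[L]]$b, "+")
  z <- z - pmax(z[, 1], z[, 2]) # stabilized softmax (binary output)
  p <- exp(z)
  list(probs = p / rowSums(p), acts = acts)
}

.mlp_loss_acc <- function(weights, X, Y) {
  p <- .mlp_forward(weights, X)$probs
  eps <- 1e-12
  list(loss = -mean(rowSums(Y * log(p + eps))),
       acc = mean(max.col(p) == max.col(Y)))
}

#' Train a multilayer perceptron classifier
#'
#' Trains the network specified by an [mlp_spec()] with mini-batch Adam on
#' the categorical cross-entropy for exactly `epochs` passes, recording
#' training and validation accuracy and loss after every epoch. Inputs are
#' expected already scaled (see [fit_robust_scaler()]).
#'
#' @param train,validation Data frames holding the feature columns and a
#'   `label` column with two classes. `validation` may be `NULL`, in which
#'   case the history's validation columns are `NA`.
#' @param spec An [mlp_spec()].
#' @param features Feature column names (length must equal
#'   `spec$input_dim`).
#' @return A list with `model` (class `qcr_mlp`) and `history` (data frame
#'   with `epoch`, `train_acc`, `train_loss`, `val_acc`, `val_loss`).
#' @export
train_mlp <- function(train, validation = NULL, spec = mlp_spec(),
                      features = c("delta_f", "delta_gamma", "eta")) {
  stopifnot(inherits(spec, "mlp_spec"))
  if (length(features) != spec$input_dim) {
    stop(sprintf("spec expects %d input features, got %d",
                 spec$input_dim, length(features)))
  }
  classes <- .class_levels(train$label)
  X <- as.matrix(train[, features, drop = FALSE])
  Y <- .one_hot(train$label, classes)
  has_val <- !is.null(validation) && nrow(validation) > 0
  if (has_val) {
    Xv <- as.matrix(validation[, features, drop = FALSE])
    Yv <- .one_hot(validation$label, classes)
  }

  with_seed(spec$seed, {
    weights <- .mlp_init(spec)
    L <- length(weights)
    # Adam state
    m <- lapply(weights, function(w) list(W = 0 * w$W, b = 0 * w$b))
    v <- m
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
    lr <- spec$learning_rate
    t <- 0
    n <- nrow(X)
    history <- data.frame(epoch = seq_len(spec$epochs), train_acc = NA_real_,
                          train_loss = NA_real_, val_acc = NA_real_,
                          val_loss = NA_real_)

    for (epoch in seq_len(spec$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = spec$batch_size)
      for (s in starts) {
        batch <- idx[s:min(s + spec$batch_size - 1, n)]
        Xb <- X[batch, , drop = FALSE]
        Yb <- Y[batch, , drop = FALSE]
        fwd <- .mlp_forward(weights, Xb)
        nb <- length(batch)
        # softmax + cross-entropy gradient at the logits
        delta <- (fwd$probs - Yb) / nb
        grads <- vector("list", L)
        for (l in L:1) {
          grads[[l]] <- list(W = crossprod(fwd$acts[[l]], delta),
                             b = colSums(delta))
          if (l > 1) {
            delta <- (delta %*% t(weights[[l]]$W)) * (fwd$acts[[l]] > 0)
          }
        }
        t <- t + 1
        corr <- sqrt(1 - beta2^t) / (1 - beta1^t)
        for (l in seq_len(L)) {
          for (p in c("W", "b")) {
            g <- grads[[l]][[p]]
            m[[l]][[p]] <- beta1 * m[[l]][[p]] + (1 - beta1) * g
            v[[l]][[p]] <- beta2 * v[[l]][[p]] + (1 - beta2) * g^2
            weights[[l]][[p]] <- weights[[l]][[p]] -
              lr * corr * m[[l]][[p]] / (sqrt(v[[l]][[p]]) + adam_eps)
          }
        }
      }
      tr <- .mlp_loss_acc(weights, X, Y)
      history$train_acc[epoch] <- tr$acc
      history$train_loss[epoch] <- tr$loss
      if (has_val) {
        va <- .mlp_loss_acc(weights, Xv, Yv)
        history$val_acc[epoch] <- va$acc
        history$val_loss[epoch] <- va$loss
      }
    }
    model <- structure(list(weights = weights, classes = classes,
                            features = features, spec = spec),
                       class = "qcr_mlp")
    list(model = model, history = history)
  })
}

#' @export
predict.qcr_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  p <- .mlp_forward(object$weights, X)$probs
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  object$classes[max.col(p)]
}

# fixed class ordering: inflammatory first (the positive class of the
# confusion-matrix orientation), then infectious; other label sets sorted
.class_levels <- function(labels) {
  u <- unique(labels)
  if (setequal(u, c("inflammatory", "infectious"))) {
    c("inflammatory", "infectious")
  } else {
    sort(u)
  }
}

.one_hot <- function(labels, classes) {
  Y <- matrix(0, nrow = length(labels), ncol = length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}
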