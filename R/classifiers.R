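# Classification workflow: train/validation/test splitting (by point or by
# whole sample), random oversampling of the minority class, robust
# median/IQR scaling, the three classifier families (MLP, linear
# squared-hinge SVM, random forest), and confusion-matrix evaluation.

#' Dataset split specification
#'
#' @param fractions Named or ordered numeric vector
#'   `(train, validation, test)` summing to 1. The validation fraction may
#'   be 0 (the SVM/RF mode uses 0.85/0/0.15).
#' @param mode `"point"` shuffles and partitions individual rows;
#'   `"grouped"` assigns whole `sample_id`s to one partition, so repeated
#'   measurements of a sample never straddle the split (leakage control).
#' @param seed Integer seed.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.70, validation = 0.15, test = 0.15),
                       mode = c("point", "grouped"), seed = 1L) {
  mode <- match.arg(mode)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be three nonnegative numbers summing to 1")
  }
  if (fractions[1] <= 0 || fractions[3] <= 0) {
    stop("train and test fractions must be positive")
  }
  structure(list(fractions = unname(fractions), mode = mode,
                 seed = as.integer(seed)),
            class = "split_spec")
}

# partition sizes: test and validation round up, train takes the remainder
# (the convention of the usual two-stage hold-out split, which yields test
# sets of 746 rows from 4972 and 788 from 5248 at 70/15/15)
.split_sizes <- function(n, fractions) {
  n_test <- ceiling(fractions[3] * n)
  rest <- n - n_test
  n_val <- if (fractions[2] > 0) {
    ceiling(fractions[2] / (fractions[1] + fractions[2]) * rest)
  } else 0L
  c(train = rest - n_val, validation = n_val, test = n_test)
}

#' Split a dataset into train/validation/test partitions
#'
#' The partition is exhaustive and disjoint. In `"point"` mode rows are
#' shuffled and dealt out with the test and validation sizes rounded up;
#' in `"grouped"` mode the same rule is applied to shuffled `sample_id`s,
#' so all rows of a sample land in one partition.
#'
#' @param rows Data frame of measurement rows.
#' @param spec A [split_spec()].
#' @return Named list of data frames `train`, `validation`, `test`
#'   (`validation` has zero rows when its fraction is 0).
#' @export
#' @examples
#' rows <- generate_cohort(cohort_config("EDTA"))
#' parts <- split_dataset(rows, split_spec(seed = 2))
#' vapply(parts, nrow, integer(1)) # 3480 / 746 / 746
split_dataset <- function(rows, spec) {
  stopifnot(inherits(spec, "split_spec"))
  if (nrow(rows) == 0) stop("cannot split an empty table")
  with_seed(spec$seed, {
    if (spec$mode == "point") {
      sizes <- .split_sizes(nrow(rows), spec$fractions)
      idx <- sample.int(nrow(rows))
      assign_part <- rep(c("train", "validation", "test"), sizes)
      parts <- split(idx, assign_part)
    } else {
      ids <- unique(rows$sample_id)
      n_parts <- 2L + (spec$fractions[2] > 0)
      if (length(ids) < n_parts) {
        stop("grouped split needs at least as many samples as partitions")
      }
      sizes <- .split_sizes(length(ids), spec$fractions)
      ids <- sample(ids)
      assign_part <- rep(c("train", "validation", "test"), sizes)
      parts <- lapply(split(ids, assign_part),
                      function(s) which(rows$sample_id %in% s))
    }
    out <- lapply(c(train = "train", validation = "validation", test = "test"),
                  function(p) {
                    r <- rows[parts[[p]] %||% integer(0), , drop = FALSE]
                    rownames(r) <- NULL
                    r
                  })
    out
  })
}

#' Randomly oversample the minority class
#'
#' Resamples minority-class rows with replacement until both classes have
#' the same count; majority rows are kept untouched. The result is
#' shuffled.
#'
#' @param rows Data frame with a two-class `label` column.
#' @param seed Integer seed.
#' @return Balanced data frame with `2 * max(class count)` rows.
#' @export
oversample_minority <- function(rows, seed = 1L) {
  counts <- table(rows$label)
  if (length(counts) < 2) stop("oversampling needs both classes present")
  majority <- names(which.max(counts))
  minority <- names(which.min(counts))
  with_seed(seed, {
    need <- counts[[majority]] - counts[[minority]]
    extra <- rows[sample(which(rows$label == minority), need, replace = TRUE), ,
                  drop = FALSE]
    out <- rbind(rows, extra)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Fit a robust (median/IQR) scaler on training data
#'
#' Centers each feature by its training median and scales by its training
#' interquartile range, with quartiles computed by linear interpolation
#' (R's default quantile type 7). Parameters are fitted on training data
#' only and applied unchanged elsewhere via [apply_scaler()].
#'
#' @param train Training data frame.
#' @param features Feature column names.
#' @return A list of class `scaler_params` with named `center` and `scale`
#'   vectors.
#' @export
#' @examples
#' fit_robust_scaler(data.frame(x = 1:5), "x") # center 3, scale 2
fit_robust_scaler <- function(train, features = c("delta_f", "delta_gamma", "eta")) {
  center <- vapply(features, function(f) stats::median(train[[f]]), numeric(1))
  scale <- vapply(features, function(f) {
    q <- stats::quantile(train[[f]], c(0.25, 0.75), names = FALSE, type = 7)
    q[2] - q[1]
  }, numeric(1))
  degenerate <- features[scale <= 0]
  if (length(degenerate) > 0) {
    stop("zero interquartile range for feature(s): ",
         paste(degenerate, collapse = ", "))
  }
  structure(list(center = center, scale = scale, features = features),
            class = "scaler_params")
}

#' Apply fitted robust-scaler parameters
#'
#' @param params A [fit_robust_scaler()] result.
#' @param table Data frame containing the scaler's feature columns.
#' @return `table` with the feature columns replaced by
#'   `(x - center) / scale`.
#' @export
apply_scaler <- function(params, table) {
  stopifnot(inherits(params, "scaler_params"))
  for (f in params$features) {
    table[[f]] <- (table[[f]] - params$center[[f]]) / params$scale[[f]]
  }
  table
}

#' Train a linear support vector machine with squared-hinge loss
#'
#' Minimizes the primal objective
#' \deqn{\tfrac12 \|w\|^2 + C \sum_i \max(0, 1 - y_i (x_i w + b))^2}
#' by L-BFGS; the objective is smooth and convex, so the quasi-Newton
#' solution is exact for practical purposes. Decisions are by the sign of
#' the decision function.
#'
#' @param train Data frame with feature columns (already scaled) and a
#'   two-class `label` column.
#' @param features Feature column names.
#' @param cost Penalty parameter C.
#' @return A model of class `qcr_svm`.
#' @export
train_svm <- function(train, features = c("delta_f", "delta_gamma", "eta"),
                      cost = 1) {
  classes <- .class_levels(train$label)
  if (length(unique(train$label)) < 2) {
    stop("SVM training needs both classes present")
  }
  X <- as.matrix(train[, features, drop = FALSE])
  y <- ifelse(train$label == classes[1], 1, -1)
  d <- ncol(X)
  obj <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1]
    margin <- 1 - y * (X %*% w + b)
    viol <- pmax(margin, 0)
    0.5 * sum(w^2) + cost * sum(viol^2)
  }
  grad <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1]
    margin <- 1 - y * (X %*% w + b)
    viol <- pmax(margin, 0)
    coef <- -2 * cost * viol * y
    c(w + drop(crossprod(X, coef)), sum(coef))
  }
  fit <- stats::optim(rep(0, d + 1), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 1000, factr = 1e4))
  structure(list(w = fit$par[seq_len(d)], b = fit$par[d + 1],
                 classes = classes, features = features, cost = cost,
                 converged = fit$convergence == 0),
            class = "qcr_svm")
}

#' @export
predict.qcr_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  score <- drop(X %*% object$w + object$b)
  ifelse(score >= 0, object$classes[1], object$classes[2])
}

#' Train a random forest classifier
#'
#' Fits a forest of Gini-impurity trees with bootstrap sampling via
#' `ranger`. Defaults follow the published configuration: 2171 trees,
#' minimum node size 1 (equivalent to a minimum split of 2 observations)
#' and a depth cap of 200.
#'
#' @param train Data frame with feature columns and a two-class `label`
#'   column.
#' @param features Feature column names.
#' @param seed Integer seed.
#' @param num_trees,max_depth,min_node_size Forest hyperparameters.
#' @return A model of class `qcr_rf`; `$num_trees` reports the fitted
#'   ensemble size.
#' @export
train_rf <- function(train, features = c("delta_f", "delta_gamma", "eta"),
                     seed = 1L, num_trees = 2171L, max_depth = 200L,
                     min_node_size = 1L) {
  if (length(unique(train$label)) < 2) {
    stop("random forest training needs both classes present")
  }
  dat <- train[, features, drop = FALSE]
  dat$label <- factor(train$label, levels = .class_levels(train$label))
  fit <- ranger::ranger(
    dependent.variable.name = "label", data = dat,
    num.trees = num_trees, splitrule = "gini", max.depth = max_depth,
    min.node.size = min_node_size, replace = TRUE, seed = seed,
    num.threads = 1L
  )
  structure(list(fit = fit, features = features,
                 classes = levels(dat$label), num_trees = fit$num.trees),
            class = "qcr_rf")
}

#' @export
predict.qcr_rf <- function(object, newdata, ...) {
  p <- stats::predict(object$fit,
                      data = newdata[, object$features, drop = FALSE],
                      num.threads = 1L)
  as.character(p$predictions)
}

#' Confusion matrix with the inflammatory-positive orientation
#'
#' TP counts inflammatory rows predicted inflammatory, TN infectious rows
#' predicted infectious, FP infectious rows predicted inflammatory, and FN
#' inflammatory rows predicted infectious.
#'
#' @param truth,predicted Character vectors of true and predicted labels.
#' @param positive Label counted as positive (default `"inflammatory"`).
#' @return A list of class `confusion_matrix` with integer `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_matrix <- function(truth, predicted, positive = "inflammatory") {
  stopifnot(length(truth) == length(predicted))
  if (length(truth) == 0) stop("confusion matrix needs at least one case")
  is_pos <- truth == positive
  pred_pos <- predicted == positive
  structure(list(tp = sum(is_pos & pred_pos),
                 fn = sum(is_pos & !pred_pos),
                 fp = sum(!is_pos & pred_pos),
                 tn = sum(!is_pos & !pred_pos)),
            class = "confusion_matrix")
}

#' Accuracy from a confusion matrix
#'
#' Pure arithmetic: `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cm A [confusion_matrix()] or a list with `tp`, `tn`, `fp`, `fn`.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
#' @examples
#' accuracy_from_matrix(list(tp = 627, fn = 4, fp = 10, tn = 147)) # 774/788
accuracy_from_matrix <- function(cm) {
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (is.null(total) || total <= 0) stop("confusion matrix is empty")
  (cm$tp + cm$tn) / total
}

#' Evaluate a classifier on a test set
#'
#' Predicts labels, forms the inflammatory-positive confusion matrix, and
#' reports the accuracy at full precision alongside two 2-decimal
#' renderings: `accuracy_rounded` (round half to even) and
#' `accuracy_truncated` (floor), the latter matching how the reference
#' accuracy tables were printed.
#'
#' @param model A fitted `qcr_mlp`, `qcr_svm` or `qcr_rf` model.
#' @param test Nonempty data frame with feature columns and `label`.
#' @return List with `confusion`, `accuracy`, `accuracy_rounded`,
#'   `accuracy_truncated`.
#' @export
evaluate <- function(model, test) {
  if (nrow(test) == 0) stop("test set is empty")
  pred <- stats::predict(model, test)
  cm <- confusion_matrix(test$label, pred)
  acc <- accuracy_from_matrix(cm)
  list(confusion = cm, accuracy = acc,
       accuracy_rounded = round2(acc), accuracy_truncated = trunc2(acc))
}
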