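# Splitting, oversampling, robust scaling, the three model families, and
# confusion-matrix arithmetic.

test_that("70/15/15 point split reproduces the published partition sizes", {
  edta <- generate_cohort(cohort_config("EDTA", seed = 3))
  parts <- split_dataset(edta, split_spec(seed = 2))
  expect_equal(vapply(parts, nrow, integer(1)),
               c(train = 3480L, validation = 746L, test = 746L))
  hep <- generate_cohort(cohort_config("heparin", seed = 3))
  parts_h <- split_dataset(hep, split_spec(seed = 2))
  expect_equal(vapply(parts_h, nrow, integer(1)),
               c(train = 3672L, validation = 788L, test = 788L))
  # exhaustive and disjoint
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(edta))
  key <- function(d) paste(d$sample_id, d$rep, d$point)
  all_keys <- unname(unlist(lapply(parts, key)))
  expect_equal(sort(all_keys), sort(key(edta)))
})

test_that("grouped split keeps each sample in one partition", {
  rows <- generate_cohort(tiny_cohort_config(seed = 5))
  parts <- split_dataset(rows, split_spec(mode = "grouped", seed = 4))
  ids <- lapply(parts, function(p) unique(p$sample_id))
  expect_equal(length(Reduce(intersect, ids[c("train", "test")])), 0)
  expect_equal(length(intersect(ids$train, ids$validation)), 0)
  expect_setequal(unlist(ids), unique(rows$sample_id))
  # too few samples for three partitions
  two <- rows[rows$sample_id %in% unique(rows$sample_id)[1:2], ]
  expect_error(split_dataset(two, split_spec(mode = "grouped", seed = 1)),
               "at least as many samples")
})

test_that("splits are reproducible under their seed", {
  rows <- generate_cohort(tiny_cohort_config(seed = 5))
  a <- split_dataset(rows, split_spec(seed = 9))
  b <- split_dataset(rows, split_spec(seed = 9))
  expect_identical(a, b)
  c <- split_dataset(rows, split_spec(seed = 10))
  expect_false(identical(a$test, c$test))
})

test_that("oversampling balances classes without touching majority rows", {
  set.seed(3)
  rows <- data.frame(id = 1:120,
                     label = rep(c("inflammatory", "infectious"), c(100, 20)),
                     delta_f = rnorm(120))
  bal <- oversample_minority(rows, seed = 6)
  expect_equal(nrow(bal), 200)
  expect_equal(unname(table(bal$label)["infectious"]), 100, ignore_attr = TRUE)
  # every majority row present exactly once
  expect_setequal(bal$id[bal$label == "inflammatory"], 1:100)
  # every synthetic minority row is a copy of an input row
  expect_true(all(bal$id[bal$label == "infectious"] %in% 101:120))
  # already balanced input is unchanged up to order
  bal2 <- oversample_minority(bal, seed = 7)
  expect_equal(nrow(bal2), nrow(bal))
  expect_setequal(paste(bal2$id, bal2$delta_f), paste(bal$id, bal$delta_f))
  expect_error(oversample_minority(rows[rows$label == "inflammatory", ]),
               "both classes")
})

test_that("robust scaler matches the hand-computed quartile convention", {
  sc <- fit_robust_scaler(data.frame(x = c(1, 2, 3, 4, 5)), "x")
  expect_equal(unname(sc$center), 3)
  expect_equal(unname(sc$scale), 2)
  out <- apply_scaler(sc, data.frame(x = c(1, 2, 3, 4, 5)))
  expect_equal(out$x, c(-1, -0.5, 0, 0.5, 1))
  expect_error(fit_robust_scaler(data.frame(x = rep(2, 10)), "x"), "x")
})

test_that("scaled training features have median 0 and IQR 1", {
  set.seed(8)
  train <- data.frame(delta_f = rnorm(500, -3700, 100),
                      delta_gamma = rnorm(500, 1800, 60),
                      eta = rnorm(500, 3.5, 0.2))
  sc <- fit_robust_scaler(train)
  scaled <- apply_scaler(sc, train)
  for (f in c("delta_f", "delta_gamma", "eta")) {
    expect_equal(median(scaled[[f]]), 0)
    expect_equal(diff(quantile(scaled[[f]], c(0.25, 0.75), names = FALSE)), 1)
  }
})

test_that("the MLP solves a well-separated two-blob problem", {
  blobs <- make_blobs(n = 1000, separation = 6)
  parts <- split_dataset(blobs, split_spec(seed = 12))
  fit <- train_mlp(parts$train, parts$validation,
                   mlp_spec(epochs = 100L, seed = 13))
  expect_equal(nrow(fit$history), 100)
  expect_true(all(fit$history$train_acc >= 0 & fit$history$train_acc <= 1))
  expect_true(all(is.finite(fit$history$val_loss)))
  ev <- evaluate(fit$model, parts$test)
  expect_gte(ev$accuracy, 0.99)
})

test_that("MLP specification and inputs are validated", {
  expect_error(mlp_spec(epochs = 0), "positive integer")
  expect_error(mlp_spec(hidden_layers = 3), "1 or 2")
  blobs <- make_blobs(n = 60)
  expect_error(train_mlp(blobs, NULL, mlp_spec(input_dim = 5L)),
               "5 input features")
})

test_that("MLP training is deterministic under its seed", {
  blobs <- make_blobs(n = 200, separation = 2)
  f1 <- train_mlp(blobs, NULL, mlp_spec(epochs = 5L, seed = 3))
  f2 <- train_mlp(blobs, NULL, mlp_spec(epochs = 5L, seed = 3))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$weights, f2$model$weights)
})

test_that("squared-hinge SVM separates a separable toy set", {
  blobs <- make_blobs(n = 200, separation = 8)
  svm <- train_svm(blobs)
  expect_true(svm$converged)
  expect_equal(mean(predict(svm, blobs) == blobs$label), 1.0)
  expect_error(train_svm(blobs[blobs$label == "infectious", ]),
               "both classes")
})

test_that("squared-hinge SVM agrees with a reference linear SVM", {
  skip_if_not_installed("e1071")
  set.seed(15)
  blobs <- make_blobs(n = 400, separation = 1.5, seed = 16)
  svm <- train_svm(blobs)
  ref <- e1071::svm(factor(label) ~ delta_f + delta_gamma + eta,
                    data = blobs, kernel = "linear", cost = 1, scale = FALSE)
  agree <- mean(predict(svm, blobs) == as.character(predict(ref, blobs)))
  # same family, different loss (squared vs plain hinge): decisions should
  # coincide away from the margin
  expect_gte(agree, 0.95)
})

test_that("random forest honors the published ensemble configuration", {
  rows <- generate_cohort(tiny_cohort_config(seed = 19))
  rf <- train_rf(rows, seed = 20)
  expect_equal(rf$num_trees, 2171)
  p1 <- predict(rf, rows)
  p2 <- predict(train_rf(rows, seed = 20), rows)
  expect_identical(p1, p2)
  expect_error(train_rf(rows[rows$label == "inflammatory", ]),
               "both classes")
})

test_that("confusion matrices follow the inflammatory-positive orientation", {
  truth <- c("inflammatory", "inflammatory", "infectious", "infectious")
  pred <- c("inflammatory", "infectious", "inflammatory", "infectious")
  cm <- confusion_matrix(truth, pred)
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")],
               list(tp = 1L, fn = 1L, fp = 1L, tn = 1L), ignore_attr = TRUE)
})

test_that("published worked accuracy examples are reproduced by the formula", {
  # 562 12 / 53 119: 681/746
  expect_equal(accuracy_from_matrix(list(tp = 562, fn = 12, fp = 53, tn = 119)),
               681 / 746)
  # 627 04 / 10 147: 774/788
  expect_equal(accuracy_from_matrix(list(tp = 627, fn = 4, fp = 10, tn = 147)),
               774 / 788)
  # 488 86 / 20 152: 640/746 = 0.8579..., truncating to 0.85 while
  # rounding would give 0.86
  acc <- accuracy_from_matrix(list(tp = 488, fn = 86, fp = 20, tn = 152))
  expect_equal(acc, 640 / 746)
  expect_equal(floor(acc * 100) / 100, 0.85)
  expect_equal(round(acc, 2), 0.86)
  expect_equal(accuracy_from_matrix(list(tp = 1, fn = 0, fp = 0, tn = 1)), 1)
  expect_equal(accuracy_from_matrix(list(tp = 0, fn = 1, fp = 1, tn = 0)), 0)
  expect_error(accuracy_from_matrix(list(tp = 0, fn = 0, fp = 0, tn = 0)),
               "empty")
})

test_that("evaluation marginals match the test-set class composition", {
  rows <- generate_cohort(tiny_cohort_config(seed = 23))
  parts <- split_dataset(rows, split_spec(c(0.85, 0, 0.15), seed = 24))
  sc <- fit_robust_scaler(parts$train)
  svm <- train_svm(apply_scaler(sc, parts$train))
  ev <- evaluate(svm, apply_scaler(sc, parts$test))
  cm <- ev$confusion
  expect_equal(cm$tp + cm$fn, sum(parts$test$label == "inflammatory"))
  expect_equal(cm$tn + cm$fp, sum(parts$test$label == "infectious"))
  expect_equal(ev$accuracy, accuracy_from_matrix(cm))
})
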