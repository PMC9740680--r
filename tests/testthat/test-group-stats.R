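# Mann-Whitney U, ROC/AUC, and the class summary tables, each checked
# against an independent oracle.

test_that("fully separated small groups give U = 0 and exact p = 0.1", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1) # 2/20 labelings are as extreme
  expect_equal(mw$method, "exact")
})

test_that("U is antisymmetric under group swap with unchanged p", {
  set.seed(7)
  for (i in 1:20) {
    x <- round(rnorm(sample(4:8, 1)), 1) # rounding induces occasional ties
    y <- round(rnorm(sample(4:8, 1)), 1)
    a <- mann_whitney_u(x, y)
    b <- mann_whitney_u(y, x)
    expect_equal(a$U + b$U, length(x) * length(y))
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("identical groups are maximally non-significant", {
  x <- c(5, 6, 7, 8, 9, 10, 11, 12)
  mw <- mann_whitney_u(x, x) # n1 + n2 = 16 -> normal approximation
  expect_equal(mw$U, length(x)^2 / 2)
  expect_equal(mw$p_value, 1)
})

test_that("package enumeration agrees with the independent enumeration oracle", {
  set.seed(11)
  for (i in 1:10) {
    x <- round(rnorm(5), 1)
    y <- round(rnorm(5, 0.5), 1)
    expect_equal(mann_whitney_u(x, y)$p_value, mw_p_enumeration(x, y))
  }
})

test_that("normal approximation tracks exact enumeration for small groups", {
  # exhaustive over all achievable U: the continuity-corrected normal
  # approximation is within 0.02 of exact for n1 = n2 of 5 and 6; at
  # n = 4 its intrinsic worst case is 0.0305 (at U = 4), so that is the
  # bound asserted there
  for (n in 4:6) {
    combos <- utils::combn(2 * n, n)
    us_all <- colSums(matrix(seq_len(2 * n)[combos], nrow = n)) -
      n * (n + 1) / 2
    mu <- n * n / 2
    for (u in unique(us_all)) {
      exact <- mean(abs(us_all - mu) >= abs(u - mu) - 1e-9)
      sigma <- sqrt(n * n / 12 * (2 * n + 1))
      z <- if (u == mu) 0 else (u - mu - sign(u - mu) * 0.5) / sigma
      p_norm <- min(1, 2 * pnorm(-abs(z)))
      expect_lt(abs(exact - p_norm), if (n == 4) 0.035 else 0.02)
    }
  }
  # and the package's normal path reproduces that approximation on data
  set.seed(13)
  x <- rnorm(6); y <- rnorm(6, 0.8)
  mw_n <- mann_whitney_u(x, y, exact_limit = 0L)
  mw_e <- mann_whitney_u(x, y)
  expect_lt(abs(mw_n$p_value - mw_e$p_value), 0.02)
  expect_equal(mw_n$method, "normal")
  expect_equal(mw_e$method, "exact")
})

test_that("exact p agrees with wilcox.test on tie-free data", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6, 0.5)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    mw <- mann_whitney_u(x, y)
    expect_equal(mw$U, unname(ref$statistic))
    expect_equal(mw$p_value, ref$p.value)
  }
})

test_that("rank AUC equals brute-force pair counting on random instances", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    labels <- sample(c("infectious", "inflammatory"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1) # ties occur
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_bruteforce(scores, labels, "infectious"))
  }
})

test_that("worked AUC example: 3 of 4 pairs concordant", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.85), c("pos", "pos", "neg", "neg"),
               positive = "pos")
  expect_equal(r$auc, 0.75)
  # Hanley-McNeil SE by hand: Q1 = 0.6, Q2 = 0.642857...
  se_hand <- sqrt((0.75 * 0.25 + (0.6 - 0.5625) + (2 * 0.5625 / 1.75 - 0.5625)) / 4)
  expect_equal(r$se, se_hand)
  expect_equal(r$ci_low, max(0, 0.75 - 1.96 * se_hand))
})

test_that("perfect separation gives AUC 1 with zero standard error", {
  r <- roc_auc(c(1, 2, 3, 10, 11, 12),
               rep(c("inflammatory", "infectious"), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$se, 0)
  expect_equal(r$ci_high, 1)
})

test_that("orientation is fixed: anti-predictive scores keep AUC below 0.5", {
  scores <- c(5, 4, 3, 2, 1, 0)
  labels <- rep(c("infectious", "inflammatory"), each = 3)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, 1) # infectious scores higher
  r_flipped <- roc_auc(-scores, labels)
  expect_equal(r_flipped$auc, 0) # reported as-is, never auto-flipped
})

test_that("ROC curve is a monotone path from (0,0) to (1,1)", {
  set.seed(23)
  r <- roc_auc(rnorm(200), sample(c("infectious", "inflammatory"), 200,
                                  replace = TRUE))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_true(r$auc >= 0.5 - 0.15 && r$auc <= 0.5 + 0.15)
})

test_that("rank AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- rnorm(300)
  labels <- ifelse(rbinom(300, 1, plogis(scores)) == 1, "infectious",
                   "inflammatory")
  r <- roc_auc(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores,
                   levels = c("inflammatory", "infectious"),
                   direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
})

test_that("simulated Gaussian AUC converges to the binormal closed form", {
  r <- simulate_binormal_auc(1, 1, 0, 1, n = 1e5, seed = 31)
  expect_lt(abs(r$auc - pnorm(1 / sqrt(2))), 0.01)
})

test_that("summary table has the published layout and sane defaults", {
  rows <- generate_cohort(cohort_config("EDTA", seed = 37))
  st <- summary_table(rows)
  expect_equal(st$feature, c("delta_f", "delta_gamma", "eta"))
  expect_equal(st$auc_n, rep(33, 3)) # per-sample mode by default
  # pooled class means of eta near the configured 3.46 / 3.43 mPa s
  eta_row <- st[st$feature == "eta", ]
  expect_lt(abs(eta_row$mean_inflammatory - 3.46) / 3.46, 0.03)
  expect_lt(abs(eta_row$mean_infectious - 3.43) / 3.43, 0.03)
  expect_true(all(st$ci_low <= st$auc & st$auc <= st$ci_high))
  # point mode uses all rows
  expect_equal(summary_table(rows, auc_mode = "point")$auc_n[1], 4972)
  expect_error(summary_table(rows, features = "nonexistent"), "nonexistent")
})

test_that("statistically identical classes give null AUC at large n", {
  set.seed(41)
  rows <- data.frame(
    sample_id = rep(sprintf("s%03d", 1:100), each = 100),
    label = rep(c("inflammatory", "infectious"), each = 5000),
    delta_f = rnorm(10000, -3700, 100)
  )
  st <- summary_table(rows, features = "delta_f", auc_mode = "point")
  expect_lt(abs(st$auc - 0.5), 0.02)
})
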