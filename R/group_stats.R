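# Nonparametric group comparison and diagnostic-accuracy statistics:
# Mann-Whitney U with exact enumeration for small groups, ROC/AUC by pair
# concordance with the Hanley-McNeil standard error, and class summary
# tables in the mean +/- SD / p / AUC (CI) layout.

#' Mann-Whitney U test
#'
#' Computes the U statistic as the number of (x, y) pairs with x > y plus
#' half the tied pairs (midranks). For combined group sizes up to
#' `exact_limit` the two-sided p-value is obtained by exact enumeration of
#' all group labelings of the pooled values; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors, both nonempty.
#' @param exact_limit Largest combined size for which the permutation
#'   distribution is enumerated exactly.
#' @return A list of class `mw_test` with `U`, `p_value`, `n1`, `n2`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  if (any(!is.finite(c(x, y)))) stop("values must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n <= exact_limit) {
    combos <- utils::combn(n, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    # two-sided: mass at least as far from the null mean as observed
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      # continuity correction of 1/2 toward the mean
      z <- (u - mu - sign(u - mu) * 0.5) / sigma
      if (u == mu) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(list(U = u, p_value = p, n1 = n1, n2 = n2, method = method),
            class = "mw_test")
}

#' ROC curve and AUC with Hanley-McNeil standard error
#'
#' The AUC is the pair-concordance probability: concordant pairs plus half
#' the ties, divided by `n_pos * n_neg`, with higher scores treated as more
#' indicative of the positive class. The orientation is fixed - an AUC
#' below 0.5 is reported as-is, never flipped - so a predictor that ranks
#' positives *lower* keeps its sub-0.5 value. The standard error follows
#' Hanley & McNeil with Q1 = A/(2-A) and Q2 = 2A^2/(1+A), and the 95% CI is
#' the Wald interval clipped to [0, 1].
#'
#' @param scores Numeric predictor values.
#' @param labels Class labels, same length as `scores`.
#' @param positive The label treated as positive (default `"infectious"`).
#' @return A list of class `roc_result` with `auc`, `se`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg` and `curve` (a data frame of FPR/TPR
#'   points from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels, positive = "infectious") {
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- labels == positive
  n_pos <- as.numeric(sum(pos)); n_neg <- as.numeric(sum(!pos))
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to form a ROC curve")
  }
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))

  # step curve over descending unique thresholds
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE) # last point of each tied block
  curve <- data.frame(fpr = c(0, fp[keep] / n_neg),
                      tpr = c(0, tp[keep] / n_pos))
  structure(list(auc = auc, se = se, ci_low = ci[1], ci_high = ci[2],
                 n_pos = n_pos, n_neg = n_neg, curve = curve),
            class = "roc_result")
}

#' Closed-form AUC of a two-Gaussian (binormal) problem
#'
#' For scores distributed `N(mu_neg, sd_neg)` in the negative class and
#' `N(mu_pos, sd_pos)` in the positive class, the concordance probability
#' is `pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))`.
#'
#' @param mu_pos,sd_pos Positive-class mean and SD.
#' @param mu_neg,sd_neg Negative-class mean and SD.
#' @return The analytic AUC.
#' @export
binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  stats::pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

#' AUC of a simulated two-Gaussian problem
#'
#' Draws `n` values per class from the given Gaussians and computes the
#' empirical pair-concordance AUC with [roc_auc()]; used to check printed
#' AUCs against the class summary statistics they accompany.
#'
#' @inheritParams binormal_auc
#' @param n Draws per class.
#' @param seed Integer seed.
#' @return A [roc_auc()] result.
#' @export
simulate_binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg,
                                  n = 1e5, seed = 1L) {
  with_seed(seed, {
    scores <- c(stats::rnorm(n, mu_neg, sd_neg), stats::rnorm(n, mu_pos, sd_pos))
    labels <- rep(c("negative", "positive"), each = n)
    roc_auc(scores, labels, positive = "positive")
  })
}

#' Class comparison summary table
#'
#' For each requested feature: class means and SDs over the supplied rows,
#' the Mann-Whitney two-sided p-value, and the AUC for predicting the
#' positive class with its Hanley-McNeil SE and 95% CI. With
#' `auc_mode = "sample"` (default) the test and ROC operate on per-sample
#' feature means - the repeated measurements of one sample are not
#' independent observations - while `"point"` uses every row.
#'
#' @param rows Measurement data frame with `label`, `sample_id` and feature
#'   columns.
#' @param features Character vector of feature column names.
#' @param auc_mode `"sample"` or `"point"`.
#' @param positive Label treated as positive for the ROC (default
#'   `"infectious"`).
#' @return Data frame with one row per feature: `feature`,
#'   `mean_inflammatory`, `sd_inflammatory`, `mean_infectious`,
#'   `sd_infectious`, `U`, `p_value`, `auc`, `se`, `ci_low`, `ci_high`,
#'   `auc_n`.
#' @export
summary_table <- function(rows, features = c("delta_f", "delta_gamma", "eta"),
                          auc_mode = c("sample", "point"),
                          positive = "infectious") {
  auc_mode <- match.arg(auc_mode)
  missing_cols <- setdiff(features, names(rows))
  if (length(missing_cols) > 0) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  labs <- unique(rows$label)
  if (length(labs) != 2) stop("rows must contain exactly two classes")
  negative <- setdiff(labs, positive)

  out <- lapply(features, function(feat) {
    vals <- if (auc_mode == "sample") {
      agg <- stats::aggregate(rows[[feat]],
                              by = list(sample_id = rows$sample_id,
                                        label = rows$label), FUN = mean)
      data.frame(value = agg$x, label = agg$label)
    } else {
      data.frame(value = rows[[feat]], label = rows$label)
    }
    mw <- mann_whitney_u(vals$value[vals$label == negative],
                         vals$value[vals$label == positive])
    roc <- roc_auc(vals$value, vals$label, positive = positive)
    data.frame(
      feature = feat,
      mean_inflammatory = mean(rows[[feat]][rows$label == "inflammatory"]),
      sd_inflammatory = stats::sd(rows[[feat]][rows$label == "inflammatory"]),
      mean_infectious = mean(rows[[feat]][rows$label == "infectious"]),
      sd_infectious = stats::sd(rows[[feat]][rows$label == "infectious"]),
      U = mw$U, p_value = mw$p_value,
      auc = roc$auc, se = roc$se,
      ci_low = roc$ci_low, ci_high = roc$ci_high,
      auc_n = roc$n_pos + roc$n_neg,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
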