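# Independent oracles and small fixtures used across the suite.

# Brute-force pair-counting AUC: concordant pairs plus half the ties over
# all positive/negative pairs. Quadratic on purpose - it is the reference
# the rank-based implementation is checked against.
auc_bruteforce <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of labelings,
# independent of the package's own enumeration path (which shares only the
# definition, not the code path for ranks-of-subsets).
mw_p_enumeration <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  mu <- n1 * length(y) / 2
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small cohort for fast classifier tests: same structure, fewer rows
tiny_cohort_config <- function(tube = "EDTA", seed = 11L) {
  cohort_config(tube,
                n_inflammatory_samples = 8L, n_infectious_samples = 4L,
                repeats_range = c(2L, 3L), points_per_repeat = 10L,
                target_rows = NULL, seed = seed)
}

# well-separated two-blob training problem for classifier sanity checks
make_blobs <- function(n = 1000, separation = 6, seed = 5L) {
  set.seed(seed)
  half <- n / 2
  data.frame(
    delta_f = c(rnorm(half, 0), rnorm(half, separation)),
    delta_gamma = c(rnorm(half, 0), rnorm(half, separation)),
    eta = c(rnorm(half, 0), rnorm(half, separation)),
    label = rep(c("inflammatory", "infectious"), each = half),
    stringsAsFactors = FALSE
  )
}
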