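# Synthetic cohort generator: study geometry, determinism, clustering
# structure, covariates, and the raw-sweep round trip.

test_that("default cohorts reproduce the study geometry exactly", {
  edta <- generate_cohort(cohort_config("EDTA", seed = 3))
  expect_equal(nrow(edta), 4972)
  expect_equal(length(unique(edta$sample_id)), 33)
  by_class <- table(unique(edta[, c("sample_id", "label")])$label)
  expect_equal(as.integer(by_class[c("inflammatory", "infectious")]), c(25, 8))

  hep <- generate_cohort(cohort_config("heparin", seed = 3))
  expect_equal(nrow(hep), 5248)
  expect_equal(length(unique(hep$sample_id)), 28)
  by_class <- table(unique(hep[, c("sample_id", "label")])$label)
  expect_equal(as.integer(by_class[c("inflammatory", "infectious")]), c(21, 7))

  # repeats stay within range and points within a repeat are 1..50
  per <- table(edta$sample_id)
  expect_true(all(per >= 50))
  expect_true(all(per <= 5 * 50 + 50))
  expect_true(all(edta$point >= 1 & edta$point <= 50))
})

test_that("generation is byte-identical under the same seed and config", {
  a <- generate_cohort(cohort_config("EDTA", seed = 9))
  b <- generate_cohort(cohort_config("EDTA", seed = 9))
  expect_identical(a, b)
  c <- generate_cohort(cohort_config("EDTA", seed = 10))
  expect_false(identical(a$delta_f, c$delta_f))
  # byte-identical CSV output
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_feature_table(a, f1); write_feature_table(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("an infeasibly small row target is rejected", {
  expect_error(cohort_config("EDTA", target_rows = 100L), "minimum")
})

test_that("vanishing between-sample fraction gives i.i.d. points", {
  cfg <- cohort_config("EDTA", between_sample_fraction = 0.02, seed = 21)
  rows <- generate_cohort(cfg)
  for (feat in c("delta_f", "delta_gamma", "eta")) {
    x <- rows[[feat]][rows$label == "inflammatory"]
    ids <- rows$sample_id[rows$label == "inflammatory"]
    pooled_sd <- sd(x)
    within_sd <- sqrt(mean(tapply(x, ids, var)))
    expect_lt(abs(within_sd - pooled_sd) / pooled_sd, 0.05)
  }
})

test_that("between-sample variance dominates at the default fraction", {
  rows <- generate_cohort(cohort_config("EDTA", seed = 33))
  x <- rows$delta_f[rows$label == "inflammatory"]
  ids <- rows$sample_id[rows$label == "inflammatory"]
  within_var <- mean(tapply(x, ids, var))
  total_var <- var(x)
  expect_lt(within_var / total_var, 0.35) # nominal share is 0.15
})

test_that("class-marginal moments recover the configured statistics", {
  # moderate size here; the 1e5-row recovery check lives with the
  # acceptance suite
  cfg <- cohort_config("EDTA", n_inflammatory_samples = 400L,
                       n_infectious_samples = 400L,
                       repeats_range = c(2L, 2L), points_per_repeat = 25L,
                       target_rows = NULL, seed = 5)
  rows <- generate_cohort(cfg)
  stats <- class_feature_stats("EDTA")
  for (i in seq_len(nrow(stats))) {
    x <- rows[[stats$feature[i]]][rows$label == stats$label[i]]
    expect_lt(abs(mean(x) - stats$mean[i]) / abs(stats$mean[i]), 0.02)
    expect_lt(abs(sd(x) - stats$sd[i]) / stats$sd[i], 0.10)
  }
})

test_that("the three features are physically coupled within samples", {
  rows <- generate_cohort(cohort_config("EDTA", seed = 13))
  one <- rows[rows$sample_id == rows$sample_id[1], ]
  # within a sample, larger |delta_f| means larger delta_gamma and eta
  expect_gt(cor(abs(one$delta_f), one$delta_gamma), 0.5)
  expect_gt(cor(abs(one$delta_f), one$eta), 0.9)
})

test_that("clinical covariates are per-sample constants within bounds", {
  cfg <- tiny_cohort_config(seed = 17)
  rows <- generate_clinical_covariates(cfg, generate_cohort(cfg))
  expect_true(all(c("wbc", "neutrophils", "glucose", "proteins") %in%
                    names(rows)))
  expect_true(all(rows$neutrophils >= 0 & rows$neutrophils <= 100))
  expect_true(all(rows$glucose >= 0))
  expect_true(all(rows$proteins > 0))
  per_sample <- tapply(rows$wbc, rows$sample_id, function(v)
    length(unique(v)))
  expect_true(all(per_sample == 1))
})

test_that("log-normal WBC matches the infectious class mean by moments", {
  cfg <- cohort_config("EDTA",
                       n_inflammatory_samples = 1L,
                       n_infectious_samples = 2000L,
                       repeats_range = c(1L, 1L), points_per_repeat = 1L,
                       target_rows = NULL, seed = 29)
  rows <- generate_clinical_covariates(cfg, generate_cohort(cfg))
  wbc <- tapply(rows$wbc, rows$sample_id, unique)
  infectious <- wbc[grepl("infe", names(wbc))]
  expect_lt(abs(mean(infectious) - 52575.62) / 52575.62, 0.10)
})

test_that("emitted raw sweeps round-trip through feature extraction", {
  cfg <- tiny_cohort_config(seed = 41)
  rows <- generate_cohort(cfg)[1:20, ]
  sweeps <- emit_raw_sweeps(rows, noise_sd = 0, seed = 1)
  feats <- featurize_pairs(lapply(sweeps, `[[`, "loaded"),
                           lapply(sweeps, `[[`, "air"))
  grid_step <- diff(sweeps[[1]]$loaded$frequencies)[1:2]
  expect_true(all(abs(feats$delta_f - rows$delta_f) < max(grid_step)))
  rel_gamma <- abs(feats$delta_gamma - rows$delta_gamma) / rows$delta_gamma
  expect_lt(median(rel_gamma), 0.02)
  # the sweep encodes viscosity only through the frequency shift: the
  # extracted eta must match the inversion of the row's delta_f (the
  # generated eta additionally carries an independent per-sample biology
  # term, so it is not recoverable from the sweep alone)
  eta_from_df <- invert_viscosity(rows$delta_f) * 1e3
  rel_eta <- abs(feats$eta * 1e3 - eta_from_df) / eta_from_df
  expect_lt(median(rel_eta), 0.02)
  # determinism of the emitter
  again <- emit_raw_sweeps(rows, noise_sd = 0.005, seed = 7)
  again2 <- emit_raw_sweeps(rows, noise_sd = 0.005, seed = 7)
  expect_identical(again, again2)
})

test_that("cohort manifest records geometry and seed", {
  cfg <- tiny_cohort_config(seed = 2)
  rows <- generate_cohort(cfg)
  dir <- tempfile()
  write_cohort(rows, cfg, dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest_EDTA.json"))
  expect_equal(manifest$n_rows, nrow(rows))
  expect_equal(manifest$seed, 2)
  expect_equal(manifest$n_samples, 12)
  back <- read_feature_table(file.path(dir, "features_EDTA.csv"))
  expect_equal(back$delta_f, rows$delta_f, tolerance = 1e-12)
  expect_equal(names(back), names(rows))
})
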