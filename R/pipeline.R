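# Orchestration: published confusion-matrix verification, the end-to-end
# simulate -> extract -> summarize -> classify -> report pipeline, and its
# configuration. The numbered scripts under analysis/ are thin drivers over
# these functions.

# The 24 published confusion matrices (6 ANN settings x 2 tubes x
# unbalanced/balanced), in TP/FN/FP/TN order, with the accuracy printed
# next to each. Layout check: within each tube and balance, TP+FN (true
# inflammatory) and FP+TN (true infectious) are constant across settings,
# except one balanced EDTA row whose cells sum to 1242 instead of 1142.
.printed_matrices <- local({
  grid <- expand.grid(epochs = c(100L, 200L, 300L), hidden_layers = c(1L, 2L),
                      balance = c("unbalanced", "balanced"),
                      tube = c("EDTA", "heparin"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$tube, grid$balance, grid$hidden_layers, grid$epochs), ]
  cells <- rbind(
    # EDTA balanced HL1 e100..300, HL2 e100..300
    c(485, 99, 5, 553), c(593, 91, 9, 549), c(501, 83, 11, 547),
    c(496, 88, 7, 551), c(516, 68, 23, 535), c(506, 78, 19, 539),
    # EDTA unbalanced
    c(488, 86, 20, 152), c(514, 60, 29, 143), c(541, 33, 35, 137),
    c(504, 70, 21, 151), c(511, 63, 26, 146), c(562, 12, 53, 119),
    # heparin balanced
    c(586, 10, 22, 623), c(580, 16, 8, 637), c(590, 6, 11, 634),
    c(589, 7, 9, 636), c(590, 6, 20, 625), c(586, 10, 5, 640),
    # heparin unbalanced
    c(627, 4, 10, 147), c(626, 5, 7, 150), c(629, 2, 5, 152),
    c(615, 16, 5, 152), c(626, 5, 6, 151), c(628, 3, 6, 151)
  )
  printed <- c(
    0.90, 0.91, 0.91, 0.91, 0.92, 0.91, # EDTA balanced
    0.85, 0.88, 0.90, 0.87, 0.88, 0.91, # EDTA unbalanced
    0.97, 0.98, 0.98, 0.98, 0.97, 0.98, # heparin balanced
    0.98, 0.98, 0.99, 0.97, 0.98, 0.98  # heparin unbalanced
  )
  grid$tp <- cells[, 1]; grid$fn <- cells[, 2]
  grid$fp <- cells[, 3]; grid$tn <- cells[, 4]
  grid$printed_accuracy <- printed
  rownames(grid) <- NULL
  grid
})

#' Verify the published confusion matrices against their accuracy table
#'
#' Recomputes `(TP + TN) / total` for each of the 24 published confusion
#' matrices and compares it to the accuracy printed for the same scenario.
#' The printed accuracies turn out to be *truncated* (not rounded) to two
#' decimals: under truncation every internally consistent matrix matches.
#' The function reports both renderings, flags rows whose cell total
#' disagrees with the modal test-set size of their tube/balance group, and
#' never adjusts a value to force agreement.
#'
#' @return Data frame with one row per scenario: the matrix cells, `total`,
#'   `accuracy` (full precision), `truncated`, `rounded`,
#'   `printed_accuracy`, `matches_truncated`, `matches_rounded`, and
#'   `geometry_consistent`.
#' @export
#' @examples
#' v <- verify_printed_tables()
#' sum(v$matches_truncated) # 24 of 24
verify_printed_tables <- function() {
  v <- .printed_matrices
  v$total <- v$tp + v$fn + v$fp + v$tn
  v$accuracy <- (v$tp + v$tn) / v$total
  v$truncated <- trunc2(v$accuracy)
  v$rounded <- round2(v$accuracy)
  v$matches_truncated <- v$truncated == v$printed_accuracy
  v$matches_rounded <- v$rounded == v$printed_accuracy
  modal <- stats::ave(v$total, v$tube, v$balance, FUN = function(x) {
    as.numeric(names(which.max(table(x))))
  })
  v$geometry_consistent <- v$total == modal
  v
}

#' Pipeline configuration
#'
#' Bundles the per-stage settings of the full workflow. One global seed
#' deterministically derives every stage seed via [derive_seed()], so
#' adding a stage never perturbs earlier stages.
#'
#' @param tube `"EDTA"` or `"heparin"`.
#' @param seed Global integer seed.
#' @param cohort A [cohort_config()]; defaults to the tube's defaults with
#'   a derived seed.
#' @param mlp_grid List of [mlp_spec()]s to train; defaults to the six
#'   published settings (1-2 hidden layers x 100/200/300 epochs).
#' @param balance Character subset of `c("unbalanced", "balanced")`.
#' @param split_mode `"point"` or `"grouped"`.
#' @param auc_mode `"sample"` or `"point"` for the summary tables.
#' @param features Feature columns used throughout.
#' @param svm,rf Logical: train those models too.
#' @param out_dir Output directory, or `NULL` to write nothing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tube = c("EDTA", "heparin"), seed = 1L,
                            cohort = NULL, mlp_grid = NULL,
                            balance = c("unbalanced", "balanced"),
                            split_mode = c("point", "grouped"),
                            auc_mode = c("sample", "point"),
                            features = c("delta_f", "delta_gamma", "eta"),
                            svm = TRUE, rf = TRUE, out_dir = NULL) {
  tube <- match.arg(tube)
  split_mode <- match.arg(split_mode)
  auc_mode <- match.arg(auc_mode)
  balance <- match.arg(balance, several.ok = TRUE)
  cohort <- cohort %||% cohort_config(tube, seed = derive_seed(seed, "cohort"))
  if (is.null(mlp_grid)) {
    grid <- expand.grid(hl = c(1L, 2L), ep = c(100L, 200L, 300L))
    mlp_grid <- lapply(seq_len(nrow(grid)), function(i) {
      mlp_spec(input_dim = length(features), hidden_layers = grid$hl[i],
               epochs = grid$ep[i], seed = derive_seed(seed, paste0("mlp", i)))
    })
  }
  structure(list(tube = tube, seed = as.integer(seed), cohort = cohort,
                 mlp_grid = mlp_grid, balance = balance,
                 split_mode = split_mode, auc_mode = auc_mode,
                 features = features, svm = svm, rf = rf, out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()] (`tube`, `seed`, `balance`, `split_mode`,
#' `auc_mode`, `svm`, `rf`, `out_dir`, plus optional `cohort` and
#' `mlp_grid` sections with their constructors' arguments).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  cohort <- if (!is.null(y$cohort)) {
    args <- y$cohort
    args$tube <- args$tube %||% y$tube %||% "EDTA"
    args$seed <- args$seed %||% derive_seed(seed, "cohort")
    do.call(cohort_config, args)
  }
  mlp_grid <- if (!is.null(y$mlp_grid)) {
    lapply(seq_along(y$mlp_grid), function(i) {
      args <- y$mlp_grid[[i]]
      args$seed <- args$seed %||% derive_seed(seed, paste0("mlp", i))
      do.call(mlp_spec, args)
    })
  }
  pipeline_config(
    tube = y$tube %||% "EDTA", seed = seed, cohort = cohort,
    mlp_grid = mlp_grid,
    balance = y$balance %||% c("unbalanced", "balanced"),
    split_mode = y$split_mode %||% "point",
    auc_mode = y$auc_mode %||% "sample",
    features = y$features %||% c("delta_f", "delta_gamma", "eta"),
    svm = y$svm %||% TRUE, rf = y$rf %||% TRUE, out_dir = y$out_dir
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> summarize -> classify for one tube under one
#' configuration: generates the synthetic cohort, produces the class
#' summary and ROC tables, then for each requested balance setting splits
#' the data, fits the robust scaler on the training partition, trains the
#' MLP grid (plus optional SVM and random forest on an 85/15 split), and
#' evaluates every model on the held-out test set. When `out_dir` is set,
#' all tables, histories, confusion matrices and a `report.json` are
#' written there.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with elements `config_echo`,
#'   `n_rows`, `summary`, `runs` (one entry per trained model with its
#'   confusion matrix and accuracies) and `accuracy_table`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rows <- generate_cohort(config$cohort)
  summary_tab <- summary_table(rows, config$features,
                               auc_mode = config$auc_mode)

  runs <- list()
  histories <- list()
  for (bal in config$balance) {
    dat <- if (bal == "balanced") {
      oversample_minority(rows, seed = derive_seed(config$seed, "oversample"))
    } else rows

    # 70/15/15 for the MLP grid
    parts <- split_dataset(dat, split_spec(
      mode = config$split_mode, seed = derive_seed(config$seed, "split")))
    scaler <- fit_robust_scaler(parts$train, config$features)
    train_s <- apply_scaler(scaler, parts$train)
    val_s <- apply_scaler(scaler, parts$validation)
    test_s <- apply_scaler(scaler, parts$test)

    for (spec in config$mlp_grid) {
      fit <- train_mlp(train_s, val_s, spec, config$features)
      ev <- evaluate(fit$model, test_s)
      id <- sprintf("ann_hl%d_e%d_%s_%s", spec$hidden_layers, spec$epochs,
                    config$tube, bal)
      runs[[id]] <- c(list(model = "ann", hidden_layers = spec$hidden_layers,
                           epochs = spec$epochs, tube = config$tube,
                           balance = bal, n_test = nrow(test_s)), ev)
      histories[[id]] <- fit$history
    }

    # 85/0/15 for SVM and RF; sharing the split seed reuses the same row
    # shuffle, so all models are evaluated on the identical held-out 15%
    parts2 <- split_dataset(dat, split_spec(
      fractions = c(0.85, 0, 0.15), mode = config$split_mode,
      seed = derive_seed(config$seed, "split")))
    if (config$svm) {
      scaler2 <- fit_robust_scaler(parts2$train, config$features)
      svm_fit <- train_svm(apply_scaler(scaler2, parts2$train),
                           config$features)
      ev <- evaluate(svm_fit, apply_scaler(scaler2, parts2$test))
      runs[[sprintf("svm_%s_%s", config$tube, bal)]] <-
        c(list(model = "svm", hidden_layers = NA, epochs = NA,
               tube = config$tube, balance = bal,
               n_test = nrow(parts2$test)), ev)
    }
    if (config$rf) {
      rf_fit <- train_rf(parts2$train, config$features,
                         seed = derive_seed(config$seed, "rf"))
      ev <- evaluate(rf_fit, parts2$test)
      runs[[sprintf("rf_%s_%s", config$tube, bal)]] <-
        c(list(model = "rf", hidden_layers = NA, epochs = NA,
               tube = config$tube, balance = bal,
               n_test = nrow(parts2$test)), ev)
    }
  }

  accuracy_table <- do.call(rbind, lapply(names(runs), function(id) {
    r <- runs[[id]]
    data.frame(run = id, model = r$model, hidden_layers = r$hidden_layers,
               epochs = r$epochs, tube = r$tube, balance = r$balance,
               n_test = r$n_test, accuracy = r$accuracy,
               accuracy_truncated = r$accuracy_truncated,
               tp = r$confusion$tp, fn = r$confusion$fn,
               fp = r$confusion$fp, tn = r$confusion$tn,
               stringsAsFactors = FALSE)
  }))

  report <- structure(list(
    config_echo = list(tube = config$tube, seed = config$seed,
                       balance = config$balance,
                       split_mode = config$split_mode,
                       auc_mode = config$auc_mode,
                       n_mlp_settings = length(config$mlp_grid)),
    version = as.character(utils::packageVersion("qcrsf")),
    n_rows = nrow(rows),
    n_samples = length(unique(rows$sample_id)),
    summary = summary_tab,
    runs = runs,
    accuracy_table = accuracy_table
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    .write_report(report, histories, rows, config)
  }
  report
}

.write_report <- function(report, histories, rows, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(rows, config$cohort, config$out_dir)
  utils::write.csv(report$summary,
                   file.path(config$out_dir,
                             sprintf("summary_%s.csv", config$tube)),
                   row.names = FALSE)
  utils::write.csv(report$accuracy_table,
                   file.path(config$out_dir, "accuracy_table.csv"),
                   row.names = FALSE)
  for (id in names(histories)) {
    utils::write.csv(histories[[id]],
                     file.path(config$out_dir,
                               sprintf("history_%s.csv", id)),
                     row.names = FALSE)
  }
  for (id in names(report$runs)) {
    r <- report$runs[[id]]
    jsonlite::write_json(
      list(run = id, confusion = r$confusion[c("tp", "fn", "fp", "tn")],
           accuracy = r$accuracy, accuracy_rounded = r$accuracy_rounded,
           accuracy_truncated = r$accuracy_truncated),
      file.path(config$out_dir, sprintf("confusion_%s.json", id)),
      auto_unbox = TRUE, digits = NA
    )
  }
  jsonlite::write_json(
    list(config = report$config_echo, version = report$version,
         n_rows = report$n_rows, n_samples = report$n_samples,
         summary = report$summary, accuracy_table = report$accuracy_table),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(NULL)
}
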