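# Plain-text interchange: feature-table CSV (with the external header
# naming convention), sweep CSV + sidecar JSON, and cohort manifests.

.feature_header <- c(sample_id = "sample_id", tube = "tube", label = "label",
                     rep = "repeat", point = "point",
                     delta_f = "delta_f_hz", delta_gamma = "delta_gamma_hz",
                     eta = "eta_mpas")

#' Write a measurement feature table to CSV
#'
#' Uses the external header `sample_id,tube,label,repeat,point,delta_f_hz,
#' delta_gamma_hz,eta_mpas`; any extra columns (e.g. clinical covariates)
#' are appended under their own names.
#'
#' @param rows Data frame from [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  out <- rows
  known <- intersect(names(.feature_header), names(out))
  names(out)[match(known, names(out))] <- .feature_header[known]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement feature table from CSV
#'
#' Inverse of [write_feature_table()]: maps the external header back to the
#' internal column names.
#'
#' @param path CSV file path.
#' @return Data frame of measurement rows.
#' @export
read_feature_table <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  hit <- match(names(rows), .feature_header)
  names(rows)[!is.na(hit)] <- names(.feature_header)[hit[!is.na(hit)]]
  rows
}

#' Write one conductance sweep to CSV with a sidecar JSON
#'
#' The CSV carries the header `frequency_hz,conductance_s`; acquisition
#' metadata (condition, sample id, repeat, point) goes into `<path>.json`.
#'
#' @param sweep A [conductance_sweep()].
#' @param path CSV file path.
#' @param meta Named list of metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path, meta = list()) {
  stopifnot(inherits(sweep, "conductance_sweep"))
  utils::write.csv(
    data.frame(frequency_hz = sweep$frequencies,
               conductance_s = sweep$conductance),
    path, row.names = FALSE, quote = FALSE
  )
  meta$condition <- sweep$condition
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a conductance sweep written by [write_sweep_csv()]
#'
#' @param path CSV file path; the sidecar `<path>.json` is read when
#'   present.
#' @return A [conductance_sweep()] with a `meta` attribute.
#' @export
read_sweep_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- list(condition = "loaded")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  sweep <- conductance_sweep(d$frequency_hz, d$conductance_s,
                             condition = meta$condition %||% "loaded")
  attr(sweep, "meta") <- meta
  sweep
}

#' Write a cohort with its manifest
#'
#' Writes the feature CSV plus a `manifest.json` echoing the configuration,
#' the seed, and per-class/per-sample row counts.
#'
#' @param rows Data frame from [generate_cohort()].
#' @param config The generating [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(rows, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(rows, file.path(dir, sprintf("features_%s.csv",
                                                   config$tube)))
  manifest <- list(
    tube = config$tube,
    seed = config$seed,
    n_rows = nrow(rows),
    n_samples = length(unique(rows$sample_id)),
    rows_per_class = as.list(table(rows$label)),
    rows_per_sample = as.list(table(rows$sample_id)),
    config = config[c("n_inflammatory_samples", "n_infectious_samples",
                      "repeats_range", "points_per_repeat",
                      "between_sample_fraction", "link_noise_rel",
                      "target_rows", "density")]
  )
  jsonlite::write_json(manifest, file.path(dir, sprintf("manifest_%s.json",
                                                        config$tube)),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
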