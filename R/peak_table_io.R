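# Data model and TSV readers/writers for feature tables and sample manifests.
#
# A feature table couples three pieces: per-feature metadata (feature_id, m/z,
# retention time, ion mode), a peak-area matrix (features x injections) and
# the sample manifest describing the injections. Missing measurements are a
# distinct state (NA) and are never conflated with a zero peak area at the
# storage level; downstream stages decide how missingness is treated
# (excluded for rank statistics, replaced by 0 for PCA).

#' Construct a validated feature table
#'
#' @param features data.frame with columns `feature_id`, `mz`, `rt`,
#'   `ion_mode`. Retention times are in seconds; `mz` in Da/e.
#' @param intensities numeric matrix of peak areas, one row per feature and
#'   one column per injection. `NA` marks a missing (undetected) measurement;
#'   stored values must be non-negative.
#' @param manifest data.frame with columns `sample_id`, `study_id`, `group`,
#'   `injection_order`, `ion_mode`. Groups are `ND_UT`, `ND_TETA`, `DM_UT`,
#'   `DM_TETA` for biological injections and `QC` for pooled-QC injections.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `features`, `intensities` (rownames = feature ids, colnames = sample
#'   ids) and `manifest`, columns ordered by (study, ion mode, injection
#'   order).
#' @export
feature_table <- function(features, intensities, manifest) {
  features <- as.data.frame(features)
  manifest <- as.data.frame(manifest)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"

  need_f <- c("feature_id", "mz", "rt", "ion_mode")
  if (!all(need_f %in% names(features))) {
    mf_stop(sprintf("features must have columns: %s", paste(need_f, collapse = ", ")),
            "mf_format_error")
  }
  if (anyDuplicated(features$feature_id)) {
    mf_stop("duplicate feature_id in feature metadata", "mf_format_error")
  }
  if (any(!is.finite(features$mz)) || any(features$mz <= 0)) {
    mf_stop("mz must be positive and finite", "mf_value_error")
  }
  if (any(!is.finite(features$rt)) || any(features$rt < 0)) {
    mf_stop("rt must be non-negative and finite", "mf_value_error")
  }
  if (!all(features$ion_mode %in% ION_MODES)) {
    mf_stop("ion_mode must be 'positive' or 'negative'", "mf_value_error")
  }

  manifest <- validate_manifest(manifest)

  if (nrow(intensities) != nrow(features)) {
    mf_stop("intensity row count does not match feature count", "mf_consistency_error")
  }
  if (ncol(intensities) != nrow(manifest)) {
    mf_stop("intensity column count does not match manifest entry count",
            "mf_consistency_error")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    mf_stop("negative intensities are not allowed", "mf_value_error")
  }
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- manifest$sample_id
  }
  if (!setequal(colnames(intensities), manifest$sample_id)) {
    mf_stop("sample_id mismatch between intensity columns and manifest",
            "mf_consistency_error")
  }
  intensities <- intensities[, manifest$sample_id, drop = FALSE]
  rownames(intensities) <- features$feature_id

  structure(
    list(features = features, intensities = intensities, manifest = manifest),
    class = "feature_table"
  )
}

validate_manifest <- function(manifest) {
  need_m <- c("sample_id", "study_id", "group", "injection_order", "ion_mode")
  if (!all(need_m %in% names(manifest))) {
    mf_stop(sprintf("manifest must have columns: %s", paste(need_m, collapse = ", ")),
            "mf_format_error")
  }
  if (anyDuplicated(manifest$sample_id)) {
    mf_stop("duplicate sample_id in manifest", "mf_format_error")
  }
  if (!all(manifest$group %in% GROUP_LEVELS)) {
    bad <- setdiff(unique(manifest$group), GROUP_LEVELS)
    mf_stop(sprintf("invalid group label(s): %s", paste(bad, collapse = ", ")),
            "mf_value_error")
  }
  if (!all(manifest$ion_mode %in% ION_MODES)) {
    mf_stop("manifest ion_mode must be 'positive' or 'negative'", "mf_value_error")
  }
  ord <- manifest$injection_order
  if (any(!is.finite(ord)) || any(ord < 1) || any(ord != round(ord))) {
    mf_stop("injection_order must be positive integers", "mf_value_error")
  }
  manifest$injection_order <- as.integer(ord)
  runs <- split(manifest, list(manifest$study_id, manifest$ion_mode), drop = TRUE)
  for (run in runs) {
    if (anyDuplicated(run$injection_order)) {
      mf_stop("injection_order must be unique within a (study, ion mode) run",
              "mf_consistency_error")
    }
    if (!any(run$group == "QC")) {
      mf_stop("every (study, ion mode) run needs at least one QC injection",
              "mf_consistency_error")
    }
  }
  manifest[order(manifest$study_id, manifest$ion_mode, manifest$injection_order), ,
           drop = FALSE] -> manifest
  rownames(manifest) <- NULL
  manifest
}

#' @export
print.feature_table <- function(x, ...) {
  n_missing <- sum(is.na(x$intensities))
  cat(sprintf(
    "feature_table: %d features x %d injections (%d QC), %d missing cells\n",
    nrow(x$intensities), ncol(x$intensities),
    sum(x$manifest$group == "QC"), n_missing
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Read a feature table and its sample manifest from TSV
#'
#' The table file carries columns `feature_id`, `mz`, `rt`, `ion_mode`
#' followed by one intensity column per sample id; empty cells, `NA` and
#' `NaN` denote missing measurements. The manifest file carries the columns
#' documented in [feature_table()].
#'
#' @param table_path path to the feature-table TSV.
#' @param manifest_path path to the manifest TSV.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(table_path, manifest_path) {
  manifest <- read_sample_manifest(manifest_path)
  tab <- utils::read.delim(table_path, check.names = FALSE,
                           na.strings = c("", "NA", "NaN"),
                           stringsAsFactors = FALSE)
  meta_cols <- c("feature_id", "mz", "rt", "ion_mode")
  if (!all(meta_cols %in% names(tab))) {
    mf_stop("feature table must start with columns feature_id, mz, rt, ion_mode",
            "mf_format_error")
  }
  sample_cols <- setdiff(names(tab), meta_cols)
  missing_samples <- setdiff(manifest$sample_id, sample_cols)
  if (length(missing_samples)) {
    mf_stop(sprintf("manifest sample_id(s) absent from table header: %s",
                    paste(missing_samples, collapse = ", ")),
            "mf_consistency_error")
  }
  extra <- setdiff(sample_cols, manifest$sample_id)
  if (length(extra)) {
    mf_stop(sprintf("table column(s) not described by manifest: %s",
                    paste(extra, collapse = ", ")),
            "mf_consistency_error")
  }
  intens <- as.matrix(tab[, manifest$sample_id, drop = FALSE])
  feature_table(tab[, meta_cols, drop = FALSE], intens, manifest)
}

#' Read a sample manifest TSV
#' @param path path to a manifest TSV.
#' @return validated manifest data.frame, ordered by injection order.
#' @export
read_sample_manifest <- function(path) {
  validate_manifest(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a feature table (and optionally its manifest) to TSV
#'
#' Missing values are written as empty cells, never as zeros.
#'
#' @param table a [feature_table()].
#' @param table_path output path for the feature-table TSV.
#' @param manifest_path optional output path for the manifest TSV.
#' @export
write_feature_table <- function(table, table_path, manifest_path = NULL) {
  stopifnot(inherits(table, "feature_table"))
  out <- cbind(table$features,
               as.data.frame(table$intensities, check.names = FALSE))
  utils::write.table(out, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(manifest_path)) {
    utils::write.table(table$manifest, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(NULL)
}

# Convenience accessors -------------------------------------------------

# Columns (sample ids) of the biological injections of a given group,
# or of all biological injections when group is NULL.
bio_samples <- function(table, group = NULL) {
  m <- table$manifest
  keep <- m$group != "QC"
  if (!is.null(group)) {
    if (!all(group %in% BIO_GROUPS)) {
      mf_stop(sprintf("unknown group label: %s",
                      paste(setdiff(group, BIO_GROUPS), collapse = ", ")),
              "mf_input_error")
    }
    keep <- m$group %in% group
  }
  m$sample_id[keep]
}

qc_samples <- function(table) {
  table$manifest$sample_id[table$manifest$group == "QC"]
}

# Subset a feature table to a set of feature ids (preserving order given).
subset_features <- function(table, feature_ids) {
  keep <- match(feature_ids, table$features$feature_id)
  if (anyNA(keep)) mf_stop("unknown feature_id in subset", "mf_input_error")
  feature_table(table$features[keep, , drop = FALSE],
                table$intensities[keep, , drop = FALSE],
                table$manifest)
}
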