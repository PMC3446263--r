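# PCA with unit-variance scaling and the zero-for-missing convention, plus
# a reproducible total-signal outlier flag.
#
# Missing values are replaced by 0 before scaling. Zero is a defensible
# stand-in here because missingness in these tables is left-censoring
# (values below the detection limit); the choice biases feature variances
# slightly and is kept as an explicit, documented convention of this
# analysis style.

#' Principal component analysis of a feature table
#'
#' Missing values are set to 0, each feature is centered and scaled to unit
#' variance (zero-variance features are dropped), and the scores/loadings of
#' the leading components are returned. Component signs are fixed by making
#' each loading's largest-magnitude entry positive.
#'
#' @param table a QA-filtered [feature_table()].
#' @param n_components number of leading components to keep (default 3).
#' @return object of class `pca_result`: list with `scores` (injection x
#'   component, rownames = sample ids), `loadings` (feature x component),
#'   `explained_variance_fraction`, `n_components` and `dropped_features`
#'   (zero-variance feature ids).
#' @export
pca_scores <- function(table, n_components = 3) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$intensities
  if (ncol(X) < 2) {
    mf_stop("PCA needs at least 2 injections", "mf_input_error")
  }
  X[!is.finite(X)] <- 0
  sds <- apply(X, 1, stats::sd)
  dropped <- rownames(X)[sds == 0]
  X <- X[sds > 0, , drop = FALSE]
  Z <- t(scale(t(X)))  # feature-wise zero mean, unit variance

  pc <- stats::prcomp(t(Z), center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = scores,
    loadings = loadings,
    explained_variance_fraction = expl[seq_len(k)],
    n_components = k,
    dropped_features = dropped
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "pca_result: %d components; explained variance: %s\n",
    x$n_components,
    paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction), collapse = ", ")
  ))
  invisible(x)
}

#' Flag low total-signal injections as potential outliers
#'
#' Formalises the manual call usually made from a PCA score plot: an
#' injection whose total non-missing peak area falls more than `k`
#' median-absolute-deviations below the median total of the biological
#' injections (a signature of a poor injection) is flagged. The flag is
#' advisory; removal is a separate, explicit action.
#'
#' @param table a [feature_table()].
#' @param k MAD multiplier (default 5). The MAD uses the consistency
#'   constant 1.4826 of [stats::mad()].
#' @return data.frame `sample_id`, `total_area`, `reason` (possibly empty).
#' @export
flag_outliers <- function(table, k = 5) {
  stopifnot(inherits(table, "feature_table"))
  cols <- bio_samples(table)
  if (length(cols) < 4) {
    mf_stop("outlier flagging needs at least 4 biological injections",
            "mf_input_error")
  }
  totals <- colSums(table$intensities[, cols, drop = FALSE], na.rm = TRUE)
  med <- stats::median(totals)
  mad_ <- stats::mad(totals)
  flagged <- totals < med - k * mad_
  data.frame(
    sample_id = cols[flagged],
    total_area = unname(totals[flagged]),
    reason = rep(
      sprintf("total peak area more than %g MADs below the biological median", k),
      sum(flagged)
    ),
    stringsAsFactors = FALSE
  )
}
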