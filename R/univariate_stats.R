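# Per-feature Mann-Whitney group comparisons, fold-ratios, and the
# two-study replication filter.
#
# The U statistic is computed from midrank sums. In the small-sample regime
# (n1 + n2 <= 20) the two-sided p-value is exact: the null distribution of U
# is obtained by enumerating all C(N, n1) assignments of the pooled midranks
# to the first group, which handles ties exactly (it is the permutation
# distribution conditional on the observed values). For larger samples the
# normal approximation with tie and continuity correction is used via
# stats::wilcox.test. Missing values are excluded before testing.

# Cache of exact U null distributions keyed by (n1, pooled midrank multiset),
# and of enumeration index matrices keyed by (N, n1). With continuous data
# every feature of a comparison shares one distribution, so the enumeration
# cost is paid once.
.mw_cache <- new.env(parent = emptyenv())

mw_combinations <- function(N, n1) {
  key <- sprintf("C_%d_%d", N, n1)
  if (is.null(.mw_cache[[key]])) {
    .mw_cache[[key]] <- utils::combn(N, n1)
  }
  .mw_cache[[key]]
}

mw_exact_u_distribution <- function(ranks, n1) {
  key <- sprintf("D_%d_%s", n1, paste(format(sort(ranks), digits = 12), collapse = ","))
  if (is.null(.mw_cache[[key]])) {
    N <- length(ranks)
    cmb <- mw_combinations(N, n1)
    rank_sums <- colSums(matrix(ranks[cmb], nrow = n1))
    .mw_cache[[key]] <- rank_sums - n1 * (n1 + 1) / 2
  }
  .mw_cache[[key]]
}

#' Mann-Whitney U test (exact in the small-sample regime)
#'
#' @param x,y numeric samples; missing values are removed.
#' @param exact_max_n largest combined sample size for which the exact
#'   permutation null of U is enumerated (default 20); above it the normal
#'   approximation with tie and continuity correction is used.
#' @return list with `u` (U statistic of `x` relative to `y`, from midrank
#'   sums), `p_value` (two-sided), `n1`, `n2` and `method` ("exact" or
#'   "normal_approx"). The exact two-sided p is
#'   P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|) under the enumeration null.
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 20) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) {
    mf_stop("each sample needs at least one non-missing value", "mf_test_error")
  }
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max_n) {
    u_null <- mw_exact_u_distribution(r, n1)
    mu <- n1 * n2 / 2
    p <- mean(abs(u_null - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    method <- "normal_approx"
  }
  list(u = u, p_value = p, n1 = n1, n2 = n2, method = method)
}

#' Group intensity ratio and direction of change
#'
#' @param x reference-group values, `y` comparison-group values (ratio is
#'   central(y) / central(x), e.g. diabetic / non-diabetic).
#' @param center `"median"` (default, consistent with the rank test) or
#'   `"mean"`.
#' @return list with `ratio` (NA when a central value is zero or
#'   undefined) and `direction` ("up", "down" or "none").
#' @export
group_ratio <- function(x, y, center = c("median", "mean")) {
  center <- match.arg(center)
  fun <- if (center == "median") stats::median else mean
  cx <- fun(x[is.finite(x)])
  cy <- fun(y[is.finite(y)])
  if (!is.finite(cx) || !is.finite(cy) || cx <= 0 || cy <= 0) {
    return(list(ratio = NA_real_, direction = "none"))
  }
  ratio <- cy / cx
  direction <- if (ratio > 1) "up" else if (ratio < 1) "down" else "none"
  list(ratio = ratio, direction = direction)
}

#' The six pairwise group comparisons
#'
#' Ordered pairs `c(reference, other)` covering every combination of the
#' four biological groups, in the conventional reporting order.
#' @export
GROUP_COMPARISONS <- list(
  c("ND_UT", "ND_TETA"),
  c("DM_TETA", "ND_TETA"),
  c("DM_UT", "ND_TETA"),
  c("DM_TETA", "ND_UT"),
  c("DM_UT", "ND_UT"),
  c("DM_UT", "DM_TETA")
)

#' Per-feature differential testing between two groups
#'
#' One Mann-Whitney test per feature with enough data in both groups;
#' ratios are oriented as second group / first group of `comparison`.
#' No multiple-testing adjustment is applied by default (false positives are
#' controlled downstream by cross-study replication); Benjamini-Hochberg is
#' available via `p_adjust = "BH"`.
#'
#' @param table a QA-filtered [feature_table()].
#' @param comparison character vector of two biological group labels
#'   `c(reference, other)`.
#' @param alpha significance level used to mark the significant subset.
#' @param center central value for the ratio, see [group_ratio()].
#' @param p_adjust p-value adjustment method (default "none").
#' @return data.frame with one row per tested feature: `feature_id`, `u`,
#'   `p_value`, `ratio`, `direction`, `n1`, `n2`, `significant`; features
#'   skipped for lack of data are listed in attribute `skipped`.
#' @export
differential_features <- function(table, comparison, alpha = 0.05,
                                  center = "median", p_adjust = "none") {
  stopifnot(inherits(table, "feature_table"))
  if (length(comparison) != 2 || !all(comparison %in% BIO_GROUPS)) {
    mf_stop("comparison must name two of the four biological groups",
            "mf_input_error")
  }
  cols1 <- bio_samples(table, comparison[1])
  cols2 <- bio_samples(table, comparison[2])
  X1 <- table$intensities[, cols1, drop = FALSE]
  X2 <- table$intensities[, cols2, drop = FALSE]

  rows <- vector("list", nrow(X1))
  skipped <- character(0)
  for (i in seq_len(nrow(X1))) {
    x <- X1[i, ]
    y <- X2[i, ]
    if (!any(is.finite(x)) || !any(is.finite(y))) {
      skipped <- c(skipped, rownames(X1)[i])
      next
    }
    tst <- mann_whitney_u(x, y)
    rat <- group_ratio(x, y, center = center)
    rows[[i]] <- data.frame(
      feature_id = rownames(X1)[i],
      u = tst$u, p_value = tst$p_value,
      ratio = rat$ratio, direction = rat$direction,
      n1 = tst$n1, n2 = tst$n2,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(feature_id = character(0), u = numeric(0),
                      p_value = numeric(0), ratio = numeric(0),
                      direction = character(0), n1 = integer(0),
                      n2 = integer(0), stringsAsFactors = FALSE)
  }
  if (p_adjust != "none") res$p_value <- stats::p.adjust(res$p_value, p_adjust)
  res$significant <- res$p_value < alpha
  rownames(res) <- NULL
  attr(res, "comparison") <- comparison
  attr(res, "skipped") <- skipped
  res
}

#' Two-study replication filter
#'
#' A feature replicates when it is significant (p < alpha) in both studies
#' with the same direction of change, the criterion used to separate
#' biologically consistent changes from single-study false positives.
#'
#' @param results_study1,results_study2 results of
#'   [differential_features()] for the same comparison in the two studies,
#'   keyed by a shared feature-id space.
#' @param alpha significance level (default 0.05, strict inequality).
#' @return data.frame of replicated features (`feature_id`, per-study p and
#'   ratio, `direction`), sorted by study-1 p-value.
#' @export
replication_filter <- function(results_study1, results_study2, alpha = 0.05) {
  merged <- merge(results_study1, results_study2, by = "feature_id",
                  suffixes = c("_study1", "_study2"))
  keep <- merged$p_value_study1 < alpha &
    merged$p_value_study2 < alpha &
    merged$direction_study1 == merged$direction_study2 &
    merged$direction_study1 %in% c("up", "down")
  out <- merged[keep, c("feature_id", "p_value_study1", "ratio_study1",
                        "p_value_study2", "ratio_study2", "direction_study1")]
  names(out)[names(out) == "direction_study1"] <- "direction"
  out <- out[order(out$p_value_study1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match features between two runs by mass and retention time
#'
#' Greedy nearest-match in ppm mass error among features within the
#' retention-time tolerance and of the same ion mode; intended for real
#' data, where feature ids differ between runs.
#'
#' @param features1,features2 feature metadata data.frames (as in a
#'   [feature_table()]).
#' @param mz_tol_ppm mass tolerance in parts per million.
#' @param rt_tol retention-time tolerance in seconds.
#' @return data.frame `feature_id_1`, `feature_id_2`, `ppm_error`,
#'   `rt_delta`; each feature appears at most once.
#' @export
match_features_between_runs <- function(features1, features2,
                                        mz_tol_ppm = 5, rt_tol = 10) {
  cand <- list()
  for (i in seq_len(nrow(features1))) {
    mz <- features1$mz[i]
    ppm <- 1e6 * abs(features2$mz - mz) / mz
    ok <- ppm <= mz_tol_ppm &
      abs(features2$rt - features1$rt[i]) <= rt_tol &
      features2$ion_mode == features1$ion_mode[i]
    if (any(ok)) {
      j <- which(ok)
      cand[[length(cand) + 1]] <- data.frame(
        i = i, j = j, ppm = ppm[j],
        rt_delta = abs(features2$rt[j] - features1$rt[i])
      )
    }
  }
  if (!length(cand)) {
    return(data.frame(feature_id_1 = character(0), feature_id_2 = character(0),
                      ppm_error = numeric(0), rt_delta = numeric(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$ppm, cand$rt_delta), ]
  used1 <- logical(nrow(features1))
  used2 <- logical(nrow(features2))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used1[cand$i[r]] && !used2[cand$j[r]]) {
      keep[r] <- TRUE
      used1[cand$i[r]] <- TRUE
      used2[cand$j[r]] <- TRUE
    }
  }
  cand <- cand[keep, ]
  data.frame(
    feature_id_1 = features1$feature_id[cand$i],
    feature_id_2 = features2$feature_id[cand$j],
    ppm_error = cand$ppm, rt_delta = cand$rt_delta,
    stringsAsFactors = FALSE
  )
}
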