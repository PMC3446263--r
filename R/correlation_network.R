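# Bootstrapped per-group Spearman correlations and the reversal-filter
# cascade.
#
# For every unordered feature pair with enough complete observations in a
# group, the Spearman coefficient is aggregated over bootstrap resamples
# (median of n_boot = 100 resample coefficients). A pair shows the reversal
# pattern when it is highly correlated (|rho| > 0.5) in untreated controls,
# loses that correlation in untreated diabetics (|rho_ND - rho_DM| > 0.5)
# and is highly correlated again in treated diabetics (|rho_DMT| > 0.5).
# Pairs whose features map to the same metabolite are removed, and a
# feature is reported as a candidate only when it shows the pattern with at
# least min_degree different partner metabolites.

#' Cascade thresholds for the reversal filter
#'
#' @param high_corr minimum |rho| called "high" in the control and
#'   treated-diabetic groups (default 0.5).
#' @param delta minimum correlation-coefficient change between controls and
#'   untreated diabetics (default 0.5).
#' @param min_pairs minimum number of complete observation pairs for a
#'   correlation to enter the analysis (default 6, binding exactly for the
#'   smallest groups).
#' @param min_degree minimum number of different partner metabolites for a
#'   feature to be reported (default 10).
#' @param n_boot bootstrap resamples per pair (default 100).
#' @return a `cascade_thresholds` list.
#' @export
cascade_thresholds <- function(high_corr = 0.5, delta = 0.5, min_pairs = 6,
                               min_degree = 10, n_boot = 100) {
  stopifnot(high_corr > 0, high_corr < 1, delta > 0, delta <= 2,
            min_pairs >= 3, min_degree >= 1, n_boot >= 1)
  structure(list(high_corr = high_corr, delta = delta, min_pairs = min_pairs,
                 min_degree = min_degree, n_boot = n_boot),
            class = "cascade_thresholds")
}

#' Spearman rank correlation with pairwise-complete observations
#'
#' @param x,y numeric vectors of equal length; incomplete pairs are
#'   excluded.
#' @return the Spearman coefficient, or `NA` when fewer than 3 complete
#'   pairs (or zero rank variance) make it undefined.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
}

#' Bootstrap-aggregated Spearman correlation
#'
#' Resamples complete pairs with replacement `n_boot` times; degenerate
#' resamples (fewer than 3 distinct pairs, or zero rank variance in either
#' margin) are redrawn. The aggregate is the median of the resample
#' coefficients, a robust summary of the bootstrap distribution.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_boot number of bootstrap resamples (default 100).
#' @param seed integer seed making the resampling deterministic.
#' @param min_pairs minimum complete pairs required (default 6).
#' @return list with `rho` (bootstrap-median Spearman coefficient) and
#'   `n_complete` (complete pairs used), or `NULL`-rho with a reason when
#'   the pair is excluded.
#' @export
bootstrap_rho <- function(x, y, n_boot = 100, seed = NULL, min_pairs = 6) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < min_pairs) {
    return(list(rho = NA_real_, n_complete = n,
                reason = sprintf("only %d complete pairs (< %d)", n, min_pairs)))
  }
  x <- x[ok]
  y <- y[ok]
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, n_complete = n, reason = "zero rank variance"))
  }
  rhos <- with_seed(seed, {
    out <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) >= 3) {
          xr <- rank(x[idx])
          yr <- rank(y[idx])
          if (stats::sd(xr) > 0 && stats::sd(yr) > 0) {
            out[b] <- stats::cor(xr, yr)
            break
          }
        }
      }
    }
    out
  })
  list(rho = stats::median(rhos), n_complete = n, reason = NA_character_)
}

#' Number of unordered feature pairs
#'
#' @param n_features number of eligible features.
#' @return n * (n - 1) / 2, the candidate pair count of a full pairwise
#'   correlation analysis.
#' @export
n_candidate_pairs <- function(n_features) {
  n_features * (n_features - 1) / 2
}

#' Bootstrapped Spearman correlations of all feature pairs within a group
#'
#' @param table a QA-filtered [feature_table()].
#' @param group biological group label.
#' @param thresholds a [cascade_thresholds()].
#' @param seed integer seed; per-pair resampling seeds are derived from it
#'   deterministically.
#' @return object of class `correlation_set`: data.frame `feature_a`,
#'   `feature_b` (feature_a < feature_b), `rho`, `n_complete`, restricted
#'   to pairs with at least `min_pairs` complete observations; attributes
#'   `group` and `n_candidate_pairs`.
#' @export
group_correlation_matrix <- function(table, group,
                                     thresholds = cascade_thresholds(),
                                     seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  cols <- bio_samples(table, group)
  X <- table$intensities[, cols, drop = FALSE]
  fids <- rownames(X)
  nf <- length(fids)
  total <- n_candidate_pairs(nf)
  rows <- vector("list", total)
  r <- 0L
  pair_id <- 0L
  for (i in seq_len(max(nf - 1, 0))) {
    for (j in seq((i + 1), nf)) {
      pair_id <- pair_id + 1L
      br <- bootstrap_rho(X[i, ], X[j, ], n_boot = thresholds$n_boot,
                          seed = derive_seed(seed, pair_id),
                          min_pairs = thresholds$min_pairs)
      if (is.na(br$rho)) next
      r <- r + 1L
      rows[[r]] <- list(feature_a = fids[i], feature_b = fids[j],
                        rho = br$rho, n_complete = br$n_complete)
    }
  }
  out <- if (r > 0) {
    do.call(rbind.data.frame, c(rows[seq_len(r)], stringsAsFactors = FALSE))
  } else {
    data.frame(feature_a = character(0), feature_b = character(0),
               rho = numeric(0), n_complete = integer(0),
               stringsAsFactors = FALSE)
  }
  attr(out, "group") <- group
  attr(out, "n_candidate_pairs") <- total
  class(out) <- c("correlation_set", class(out))
  out
}

#' Reversal-pattern candidates from three group correlation sets
#'
#' A pair passes the cascade when |rho_ND| > high_corr, |rho_DMT| >
#' high_corr and |rho_ND - rho_DM| > delta. Pairs of features assigned to
#' the same metabolite are removed; a feature is emitted when it passes
#' with at least `min_degree` different partner metabolites.
#'
#' @param c_nd,c_dm,c_dmt [group_correlation_matrix()] results for the
#'   untreated-control, untreated-diabetic and treated-diabetic groups.
#' @param thresholds a [cascade_thresholds()].
#' @param metabolite_map named character vector feature_id -> metabolite id;
#'   unmapped features are treated as singleton metabolites.
#' @return list with `candidates` (data.frame `feature_id`,
#'   `partner_metabolite_count`, sorted by decreasing count) and `edges`
#'   (passing pairs with their three coefficients).
#' @export
reversal_candidates <- function(c_nd, c_dm, c_dmt,
                                thresholds = cascade_thresholds(),
                                metabolite_map = NULL) {
  key <- function(d) paste(d$feature_a, d$feature_b, sep = "\r")
  m1 <- merge(
    data.frame(k = key(c_nd), feature_a = c_nd$feature_a,
               feature_b = c_nd$feature_b, rho_nd = c_nd$rho,
               stringsAsFactors = FALSE),
    data.frame(k = key(c_dm), rho_dm = c_dm$rho, stringsAsFactors = FALSE),
    by = "k"
  )
  m <- merge(m1, data.frame(k = key(c_dmt), rho_dmt = c_dmt$rho,
                            stringsAsFactors = FALSE), by = "k")
  if (nrow(m) == 0 && (nrow(c_nd) > 0 || nrow(c_dm) > 0 || nrow(c_dmt) > 0)) {
    mf_stop("the three correlation sets share no feature pairs", "mf_input_error")
  }

  met_of <- function(f) {
    if (is.null(metabolite_map)) return(f)
    out <- unname(metabolite_map[f])
    out[is.na(out)] <- f[is.na(out)]  # unmapped -> singleton metabolite
    out
  }

  pass <- abs(m$rho_nd) > thresholds$high_corr &
    abs(m$rho_dmt) > thresholds$high_corr &
    abs(m$rho_nd - m$rho_dm) > thresholds$delta
  edges <- m[pass, c("feature_a", "feature_b", "rho_nd", "rho_dm", "rho_dmt")]
  same_met <- met_of(edges$feature_a) == met_of(edges$feature_b)
  edges <- edges[!same_met, , drop = FALSE]
  rownames(edges) <- NULL

  if (nrow(edges) == 0) {
    return(list(
      candidates = data.frame(feature_id = character(0),
                              partner_metabolite_count = integer(0),
                              stringsAsFactors = FALSE),
      edges = edges
    ))
  }
  # Distinct partner metabolites per feature, counting both orientations.
  long <- rbind(
    data.frame(feature_id = edges$feature_a,
               partner_met = met_of(edges$feature_b), stringsAsFactors = FALSE),
    data.frame(feature_id = edges$feature_b,
               partner_met = met_of(edges$feature_a), stringsAsFactors = FALSE)
  )
  long <- unique(long)
  counts <- tapply(long$partner_met, long$feature_id, length)
  cand <- data.frame(feature_id = names(counts),
                     partner_metabolite_count = as.integer(counts),
                     stringsAsFactors = FALSE)
  cand <- cand[cand$partner_metabolite_count >= thresholds$min_degree, ,
               drop = FALSE]
  cand <- cand[order(-cand$partner_metabolite_count, cand$feature_id), ,
               drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand, edges = edges)
}
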