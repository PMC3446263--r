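# Small in-code fixtures shared across test files.

# A minimal valid manifest: two QCs bracketing two biological injections.
toy_manifest <- function() {
  data.frame(
    sample_id = c("QC1", "A1", "B1", "QC2"),
    study_id = 1L,
    group = c("QC", "ND_UT", "DM_UT", "QC"),
    injection_order = 1:4,
    ion_mode = "positive",
    stringsAsFactors = FALSE
  )
}

toy_features <- function(n = 3) {
  data.frame(
    feature_id = sprintf("F%d", seq_len(n)),
    mz = 100 + seq_len(n),
    rt = 10 * seq_len(n),
    ion_mode = rep("positive", n),
    stringsAsFactors = FALSE
  )
}

toy_table <- function(intensities = NULL) {
  f <- toy_features(3)
  if (is.null(intensities)) {
    intensities <- matrix(seq_len(12), nrow = 3,
                          dimnames = list(f$feature_id, toy_manifest()$sample_id))
  }
  feature_table(f, intensities, toy_manifest())
}

# Small, fast generator configuration used by several tests; any generator
# setting can be overridden.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_metabolites = 30, n_differential = 6,
         n_reversal_blocks = 1, block_size = 5),
    list(...)
  )
  do.call(synthetic_config, args)
}

# Independent Spearman oracle: midranks then the Pearson product-moment
# formula written out directly.
oracle_spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Independent Mann-Whitney oracle: U from pairwise win/tie counts and the
# two-sided p from exhaustive enumeration of group assignments.
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  mu <- n1 * n2 / 2
  u_all <- apply(idx, 2, function(s) u_of(pooled[s], pooled[-s]))
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  list(u = u_obs, p_value = p)
}
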