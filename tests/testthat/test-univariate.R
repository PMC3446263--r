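# Mann-Whitney testing, ratios and the two-study replication filter.

test_that("fully separated small samples give U = 0 and exact p = 0.1", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")
})

test_that("identical tied samples give p = 1", {
  res <- mann_whitney_u(c(1, 1, 2, 3), c(1, 1, 2, 3))
  expect_equal(res$p_value, 1)
})

test_that("exact p matches the permutation oracle for random tied samples", {
  set.seed(71)
  for (i in 1:40) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:8, 1)
    x <- sample(1:5, n1, replace = TRUE)  # coarse grid forces ties
    y <- sample(1:5, n2, replace = TRUE)
    res <- mann_whitney_u(x, y)
    orc <- oracle_mann_whitney(x, y)
    expect_equal(res$u, orc$u)
    expect_lt(abs(res$p_value - orc$p_value), 1e-9)
  }
})

test_that("the exact branch agrees with wilcox.test in the tie-free regime", {
  set.seed(72)
  for (i in 1:20) {
    x <- rnorm(sample(3:9, 1))
    y <- rnorm(sample(3:9, 1))
    res <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(res$u, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(73)
  x <- rlnorm(7)
  y <- rlnorm(9)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(log(x), log(y))
  c <- mann_whitney_u(x^3, y^3)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$u, c$u)
})

test_that("group ratios and directions follow the median convention", {
  expect_equal(group_ratio(c(9, 10, 11), c(20, 25, 30)),
               list(ratio = 2.5, direction = "up"))
  expect_equal(group_ratio(c(9, 10, 11), c(4, 5, 6)),
               list(ratio = 0.5, direction = "down"))
  expect_equal(group_ratio(c(0, 0, 0), c(1, 2, 3))$direction, "none")
})

test_that("estimated ratios recover injected fold-changes within 25%", {
  rel_err <- c()
  for (seed in 1:20) {
    cfg <- small_config(noise_cv = 0.1, drift_amplitude = 0, missing_rate = 0,
                        n_reversal_blocks = 0)
    st <- generate_study(cfg, 2, seed = seed)
    man <- st$table$manifest
    X <- st$table$intensities
    nd <- man$sample_id[man$group == "ND_UT"]
    dm <- man$sample_id[man$group == "DM_UT"]
    tr <- st$truth
    for (r in seq_len(nrow(tr$differential))) {
      fid <- names(tr$feature_to_metabolite)[
        tr$feature_to_metabolite == tr$differential$metabolite_id[r]][1]
      est <- group_ratio(X[fid, nd], X[fid, dm])$ratio
      rel_err <- c(rel_err, abs(est - tr$differential$fold[r]) /
                     tr$differential$fold[r])
    }
  }
  expect_lt(mean(rel_err), 0.25)
})

test_that("differential testing skips all-missing features and flags significance", {
  st <- generate_study(small_config(missing_rate = 0), 2, seed = 31)
  X <- st$table$intensities
  X[2, ] <- NA
  ft <- feature_table(st$table$features, X, st$table$manifest)
  res <- differential_features(ft, c("ND_UT", "DM_UT"))
  skipped_id <- st$table$features$feature_id[2]
  expect_false(skipped_id %in% res$feature_id)
  expect_true(skipped_id %in% attr(res, "skipped"))
  expect_identical(res$significant, res$p_value < 0.05)
  expect_error(differential_features(ft, c("ND_UT", "HEALTHY")),
               class = "mf_input_error")
})

test_that("replication requires significance in both studies with equal direction", {
  r1 <- data.frame(feature_id = c("a", "b", "c", "d"),
                   p_value = c(0.01, 0.01, 0.2, 0.04),
                   ratio = c(2, 2, 2, 0.5),
                   direction = c("up", "up", "up", "down"))
  r2 <- data.frame(feature_id = c("a", "b", "c", "d"),
                   p_value = c(0.02, 0.01, 0.01, 0.03),
                   ratio = c(3, 0.4, 3, 0.7),
                   direction = c("up", "down", "up", "down"))
  rep_ <- replication_filter(r1, r2)
  # a: both significant, same direction; b: directions differ; c: study-1 only;
  # d: both significant, both down.
  expect_setequal(rep_$feature_id, c("a", "d"))
  expect_equal(rep_$feature_id, c("a", "d"))  # sorted by study-1 p
  # monotone filtering: replicated set within each study's significant set
  expect_true(all(rep_$feature_id %in% r1$feature_id[r1$p_value < 0.05]))
  expect_true(all(rep_$feature_id %in% r2$feature_id[r2$p_value < 0.05]))
})

test_that("results are permutation-equivariant in sample order", {
  st <- generate_study(small_config(), 2, seed = 33)
  res1 <- differential_features(st$table, c("ND_UT", "DM_UT"))
  man <- st$table$manifest
  perm <- sample(nrow(man))
  ft2 <- feature_table(st$table$features,
                       st$table$intensities[, man$sample_id[perm]],
                       man[perm, ])
  res2 <- differential_features(ft2, c("ND_UT", "DM_UT"))
  expect_equal(res1$p_value, res2$p_value)
  expect_equal(res1$ratio, res2$ratio)
})

test_that("feature matching across runs respects ppm and rt tolerances", {
  f1 <- data.frame(feature_id = c("x1", "x2"), mz = c(200.0000, 300.0000),
                   rt = c(100, 200), ion_mode = "positive")
  f2 <- data.frame(feature_id = c("y1", "y2", "y3"),
                   mz = c(200.0006, 300.0100, 200.0004),
                   rt = c(102, 201, 300), ion_mode = "positive")
  m <- match_features_between_runs(f1, f2, mz_tol_ppm = 5, rt_tol = 10)
  # y3 co-masses with x1 but elutes 200 s away; y2 is 33 ppm off.
  expect_equal(m$feature_id_1, "x1")
  expect_equal(m$feature_id_2, "y1")
})
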