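# Spearman, bootstrap aggregation and the reversal cascade.

test_that("spearman handles monotone, reversed and tied data", {
  x <- 1:8
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_true(is.na(spearman_rho(c(1, 2), c(3, 4))))  # < 3 complete pairs

  set.seed(41)
  for (i in 1:25) {
    n <- sample(5:15, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_lt(abs(spearman_rho(x, y) - oracle_spearman(x, y)), 1e-12)
  }
})

test_that("bootstrap aggregation is deterministic and exact on monotone data", {
  x <- rnorm(10)
  y <- 2 * x + 10
  for (seed in c(1, 99, 1234)) {
    expect_equal(bootstrap_rho(x, y, seed = seed)$rho, 1)
  }
  z <- rnorm(10)
  a <- bootstrap_rho(x, z, seed = 5)
  b <- bootstrap_rho(x, z, seed = 5)
  expect_identical(a, b)
  expect_equal(a$n_complete, 10)
})

test_that("pairs below the minimum complete-pair count are excluded with a reason", {
  x <- c(1, 2, 3, 4, 5, NA, NA, NA, NA, NA)
  y <- c(5, 4, 3, 2, 1, 1, 2, 3, 4, 5)
  out <- bootstrap_rho(x, y, seed = 1, min_pairs = 6)
  expect_true(is.na(out$rho))
  expect_equal(out$n_complete, 5)
  expect_match(out$reason, "complete pairs")
})

test_that("bootstrap-median Spearman is calibrated on correlated bivariate data", {
  # rank correlation ~0.7 at n = 10; the aggregate should land within 0.1
  # of the target on average across seeds.
  rho_p <- 2 * sin(pi * 0.7 / 6)
  agg <- vapply(1:150, function(seed) {
    set.seed(seed)
    z <- rnorm(10)
    x <- sqrt(rho_p) * z + sqrt(1 - rho_p) * rnorm(10)
    y <- sqrt(rho_p) * z + sqrt(1 - rho_p) * rnorm(10)
    bootstrap_rho(x, y, seed = seed)$rho
  }, numeric(1))
  expect_lt(abs(mean(agg) - 0.7), 0.1)
})

test_that("group correlation matrices enumerate all unordered pairs", {
  st <- generate_study(small_config(n_metabolites = 4,
                                    features_per_metabolite = c(1, 0, 0),
                                    n_differential = 0, n_reversal_blocks = 0,
                                    missing_rate = 0), 2, seed = 51)
  cs <- group_correlation_matrix(st$table, "ND_UT", seed = 1)
  expect_equal(nrow(cs), 6)  # C(4,2)
  expect_equal(attr(cs, "n_candidate_pairs"), 6)
  expect_true(all(cs$feature_a != cs$feature_b))
  expect_true(all(abs(cs$rho) <= 1))
  expect_error(group_correlation_matrix(st$table, "NOPE"),
               class = "mf_input_error")
})

test_that("pair retention equals a brute-force completeness count under missingness", {
  st <- generate_study(small_config(n_metabolites = 8,
                                    features_per_metabolite = c(1, 0, 0),
                                    n_differential = 0, n_reversal_blocks = 0,
                                    missing_rate = 0.35), 2, seed = 52)
  cs <- group_correlation_matrix(st$table, "DM_UT", seed = 2)
  cols <- st$table$manifest$sample_id[st$table$manifest$group == "DM_UT"]
  X <- st$table$intensities[, cols]
  fids <- rownames(X)
  expected <- c()
  for (i in seq_len(length(fids) - 1)) {
    for (j in seq(i + 1, length(fids))) {
      if (sum(is.finite(X[i, ]) & is.finite(X[j, ])) >= 6) {
        expected <- c(expected, paste(fids[i], fids[j]))
      }
    }
  }
  expect_setequal(paste(cs$feature_a, cs$feature_b), expected)
})

test_that("the cascade rule accepts and rejects the canonical triples", {
  mk <- function(rho_nd, rho_dm, rho_dmt) {
    pairs <- data.frame(feature_a = "f1", feature_b = "f2")
    list(nd = cbind(pairs, rho = rho_nd, n_complete = 10L),
         dm = cbind(pairs, rho = rho_dm, n_complete = 10L),
         dmt = cbind(pairs, rho = rho_dmt, n_complete = 10L))
  }
  th <- cascade_thresholds(min_degree = 1)
  passes <- function(s) {
    nrow(reversal_candidates(s$nd, s$dm, s$dmt, th)$edges) == 1
  }
  expect_true(passes(mk(0.9, 0.1, 0.8)))
  expect_false(passes(mk(0.9, 0.6, 0.8)))   # change 0.3 <= 0.5
  expect_true(passes(mk(0.6, -0.6, 0.55)))  # sign switch, change 1.2
  expect_false(passes(mk(0.4, -0.4, 0.8)))  # |rho_ND| too low
  expect_false(passes(mk(0.9, 0.1, 0.3)))   # |rho_DMT| too low
})

test_that("same-metabolite pairs are removed and degree counts partner metabolites", {
  pairs <- data.frame(
    feature_a = c("m1a", "m1a", "m1b"),
    feature_b = c("m1b", "m2a", "m2a")
  )
  mk_set <- function(rho) cbind(pairs, rho = rho, n_complete = 10L)
  th <- cascade_thresholds(min_degree = 1)
  map <- c(m1a = "M1", m1b = "M1", m2a = "M2")
  out <- reversal_candidates(mk_set(0.9), mk_set(0.0), mk_set(0.9), th, map)
  # m1a-m1b is a same-metabolite pair and must vanish
  expect_equal(nrow(out$edges), 2)
  cand <- out$candidates
  expect_equal(cand$partner_metabolite_count[cand$feature_id == "m2a"], 1L)
  # m2a's partners m1a and m1b are one metabolite, not two
})

test_that("candidate sets shrink as thresholds tighten", {
  st <- generate_study(small_config(n_metabolites = 12, block_size = 6,
                                    missing_rate = 0, drift_amplitude = 0),
                       2, seed = 53)
  th_loose <- cascade_thresholds(high_corr = 0.3, delta = 0.3, min_degree = 1)
  th_tight <- cascade_thresholds(high_corr = 0.6, delta = 0.6, min_degree = 1)
  sets <- lapply(c("ND_UT", "DM_UT", "DM_TETA"), function(g) {
    group_correlation_matrix(st$table, g, th_loose,
                             seed = match(g, c("ND_UT", "DM_UT", "DM_TETA")))
  })
  map <- st$truth$feature_to_metabolite
  loose <- reversal_candidates(sets[[1]], sets[[2]], sets[[3]], th_loose, map)
  tight <- reversal_candidates(sets[[1]], sets[[2]], sets[[3]], th_tight, map)
  key <- function(e) paste(e$feature_a, e$feature_b)
  expect_true(all(key(tight$edges) %in% key(loose$edges)))
  th_deg <- cascade_thresholds(high_corr = 0.3, delta = 0.3, min_degree = 3)
  deg3 <- reversal_candidates(sets[[1]], sets[[2]], sets[[3]], th_deg, map)
  expect_true(all(deg3$candidates$feature_id %in% loose$candidates$feature_id))
})

test_that("pair counts follow n(n-1)/2", {
  expect_equal(n_candidate_pairs(4), 6)
  expect_equal(n_candidate_pairs(1), 0)
})
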