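# QC-RLSC trend fitting, correction and the QA filter.

test_that("constant QC intensities give a constant trend", {
  orders <- c(1, 4, 8, 15, 20, 25, 30, 40)
  tr <- fit_qc_trend(orders, rep(250, 8), all_orders = 1:40)
  expect_equal(tr, rep(250, 40), tolerance = 1e-8)
})

test_that("a linear QC series at full span is recovered within 1%", {
  orders <- seq(2, 50, by = 4)
  y <- 100 + 3 * orders
  tr <- fit_qc_trend(orders, y, all_orders = orders, span = 1)
  expect_true(all(abs(tr - y) / y < 0.01))
})

test_that("fewer than 4 usable QC points is a trend-fit error", {
  expect_error(fit_qc_trend(c(1, 5, 9), c(10, 11, 12), 1:10),
               class = "mf_trendfit_error")
  # non-detected (zero / missing) QC values do not count as usable
  expect_error(fit_qc_trend(1:6, c(10, 11, 12, 0, NA, NA), 1:10),
               class = "mf_trendfit_error")
})

test_that("trend values outside the QC order range are held at the boundary", {
  orders <- 10:20
  y <- 100 + 2 * orders
  tr <- fit_qc_trend(orders, y, all_orders = c(1, 5, 25, 30), span = 1)
  expect_equal(tr[1], tr[2], tolerance = 1e-9)
  expect_equal(tr[3], tr[4], tolerance = 1e-9)
})

test_that("correction is the identity on drift-free, noise-free data", {
  cfg <- small_config(drift_amplitude = 0, noise_cv = 0, missing_rate = 0)
  st <- generate_study(cfg, 1, seed = 2)
  out <- qc_rlsc_correct(st$table)
  expect_equal(nrow(out$dropped), 0)
  rel <- abs(out$table$intensities - st$table$intensities) / st$table$intensities
  expect_lt(max(rel, na.rm = TRUE), 1e-9)
})

test_that("correction reduces QC RSD in the presence of smooth drift", {
  cfg <- small_config(drift_amplitude = 0.3, noise_cv = 0.05, missing_rate = 0)
  st <- generate_study(cfg, 2, seed = 8)
  out <- qc_rlsc_correct(st$table)
  qc <- qc_samples(st$table)
  rsd <- function(M) apply(M[, qc], 1, function(v) {
    v <- v[is.finite(v)]
    100 * sd(v) / mean(v)
  })
  before <- rsd(st$table$intensities[rownames(out$table$intensities), ])
  after <- rsd(out$table$intensities)
  expect_lt(median(after), median(before))
})

test_that("features undetected in QCs are dropped with a reason", {
  st <- generate_study(small_config(missing_rate = 0), 1, seed = 4)
  X <- st$table$intensities
  X[1, qc_samples(st$table)] <- NA
  ft <- feature_table(st$table$features, X, st$table$manifest)
  out <- qc_rlsc_correct(ft)
  expect_true(st$table$features$feature_id[1] %in% out$dropped$feature_id)
  expect_false(st$table$features$feature_id[1] %in%
                 rownames(out$table$intensities))
  expect_match(out$dropped$reason[1], "QC")
})

test_that("correction is scale-equivariant", {
  cfg <- small_config(drift_amplitude = 0.2, noise_cv = 0.05, missing_rate = 0)
  st <- generate_study(cfg, 1, seed = 6)
  out1 <- qc_rlsc_correct(st$table)
  X2 <- st$table$intensities
  X2[3, ] <- X2[3, ] * 7
  out2 <- qc_rlsc_correct(feature_table(st$table$features, X2, st$table$manifest))
  fid <- rownames(st$table$intensities)[3]
  expect_equal(out2$table$intensities[fid, ],
               7 * out1$table$intensities[fid, ], tolerance = 1e-9)
})

test_that("QA filter applies both strict criteria over the QC window", {
  # 10 window QCs; feature A detected in 5/10 (50%) -> removed regardless of RSD;
  # feature B constant {100} -> RSD 0, detection 100% -> retained.
  n_qc <- 12
  man <- data.frame(
    sample_id = c(sprintf("QC%d", 1:n_qc), "A1", "B1"),
    study_id = 1L,
    group = c(rep("QC", n_qc), "ND_UT", "DM_UT"),
    injection_order = 1:(n_qc + 2),
    ion_mode = "positive"
  )
  f <- data.frame(feature_id = c("A", "B"), mz = c(100, 200), rt = c(10, 20),
                  ion_mode = "positive")
  qc_a <- c(50, 50, rep(c(100, NA), 5))           # orders 3..12 in window: 5/10
  qc_b <- c(80, 80, rep(100, 10))                 # window RSD 0
  X <- rbind(A = c(qc_a, 60, 70), B = c(qc_b, 90, 95))
  colnames(X) <- man$sample_id
  out <- qa_filter(feature_table(f, X, man), qc_from_injection = 3)
  expect_false(out$report$passed[out$report$feature_id == "A"])
  expect_true(out$report$passed[out$report$feature_id == "B"])
  expect_equal(out$report$qc_detection_fraction,  c(0.5, 1))
  expect_equal(out$report$qc_rsd_percent[2], 0)
})

test_that("QA verdicts equal a brute-force recomputation on randomized tables", {
  for (seed in c(13, 14)) {
    st <- generate_study(small_config(missing_rate = 0.2, noise_cv = 0.3), 2,
                         seed = seed)
    out <- qa_filter(st$table)
    man <- st$table$manifest
    win_cols <- man$sample_id[man$group == "QC" & man$injection_order >= 8]
    expected <- vapply(rownames(st$table$intensities), function(fid) {
      v <- st$table$intensities[fid, win_cols]
      det <- sum(!is.na(v) & v > 0) / length(v)
      vv <- v[!is.na(v)]
      rsd <- if (length(vv) >= 2) 100 * sd(vv) / mean(vv) else NA_real_
      det > 0.6 && !is.na(rsd) && rsd < 20
    }, logical(1))
    retained <- out$report$feature_id[out$report$passed]
    expect_setequal(as.character(rownames(out$table$intensities)),
                    as.character(retained))
    expect_identical(unname(expected[out$report$feature_id]),
                     out$report$passed)
    # report accounting: in = retained + removed
    expect_equal(attr(out$report, "n_in"),
                 attr(out$report, "n_retained") + sum(!out$report$passed))
  }
})
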