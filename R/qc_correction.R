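# QC-RLSC injection-order signal correction and QC-based QA filtering.
#
# Each feature's pooled-QC intensities are regressed on injection order with
# a robust (iteratively reweighted) loess; every injection's measurement is
# divided by the fitted trend at its order and rescaled to a per-feature
# reference level (median raw QC intensity by default). After correction,
# features are retained only if detected in > 60% of the QC injections from
# injection 8 onward with a QC relative standard deviation < 20%.

#' Fit a robust loess trend through a feature's QC intensities
#'
#' @param qc_orders injection orders of the usable QC measurements
#'   (increasing integers).
#' @param qc_intensities positive QC peak areas at those orders.
#' @param all_orders injection orders at which the trend is evaluated.
#' @param span loess smoothing fraction. With few QC points the effective
#'   span is widened (and the local degree lowered) so the local windows
#'   still contain enough points for a stable fit.
#' @param degree local polynomial degree (1 or 2).
#' @return numeric vector of strictly positive fitted trend values, one per
#'   entry of `all_orders`; orders outside the QC range take the nearest
#'   fitted value.
#' @export
fit_qc_trend <- function(qc_orders, qc_intensities, all_orders,
                         span = 0.6, degree = 2) {
  ok <- is.finite(qc_intensities) & qc_intensities > 0
  qc_orders <- qc_orders[ok]
  qc_intensities <- qc_intensities[ok]
  n_qc <- length(qc_orders)
  if (n_qc < 4) {
    mf_stop("fewer than 4 usable QC intensities; trend cannot be fitted",
            "mf_trendfit_error")
  }
  if (is.unsorted(qc_orders, strictly = FALSE)) {
    o <- order(qc_orders)
    qc_orders <- qc_orders[o]
    qc_intensities <- qc_intensities[o]
  }
  deg <- if (n_qc < 8) 1L else as.integer(degree)
  span_eff <- max(span, min(1, (deg * 3 + 2) / n_qc))

  fit <- tryCatch(
    stats::loess(y ~ x,
                 data = data.frame(x = qc_orders, y = qc_intensities),
                 span = span_eff, degree = deg, family = "symmetric",
                 control = stats::loess.control(surface = "direct")),
    error = function(e) mf_stop(paste0("loess fit failed: ", conditionMessage(e)),
                                "mf_trendfit_error")
  )
  # Hold the boundary value constant outside the QC-anchored range.
  eval_at <- pmin(pmax(all_orders, min(qc_orders)), max(qc_orders))
  trend <- stats::predict(fit, newdata = data.frame(x = eval_at))
  if (anyNA(trend)) {
    mf_stop("trend evaluation produced non-finite values", "mf_trendfit_error")
  }
  # Clip to positivity: a trend crossing zero would flip corrected signs.
  if (!any(trend > 0)) {
    mf_stop("fitted trend is nowhere positive", "mf_trendfit_error")
  }
  floor_val <- max(min(trend[trend > 0], na.rm = TRUE),
                   1e-6 * stats::median(qc_intensities))
  unname(pmax(trend, floor_val))
}

#' QC-RLSC correction of a feature table
#'
#' Each (study, ion mode) run is corrected independently. For every feature,
#' corrected = raw / trend(order) * reference. Missing values stay missing;
#' features whose trend cannot be fitted (fewer than 4 usable QC points) are
#' dropped and listed in the result.
#'
#' @param table a [feature_table()].
#' @param span loess span passed to [fit_qc_trend()].
#' @param reference per-feature rescaling level; default is each feature's
#'   median raw QC intensity.
#' @return list with `table` (corrected [feature_table()], uncorrectable
#'   features removed) and `dropped` (data.frame feature_id, reason).
#' @export
qc_rlsc_correct <- function(table, span = 0.6, reference = NULL) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$manifest
  if (!any(m$group == "QC")) {
    mf_stop("run contains no QC injections; QC-RLSC is not applicable",
            "mf_input_error")
  }
  X <- table$intensities
  corrected <- X
  dropped <- list()

  runs <- split(seq_len(nrow(m)), list(m$study_id, m$ion_mode), drop = TRUE)
  for (run_idx in runs) {
    rm_ <- m[run_idx, ]
    run_cols <- rm_$sample_id
    qc_cols <- rm_$sample_id[rm_$group == "QC"]
    all_orders <- rm_$injection_order
    qc_orders <- rm_$injection_order[rm_$group == "QC"]
    for (i in seq_len(nrow(X))) {
      qc_vals <- X[i, qc_cols]
      ref <- if (is.null(reference)) {
        stats::median(qc_vals[is.finite(qc_vals) & qc_vals > 0])
      } else {
        reference[i]
      }
      trend <- tryCatch(
        fit_qc_trend(qc_orders, qc_vals, all_orders, span = span),
        mf_trendfit_error = function(e) e
      )
      if (inherits(trend, "condition")) {
        dropped[[length(dropped) + 1]] <- data.frame(
          feature_id = rownames(X)[i], reason = conditionMessage(trend),
          stringsAsFactors = FALSE
        )
        corrected[i, run_cols] <- NA_real_
        next
      }
      corrected[i, run_cols] <- X[i, run_cols] / trend * ref
    }
  }

  dropped <- if (length(dropped)) {
    unique(do.call(rbind, dropped))
  } else {
    data.frame(feature_id = character(0), reason = character(0))
  }
  keep <- setdiff(rownames(X), dropped$feature_id)
  keep_idx <- match(keep, table$features$feature_id)
  out <- feature_table(table$features[keep_idx, , drop = FALSE],
                       corrected[keep, , drop = FALSE],
                       table$manifest)
  list(table = out, dropped = dropped)
}

#' QC-based quality-assurance filter
#'
#' Retains only features detected in more than `detection_threshold` of the
#' QC injections from injection `qc_from_injection` onward and whose QC
#' relative standard deviation is below `rsd_threshold` percent. "Detected"
#' means non-missing with a positive peak area. Both inequalities are
#' strict; all other features are removed.
#'
#' @param table a (corrected) [feature_table()].
#' @param detection_threshold minimum QC detection fraction (default 0.60).
#' @param rsd_threshold maximum QC RSD in percent (default 20).
#' @param qc_from_injection first injection order included in the QC window
#'   (default 8; the earlier QC injections condition the column and are not
#'   representative).
#' @return list with `table` (filtered [feature_table()]) and `report`
#'   (data.frame feature_id, qc_detection_fraction, qc_rsd_percent, passed;
#'   attributes `n_in` and `n_retained`).
#' @export
qa_filter <- function(table, detection_threshold = 0.60, rsd_threshold = 20,
                      qc_from_injection = 8) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$manifest
  win <- m$group == "QC" & m$injection_order >= qc_from_injection
  if (!any(win)) {
    mf_stop("no QC injections at or after qc_from_injection", "mf_input_error")
  }
  Q <- table$intensities[, m$sample_id[win], drop = FALSE]
  detected <- is.finite(Q) & Q > 0
  det_frac <- rowMeans(detected)
  rsd <- apply(Q, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    100 * stats::sd(v) / mean(v)
  })
  passed <- det_frac > detection_threshold & !is.na(rsd) & rsd < rsd_threshold
  report <- data.frame(
    feature_id = rownames(Q),
    qc_detection_fraction = det_frac,
    qc_rsd_percent = rsd,
    passed = passed,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(report, "n_in") <- nrow(Q)
  attr(report, "n_retained") <- sum(passed)
  keep_idx <- which(passed)
  out <- feature_table(table$features[keep_idx, , drop = FALSE],
                       table$intensities[keep_idx, , drop = FALSE],
                       table$manifest)
  list(table = out, report = report)
}
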