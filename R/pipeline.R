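# End-to-end orchestration: QC-RLSC -> QA filter -> PCA + outlier flags ->
# six pairwise comparisons per study -> two-study replication filter ->
# reversal-correlation cascade on the configured study.

#' Pipeline parameters
#'
#' @param span loess span for [qc_rlsc_correct()].
#' @param detection_threshold,rsd_threshold,qc_from_injection QA-filter
#'   settings, see [qa_filter()].
#' @param alpha significance level of the univariate stage.
#' @param ratio_center "median" or "mean", see [group_ratio()].
#' @param n_components PCA components kept.
#' @param outlier_k MAD multiplier of [flag_outliers()].
#' @param act_on_outliers when TRUE, flagged injections are removed before
#'   the univariate stage (flagging alone is advisory).
#' @param thresholds [cascade_thresholds()] of the correlation stage.
#' @param stages character vector of enabled stages, any of "correction",
#'   "qa", "pca", "stats", "correlation".
#' @return a `pipeline_params` list.
#' @export
pipeline_params <- function(span = 0.6,
                            detection_threshold = 0.60,
                            rsd_threshold = 20,
                            qc_from_injection = 8,
                            alpha = 0.05,
                            ratio_center = "median",
                            n_components = 3,
                            outlier_k = 5,
                            act_on_outliers = FALSE,
                            thresholds = cascade_thresholds(),
                            stages = c("correction", "qa", "pca", "stats",
                                       "correlation")) {
  structure(list(span = span, detection_threshold = detection_threshold,
                 rsd_threshold = rsd_threshold,
                 qc_from_injection = qc_from_injection, alpha = alpha,
                 ratio_center = ratio_center, n_components = n_components,
                 outlier_k = outlier_k, act_on_outliers = act_on_outliers,
                 thresholds = thresholds, stages = stages),
            class = "pipeline_params")
}

drop_samples <- function(table, sample_ids) {
  keep <- !(table$manifest$sample_id %in% sample_ids)
  feature_table(table$features,
                table$intensities[, table$manifest$sample_id[keep], drop = FALSE],
                table$manifest[keep, , drop = FALSE])
}

#' Run the full analysis pipeline on one or two studies
#'
#' @param studies named list of [feature_table()] objects (names are study
#'   labels, e.g. `"1"`, `"2"`); entries may also be
#'   `list(table = path, manifest = path)` to read from TSV.
#' @param params a [pipeline_params()].
#' @param master_seed integer; every stochastic stage derives its seed from
#'   it deterministically.
#' @param metabolite_map named vector feature_id -> metabolite id used by
#'   the same-metabolite pair-removal rule (e.g. synthetic ground truth or
#'   [group_features_by_metabolite()]); unmapped features are singletons.
#' @param correlation_study label of the study the correlation cascade is
#'   run on; default is the study whose smallest biological group is
#'   largest (more complete pairs per correlation).
#' @param outdir optional directory; when given, stage outputs are written
#'   as TSV under it.
#' @return a `pipeline_summary` list: per-study stage results and counts,
#'   cross-study replication tables, correlation-stage results, and a
#'   `counts` data.frame recording feature numbers at every stage.
#' @export
run_pipeline <- function(studies, params = pipeline_params(), master_seed = 1,
                         metabolite_map = NULL, correlation_study = NULL,
                         outdir = NULL) {
  stopifnot(inherits(params, "pipeline_params"))
  studies <- lapply(studies, function(s) {
    if (inherits(s, "feature_table")) s else read_feature_table(s$table, s$manifest)
  })
  if (is.null(names(studies)) || any(names(studies) == "")) {
    names(studies) <- as.character(seq_along(studies))
  }
  on_stage <- function(s) s %in% params$stages
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  per_study <- list()
  counts <- list()
  for (sn in names(studies)) {
    ft <- studies[[sn]]
    n_in <- nrow(ft$intensities)
    dropped <- data.frame(feature_id = character(0), reason = character(0))

    if (on_stage("correction")) {
      corr <- qc_rlsc_correct(ft, span = params$span)
      ft <- corr$table
      dropped <- corr$dropped
    }
    qa_report <- NULL
    if (on_stage("qa")) {
      qa <- qa_filter(ft, params$detection_threshold, params$rsd_threshold,
                      params$qc_from_injection)
      ft <- qa$table
      qa_report <- qa$report
    }
    pca <- NULL
    outliers <- data.frame(sample_id = character(0))
    if (on_stage("pca")) {
      pca <- pca_scores(ft, n_components = params$n_components)
      outliers <- flag_outliers(ft, k = params$outlier_k)
      if (params$act_on_outliers && nrow(outliers) > 0) {
        ft <- drop_samples(ft, outliers$sample_id)
      }
    }
    stats_res <- NULL
    if (on_stage("stats")) {
      stats_res <- lapply(GROUP_COMPARISONS, function(cmp) {
        differential_features(ft, cmp, alpha = params$alpha,
                              center = params$ratio_center)
      })
      names(stats_res) <- vapply(GROUP_COMPARISONS,
                                 function(cmp) paste(cmp[2], "vs", cmp[1]),
                                 character(1))
    }
    per_study[[sn]] <- list(table = ft, dropped = dropped,
                            qa_report = qa_report, pca = pca,
                            outliers = outliers, stats = stats_res)
    counts[[sn]] <- data.frame(
      study = sn,
      features_in = n_in,
      uncorrectable = nrow(dropped),
      retained = nrow(ft$intensities),
      stringsAsFactors = FALSE
    )
  }

  # Cross-study replication, per comparison.
  replication <- NULL
  summary_table <- NULL
  if (on_stage("stats") && length(studies) >= 2) {
    s1 <- per_study[[1]]$stats
    s2 <- per_study[[2]]$stats
    replication <- lapply(names(s1), function(nm) {
      replication_filter(s1[[nm]], s2[[nm]], alpha = params$alpha)
    })
    names(replication) <- names(s1)
    summary_table <- data.frame(
      comparison = names(s1),
      study1_significant = vapply(s1, function(d) sum(d$significant), integer(1)),
      study2_significant = vapply(s2, function(d) sum(d$significant), integer(1)),
      both_studies = vapply(replication, nrow, integer(1)),
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  }

  # Reversal cascade on the study with the largest smallest group.
  correlation <- NULL
  if (on_stage("correlation")) {
    if (is.null(correlation_study)) {
      min_group <- vapply(per_study, function(s) {
        grp <- s$table$manifest$group
        min(table(grp[grp != "QC"]))
      }, numeric(1))
      correlation_study <- names(per_study)[which.max(min_group)]
    }
    ft_c <- per_study[[correlation_study]]$table
    th <- params$thresholds
    c_nd <- group_correlation_matrix(ft_c, "ND_UT", th, derive_seed(master_seed, 101))
    c_dm <- group_correlation_matrix(ft_c, "DM_UT", th, derive_seed(master_seed, 102))
    c_dmt <- group_correlation_matrix(ft_c, "DM_TETA", th, derive_seed(master_seed, 103))
    rev_ <- reversal_candidates(c_nd, c_dm, c_dmt, th, metabolite_map)
    correlation <- list(study = correlation_study,
                        n_candidate_pairs = attr(c_nd, "n_candidate_pairs"),
                        sets = list(ND_UT = c_nd, DM_UT = c_dm, DM_TETA = c_dmt),
                        candidates = rev_$candidates, edges = rev_$edges)
  }

  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL
  out <- structure(list(per_study = per_study, replication = replication,
                        summary_table = summary_table, correlation = correlation,
                        counts = counts, params = params,
                        master_seed = master_seed),
                   class = "pipeline_summary")
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

write_pipeline_outputs <- function(summary, outdir) {
  wt <- function(d, f) {
    utils::write.table(d, file.path(outdir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  wt(summary$counts, "stage_counts.tsv")
  for (sn in names(summary$per_study)) {
    s <- summary$per_study[[sn]]
    if (!is.null(s$qa_report)) wt(s$qa_report, sprintf("qa_report_study%s.tsv", sn))
    if (!is.null(s$pca)) {
      wt(data.frame(sample_id = rownames(s$pca$scores), s$pca$scores),
         sprintf("pca_scores_study%s.tsv", sn))
    }
    if (!is.null(s$stats)) {
      for (nm in names(s$stats)) {
        wt(s$stats[[nm]],
           sprintf("univariate_study%s_%s.tsv", sn, gsub(" ", "_", nm)))
      }
    }
  }
  if (!is.null(summary$summary_table)) wt(summary$summary_table, "replication_summary.tsv")
  if (!is.null(summary$replication)) {
    for (nm in names(summary$replication)) {
      wt(summary$replication[[nm]],
         sprintf("replicated_%s.tsv", gsub(" ", "_", nm)))
    }
  }
  if (!is.null(summary$correlation)) {
    wt(summary$correlation$edges, "reversal_edges.tsv")
    wt(summary$correlation$candidates, "reversal_candidates.tsv")
  }
  invisible(NULL)
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("pipeline_summary\n")
  print(x$counts)
  if (!is.null(x$summary_table)) {
    cat("\nreplication summary:\n")
    print(x$summary_table)
  }
  if (!is.null(x$correlation)) {
    cat(sprintf("\ncorrelation cascade (study %s): %d passing edges, %d candidate features\n",
                x$correlation$study, nrow(x$correlation$edges),
                nrow(x$correlation$candidates)))
  }
  invisible(x)
}
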