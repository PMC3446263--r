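# Simplified putative annotation (Metabolomics Standards Initiative
# level 2): ppm-tolerance matching against a user-supplied reference table,
# isotope-spacing charge-state assignment, and grouping of adduct/isotope
# sibling features under one metabolite for the same-metabolite
# pair-removal rule of the correlation stage.

# 13C - 12C mass difference in Da.
C13_DELTA <- 1.003355

#' Default adduct hypotheses
#'
#' @param ion_mode "positive" or "negative".
#' @return data.frame `adduct`, `mass_offset` (Da), `charge`, `ion_mode`.
#' @export
default_adducts <- function(ion_mode = c("positive", "negative")) {
  ion_mode <- match.arg(ion_mode)
  if (ion_mode == "positive") {
    data.frame(
      adduct = c("[M+H]+", "[M+Na]+", "[M+NH4]+"),
      mass_offset = c(1.007276, 22.989218, 18.033823),
      charge = c(1L, 1L, 1L),
      ion_mode = "positive",
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      adduct = c("[M-H]-", "[M+HCOO]-"),
      mass_offset = c(-1.007276, 44.998201),
      charge = c(1L, 1L),
      ion_mode = "negative",
      stringsAsFactors = FALSE
    )
  }
}

#' Assign a charge state from isotopologue m/z spacings
#'
#' Consecutive isotopologue peaks of a z-charged species are separated by
#' (13C-12C)/z = 1.003355/z in m/z; the assigned charge is the z in
#' 1..z_max whose predicted spacing is closest to the observed one.
#'
#' @param isotope_mz_spacings observed positive spacings between
#'   consecutive isotopologue peaks; their median is matched.
#' @param z_max largest charge considered (default 4).
#' @param tol maximum acceptable residual in Da (default 0.01); a larger
#'   best residual returns `NA` (unknown).
#' @return integer charge state, or `NA_integer_`.
#' @export
assign_charge_state <- function(isotope_mz_spacings, z_max = 4, tol = 0.01) {
  if (any(!is.finite(isotope_mz_spacings)) || any(isotope_mz_spacings <= 0)) {
    mf_stop("isotope spacings must be positive", "mf_value_error")
  }
  spacing <- stats::median(isotope_mz_spacings)
  z <- seq_len(z_max)
  resid <- abs(spacing - C13_DELTA / z)
  best <- which.min(resid)
  if (resid[best] > tol) NA_integer_ else as.integer(best)
}

#' Read a metabolite reference table
#'
#' @param path TSV with columns `metabolite_id`, `name`,
#'   `monoisotopic_mass` and optional `rt_low`, `rt_high` (seconds).
#' @return validated data.frame.
#' @export
read_reference_table <- function(path) {
  ref <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "name", "monoisotopic_mass")
  if (!all(need %in% names(ref))) {
    mf_stop("reference table needs columns metabolite_id, name, monoisotopic_mass",
            "mf_format_error")
  }
  if (any(ref$monoisotopic_mass <= 0)) {
    mf_stop("monoisotopic_mass must be positive", "mf_value_error")
  }
  if (all(c("rt_low", "rt_high") %in% names(ref)) &&
      any(ref$rt_low > ref$rt_high, na.rm = TRUE)) {
    mf_stop("rt_low must not exceed rt_high", "mf_value_error")
  }
  ref
}

#' Match a feature to reference metabolites within a ppm tolerance
#'
#' For each adduct hypothesis of the feature's ion mode, the neutral mass is
#' reconstructed as mz * z - mass_offset and compared with every reference
#' mass; candidates within `tol_ppm` (and inside the reference
#' retention-time window, when one is given) are reported, sorted by
#' absolute ppm error. All surviving candidates (isomers) are kept.
#'
#' @param feature one-row feature metadata (feature_id, mz, rt, ion_mode).
#' @param charge_state integer charge, or `NA` (treated as 1).
#' @param reference a reference table as from [read_reference_table()].
#' @param adducts adduct table (default [default_adducts()] for the
#'   feature's ion mode).
#' @param tol_ppm mass tolerance in parts per million (default 5).
#' @return data.frame `feature_id`, `adduct`, `metabolite_id`, `name`,
#'   `ppm_error`, `rt`, one row per surviving (adduct, candidate).
#' @export
match_metabolites <- function(feature, charge_state = 1L, reference,
                              adducts = NULL, tol_ppm = 5) {
  if (is.null(reference) || nrow(reference) == 0) {
    mf_stop("reference table is empty", "mf_input_error")
  }
  if (is.null(adducts)) adducts <- default_adducts(feature$ion_mode)
  z <- if (is.na(charge_state)) 1L else as.integer(charge_state)
  rows <- list()
  has_rt_window <- all(c("rt_low", "rt_high") %in% names(reference))
  for (a in seq_len(nrow(adducts))) {
    neutral <- feature$mz * z - adducts$mass_offset[a]
    ppm <- 1e6 * (neutral - reference$monoisotopic_mass) /
      reference$monoisotopic_mass
    ok <- abs(ppm) <= tol_ppm
    if (has_rt_window) {
      in_window <- is.na(reference$rt_low) |
        (feature$rt >= reference$rt_low & feature$rt <= reference$rt_high)
      ok <- ok & in_window
    }
    if (any(ok)) {
      rows[[length(rows) + 1]] <- data.frame(
        feature_id = feature$feature_id,
        adduct = adducts$adduct[a],
        metabolite_id = reference$metabolite_id[ok],
        name = reference$name[ok],
        ppm_error = ppm[ok],
        rt = feature$rt,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(feature_id = character(0), adduct = character(0),
               metabolite_id = character(0), name = character(0),
               ppm_error = numeric(0), rt = numeric(0),
               stringsAsFactors = FALSE)
  }
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate every feature of a table
#'
#' @param features feature metadata data.frame.
#' @param reference reference table.
#' @param tol_ppm ppm tolerance.
#' @param adducts optional adduct table used for all features.
#' @return single data.frame of all [match_metabolites()] rows.
#' @export
annotate_features <- function(features, reference, tol_ppm = 5, adducts = NULL) {
  out <- lapply(seq_len(nrow(features)), function(i) {
    match_metabolites(features[i, , drop = FALSE], 1L, reference,
                      adducts = adducts, tol_ppm = tol_ppm)
  })
  do.call(rbind, out)
}

#' Group features under metabolites from their annotations
#'
#' Features sharing a unique top candidate and co-eluting within
#' `rt_tol` seconds are grouped under that metabolite; unannotated or
#' ambiguous features become singleton metabolites (their own feature id).
#' The result feeds the same-metabolite pair-removal rule of
#' [reversal_candidates()].
#'
#' @param annotations output of [annotate_features()].
#' @param features feature metadata data.frame (supplies the full feature
#'   set and retention times).
#' @param rt_tol co-elution tolerance in seconds (default 5).
#' @return named character vector feature_id -> metabolite group id; a
#'   partition (every feature appears exactly once).
#' @export
group_features_by_metabolite <- function(annotations, features, rt_tol = 5) {
  top <- lapply(split(annotations, annotations$feature_id), function(d) {
    d <- d[order(abs(d$ppm_error)), , drop = FALSE]
    best <- abs(d$ppm_error) - abs(d$ppm_error[1]) < 1e-12
    mets <- unique(d$metabolite_id[best])
    if (length(mets) != 1) NULL else d[1, c("metabolite_id", "rt")]
  })
  top <- top[!vapply(top, is.null, logical(1))]

  map <- stats::setNames(features$feature_id, features$feature_id)  # singletons
  if (length(top)) {
    tf <- do.call(rbind, top)
    tf$feature_id <- names(top)
    # Within each top metabolite, cluster features by retention time: a
    # feature joins the group when within rt_tol of the group's first member.
    for (met in unique(tf$metabolite_id)) {
      sub <- tf[tf$metabolite_id == met, , drop = FALSE]
      sub <- sub[order(sub$rt), , drop = FALSE]
      grp_anchor <- sub$rt[1]
      grp_idx <- 1L
      for (r in seq_len(nrow(sub))) {
        if (sub$rt[r] - grp_anchor > rt_tol) {
          grp_idx <- grp_idx + 1L
          grp_anchor <- sub$rt[r]
        }
        gid <- if (grp_idx == 1L) met else sprintf("%s_g%d", met, grp_idx)
        map[sub$feature_id[r]] <- gid
      }
    }
  }
  map
}
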