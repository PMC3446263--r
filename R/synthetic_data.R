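# Synthetic two-study, four-group UPLC-MS study generator.
#
# Emulates the design the downstream stages are built for: a pooled-QC
# injection schedule (ten conditioning QCs, a QC every fifth injection, two
# closing QCs), smooth injection-order drift, multiplicative measurement
# noise, intensity-dependent left-censoring, adduct redundancy (one
# metabolite -> 1..3 features), diabetes fold-changes applied to the
# STZ-diabetic groups, and correlation blocks that are present in controls,
# disrupted in untreated diabetics and restored under treatment. The
# generator also returns the ground truth (which metabolites carry effects,
# which pairs carry the reversal pattern, the injected drift curves) so
# recovery tests have an exact target.

#' Configuration for the synthetic study generator
#'
#' Defaults reproduce the emulated study design: study 1 group sizes
#' ND_UT 9, ND_TETA 6, DM_UT 9, DM_TETA 6; study 2 with 10 animals per
#' group.
#'
#' @param n_per_group named list with one integer vector per study id
#'   (`"1"`, `"2"`), each named by biological group.
#' @param n_metabolites number of simulated metabolites.
#' @param features_per_metabolite probabilities for a metabolite emitting
#'   1, 2 or 3 features (adduct redundancy).
#' @param n_differential number of metabolites given a diabetes effect.
#' @param effect_ratio_range fold-change interval the diabetes effects are
#'   drawn from (applied as f or 1/f with equal probability).
#' @param n_reversal_blocks number of correlated metabolite blocks with the
#'   control-present / diabetes-lost / treatment-restored pattern.
#' @param block_size metabolites per reversal block.
#' @param within_block_rho target Spearman correlation between block
#'   features in the control and treated-diabetic groups. The latent-factor
#'   correlation is inflated internally to compensate for measurement-noise
#'   attenuation so the observable feature-level rank correlation matches
#'   the target.
#' @param drift_amplitude maximum fractional intensity change across the
#'   run induced by the smooth drift curve.
#' @param noise_cv coefficient of variation of the multiplicative
#'   (log-normal) measurement noise.
#' @param missing_rate fraction of intensities left-censored to missing
#'   (the censoring threshold is the corresponding quantile of the run's
#'   intensities, so missingness is intensity-dependent).
#' @param bio_sd log-scale between-animal biological variation for
#'   metabolites outside reversal blocks.
#' @param block_sd log-scale biological variation of block metabolites
#'   (carried by the shared latent factor plus an independent residual).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_group = list(
                               `1` = c(ND_UT = 9, ND_TETA = 6, DM_UT = 9, DM_TETA = 6),
                               `2` = c(ND_UT = 10, ND_TETA = 10, DM_UT = 10, DM_TETA = 10)
                             ),
                             n_metabolites = 150,
                             features_per_metabolite = c(0.5, 0.3, 0.2),
                             n_differential = 30,
                             effect_ratio_range = c(1.5, 5),
                             n_reversal_blocks = 2,
                             block_size = 6,
                             within_block_rho = 0.9,
                             drift_amplitude = 0.2,
                             noise_cv = 0.1,
                             missing_rate = 0.05,
                             bio_sd = 0.3,
                             block_sd = 0.5) {
  cfg <- list(
    n_per_group = n_per_group,
    n_metabolites = as.integer(n_metabolites),
    features_per_metabolite = features_per_metabolite / sum(features_per_metabolite),
    n_differential = as.integer(n_differential),
    effect_ratio_range = effect_ratio_range,
    n_reversal_blocks = as.integer(n_reversal_blocks),
    block_size = as.integer(block_size),
    within_block_rho = within_block_rho,
    drift_amplitude = drift_amplitude,
    noise_cv = noise_cv,
    missing_rate = missing_rate,
    bio_sd = bio_sd,
    block_sd = block_sd
  )
  if (cfg$n_metabolites < 1) mf_stop("n_metabolites must be positive", "mf_config_error")
  if (cfg$n_differential < 0 || cfg$n_differential > cfg$n_metabolites) {
    mf_stop("n_differential must be in [0, n_metabolites]", "mf_config_error")
  }
  if (cfg$n_reversal_blocks * cfg$block_size > cfg$n_metabolites) {
    mf_stop("block_size x n_reversal_blocks exceeds n_metabolites", "mf_config_error")
  }
  if (cfg$n_reversal_blocks > 0 &&
      (cfg$within_block_rho <= 0.5 || cfg$within_block_rho > 1)) {
    mf_stop("within_block_rho must lie in (0.5, 1]", "mf_config_error")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.5) {
    mf_stop("missing_rate must lie in [0, 0.5]", "mf_config_error")
  }
  if (any(unlist(n_per_group) < 1)) {
    mf_stop("all group sizes must be positive", "mf_config_error")
  }
  if (length(cfg$effect_ratio_range) != 2 || cfg$effect_ratio_range[1] < 1 ||
      diff(cfg$effect_ratio_range) < 0) {
    mf_stop("effect_ratio_range must be an increasing interval with lower bound >= 1",
            "mf_config_error")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Pooled-QC injection schedule
#'
#' The run opens with ten QC injections (column conditioning), a QC then
#' occupies every fifth injection while biological samples fill the
#' remaining slots, and the run closes with two consecutive QC injections.
#'
#' @param n_biological number of biological samples to schedule (>= 1).
#' @return data.frame with columns `slot` (1-based injection order) and
#'   `is_qc`.
#' @export
make_injection_sequence <- function(n_biological) {
  if (n_biological < 1) {
    mf_stop("n_biological must be >= 1", "mf_input_error")
  }
  is_qc <- rep(TRUE, 10)
  remaining <- n_biological
  pos <- 11L
  while (remaining > 0) {
    qc <- (pos %% 5L) == 0L
    is_qc <- c(is_qc, qc)
    if (!qc) remaining <- remaining - 1
    pos <- pos + 1L
  }
  is_qc <- c(is_qc, TRUE, TRUE)
  data.frame(slot = seq_along(is_qc), is_qc = is_qc)
}

# Smooth per-feature drift curve: random cubic in the normalised injection
# index, rescaled so the maximum fractional deviation equals the configured
# amplitude. Smoothness is the only property the loess correction assumes.
random_drift_curve <- function(n_injections, amplitude) {
  t <- seq(0, 1, length.out = n_injections)
  co <- stats::runif(3, -1, 1)
  p <- co[1] * t + co[2] * t^2 + co[3] * t^3
  if (max(abs(p)) < .Machine$double.eps || amplitude == 0) {
    return(rep(1, n_injections))
  }
  1 + amplitude * p / max(abs(p))
}

# Positive-mode adduct m/z offsets used to give sibling features distinct
# masses; negative-mode counterparts for completeness.
ADDUCT_OFFSETS <- list(
  positive = c("[M+H]+" = 1.007276, "[M+Na]+" = 22.989218, "[M+NH4]+" = 18.033823),
  negative = c("[M-H]-" = -1.007276, "[M+HCOO]-" = 44.998201)
)

# Draw the biological truth shared by replication studies: metabolite
# masses, retention times, baselines, the differential set with its
# fold-changes, the reversal blocks, and the feature layout (adduct
# redundancy and response factors). Called inside with_seed().
draw_metabolome <- function(cfg, ion_mode) {
  M <- cfg$n_metabolites

  masses <- stats::runif(M, 100, 900)
  rts <- stats::runif(M, 60, 900)
  baseline <- stats::rlnorm(M, meanlog = log(1e5), sdlog = 1)

  block_ids <- list()
  block_members <- integer(0)
  if (cfg$n_reversal_blocks > 0) {
    pool <- sample.int(M, cfg$n_reversal_blocks * cfg$block_size)
    block_ids <- split(pool, rep(seq_len(cfg$n_reversal_blocks), each = cfg$block_size))
    block_members <- pool
  }

  diff_pool <- setdiff(seq_len(M), block_members)
  if (length(diff_pool) < cfg$n_differential) diff_pool <- seq_len(M)
  diff_mets <- sort(sample(diff_pool, cfg$n_differential))
  fold <- stats::runif(cfg$n_differential, cfg$effect_ratio_range[1],
                       cfg$effect_ratio_range[2])
  flip <- sample(c(TRUE, FALSE), cfg$n_differential, replace = TRUE)
  fold[flip] <- 1 / fold[flip]
  effect <- rep(1, M)
  effect[diff_mets] <- fold

  adducts <- ADDUCT_OFFSETS[[ion_mode]]
  k <- sample(1:3, M, replace = TRUE, prob = cfg$features_per_metabolite)
  k <- pmin(k, length(adducts))  # a mode can only emit as many adducts as it has
  feat_met <- rep(seq_len(M), k)
  F <- length(feat_met)
  adduct_idx <- unlist(lapply(k, seq_len))        # which adduct each feature is
  features <- data.frame(
    feature_id = sprintf("M%03d_F%d", feat_met, adduct_idx),
    mz = masses[feat_met] + adducts[adduct_idx],
    rt = pmax(0, rts[feat_met] + stats::runif(F, -1, 1)),
    ion_mode = ion_mode,
    stringsAsFactors = FALSE
  )
  # Adduct response factors: the primary adduct carries the full signal,
  # siblings a proportional fraction.
  response <- ifelse(adduct_idx == 1, 1, stats::runif(F, 0.3, 1))

  list(masses = masses, rts = rts, baseline = baseline,
       block_ids = block_ids, diff_mets = diff_mets, fold = fold,
       effect = effect, feat_met = feat_met, features = features,
       response = response, ion_mode = ion_mode)
}

#' Generate one synthetic study
#'
#' @param config a [synthetic_config()].
#' @param study_id `1` or `2` (selects the per-group sample sizes).
#' @param seed integer seed; the same (config, study_id, seed) always
#'   produces bit-identical output.
#' @param ion_mode ion mode label stamped on the run.
#' @param metabolome shared biological truth, as drawn internally (and
#'   reused across studies) by [generate_two_studies()]; the default
#'   derives one deterministically from `seed`.
#' @return list with elements `table` (a [feature_table()]) and `truth`
#'   (a `ground_truth` list: `differential` data.frame, `blocks` list of
#'   metabolite-id vectors, `reversal_pairs` data.frame of feature pairs,
#'   `feature_to_metabolite` named vector, `drift` matrix, `censor_threshold`).
#' @export
generate_study <- function(config, study_id = 1, seed = 1, ion_mode = "positive",
                           metabolome = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  sid <- as.character(study_id)
  if (!sid %in% names(config$n_per_group)) {
    mf_stop(sprintf("no group sizes configured for study '%s'", sid), "mf_config_error")
  }
  npg <- config$n_per_group[[sid]]
  if (!setequal(names(npg), BIO_GROUPS)) {
    mf_stop("n_per_group entries must be named by the four biological groups",
            "mf_config_error")
  }
  if (is.null(metabolome)) {
    metabolome <- with_seed(derive_seed(seed, 7777), draw_metabolome(config, ion_mode))
  }
  with_seed(seed, generate_study_impl(config, metabolome, as.integer(study_id),
                                      npg, ion_mode))
}

generate_study_impl <- function(cfg, met, study_id, npg, ion_mode) {
  n_bio <- sum(npg)
  sigma_n <- sqrt(log(1 + cfg$noise_cv^2))
  M <- cfg$n_metabolites
  block_ids <- met$block_ids

  # --- sample layout ----------------------------------------------------
  groups <- rep(names(npg), npg)
  groups <- sample(groups)  # randomised acquisition order
  seq_df <- make_injection_sequence(n_bio)
  n_inj <- nrow(seq_df)
  qc_slots <- seq_df$slot[seq_df$is_qc]
  bio_slots <- seq_df$slot[!seq_df$is_qc]

  grp_counter <- stats::setNames(integer(length(BIO_GROUPS)), BIO_GROUPS)
  bio_names <- character(n_bio)
  for (i in seq_len(n_bio)) {
    g <- groups[i]
    grp_counter[g] <- grp_counter[g] + 1L
    bio_names[i] <- sprintf("S%d_%s_%02d", study_id, g, grp_counter[g])
  }
  manifest <- data.frame(
    sample_id = character(n_inj), study_id = study_id,
    group = character(n_inj), injection_order = seq_len(n_inj),
    ion_mode = ion_mode, stringsAsFactors = FALSE
  )
  manifest$sample_id[qc_slots] <- sprintf("S%d_QC_%02d", study_id, seq_along(qc_slots))
  manifest$group[qc_slots] <- "QC"
  manifest$sample_id[bio_slots] <- bio_names
  manifest$group[bio_slots] <- groups

  # --- metabolite log-abundances per biological sample ------------------
  # Latent Pearson correlation needed so the observable feature-level rank
  # correlation hits the target despite measurement noise:
  # rank -> Pearson via 2*sin(pi*rho/6), then de-attenuation.
  restored <- c("ND_UT", "ND_TETA", "DM_TETA")
  rho_latent <- 0
  if (cfg$n_reversal_blocks > 0) {
    rho_p <- 2 * sin(pi * cfg$within_block_rho / 6)
    rho_latent <- min(0.999, rho_p * (cfg$block_sd^2 + sigma_n^2) / cfg$block_sd^2)
  }

  logA <- matrix(0, nrow = M, ncol = n_bio)  # deviation from baseline
  in_block <- rep(FALSE, M)
  for (b in block_ids) in_block[b] <- TRUE
  logA[!in_block, ] <- stats::rnorm(sum(!in_block) * n_bio, sd = cfg$bio_sd)
  for (b in block_ids) {
    z <- stats::rnorm(n_bio)               # shared latent factor per sample
    for (j in b) {
      e <- stats::rnorm(n_bio)
      corr_part <- sqrt(rho_latent) * z + sqrt(1 - rho_latent) * e
      indep_part <- stats::rnorm(n_bio)
      use_latent <- groups %in% restored
      logA[j, ] <- cfg$block_sd * ifelse(use_latent, corr_part, indep_part)
    }
  }
  dm <- groups %in% c("DM_UT", "DM_TETA")
  abund <- met$baseline * exp(logA)        # M x n_bio
  abund[, dm] <- abund[, dm] * met$effect

  feat_met <- met$feat_met
  features <- met$features
  response <- met$response
  F <- length(feat_met)

  # --- intensity matrix over all injections -----------------------------
  drift <- t(vapply(seq_len(F), function(i) {
    random_drift_curve(n_inj, cfg$drift_amplitude)
  }, numeric(n_inj)))

  signal_bio <- abund[feat_met, , drop = FALSE] * response   # F x n_bio
  qc_signal <- rowMeans(signal_bio)                          # pooled sample

  intens <- matrix(NA_real_, nrow = F, ncol = n_inj)
  intens[, bio_slots] <- signal_bio
  intens[, qc_slots] <- qc_signal
  noise <- matrix(stats::rlnorm(F * n_inj, meanlog = -sigma_n^2 / 2, sdlog = sigma_n),
                  nrow = F)
  intens <- intens * drift * noise

  censor <- if (cfg$missing_rate > 0) {
    stats::quantile(intens, probs = cfg$missing_rate, na.rm = TRUE)
  } else {
    -Inf
  }
  intens[intens < censor] <- NA_real_

  colnames(intens) <- manifest$sample_id
  rownames(intens) <- features$feature_id
  rownames(drift) <- features$feature_id

  ft <- feature_table(features, intens, manifest)

  f2m <- stats::setNames(sprintf("MET%03d", feat_met), features$feature_id)
  block_met_ids <- lapply(block_ids, function(b) sprintf("MET%03d", sort(b)))

  reversal_pairs <- do.call(rbind, lapply(block_ids, function(b) {
    fids <- features$feature_id[feat_met %in% b]
    mets <- f2m[fids]
    cmb <- utils::combn(seq_along(fids), 2)
    keep <- mets[cmb[1, ]] != mets[cmb[2, ]]
    data.frame(feature_a = fids[cmb[1, keep]], feature_b = fids[cmb[2, keep]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(reversal_pairs)) {
    reversal_pairs <- data.frame(feature_a = character(0), feature_b = character(0))
  }

  truth <- structure(list(
    differential = data.frame(
      metabolite_id = sprintf("MET%03d", met$diff_mets),
      fold = met$fold,
      direction = ifelse(met$fold > 1, "up", "down"),
      stringsAsFactors = FALSE
    ),
    blocks = block_met_ids,
    reversal_pairs = reversal_pairs,
    feature_to_metabolite = f2m,
    drift = drift,
    censor_threshold = censor
  ), class = "ground_truth")

  list(table = ft, truth = truth)
}

#' Generate the two replication studies
#'
#' The biological truth (metabolome, feature layout, differential set,
#' reversal blocks) is drawn once and shared; the two studies then sample
#' it with independent animals, acquisition orders, drift, noise and
#' censoring, and with their own per-group sample sizes — mirroring a
#' discovery/validation replication design over one biology.
#'
#' @inheritParams generate_study
#' @return named list `study1`, `study2`, each as returned by
#'   [generate_study()].
#' @export
generate_two_studies <- function(config = synthetic_config(), seed = 1,
                                 ion_mode = "positive") {
  met <- with_seed(derive_seed(seed, 7777), draw_metabolome(config, ion_mode))
  list(
    study1 = generate_study(config, 1, derive_seed(seed, 1), ion_mode,
                            metabolome = met),
    study2 = generate_study(config, 2, derive_seed(seed, 2), ion_mode,
                            metabolome = met)
  )
}
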