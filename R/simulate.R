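#' Simulate latent (pre-measurement) abundances and sample metadata
#'
#' Draws each subject's true metabolite abundances: log2 abundance is
#' `N(mu_f, bio_log_sd^2)` around a feature-specific mean, plus every planted
#' effect whose contrast covers the subject's group, scaled by its stage
#' multiplier. Group and stage counts match the config exactly
#' (largest-remainder apportionment of the stage fractions). Deterministic
#' given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `latent` (named list of samples x features matrices, one
#'   per platform, strictly positive, no missing), `metadata` (data.frame with
#'   sample_id, group, stage, age, sex, batch), and `baseline_log2` (the
#'   feature mean log2 abundances, used as the QC reference profile).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, "simulate_truth"), {
    groups <- names(config$n_per_group)
    n_total <- sum(config$n_per_group)
    group <- rep(groups, times = config$n_per_group)
    sample_id <- sprintf("S%04d", seq_len(n_total))

    stage <- rep("not-applicable", n_total)
    for (g in c("LC", "GC", "CRC")) {
      idx <- which(group == g)
      counts <- apportion(length(idx), config$stage_fractions)
      stage[idx] <- rep(names(config$stage_fractions), times = counts)
    }

    # age/sex distributions loosely matching a cancer-enriched case-control mix
    age <- numeric(n_total)
    sex <- character(n_total)
    for (g in groups) {
      idx <- which(group == g)
      pars <- switch(g,
                     LC = , GC = , CRC = list(mu = 62, sd = 12, lo = 21, hi = 93, p_male = 0.65),
                     NCD = list(mu = 55, sd = 13, lo = 18, hi = 88, p_male = 0.59),
                     HC  = list(mu = 48, sd = 10, lo = 18, hi = 67, p_male = 0.465))
      age[idx] <- pmin(pars$hi, pmax(pars$lo, round(stats::rnorm(length(idx), pars$mu, pars$sd))))
      sex[idx] <- ifelse(stats::runif(length(idx)) < pars$p_male, "M", "F")
    }
    batch <- as.character(sample(rep_len(seq_len(config$n_batches), n_total)))

    metadata <- data.frame(sample_id = sample_id, group = group, stage = stage,
                           age = age, sex = sex, batch = batch,
                           stringsAsFactors = FALSE)

    feat_ids <- platform_feature_ids(config$platform_sizes)
    baseline <- lapply(feat_ids, function(f) {
      stats::setNames(stats::runif(length(f), config$baseline_log2_range[1],
                                   config$baseline_log2_range[2]), f)
    })
    # Planted markers get lower-mid baselines (30th-50th percentile of the
    # range): disease markers are minor contributors to the total urinary
    # signal -- the premise that makes total-signal (MSTUS) normalization track
    # dilution rather than pathology (in real data bulk compounds such as urea
    # and creatinine sit orders of magnitude above any marker) -- yet abundant
    # enough to sit clear of the low-intensity censoring zone.
    planted_ids <- vapply(config$planted, `[[`, "", "feature_id")
    if (length(planted_ids)) {
      lo <- config$baseline_log2_range[1]
      span <- diff(config$baseline_log2_range)
      for (p in names(baseline)) {
        hit <- names(baseline[[p]]) %in% planted_ids
        if (any(hit)) {
          baseline[[p]][hit] <- lo + span * stats::runif(sum(hit), 0.30, 0.50)
        }
      }
    }

    # planted log2 shift per sample x feature, indexed by platform
    shift <- lapply(feat_ids, function(f) {
      matrix(0, n_total, length(f), dimnames = list(sample_id, f))
    })
    for (eff in config$planted) {
      plat <- names(Filter(function(f) eff$feature_id %in% f, feat_ids))
      in_contrast <- metadata$group %in% eff$contrast
      mult <- ifelse(metadata$stage == "not-applicable", 1,
                     eff$stage_multipliers[metadata$stage])
      delta <- ifelse(in_contrast, eff$direction * eff$base_log2_effect * mult, 0)
      shift[[plat]][, eff$feature_id] <- shift[[plat]][, eff$feature_id] + delta
    }

    latent <- lapply(names(feat_ids), function(p) {
      f <- feat_ids[[p]]
      log2x <- matrix(rep(baseline[[p]], each = n_total), n_total, length(f),
                      dimnames = list(sample_id, f)) +
        matrix(stats::rnorm(n_total * length(f), 0, config$bio_log_sd),
               n_total, length(f)) +
        shift[[p]]
      2^log2x
    })
    names(latent) <- names(feat_ids)
    list(latent = latent, metadata = metadata, baseline_log2 = baseline)
  })
}

#' Apply measurement structure: dilution, batch effects, noise, QC, missingness
#'
#' Each subject sample is multiplied by one urine-dilution factor
#' `exp(N(0, dilution_log_sd^2))` shared across all its features and
#' platforms; each (batch, feature) pair carries a multiplicative shift
#' `exp(N(0, batch_log_sd^2))`; every cell gets log-normal measurement noise.
#' QC rows are generated per batch from the fixed reference profile
#' (`2^baseline_log2`) plus that batch's effect and noise — no dilution and no
#' group effects, which is what makes QC-anchored batch correction
#' identifiable. Cells are then censored to missing with probability
#' `mcar_prob` plus an intensity-dependent component rising to `mnar_max_prob`
#' at the lowest intensities.
#'
#' @param truth output of [simulate_truth()].
#' @param config the same [cohort_config()].
#' @return list with `matrices` (named list of [feature_matrix()]), `metadata`
#'   (subject rows), and a `truth` record (`latent`, `dilution` factors,
#'   per-platform `batch_effects` matrices, `planted` feature table) kept for
#'   test oracles.
#' @export
corrupt_cohort <- function(truth, config) {
  with_seed(derive_seed(config$seed, "corrupt"), {
    meta <- truth$metadata
    n_sub <- nrow(meta)
    dilution <- stats::setNames(exp(stats::rnorm(n_sub, 0, config$dilution_log_sd)),
                                meta$sample_id)
    batches <- sort(unique(meta$batch))
    ms <- config$missingness

    matrices <- list()
    batch_effects <- list()
    for (p in names(truth$latent)) {
      lat <- truth$latent[[p]]
      stopifnot(all(lat > 0))
      nf <- ncol(lat)
      bfx <- matrix(exp(stats::rnorm(length(batches) * nf, 0, config$batch_log_sd)),
                    length(batches), nf, dimnames = list(batches, colnames(lat)))
      obs <- lat * dilution[rownames(lat)] * bfx[meta$batch, , drop = FALSE] *
        exp(matrix(stats::rnorm(n_sub * nf, 0, config$noise_log_sd), n_sub, nf))

      # QC rows: one shared reference profile + batch effect + noise
      qc_rows <- NULL
      qc_batch <- character(0)
      if (config$qc_per_batch > 0) {
        ref <- 2^truth$baseline_log2[[p]]
        qc_batch <- rep(batches, each = config$qc_per_batch)
        qc_rows <- matrix(rep(ref, each = length(qc_batch)), length(qc_batch), nf,
                          dimnames = list(NULL, colnames(lat))) *
          bfx[qc_batch, , drop = FALSE] *
          exp(matrix(stats::rnorm(length(qc_batch) * nf, 0, config$noise_log_sd),
                     length(qc_batch), nf))
        rownames(qc_rows) <- sprintf("QC_%s_B%s_%d", p, qc_batch,
                                     sequence(rep(config$qc_per_batch, length(batches))))
      }
      full <- rbind(obs, qc_rows)
      batch_vec <- c(meta$batch, qc_batch)
      is_qc <- c(rep(FALSE, n_sub), rep(TRUE, length(qc_batch)))

      # censoring: MCAR + linear MNAR ramp below the pooled intensity quantile
      logx <- log(full)
      q_thr <- stats::quantile(logx, ms$mnar_intensity_quantile, names = FALSE)
      lo <- min(logx)
      p_mnar <- if (q_thr > lo) {
        pmax(0, pmin(1, (q_thr - logx) / (q_thr - lo))) * ms$mnar_max_prob
      } else matrix(0, nrow(full), nf)
      p_miss <- pmin(1, ms$mcar_prob + p_mnar)
      drop_mask <- matrix(stats::runif(length(full)) < p_miss, nrow(full), nf)
      full[drop_mask] <- NA_real_

      matrices[[p]] <- feature_matrix(p, full, batch_vec, is_qc)
      batch_effects[[p]] <- bfx
    }

    planted <- if (length(config$planted)) {
      data.frame(
        feature_id = vapply(config$planted, `[[`, "", "feature_id"),
        contrast = vapply(config$planted, function(e) paste(e$contrast, collapse = "+"), ""),
        base_log2_effect = vapply(config$planted, `[[`, 0, "base_log2_effect"),
        direction = vapply(config$planted, `[[`, 0, "direction"),
        stringsAsFactors = FALSE)
    } else {
      data.frame(feature_id = character(0), contrast = character(0),
                 base_log2_effect = numeric(0), direction = numeric(0))
    }

    list(matrices = matrices, metadata = meta,
         truth = list(latent = truth$latent, dilution = dilution,
                      batch_effects = batch_effects, planted = planted,
                      baseline_log2 = truth$baseline_log2))
  })
}

#' Generate a complete synthetic cohort
#'
#' Composes [simulate_truth()] and [corrupt_cohort()], then assigns subjects
#' to discovery/validation cohorts at `config$split_ratio`, stratified by
#' clinical group (per-group discovery counts are `round(n * ratio)`).
#' Identical config + seed gives bit-identical output.
#'
#' @param config a [cohort_config()].
#' @return list with `matrices` (per-platform [feature_matrix()]), `metadata`
#'   (including a `cohort` column), and `truth` (planted features, dilution
#'   factors, batch effects, latent matrices).
#' @export
generate_cohort <- function(config) {
  out <- corrupt_cohort(simulate_truth(config), config)
  with_seed(derive_seed(config$seed, "cohort_split"), {
    meta <- out$metadata
    meta$cohort <- "validation"
    for (g in unique(meta$group)) {
      idx <- which(meta$group == g)
      n_disc <- round(length(idx) * config$split_ratio)
      meta$cohort[sample(idx, n_disc)] <- "discovery"
    }
    out$metadata <- meta
  })
  out$config <- config
  out
}

#' Write a generated cohort to a directory
#'
#' Per-platform feature tables and the metadata as TSV; the truth record
#' (planted features, dilution factors, batch effects) as JSON.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(cohort$matrices)) {
    write_feature_table(cohort$matrices[[p]], file.path(dir, paste0(p, ".tsv")))
  }
  write_sample_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(planted = truth$planted,
         dilution = as.list(truth$dilution),
         batch_effects = lapply(truth$batch_effects, function(m) {
           stats::setNames(as.data.frame(m), colnames(m))
         }),
         seed = cohort$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
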