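#' Preprocessing configuration
#'
#' Controls the fixed five-stage chain: detection filter, batchwise
#' conditional imputation, MSTUS normalization, QC-anchored batch correction,
#' log transform + scaling.
#'
#' @param min_detection_fraction keep a feature only if observed in at least
#'   this fraction of subject samples (strictly-less is discarded).
#' @param impute_missing_rate_threshold within a batch, features with missing
#'   rate at or below this AND high mean intensity go to the iterative
#'   (chained-model) imputer; all others with missing go to half-minimum.
#' @param impute_intensity_quantile_threshold "high mean intensity" means
#'   above this quantile of the batch's per-feature mean observed intensities.
#' @param impute_rounds rounds of chained conditional-mean updates.
#' @param impute_predictors number of most-correlated predictor features per
#'   imputed feature.
#' @param scaling_mode `"unit-variance"` (autoscaling, default), `"pareto"`,
#'   or `"none"` (log transform only).
#' @param log_base base of the log transform (> 1).
#' @param batch_correction_mode `"qc-median"` or `"none"`.
#' @param seed RNG seed for any stochastic step.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(min_detection_fraction = 0.80,
                              impute_missing_rate_threshold = 0.30,
                              impute_intensity_quantile_threshold = 0.25,
                              impute_rounds = 3L,
                              impute_predictors = 5L,
                              scaling_mode = c("unit-variance", "pareto", "none"),
                              log_base = 2,
                              batch_correction_mode = c("qc-median", "none"),
                              seed = 1L) {
  scaling_mode <- match.arg(scaling_mode)
  batch_correction_mode <- match.arg(batch_correction_mode)
  stopifnot(min_detection_fraction > 0, min_detection_fraction <= 1,
            impute_missing_rate_threshold > 0, impute_missing_rate_threshold < 1,
            impute_intensity_quantile_threshold > 0, impute_intensity_quantile_threshold < 1,
            log_base > 1)
  structure(list(min_detection_fraction = min_detection_fraction,
                 impute_missing_rate_threshold = impute_missing_rate_threshold,
                 impute_intensity_quantile_threshold = impute_intensity_quantile_threshold,
                 impute_rounds = as.integer(impute_rounds),
                 impute_predictors = as.integer(impute_predictors),
                 scaling_mode = scaling_mode, log_base = log_base,
                 batch_correction_mode = batch_correction_mode,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Detection-rate feature filter
#'
#' Discards metabolic features detected in less than `min_detection_fraction`
#' of the subject (non-QC) samples: a feature observed in exactly the
#' threshold fraction is kept, one observed in any smaller fraction is
#' dropped. Column order of survivors is preserved.
#'
#' @param fm a [feature_matrix()].
#' @param min_detection_fraction detection threshold in (0, 1].
#' @return list with `matrix` (filtered [feature_matrix()]) and `dropped`
#'   (character vector of discarded feature ids).
#' @export
filter_features <- function(fm, min_detection_fraction = 0.80) {
  subj <- subject_matrix(fm)
  det <- colMeans(!is.na(subj))
  keep <- det >= min_detection_fraction
  if (!any(keep)) stop("all features dropped by the detection filter (platform ",
                       fm$platform, ")")
  out <- fm
  out$intensities <- fm$intensities[, keep, drop = FALSE]
  list(matrix = out, dropped = colnames(subj)[!keep])
}

#' Batchwise conditional imputation
#'
#' Missing values are filled batch by batch, subject and QC samples
#' separately. Within a batch, a feature with low missing rate
#' (<= `impute_missing_rate_threshold`) and high mean observed intensity
#' (above the `impute_intensity_quantile_threshold` quantile of the batch's
#' per-feature means) is imputed by iterative chained conditional-mean models
#' (each incomplete feature regressed on its most-correlated complete-initialized
#' neighbours on the log scale, repeated for `impute_rounds` rounds);
#' any other feature with missing cells gets half its minimum observed value
#' in that batch. A feature entirely missing within a batch falls back to
#' half its global minimum and is flagged in the routes. Observed cells are
#' never altered; the output has no missing cells; the procedure is
#' deterministic.
#'
#' @param fm a [feature_matrix()].
#' @param config a [preprocess_config()].
#' @return list with `matrix` (complete [feature_matrix()]) and `routes`
#'   (data.frame: batch, feature_id, route in
#'   \{iterative, half-minimum, half-minimum-global, none\}).
#' @export
impute_features <- function(fm, config = preprocess_config()) {
  x <- fm$intensities
  routes <- list()
  global_min <- suppressWarnings(apply(x, 2, min, na.rm = TRUE))
  global_min[!is.finite(global_min)] <- NA_real_

  for (qc_part in c(FALSE, TRUE)) {
    rows_part <- which(fm$is_qc == qc_part)
    if (!length(rows_part)) next
    for (b in unique(fm$batch[rows_part])) {
      rows <- rows_part[fm$batch[rows_part] == b]
      sub <- x[rows, , drop = FALSE]
      miss_rate <- colMeans(is.na(sub))
      if (all(miss_rate == 0)) {
        routes[[length(routes) + 1L]] <- data.frame(
          batch = b, is_qc = qc_part, feature_id = colnames(sub),
          route = "none", stringsAsFactors = FALSE)
        next
      }
      mean_int <- suppressWarnings(colMeans(sub, na.rm = TRUE))
      int_cut <- stats::quantile(mean_int[is.finite(mean_int)],
                                 config$impute_intensity_quantile_threshold,
                                 names = FALSE)
      route <- rep("none", ncol(sub))
      incomplete <- miss_rate > 0
      all_missing <- miss_rate == 1
      iterative <- incomplete & !all_missing &
        miss_rate <= config$impute_missing_rate_threshold &
        is.finite(mean_int) & mean_int > int_cut
      halfmin <- incomplete & !all_missing & !iterative
      route[iterative] <- "iterative"
      route[halfmin] <- "half-minimum"
      route[all_missing] <- "half-minimum-global"

      if (any(halfmin)) {
        for (j in which(halfmin)) {
          sub[is.na(sub[, j]), j] <- min(sub[, j], na.rm = TRUE) / 2
        }
      }
      if (any(all_missing)) {
        warning("feature(s) entirely missing in batch ", b, ": ",
                paste(colnames(sub)[all_missing], collapse = ", "),
                "; imputed with half the global minimum")
        for (j in which(all_missing)) {
          fill <- if (is.na(global_min[j])) 1 else global_min[j] / 2
          sub[, j] <- fill
        }
      }
      if (any(iterative)) {
        sub <- chained_impute(sub, which(iterative),
                              rounds = config$impute_rounds,
                              k = config$impute_predictors)
      }
      x[rows, ] <- sub
      routes[[length(routes) + 1L]] <- data.frame(
        batch = b, is_qc = qc_part, feature_id = colnames(sub),
        route = route, stringsAsFactors = FALSE)
    }
  }
  out <- fm
  out$intensities <- x
  list(matrix = out, routes = do.call(rbind, routes))
}

# Chained conditional-mean imputation on the log2 scale. `cols` indexes the
# features to impute iteratively; all other columns are already complete.
# Deterministic: no posterior draws, plain least-squares predictions.
chained_impute <- function(sub, cols, rounds = 3L, k = 5L) {
  lx <- log2(sub)
  na_mask <- is.na(lx)
  # initialize with observed feature means
  for (j in cols) lx[na_mask[, j], j] <- mean(lx[, j], na.rm = TRUE)
  if (nrow(lx) >= 4L && ncol(lx) >= 2L) {
    cors <- suppressWarnings(stats::cor(lx))
    cors[!is.finite(cors)] <- 0
    for (r in seq_len(rounds)) {
      for (j in cols) {
        miss <- na_mask[, j]
        obs <- !miss
        if (sum(obs) < 3L) next
        pred <- order(abs(cors[, j]), decreasing = TRUE)
        pred <- setdiff(pred, j)[seq_len(min(k, ncol(lx) - 1L))]
        X <- cbind(1, lx[, pred, drop = FALSE])
        fit <- tryCatch(qr.solve(X[obs, , drop = FALSE], lx[obs, j]),
                        error = function(e) NULL)
        if (is.null(fit)) next
        lx[miss, j] <- X[miss, , drop = FALSE] %*% fit
      }
    }
  }
  out <- 2^lx
  out[!na_mask] <- sub[!na_mask]  # observed cells untouched, bit-exactly
  out
}

#' MSTUS normalization
#'
#' Divides each sample's intensities by that sample's total useful MS signal:
#' the sum over the "useful" feature set, defined as the features observed
#' (pre-imputation) in every subject sample of the platform — the signals
#' shared by all samples. If that set is empty the denominator falls back to
#' the sum over all retained features. Removes per-sample urine dilution
#' exactly: rescaling any sample by c > 0 leaves its normalized profile
#' unchanged.
#'
#' @param fm a complete [feature_matrix()] (run after [impute_features()]).
#' @param useful_features optional character vector overriding the useful set
#'   (e.g. computed on the pre-imputation mask).
#' @return list with `matrix` (normalized), `denominators` (named per-sample
#'   totals) and `useful_features`.
#' @export
mstus_normalize <- function(fm, useful_features = NULL) {
  x <- fm$intensities
  if (anyNA(x)) stop("mstus_normalize requires a complete matrix; impute first")
  if (is.null(useful_features)) useful_features <- colnames(x)
  useful_features <- intersect(colnames(x), useful_features)
  if (!length(useful_features)) useful_features <- colnames(x)
  denom <- rowSums(x[, useful_features, drop = FALSE])
  if (any(denom <= 0)) {
    stop("nonpositive MSTUS denominator for sample(s): ",
         paste(rownames(x)[denom <= 0], collapse = ", "))
  }
  out <- fm
  out$intensities <- x / denom
  list(matrix = out, denominators = stats::setNames(denom, rownames(x)),
       useful_features = useful_features)
}

#' QC-anchored batch correction
#'
#' In log space, shifts each feature within each batch so that the batch's QC
#' median matches the grand QC median for that feature; subject and QC rows in
#' the batch are corrected with the same factors. With a single batch the
#' correction is exactly zero.
#'
#' @param fm a complete [feature_matrix()].
#' @param mode `"qc-median"` or `"none"`.
#' @return list with `matrix` (corrected) and `log2_shifts` (batches x
#'   features matrix of applied log2 corrections).
#' @export
qc_batch_correct <- function(fm, mode = c("qc-median", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(list(matrix = fm,
                log2_shifts = matrix(0, 0, ncol(fm$intensities))))
  }
  x <- log2(fm$intensities)
  batches <- sort(unique(fm$batch))
  no_qc <- batches[!batches %in% fm$batch[fm$is_qc]]
  if (length(no_qc)) {
    stop("qc-median correction needs >= 1 QC sample per batch; none in batch(es): ",
         paste(no_qc, collapse = ", "))
  }
  qc_all <- x[fm$is_qc, , drop = FALSE]
  grand <- apply(qc_all, 2, stats::median)
  shifts <- matrix(0, length(batches), ncol(x),
                   dimnames = list(batches, colnames(x)))
  for (b in batches) {
    qc_b <- x[fm$is_qc & fm$batch == b, , drop = FALSE]
    shifts[b, ] <- apply(qc_b, 2, stats::median) - grand
    rows <- fm$batch == b
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2, shifts[b, ], `-`)
  }
  out <- fm
  out$intensities <- 2^x
  list(matrix = out, log2_shifts = shifts)
}

#' Log transform and feature scaling
#'
#' Log transform (base `config$log_base`) followed by per-feature centering
#' and scaling. Scaling parameters are fitted on the discovery-cohort subject
#' samples only and reapplied unchanged to validation and QC rows, so no
#' information leaks from the validation cohort. Modes: `"unit-variance"`
#' (autoscaling: center, divide by SD), `"pareto"` (center, divide by
#' sqrt(SD)), `"none"` (log transform only).
#'
#' @param fm a complete, strictly positive [feature_matrix()].
#' @param config a [preprocess_config()].
#' @param discovery_ids sample ids of the discovery cohort; defaults to all
#'   subject samples.
#' @return list with `matrix` (transformed; values may be negative) and
#'   `scaling` (data.frame of per-feature center/scale used).
#' @export
log_scale <- function(fm, config = preprocess_config(), discovery_ids = NULL) {
  x <- fm$intensities
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("nonpositive intensity at sample ", rownames(x)[bad[1, 1]],
         ", feature ", colnames(x)[bad[1, 2]])
  }
  lx <- log(x, base = config$log_base)
  if (is.null(discovery_ids)) discovery_ids <- rownames(x)[!fm$is_qc]
  fit_rows <- rownames(x) %in% discovery_ids & !fm$is_qc
  if (!any(fit_rows)) stop("no discovery subject samples to fit scaling on")
  if (config$scaling_mode == "none") {
    center <- rep(0, ncol(lx)); scale <- rep(1, ncol(lx))
  } else {
    center <- colMeans(lx[fit_rows, , drop = FALSE])
    sds <- apply(lx[fit_rows, , drop = FALSE], 2, stats::sd)
    sds[sds == 0 | !is.finite(sds)] <- 1
    scale <- switch(config$scaling_mode,
                    "unit-variance" = sds,
                    "pareto" = sqrt(sds))
  }
  lx <- sweep(sweep(lx, 2, center, `-`), 2, scale, `/`)
  out <- fm
  out$intensities <- lx
  list(matrix = out,
       scaling = data.frame(feature_id = colnames(lx), center = center,
                            scale = scale, row.names = NULL,
                            stringsAsFactors = FALSE))
}

#' Full preprocessing chain for one platform
#'
#' Fixed order: detection filter, batchwise conditional imputation, MSTUS
#' normalization (useful set computed on the pre-imputation missing mask),
#' QC-anchored batch correction, log transform + scaling (fitted on
#' discovery). Returns the processed matrix and a report recording every
#' stage. Deterministic given the config seed.
#'
#' @param fm a raw [feature_matrix()].
#' @param config a [preprocess_config()].
#' @param discovery_ids discovery-cohort sample ids for scaling (optional).
#' @return list with `matrix` (processed [feature_matrix()]; QC rows retained,
#'   flagged) and `report` (dropped features, imputation routes, MSTUS
#'   denominators, batch shifts, before/after QC relative SDs, scaling table).
#' @export
preprocess <- function(fm, config = preprocess_config(), discovery_ids = NULL) {
  filt <- filter_features(fm, config$min_detection_fraction)
  # useful set for MSTUS: features with no missing among subject samples
  subj <- subject_matrix(filt$matrix)
  useful <- colnames(subj)[colSums(is.na(subj)) == 0]
  imp <- impute_features(filt$matrix, config)
  qc_rsd_before <- qc_rsd(imp$matrix)
  norm <- mstus_normalize(imp$matrix, useful_features = useful)
  corr <- qc_batch_correct(norm$matrix, config$batch_correction_mode)
  qc_rsd_after <- qc_rsd(corr$matrix)
  scal <- log_scale(corr$matrix, config, discovery_ids)
  list(matrix = scal$matrix,
       report = list(platform = fm$platform,
                     dropped = filt$dropped,
                     imputation_routes = imp$routes,
                     mstus_useful_features = norm$useful_features,
                     mstus_denominators = norm$denominators,
                     batch_log2_shifts = corr$log2_shifts,
                     qc_rsd_before = qc_rsd_before,
                     qc_rsd_after = qc_rsd_after,
                     scaling = scal$scaling))
}

# Per-feature relative SD (CV) across pooled QC rows; NA if < 2 QC samples.
qc_rsd <- function(fm) {
  qc <- fm$intensities[fm$is_qc, , drop = FALSE]
  if (nrow(qc) < 2L) return(rep(NA_real_, ncol(qc)))
  apply(qc, 2, function(v) stats::sd(v) / mean(v))
}

#' Preprocess all platforms and assemble the modeling matrix
#'
#' Runs [preprocess()] per platform, then column-binds the subject rows of all
#' platforms into one samples x features matrix (feature ids are unique across
#' platforms), aligned to the metadata order.
#'
#' @param matrices named list of [feature_matrix()] (one per platform).
#' @param metadata sample metadata with `sample_id` and `cohort` columns.
#' @param config a [preprocess_config()].
#' @return list with `X` (combined numeric matrix, subject rows only),
#'   `platform_of` (named platform per feature), `reports` (per platform) and
#'   `processed` (per-platform processed matrices incl. QC rows).
#' @export
preprocess_cohort <- function(matrices, metadata, config = preprocess_config()) {
  discovery_ids <- metadata$sample_id[metadata$cohort == "discovery"]
  processed <- lapply(matrices, preprocess, config = config,
                      discovery_ids = discovery_ids)
  subj_mats <- lapply(processed, function(p) subject_matrix(p$matrix))
  ids <- rownames(subj_mats[[1]])
  for (m in subj_mats) {
    if (!identical(rownames(m), ids)) stop("platforms disagree on subject sample order")
  }
  X <- do.call(cbind, subj_mats)
  X <- X[metadata$sample_id, , drop = FALSE]
  platform_of <- unlist(lapply(names(subj_mats), function(p) {
    stats::setNames(rep(p, ncol(subj_mats[[p]])), colnames(subj_mats[[p]]))
  }))
  list(X = X, platform_of = platform_of,
       reports = lapply(processed, `[[`, "report"),
       processed = lapply(processed, `[[`, "matrix"))
}
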