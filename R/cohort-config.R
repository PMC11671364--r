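#' Cohort simulation configuration
#'
#' Defines a synthetic multi-platform urinary-metabolomics cohort: clinical
#' group sizes, tumor-stage mix, per-platform feature counts, batch layout,
#' dilution/batch/noise magnitudes, planted group effects and missingness.
#' Defaults mirror a large five-group case-control study (three cancer groups
#' LC/GC/CRC, benign-disease controls NCD, healthy controls HC) profiled on
#' three MS platforms with 125, 13 and 222 annotated metabolites.
#'
#' Scales: baseline log2 abundances have feature means drawn uniformly on
#' `baseline_log2_range` and between-subject SD `bio_log_sd` (log2 units);
#' planted effects are log2 fold changes. Dilution, batch and measurement
#' noise are multiplicative factors `exp(N(0, sd^2))` (natural-log SDs), the
#' dilution factor being shared by all features and platforms of a sample.
#'
#' @param n_per_group named integer vector of subject counts for groups
#'   `LC`, `GC`, `CRC`, `NCD`, `HC`.
#' @param stage_fractions named proportions over stages `I`,`II`,`III`,`IV`,
#'   `unknown` (cancer groups only); must sum to 1.
#' @param platform_sizes named feature counts per platform.
#' @param n_batches number of acquisition batches (>= 1).
#' @param qc_per_batch pooled-reference QC injections per batch (>= 0).
#' @param dilution_log_sd per-sample urine dilution SD (natural log scale).
#' @param batch_log_sd per-batch, per-feature multiplicative shift SD.
#' @param noise_log_sd per-cell measurement noise SD.
#' @param bio_log_sd between-subject biological SD of log2 abundance.
#' @param baseline_log2_range range for feature mean log2 abundances.
#' @param planted list of [effect_spec()] entries; `default_effect_specs()`
#'   plants 18 pan-cancer, 17 LC-vs-non-LC and 21 GC-vs-CRC markers.
#' @param missingness a [missingness_spec()].
#' @param split_ratio fraction of subjects assigned to the discovery cohort
#'   (stratified by group).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(LC = 548, GC = 177, CRC = 186, NCD = 563, HC = 229),
                          stage_fractions = c(I = 0.300, II = 0.112, III = 0.172,
                                              IV = 0.150, unknown = 0.266),
                          platform_sizes = c(polar = 125, lipid = 13, GC = 222),
                          n_batches = 4,
                          qc_per_batch = 3,
                          dilution_log_sd = 0.5,
                          batch_log_sd = 0.2,
                          noise_log_sd = 0.1,
                          bio_log_sd = 1.0,
                          baseline_log2_range = c(10, 20),
                          planted = default_effect_specs(platform_sizes),
                          missingness = missingness_spec(),
                          split_ratio = 0.77,
                          seed = 1L) {
  groups <- c("LC", "GC", "CRC", "NCD", "HC")
  stages <- c("I", "II", "III", "IV", "unknown")
  stopifnot(setequal(names(n_per_group), groups),
            setequal(names(stage_fractions), stages))
  n_per_group <- n_per_group[groups]
  stage_fractions <- stage_fractions[stages]
  if (any(n_per_group < 0) || n_batches < 1 || qc_per_batch < 0) {
    stop("counts must be nonnegative and n_batches >= 1")
  }
  if (abs(sum(stage_fractions) - 1) > 1e-9) stop("stage_fractions must sum to 1")
  if (anyDuplicated(names(platform_sizes))) stop("platform names must be unique")
  if (min(dilution_log_sd, batch_log_sd, noise_log_sd, bio_log_sd) < 0) {
    stop("log-scale SDs must be nonnegative")
  }
  if (split_ratio <= 0 || split_ratio >= 1) stop("split_ratio must be in (0,1)")
  cfg <- structure(
    list(n_per_group = n_per_group, stage_fractions = stage_fractions,
         platform_sizes = platform_sizes, n_batches = as.integer(n_batches),
         qc_per_batch = as.integer(qc_per_batch),
         dilution_log_sd = dilution_log_sd, batch_log_sd = batch_log_sd,
         noise_log_sd = noise_log_sd, bio_log_sd = bio_log_sd,
         baseline_log2_range = baseline_log2_range, planted = planted,
         missingness = missingness, split_ratio = split_ratio,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
  all_features <- platform_feature_ids(platform_sizes)
  for (eff in planted) {
    hits <- vapply(all_features, function(f) eff$feature_id %in% f, logical(1))
    if (sum(hits) != 1L) {
      stop("EffectSpec feature '", eff$feature_id, "' not found in exactly one platform")
    }
  }
  cfg
}

# Deterministic per-platform feature ids, e.g. polar_001 ... polar_125.
platform_feature_ids <- function(platform_sizes) {
  lapply(stats::setNames(names(platform_sizes), names(platform_sizes)), function(p) {
    n <- platform_sizes[[p]]
    if (n == 0L) return(character(0))
    sprintf("%s_%03d", tolower(p), seq_len(n))
  })
}

#' Planted group-effect specification
#'
#' One metabolite shifted between clinical groups. The log2 shift applied to a
#' sample in a `contrast` group is
#' `direction * base_log2_effect * stage_multipliers[stage]` (multiplier 1 for
#' non-cancer groups). Default stage multipliers encode the typical trajectory
#' of a progression-linked urinary marker: muted at stage I, fully elevated at
#' II/III, partly reversed at IV.
#'
#' @param feature_id metabolite id (must exist in exactly one platform).
#' @param contrast character vector of groups receiving the shift, e.g.
#'   `c("LC","GC","CRC")` for a pan-cancer marker or `"GC"` for a GC-vs-CRC one.
#' @param base_log2_effect log2 fold change magnitude.
#' @param stage_multipliers named multipliers over `I`,`II`,`III`,`IV`,`unknown`.
#' @param direction `+1` or `-1`.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(feature_id, contrast, base_log2_effect,
                        stage_multipliers = c(I = 0.3, II = 1.0, III = 1.0,
                                              IV = 0.6, unknown = 0.8),
                        direction = 1) {
  stopifnot(direction %in% c(-1, 1), is.character(contrast))
  stages <- c("I", "II", "III", "IV", "unknown")
  if (!all(stages %in% names(stage_multipliers))) {
    stop("stage_multipliers must cover stages ", paste(stages, collapse = ", "))
  }
  structure(list(feature_id = feature_id, contrast = contrast,
                 base_log2_effect = base_log2_effect,
                 stage_multipliers = stage_multipliers[stages],
                 direction = direction),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @param platform_sizes named platform feature counts (to pick marker ids).
#' @details `default_effect_specs()` plants the study-like marker structure:
#'   18 pan-cancer markers (log2 effect 2, alternating sign), 17 markers
#'   separating LC from GC+CRC and 21 separating GC from CRC (log2 effect 1.5
#'   each, disjoint feature sets spread over the platforms).
#' @export
default_effect_specs <- function(platform_sizes = c(polar = 125, lipid = 13, GC = 222)) {
  ids <- platform_feature_ids(platform_sizes)
  pool <- unlist(ids, use.names = FALSE)
  n_needed <- 18 + 17 + 21
  if (length(pool) < n_needed) return(list())
  # spread markers across platforms deterministically: take every k-th feature
  take <- pool[seq(1, length(pool), length.out = n_needed)]
  pan <- take[1:18]; lc <- take[19:35]; gcc <- take[36:56]
  c(
    lapply(seq_along(pan), function(i) {
      effect_spec(pan[i], c("LC", "GC", "CRC"), 2.0, direction = if (i %% 4 == 0) -1 else 1)
    }),
    lapply(seq_along(lc), function(i) {
      effect_spec(lc[i], "LC", 1.5, direction = if (i %% 3 == 0) -1 else 1)
    }),
    lapply(seq_along(gcc), function(i) {
      effect_spec(gcc[i], "GC", 1.5, direction = if (i %% 2 == 0) -1 else 1)
    })
  )
}

#' Missingness specification
#'
#' Missing cells arise from censoring at low intensity (probability ramping
#' linearly from `mnar_max_prob` at the platform's minimum intensity to zero
#' at the `mnar_intensity_quantile` pooled quantile) plus a uniform MCAR
#' component — the structure that motivates routing low-intensity features to
#' half-minimum imputation.
#'
#' @param mnar_intensity_quantile pooled-intensity quantile below which
#'   censoring probability rises, in (0,1).
#' @param mnar_max_prob maximal censoring probability, in \[0,1\].
#' @param mcar_prob missing-completely-at-random probability, in \[0,1\].
#' @return an object of class `missingness_spec`.
#' @export
missingness_spec <- function(mnar_intensity_quantile = 0.15,
                             mnar_max_prob = 0.4,
                             mcar_prob = 0.01) {
  stopifnot(mnar_intensity_quantile > 0, mnar_intensity_quantile < 1,
            mnar_max_prob >= 0, mnar_max_prob <= 1,
            mcar_prob >= 0, mcar_prob <= 1)
  structure(list(mnar_intensity_quantile = mnar_intensity_quantile,
                 mnar_max_prob = mnar_max_prob, mcar_prob = mcar_prob),
            class = "missingness_spec")
}
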