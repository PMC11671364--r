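# Shared fixtures: compact cohorts and quick configs used across test files.

flat_stages <- c(I = 1, II = 1, III = 1, IV = 1, unknown = 1)

# Two-arm cohort (cancer vs HC) on one platform with `n_markers` planted
# pan-cancer effects among nulls; stage multipliers flat unless given.
two_arm_config <- function(n_cancer = 100, n_hc = 100, n_features = 30,
                           n_markers = 3, effect = 2.5,
                           stage_multipliers = flat_stages,
                           dilution_log_sd = 0.5, noise_log_sd = 0.1,
                           batch_log_sd = 0.2, missingness = missingness_spec(),
                           split_ratio = 0.77, seed = 1) {
  ids <- sprintf("polar_%03d", seq_len(n_features))
  planted <- lapply(ids[seq_len(n_markers)], function(f) {
    effect_spec(f, c("LC", "GC", "CRC"), effect,
                stage_multipliers = stage_multipliers)
  })
  n_lc <- ceiling(n_cancer / 2)
  cohort_config(
    n_per_group = c(LC = n_lc, GC = floor(n_cancer / 4),
                    CRC = n_cancer - n_lc - floor(n_cancer / 4),
                    NCD = 0, HC = n_hc),
    platform_sizes = c(polar = n_features),
    planted = planted, n_batches = 2, qc_per_batch = 2,
    dilution_log_sd = dilution_log_sd, batch_log_sd = batch_log_sd,
    noise_log_sd = noise_log_sd, missingness = missingness,
    split_ratio = split_ratio, seed = seed)
}

# Preprocessed modeling matrix + metadata for a config.
prepped <- function(config, prep = preprocess_config()) {
  co <- generate_cohort(config)
  pr <- preprocess_cohort(co$matrices, co$metadata, prep)
  list(X = pr$X, meta = co$metadata, platform_of = pr$platform_of,
       truth = co$truth, cohort = co)
}

quick_selection <- function(n_rounds = 25L, ...) {
  selection_config(n_rounds = n_rounds, ...)
}
quick_training <- function(cv_repeats = 2L, cost = c(0.1, 1, 10), ...) {
  train_config(cv_repeats = cv_repeats, cost = cost, ...)
}

# Independent AUC oracle: brute-force pairwise concordance with ties at 1/2.
brute_force_auc <- function(scores, pos) {
  s_pos <- scores[pos]; s_neg <- scores[!pos]
  total <- 0
  for (a in s_pos) for (b in s_neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(s_pos) * length(s_neg))
}

# Independent hypergeometric upper-tail oracle by direct combinatorial
# summation of binomial-coefficient ratios.
hyper_tail_oracle <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
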