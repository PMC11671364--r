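test_that("group, stage and cancer counts match the config exactly", {
  cfg <- cohort_config(
    n_per_group = c(LC = 431, GC = 142, CRC = 140, NCD = 422, HC = 172),
    platform_sizes = c(polar = 10), planted = list(), seed = 11)
  truth <- simulate_truth(cfg)
  meta <- truth$metadata
  expect_equal(sum(meta$group %in% c("LC", "GC", "CRC")), 713)
  expect_equal(as.vector(table(meta$group)[c("LC", "GC", "CRC", "NCD", "HC")]),
               c(431, 142, 140, 422, 172))
  # stage only for cancer groups, apportioned to the configured fractions
  expect_true(all(meta$stage[meta$group %in% c("NCD", "HC")] == "not-applicable"))
  lc_stages <- table(meta$stage[meta$group == "LC"])
  expect_equal(sum(lc_stages), 431)
  expect_equal(unname(lc_stages["I"]), round(431 * 0.300), tolerance = 1)
})

test_that("zero planted effects give near-zero group differences; a planted
          effect reproduces its log2 magnitude at large n", {
  # null case
  cfg0 <- two_arm_config(n_cancer = 200, n_hc = 200, n_markers = 0, seed = 5,
                         dilution_log_sd = 0, noise_log_sd = 0, batch_log_sd = 0,
                         missingness = missingness_spec(mnar_max_prob = 0, mcar_prob = 0.001))
  t0 <- simulate_truth(cfg0)
  cancer <- t0$metadata$group %in% c("LC", "GC", "CRC")
  diffs <- colMeans(log2(t0$latent$polar[cancer, ])) -
    colMeans(log2(t0$latent$polar[!cancer, ]))
  expect_lt(max(abs(diffs)), 4 * 1 / sqrt(200))  # ~4 MC standard errors

  # planted case: base effect 2, flat multipliers, n = 500/group
  cfg1 <- cohort_config(
    n_per_group = c(LC = 500, GC = 0, CRC = 0, NCD = 0, HC = 500),
    platform_sizes = c(polar = 10),
    planted = list(effect_spec("polar_001", c("LC", "GC", "CRC"), 2,
                               stage_multipliers = flat_stages)),
    seed = 5)
  t1 <- simulate_truth(cfg1)
  cancer <- t1$metadata$group == "LC"
  d <- mean(log2(t1$latent$polar[cancer, "polar_001"])) -
    mean(log2(t1$latent$polar[!cancer, "polar_001"]))
  expect_equal(d, 2, tolerance = 4 / sqrt(500))
})

test_that("stage multipliers scale the planted effect per stage", {
  cfg <- cohort_config(
    n_per_group = c(LC = 2000, GC = 0, CRC = 0, NCD = 0, HC = 2000),
    stage_fractions = c(I = 0.25, II = 0.25, III = 0.25, IV = 0.25, unknown = 0),
    platform_sizes = c(polar = 5),
    planted = list(effect_spec("polar_001", "LC", 2)),  # default multipliers
    seed = 9)
  truth <- simulate_truth(cfg)
  meta <- truth$metadata
  base <- mean(log2(truth$latent$polar[meta$group == "HC", "polar_001"]))
  shifts <- sapply(c("I", "II", "III", "IV"), function(st) {
    mean(log2(truth$latent$polar[meta$group == "LC" & meta$stage == st,
                                 "polar_001"])) - base
  })
  expect_equal(unname(shifts), 2 * c(0.3, 1.0, 1.0, 0.6), tolerance = 0.3)
})

test_that("corrupt is the identity when all corruption is off, and QC rows
          are counted per batch", {
  cfg <- two_arm_config(n_cancer = 20, n_hc = 20, n_features = 8, n_markers = 0,
                        dilution_log_sd = 0, batch_log_sd = 0, noise_log_sd = 0,
                        missingness = missingness_spec(mnar_max_prob = 0, mcar_prob = 0),
                        seed = 3)
  cfg$n_batches <- 4L
  cfg$qc_per_batch <- 3L
  truth <- simulate_truth(cfg)
  out <- corrupt_cohort(truth, cfg)
  fm <- out$matrices$polar
  expect_equal(fm$intensities[!fm$is_qc, ], truth$latent$polar)
  expect_equal(sum(fm$is_qc), 12L)
})

test_that("censoring concentrates missingness at low intensities", {
  cfg <- two_arm_config(n_cancer = 100, n_hc = 100, n_features = 20, n_markers = 0,
                        missingness = missingness_spec(mnar_max_prob = 0.5,
                                                       mcar_prob = 0,
                                                       mnar_intensity_quantile = 0.3),
                        seed = 21)
  truth <- simulate_truth(cfg)
  out <- corrupt_cohort(truth, cfg)
  fm <- out$matrices$polar
  # reconstruct the pre-censoring values for subject rows via the truth record
  lat <- truth$latent$polar
  deciles <- stats::quantile(log(lat), c(0.1, 0.9))
  obs <- fm$intensities[!fm$is_qc, ]
  low <- log(lat) <= deciles[1]
  high <- log(lat) >= deciles[2]
  expect_gt(mean(is.na(obs[low])), mean(is.na(obs[high])))
  expect_gt(mean(is.na(obs[low])), 0.1)
})

test_that("dilution bookkeeping: dividing by recorded factors recovers the
          latent matrix exactly when noise and batch effects are off", {
  cfg <- two_arm_config(n_cancer = 30, n_hc = 30, n_features = 10, n_markers = 0,
                        dilution_log_sd = 0.5, batch_log_sd = 0, noise_log_sd = 0,
                        missingness = missingness_spec(mnar_max_prob = 0, mcar_prob = 0),
                        seed = 17)
  co <- generate_cohort(cfg)
  fm <- co$matrices$polar
  obs <- fm$intensities[!fm$is_qc, ]
  recovered <- obs / co$truth$dilution[rownames(obs)]
  expect_equal(recovered, co$truth$latent$polar)
})

test_that("generation is deterministic and the stratified split hits the
          target ratio within one sample per group", {
  cfg <- two_arm_config(n_cancer = 60, n_hc = 40, seed = 123, split_ratio = 0.77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  for (g in unique(a$metadata$group)) {
    idx <- a$metadata$group == g
    n_disc <- sum(a$metadata$cohort[idx] == "discovery")
    expect_lte(abs(n_disc - 0.77 * sum(idx)), 1)
  }
})

test_that("default platform sizes give 125/13/222 feature columns", {
  cfg <- cohort_config(n_per_group = c(LC = 5, GC = 5, CRC = 5, NCD = 5, HC = 5),
                       seed = 2)
  co <- generate_cohort(cfg)
  expect_equal(vapply(co$matrices, function(m) ncol(m$intensities), 0L),
               c(polar = 125L, lipid = 13L, GC = 222L))
})

test_that("an effect spec referencing an unknown feature is rejected", {
  expect_error(
    cohort_config(n_per_group = c(LC = 5, GC = 5, CRC = 5, NCD = 5, HC = 5),
                  platform_sizes = c(polar = 10),
                  planted = list(effect_spec("gc_001", "LC", 1))),
    "not found in exactly one platform")
})

test_that("cohort round-trips through the TSV writer", {
  cfg <- two_arm_config(n_cancer = 20, n_hc = 20, n_features = 6, seed = 8)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_feature_table(file.path(dir, "polar.tsv"), platform = "polar",
                             batch = stats::setNames(co$matrices$polar$batch,
                                                     rownames(co$matrices$polar$intensities)),
                             is_qc = co$matrices$polar$is_qc)
  expect_equal(back$intensities, co$matrices$polar$intensities)
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(meta$sample_id, co$metadata$sample_id)
})
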