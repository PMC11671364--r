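qc_rsd_of <- function(fm) {
  qc <- fm$intensities[fm$is_qc, , drop = FALSE]
  apply(qc, 2, function(v) stats::sd(v) / mean(v))
}

make_fm <- function(mat, batch = rep("1", nrow(mat)), is_qc = rep(FALSE, nrow(mat)),
                    platform = "polar") {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("S%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("f%02d", seq_len(ncol(mat)))
  feature_matrix(platform, mat, batch, is_qc)
}

test_that("detection filter drops strictly-below-threshold features and keeps
          the boundary", {
  set.seed(1)
  mat <- matrix(stats::runif(100 * 3, 1, 10), 100, 3)
  mat[1:21, 1] <- NA  # detected in 79/100 -> dropped
  mat[1:20, 2] <- NA  # detected in 80/100 -> kept
  fm <- make_fm(mat)
  out <- filter_features(fm, 0.80)
  expect_equal(out$dropped, "f01")
  expect_equal(colnames(out$matrix$intensities), c("f02", "f03"))

  # complete matrix is untouched
  fm2 <- make_fm(matrix(stats::runif(20, 1, 2), 5, 4))
  out2 <- filter_features(fm2, 0.80)
  expect_equal(out2$matrix$intensities, fm2$intensities)
  expect_length(out2$dropped, 0)

  expect_error(filter_features(make_fm(matrix(c(NA, NA, 1, NA), 4, 1)), 0.8),
               "all features dropped")
})

test_that("half-minimum route fills half the batch minimum; observed cells and
          complete matrices are untouched", {
  mat <- matrix(c(8, 10, 12, NA,
                  5, 6, 7, 8), 4, 2,
                dimnames = list(sprintf("S%d", 1:4), c("f01", "f02")))
  fm <- make_fm(mat)
  # force the half-minimum route by making the missing-rate threshold tiny
  cfg <- preprocess_config(impute_missing_rate_threshold = 0.05)
  out <- impute_features(fm, cfg)
  expect_equal(out$matrix$intensities["S4", "f01"], 4.0)
  expect_equal(out$matrix$intensities[, "f02"], mat[, "f02"])
  route <- out$routes
  expect_equal(route$route[route$feature_id == "f01"], "half-minimum")
  expect_equal(route$route[route$feature_id == "f02"], "none")

  complete <- make_fm(matrix(stats::runif(12, 1, 2), 4, 3))
  out2 <- impute_features(complete, preprocess_config())
  expect_equal(out2$matrix$intensities, complete$intensities)
  expect_true(all(out2$routes$route == "none"))
})

test_that("iterative imputation beats half-minimum on a strongly correlated
          feature pair", {
  set.seed(42)
  n <- 60
  base <- stats::rnorm(n, 10, 1)
  lx <- cbind(f01 = base + stats::rnorm(n, 0, 0.1),
              f02 = base + stats::rnorm(n, 0, 0.1),
              f03 = stats::rnorm(n, 12, 1), f04 = stats::rnorm(n, 12, 1))
  mat <- 2^lx
  truth_val <- mat[5, "f01"]
  mat[5, "f01"] <- NA
  fm <- make_fm(mat)
  out <- impute_features(fm, preprocess_config())
  route <- out$routes
  expect_equal(route$route[route$feature_id == "f01"], "iterative")
  half_min_val <- min(mat[, "f01"], na.rm = TRUE) / 2
  err_iter <- abs(out$matrix$intensities[5, "f01"] - truth_val)
  err_half <- abs(half_min_val - truth_val)
  expect_lt(err_iter, err_half)
  # and by a wide margin on the log scale
  expect_lt(err_iter / truth_val, 0.5)
})

test_that("a feature entirely missing within a batch falls back to half the
          global minimum with a warning", {
  mat <- matrix(c(4, 6, NA, NA,
                  1, 2, 3, 4), 4, 2,
                dimnames = list(sprintf("S%d", 1:4), c("f01", "f02")))
  fm <- make_fm(mat, batch = c("1", "1", "2", "2"))
  expect_warning(out <- impute_features(fm, preprocess_config()),
                 "entirely missing in batch 2")
  expect_equal(unname(out$matrix$intensities[3:4, "f01"]), c(2, 2))
})

test_that("MSTUS divides by the useful-signal sum and is exactly invariant to
          per-sample rescaling", {
  mat <- matrix(c(2, 4, 6,
                  1, 5, 4), 2, 3, byrow = TRUE,
                dimnames = list(c("S1", "S2"), c("f01", "f02", "f03")))
  fm <- make_fm(mat)
  out <- mstus_normalize(fm)
  expect_equal(unname(out$matrix$intensities["S1", ]), c(2, 4, 6) / 12)
  expect_equal(unname(out$denominators), c(12, 10))

  scaled <- fm
  scaled$intensities["S1", ] <- scaled$intensities["S1", ] * 7.3
  expect_equal(mstus_normalize(scaled)$matrix$intensities,
               out$matrix$intensities)

  fm_bad <- fm
  fm_bad$intensities[1, 1] <- NA
  expect_error(mstus_normalize(fm_bad), "impute first")
})

test_that("QC-median batch correction is the identity for a single batch,
          shrinks pooled QC RSD across batches, and is ~zero when batch
          effects are absent", {
  # single batch: identity
  set.seed(7)
  mat <- matrix(stats::runif(40, 10, 20), 8, 5)
  fm <- make_fm(mat, is_qc = c(rep(FALSE, 6), TRUE, TRUE))
  out <- qc_batch_correct(fm)
  expect_equal(out$matrix$intensities, fm$intensities)

  # four batches with real batch effects: QC RSD strictly decreases
  cfg <- two_arm_config(n_cancer = 40, n_hc = 40, n_features = 15, n_markers = 0,
                        batch_log_sd = 0.4, noise_log_sd = 0.05,
                        missingness = missingness_spec(mnar_max_prob = 0, mcar_prob = 0),
                        seed = 31)
  cfg$n_batches <- 4L; cfg$qc_per_batch <- 3L
  co <- generate_cohort(cfg)
  fm4 <- co$matrices$polar
  rsd_before <- qc_rsd_of(fm4)
  corr <- qc_batch_correct(fm4)
  rsd_after <- qc_rsd_of(corr$matrix)
  expect_lt(mean(rsd_after), mean(rsd_before))

  # no batch effect in truth: correction factors ~ 0 within noise
  cfg0 <- cfg; cfg0$batch_log_sd <- 0; cfg0$noise_log_sd <- 0.02
  co0 <- generate_cohort(cfg0)
  corr0 <- qc_batch_correct(co0$matrices$polar)
  expect_lt(max(abs(corr0$log2_shifts)), 0.2)

  # a batch without QC is named in the error
  fm_noqc <- fm4
  fm_noqc$is_qc[fm_noqc$batch == "2"] <- FALSE
  expect_error(qc_batch_correct(fm_noqc), "batch\\(es\\): 2")
})


test_that("log/scale fits on discovery only: discovery features are centered
          and unit variance, validation generally is not", {
  cfg <- two_arm_config(n_cancer = 60, n_hc = 60, n_features = 10, n_markers = 2,
                        seed = 13)
  co <- generate_cohort(cfg)
  pr <- preprocess_cohort(co$matrices, co$metadata, preprocess_config())
  disc <- co$metadata$cohort == "discovery"
  m_disc <- colMeans(pr$X[disc, ])
  sd_disc <- apply(pr$X[disc, ], 2, sd)
  expect_lt(max(abs(m_disc)), 1e-10)
  expect_equal(unname(sd_disc), rep(1, ncol(pr$X)), tolerance = 1e-10)
  m_val <- colMeans(pr$X[!disc, ])
  expect_gt(max(abs(m_val)), 0.01)

  # no-scaling mode is a pure log transform: 8 -> 3 in base 2
  mat <- matrix(c(8, 8, 8, 8), 2, 2,
                dimnames = list(c("S1", "S2"), c("f01", "f02")))
  fm <- make_fm(mat)
  out <- log_scale(fm, preprocess_config(scaling_mode = "none"))
  expect_equal(unname(out$matrix$intensities[1, 1]), 3)

  fm_bad <- fm; fm_bad$intensities[2, 1] <- -1
  expect_error(log_scale(fm_bad, preprocess_config()), "S2.*f01")
})

test_that("the full preprocess chain is deterministic and never alters
          observed cells during imputation", {
  cfg <- two_arm_config(n_cancer = 40, n_hc = 40, n_features = 12, seed = 19)
  co <- generate_cohort(cfg)
  p1 <- preprocess_cohort(co$matrices, co$metadata, preprocess_config())
  p2 <- preprocess_cohort(co$matrices, co$metadata, preprocess_config())
  expect_identical(p1$X, p2$X)

  # imputation preserves observed cells bit-exactly
  filt <- filter_features(co$matrices$polar, 0.8)
  imp <- impute_features(filt$matrix, preprocess_config())
  obs_mask <- !is.na(filt$matrix$intensities)
  expect_identical(imp$matrix$intensities[obs_mask],
                   filt$matrix$intensities[obs_mask])
})
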