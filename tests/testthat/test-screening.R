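test_that("the balanced SVM separates well-separated Gaussian clouds and
          scores deterministically", {
  set.seed(5)
  n <- 100
  X <- rbind(matrix(stats::rnorm(n * 4, 0, 1), n, 4),
             matrix(stats::rnorm(n * 4, 4, 1), n, 4))  # delta-mu = 4 SD
  colnames(X) <- sprintf("f%02d", 1:4)
  y <- rep(c("control", "cancer"), each = n)
  model <- train_screening_model(X, y, quick_training(), positive = "cancer")
  expect_gte(model$cv_auc, 0.99)
  s1 <- score_samples(model, X)
  s2 <- score_samples(model, X)
  expect_identical(s1, s2)
  # orientation: cancer scores higher
  expect_gt(mean(s1[y == "cancer"]), mean(s1[y == "control"]))
})

test_that("permuted labels give a cross-validated AUC near 0.5", {
  set.seed(6)
  n <- 80
  X <- matrix(stats::rnorm(2 * n * 5), 2 * n, 5,
              dimnames = list(NULL, sprintf("f%02d", 1:5)))
  aucs <- vapply(1:5, function(r) {
    set.seed(r)
    y <- sample(rep(c("control", "cancer"), each = n))
    train_screening_model(X, y, train_config(cv_repeats = 1L, cost = 1,
                                             seed = r))$cv_auc
  }, 0)
  band <- 1.96 * sqrt((2 * n + 1) / (12 * n * n))
  expect_true(all(abs(aucs - 0.5) < band * 2))  # individual runs, wide check
  expect_lt(abs(mean(aucs) - 0.5), band)
})

test_that("threshold calibration hits the requested specificity on the
          calibration controls, including boundary and tie cases", {
  thr <- calibrate_threshold(c(0.1, 0.2, 0.3, 0.9), 0.75)
  expect_gt(thr$threshold, 0.3)
  expect_lte(thr$threshold, 0.9)
  expect_equal(thr$achieved_specificity, 0.75)

  thr1 <- calibrate_threshold(c(0.1, 0.2, 0.3, 0.9), 1.0)
  expect_gt(thr1$threshold, 0.9)
  expect_equal(thr1$achieved_specificity, 1.0)

  thr2 <- calibrate_threshold(rep(2.5, 10), 0.6)
  expect_gt(thr2$threshold, 2.5)
  expect_equal(thr2$achieved_specificity, 1.0)

  expect_warning(calibrate_threshold(c(0.1, 0.2), 0.9), "unreachable")

  # enumeration oracle: on a random score set, the achieved specificity is the
  # largest reachable value not below target
  set.seed(8)
  sc <- stats::rnorm(57)
  for (target in c(0.5, 0.9, 0.95)) {
    th <- calibrate_threshold(sc, target)
    reachable <- vapply(c(sc, max(sc) + 1), function(t) mean(sc < t), 0)
    want <- min(reachable[reachable >= target])
    expect_equal(th$achieved_specificity, want)
  }
})

test_that("stage-stratified detection rates saturate, mark empty strata as
          undefined, and carry exact binomial CIs", {
  set.seed(9)
  X <- matrix(stats::rnorm(40), 20, 2, dimnames = list(NULL, c("f01", "f02")))
  y <- rep(c("control", "cancer"), each = 10)
  model <- train_screening_model(X, y, train_config(cv_repeats = 1L, cost = 1,
                                                    cv_folds = 3L),
                                 positive = "cancer")
  # threshold below every score: all cancers detected
  cal <- calibrated_classifier(model, score_samples(model, X), 0.5)
  cal$threshold <- min(score_samples(model, X)) - 1
  meta <- data.frame(group = c(rep("HC", 10), rep("LC", 10)),
                     stage = c(rep("not-applicable", 10),
                               rep(c("I", "II", "III", "IV"), length.out = 10)))
  tab <- detection_rate_by_stage(cal, X, meta)
  expect_equal(tab$detection_rate[tab$stage %in% c("I", "II", "III", "IV")],
               rep(1, 4))
  expect_true(is.na(tab$detection_rate[tab$stage == "unknown"]))
  expect_equal(tab$n[tab$stage == "overall"], 10)
  ci <- stats::binom.test(tab$n_detected[tab$stage == "overall"], 10)$conf.int
  expect_equal(tab$ci_lower[tab$stage == "overall"], ci[1])
})

test_that("age confounding check matches the Pearson correlation, including
          the identity and anti-identity cases", {
  ages <- c(30, 40, 50, 60, 70)
  expect_equal(age_confound_check(ages, ages)$r, 1.0)
  expect_equal(age_confound_check(rev(ages), ages)$r, -1.0)
  set.seed(10)
  s <- stats::rnorm(400); a <- stats::rnorm(400, 55, 10)
  chk <- age_confound_check(s, a)
  expect_lt(abs(chk$r), 0.15)
  expect_equal(chk$p_value, stats::cor.test(s, a)$p.value)
  expect_error(age_confound_check(rep(1, 5), ages), "constant")
})

test_that("validation labels play no role in training or calibration", {
  cfg <- two_arm_config(n_cancer = 60, n_hc = 60, n_features = 15, n_markers = 3,
                        seed = 77)
  pp <- prepped(cfg)
  disc <- pp$meta$cohort == "discovery"
  y <- ifelse(pp$meta$group == "HC", "control", "cancer")
  train_once <- function(y_valid_labels) {
    y_all <- y
    y_all[!disc] <- y_valid_labels
    panel <- ensemble_lasso_select(pp$X[disc, ], y_all[disc],
                                   quick_selection(n_rounds = 15L))
    model <- train_screening_model(pp$X[disc, panel$entries$feature_id],
                                   y_all[disc], quick_training(),
                                   positive = "cancer")
    score_samples(model, pp$X[!disc, panel$entries$feature_id])
  }
  set.seed(3)
  scrambled <- sample(y[!disc])
  expect_identical(train_once(y[!disc]), train_once(scrambled))
})

test_that("a linear-kernel score responds monotonically to a uniform shift of
          one sample in the direction of the positive class", {
  set.seed(12)
  n <- 60
  X <- rbind(matrix(stats::rnorm(n * 3, 0), n, 3),
             matrix(stats::rnorm(n * 3, 3), n, 3))
  colnames(X) <- c("f01", "f02", "f03")
  y <- rep(c("control", "cancer"), each = n)
  model <- train_screening_model(X, y, train_config(cv_repeats = 1L, cost = 1),
                                 positive = "cancer")
  x0 <- X[1, , drop = FALSE]
  s0 <- score_samples(model, x0)
  s_up <- score_samples(model, x0 + 2)  # toward the cancer cloud
  expect_gt(s_up, s0)
})
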