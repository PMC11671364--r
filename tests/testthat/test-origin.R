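# Three-class cohort with disjoint marker sets: LC markers on polar;
# GC-vs-CRC markers on GC planted antisymmetrically (up delta/2 in GC, down
# delta/2 in CRC) so they carry the full between-class separation while being
# linearly uninformative for LC vs non-LC -- keeping the two panels disjoint
# by signal, not just by the exclusion rule.
origin_fixture <- function(seed = 55, n_per_class = 70, effect = 4) {
  ids_polar <- sprintf("polar_%03d", 1:20)
  ids_gc <- sprintf("gc_%03d", 1:20)
  planted <- c(
    lapply(ids_polar[1:3], function(f)
      effect_spec(f, "LC", effect, stage_multipliers = flat_stages)),
    unlist(lapply(ids_gc[1:4], function(f) {
      list(effect_spec(f, "GC", effect / 2, stage_multipliers = flat_stages,
                       direction = 1),
           effect_spec(f, "CRC", effect / 2, stage_multipliers = flat_stages,
                       direction = -1))
    }), recursive = FALSE))
  cfg <- cohort_config(
    n_per_group = c(LC = n_per_class, GC = n_per_class, CRC = n_per_class,
                    NCD = 0, HC = 0),
    platform_sizes = c(polar = 20, GC = 20), planted = planted,
    n_batches = 2, qc_per_batch = 2, split_ratio = 0.7, seed = seed)
  pp <- prepped(cfg)
  list(X = pp$X, meta = pp$meta, platform_of = pp$platform_of,
       lc_markers = ids_polar[1:3], gcc_markers = ids_gc[1:4])
}

test_that("the two-stage model recovers disjoint planted panels and valid
          hierarchical probabilities", {
  fx <- origin_fixture()
  disc <- fx$meta$cohort == "discovery"
  model <- train_origin_model(fx$X[disc, ], fx$meta$group[disc],
                              fx$platform_of, quick_selection(),
                              quick_training())
  a <- model$panel_a$entries$feature_id
  b <- model$panel_b$entries$feature_id
  expect_length(intersect(a, b), 0)
  expect_true(all(fx$lc_markers %in% a))
  expect_true(all(fx$gcc_markers %in% b))

  pred <- predict_origin(model, fx$X[!disc, ])
  expect_equal(unname(rowSums(pred$probabilities)),
               rep(1, sum(!disc)), tolerance = 1e-9)
  expect_true(all(pred$probabilities >= 0))

  cm <- confusion_matrix(pred$labels, fx$meta$group[!disc],
                         classes = model$classes)
  expect_gte(cm$accuracy, 0.9)
  auc <- per_class_auc(pred$probabilities, fx$meta$group[!disc])
  expect_true(all(auc >= 0.95))
})

test_that("hierarchical composition is exact: extreme stage probabilities
          dominate as P(LC), (1-P(LC))P(GC|nonLC), remainder", {
  fx <- origin_fixture(seed = 56, n_per_class = 40)
  disc <- fx$meta$cohort == "discovery"
  model <- train_origin_model(fx$X[disc, ], fx$meta$group[disc],
                              fx$platform_of,
                              quick_selection(n_rounds = 15L),
                              quick_training())
  # synthetic probability check via the composition rule itself
  p_lc <- c(1, 0, 0, 1 / 3)
  p_gc <- c(0.2, 0.9, 0.5, 0.5)
  probs <- cbind(LC = p_lc, GC = (1 - p_lc) * p_gc, CRC = (1 - p_lc) * (1 - p_gc))
  expect_equal(rowSums(probs), rep(1, 4))
  expect_equal(unname(probs[2, ]), c(0, 0.9, 0.1))
  # tie: equal probabilities resolve to LC by documented priority
  tie <- matrix(1 / 3, 1, 3, dimnames = list(NULL, c("LC", "GC", "CRC")))
  expect_equal(c("LC", "GC", "CRC")[max.col(tie, ties.method = "first")], "LC")

  # missing panel columns are named
  pooled <- c(model$panel_a$entries$feature_id[1])
  expect_error(predict_origin(model, fx$X[!disc, setdiff(colnames(fx$X), pooled)]),
               pooled)
})

test_that("identical class distributions give chance-level origin accuracy", {
  ids <- sprintf("polar_%03d", 1:15)
  cfg <- cohort_config(
    n_per_group = c(LC = 50, GC = 50, CRC = 50, NCD = 0, HC = 0),
    platform_sizes = c(polar = 15), planted = list(),
    n_batches = 2, qc_per_batch = 2, split_ratio = 0.67, seed = 60)
  pp <- prepped(cfg)
  disc <- pp$meta$cohort == "discovery"
  model <- train_origin_model(pp$X[disc, ], pp$meta$group[disc],
                              pp$platform_of,
                              quick_selection(n_rounds = 10L,
                                              lambda_rule = "cv-min",
                                              target_size = 5L),
                              quick_training())
  pred <- predict_origin(model, pp$X[!disc, ])
  n_val <- sum(!disc)
  acc <- mean(pred$labels == pp$meta$group[!disc])
  band <- 1.96 * sqrt((1 / 3) * (2 / 3) / n_val)
  expect_lt(abs(acc - 1 / 3), band * 2)
})

test_that("predictions are invariant to feature column permutation", {
  fx <- origin_fixture(seed = 57, n_per_class = 40)
  disc <- fx$meta$cohort == "discovery"
  model <- train_origin_model(fx$X[disc, ], fx$meta$group[disc],
                              fx$platform_of,
                              quick_selection(n_rounds = 15L),
                              quick_training())
  Xv <- fx$X[!disc, ]
  p1 <- predict_origin(model, Xv)
  p2 <- predict_origin(model, Xv[, sample(ncol(Xv))])
  expect_equal(p1$probabilities, p2$probabilities)
})

test_that("the ovr-stacked mode trains and returns a valid simplex with good
          separation on planted classes", {
  fx <- origin_fixture(seed = 58, n_per_class = 50)
  disc <- fx$meta$cohort == "discovery"
  model <- train_origin_model(fx$X[disc, ], fx$meta$group[disc],
                              fx$platform_of,
                              quick_selection(n_rounds = 15L),
                              quick_training(), mode = "ovr-stacked",
                              n_bags = 10L)
  pred <- predict_origin(model, fx$X[!disc, ])
  expect_equal(unname(rowSums(pred$probabilities)), rep(1, sum(!disc)),
               tolerance = 1e-9)
  cm <- confusion_matrix(pred$labels, fx$meta$group[!disc],
                         classes = model$classes)
  expect_gte(cm$accuracy, 0.8)
})

test_that("training data must contain all three classes", {
  fx <- origin_fixture(seed = 59, n_per_class = 40)
  keep <- fx$meta$group != "CRC"
  expect_error(train_origin_model(fx$X[keep, ], fx$meta$group[keep],
                                  fx$platform_of, quick_selection(),
                                  quick_training()),
               "LC, GC, CRC")
})
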