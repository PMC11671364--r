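#' Train the two-stage tumor-origin model
#'
#' Stage 1 separates lung cancer (LC) from the digestive-tract cancers
#' (GC + CRC) on panel A; stage 2 separates GC from CRC on panel B, selected
#' with panel A excluded so the two panels are disjoint by construction. Both
#' stage scorers are class-balanced SVMs tuned by repeated stratified CV (as
#' in the screening model) with Platt-calibrated probabilities fitted on
#' out-of-fold decision scores. In `"hierarchical"` mode (default) the
#' three-class probabilities are composed exactly as
#' `P(LC)`, `(1 - P(LC)) * P(GC | non-LC)`, `(1 - P(LC)) * (1 - P(GC | non-LC))`,
#' which sum to 1 per sample. `"ovr-stacked"` mode additionally trains bagged
#' one-vs-rest scorers on the pooled panel plus a regularized multinomial
#' stacking combiner over the five base scores, fitted on out-of-fold stacks.
#'
#' @param X preprocessed matrix (training samples x features).
#' @param labels class labels in `{LC, GC, CRC}`.
#' @param platform_of named platform per feature (for panel tagging).
#' @param selection a [selection_config()] for both panel selections.
#' @param training a [train_config()] for both stage scorers.
#' @param mode `"hierarchical"` or `"ovr-stacked"`.
#' @param n_bags bootstrap replicates per one-vs-rest bagged scorer.
#' @return an object of class `origin_model` with `panel_a`, `panel_b`
#'   (disjoint), `stage1`, `stage2`, `mode`, `classes = c("LC","GC","CRC")`.
#' @export
train_origin_model <- function(X, labels, platform_of = NULL,
                               selection = selection_config(),
                               training = train_config(),
                               mode = c("hierarchical", "ovr-stacked"),
                               n_bags = 25L) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  if (!all(c("LC", "GC", "CRC") %in% labels)) {
    stop("training data must contain all of LC, GC, CRC")
  }
  if (is.null(platform_of)) {
    platform_of <- stats::setNames(rep("platform", ncol(X)), colnames(X))
  }

  y1 <- factor(ifelse(labels == "LC", "LC", "nonLC"),
               levels = c("nonLC", "LC"))  # LC-directed coefficient signs
  panel_a <- select_per_platform_and_merge(X, platform_of, y1,
                                           selection, label = "LC-vs-nonLC")
  if (!nrow(panel_a$entries)) stop("panel A empty; lower the frequency threshold")

  gc_crc <- labels %in% c("GC", "CRC")
  panel_b <- select_per_platform_and_merge(
    X[gc_crc, , drop = FALSE], platform_of, labels[gc_crc],
    selection, exclude = panel_features(panel_a), label = "GC-vs-CRC")
  if (!nrow(panel_b$entries)) {
    stop("panel B empty after excluding panel A; lower the frequency threshold")
  }
  stopifnot(length(intersect(panel_features(panel_a), panel_features(panel_b))) == 0L)

  stage1 <- platt_scorer(X[, panel_features(panel_a), drop = FALSE], y1,
                         positive = "LC", training)
  stage2 <- platt_scorer(X[gc_crc, panel_features(panel_b), drop = FALSE],
                         labels[gc_crc], positive = "GC", training)

  model <- list(panel_a = panel_a, panel_b = panel_b,
                stage1 = stage1, stage2 = stage2, mode = mode,
                classes = c("LC", "GC", "CRC"))
  if (mode == "ovr-stacked") {
    model$ovr <- train_ovr_stack(X, labels, model, training, n_bags)
  }
  structure(model, class = "origin_model")
}

# SVM scorer + Platt sigmoid fitted on out-of-fold decision scores (the
# deterministic alternative to libsvm's internal probability machinery).
platt_scorer <- function(X, y, positive, training) {
  base <- train_screening_model(X, y, training, positive = positive)
  oof <- base$oof
  df <- data.frame(y = as.numeric(oof$label == positive), s = oof$score)
  platt <- suppressWarnings(stats::glm(y ~ s, family = stats::binomial(), data = df))
  list(base = base, platt_coef = stats::coef(platt), positive = positive)
}

platt_prob <- function(scorer, X) {
  s <- score_samples(scorer$base, X)
  eta <- scorer$platt_coef[1] + scorer$platt_coef[2] * s
  1 / (1 + exp(-eta))
}

# Bagged one-vs-rest scorers on the pooled panel and a regularized multinomial
# stacking combiner over (stage1, stage2, 3 OvR) scores, fitted on
# out-of-fold stacked features.
train_ovr_stack <- function(X, labels, model, training, n_bags) {
  pooled <- c(panel_features(model$panel_a), panel_features(model$panel_b))
  Xp <- X[, pooled, drop = FALSE]
  ovr <- lapply(stats::setNames(model$classes, model$classes), function(cl) {
    yb <- ifelse(labels == cl, cl, "rest")
    with_seed(derive_seed(training$seed, paste0("bag_", cl)), {
      lapply(seq_len(n_bags), function(b) {
        idx <- sample(nrow(Xp), nrow(Xp), replace = TRUE)
        if (length(unique(yb[idx])) < 2L) idx <- seq_len(nrow(Xp))
        fit_svm_scorer(Xp[idx, , drop = FALSE], yb[idx], cl, training,
                       cost = training$cost[pmin(3L, length(training$cost))],
                       gamma = training$gamma[1])
      })
    })
  })
  stack_X <- stack_features(model, ovr, X)
  yf <- factor(labels, model$classes)
  foldid <- with_seed(derive_seed(training$seed, "stack_folds"),
                      stratified_folds(yf, 5L))
  comb <- glmnet::cv.glmnet(stack_X, yf, family = "multinomial", alpha = 0,
                            foldid = foldid, standardize = TRUE)
  list(baggers = ovr, combiner = comb, pooled = pooled)
}

stack_features <- function(model, ovr, X) {
  Xp <- X[, c(panel_features(model$panel_a), panel_features(model$panel_b)),
          drop = FALSE]
  bag_score <- vapply(model$classes, function(cl) {
    rowMeans(vapply(ovr[[cl]], function(sc) score_svm(sc, Xp),
                    numeric(nrow(Xp))))
  }, numeric(nrow(X)))
  cbind(stage1 = platt_prob(model$stage1, X),
        stage2 = platt_prob(model$stage2, X),
        bag_score)
}

#' Predict tumor origin
#'
#' Per-sample class probabilities over (LC, GC, CRC) and the argmax label;
#' exact ties resolve by the documented priority LC > GC > CRC.
#'
#' @param model an `origin_model`.
#' @param X matrix containing every pooled-panel feature column.
#' @return list: `probabilities` (samples x 3 matrix), `labels` (character).
#' @export
predict_origin <- function(model, X) {
  probs <- if (model$mode == "hierarchical") {
    p_lc <- platt_prob(model$stage1, X)
    p_gc_given <- platt_prob(model$stage2, X)
    cbind(LC = p_lc, GC = (1 - p_lc) * p_gc_given,
          CRC = (1 - p_lc) * (1 - p_gc_given))
  } else {
    sf <- stack_features(model, model$ovr$baggers, X)
    pr <- stats::predict(model$ovr$combiner, sf, s = "lambda.min",
                         type = "response")[, , 1]
    pr <- pr[, model$classes, drop = FALSE]
    pr / rowSums(pr)
  }
  rownames(probs) <- rownames(X)
  # argmax with LC > GC > CRC priority on exact ties: max.col("first") over
  # the class order already encodes the priority
  labels <- model$classes[max.col(probs, ties.method = "first")]
  list(probabilities = probs, labels = labels)
}

#' One-vs-rest AUC per class
#'
#' @param probabilities samples x classes probability matrix.
#' @param truth true labels.
#' @return named numeric AUC per class.
#' @export
per_class_auc <- function(probabilities, truth) {
  vapply(colnames(probabilities), function(cl) {
    roc_auc(probabilities[, cl], truth == cl)$auc
  }, 0)
}
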