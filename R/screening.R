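#' SVM training configuration
#'
#' @param cv_folds folds of the stratified cross-validation (default 5).
#' @param cv_repeats repetitions of the CV (default 5).
#' @param kernel `"linear"` (default) or `"radial"`; both may appear in the
#'   grid via `cost`/`gamma`.
#' @param cost candidate SVM regularization values.
#' @param gamma candidate RBF kernel widths (ignored for linear kernel).
#' @param class_weight `"balanced"` (inverse class frequency, default) or
#'   `"none"`.
#' @param seed RNG seed (fold assignment).
#' @return an object of class `train_config`.
#' @export
train_config <- function(cv_folds = 5L, cv_repeats = 5L,
                         kernel = c("linear", "radial"),
                         cost = c(0.01, 0.1, 1, 10),
                         gamma = c(0.01, 0.1, 1),
                         class_weight = c("balanced", "none"), seed = 1L) {
  kernel <- match.arg(kernel)
  class_weight <- match.arg(class_weight)
  stopifnot(cv_folds >= 2, cv_repeats >= 1)
  structure(list(cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats), kernel = kernel,
                 cost = cost, gamma = gamma, class_weight = class_weight,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Fit one class-weight-balanced SVM and return a scorer whose decision values
# are oriented so that larger = more `positive` class. e1071's decision-value
# sign depends on class order in the training data, so orientation is fixed
# against the training labels.
fit_svm_scorer <- function(X, y, positive, config, cost, gamma = NULL) {
  yf <- factor(y, levels = c(setdiff(unique(y), positive), positive))
  cw <- if (config$class_weight == "balanced") balanced_weights(yf) else NULL
  args <- list(x = X, y = yf, kernel = config$kernel, cost = cost,
               scale = FALSE, probability = FALSE)
  if (!is.null(cw)) args$class.weights <- cw
  if (config$kernel == "radial") args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  dv <- as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                        "decision.values"))
  flip <- mean(dv[yf == positive]) < mean(dv[yf != positive])
  list(fit = fit, flip = flip, features = colnames(X), positive = positive)
}

score_svm <- function(scorer, X) {
  missing_feats <- setdiff(scorer$features, colnames(X))
  if (length(missing_feats)) {
    stop("missing panel feature column(s): ", paste(missing_feats, collapse = ", "))
  }
  X <- X[, scorer$features, drop = FALSE]
  dv <- as.numeric(attr(stats::predict(scorer$fit, X, decision.values = TRUE),
                        "decision.values"))
  if (scorer$flip) -dv else dv
}

#' Train the class-balanced SVM screening scorer
#'
#' Hyperparameters (cost, and kernel width for the radial kernel) are chosen
#' by repeated stratified k-fold cross-validation maximizing mean out-of-fold
#' AUC; the model is then refitted on the full training set. Class weights
#' are inversely proportional to class frequencies ("balanced"). Out-of-fold
#' decision scores of the winning configuration are kept for Platt
#' calibration. Deterministic given the config seed.
#'
#' @param X preprocessed matrix restricted to the panel's features.
#' @param y binary labels; `positive` names the positive (cancer) class.
#' @param config a [train_config()].
#' @param positive positive class label (default the second factor level).
#' @return an object of class `svm_scorer` with elements `fit`, `cv_auc`
#'   (mean CV AUC of the chosen configuration), `best` (chosen
#'   hyperparameters), `oof` (out-of-fold scores and labels) and a
#'   [score_samples()] method via `score_samples()`.
#' @export
train_screening_model <- function(X, y, config = train_config(), positive = NULL) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("y must have exactly two classes")
  if (is.null(positive)) positive <- classes[2L]
  n_min <- min(table(y))
  if (n_min < config$cv_folds) {
    stop("fewer samples (", n_min, ") in a class than cv_folds (", config$cv_folds, ")")
  }

  grid <- if (config$kernel == "radial") {
    expand.grid(cost = config$cost, gamma = config$gamma)
  } else {
    data.frame(cost = config$cost, gamma = NA_real_)
  }
  cv_scores <- matrix(NA_real_, nrow(grid), config$cv_repeats)
  oof_best <- NULL

  fold_plan <- lapply(seq_len(config$cv_repeats), function(rep) {
    with_seed(derive_seed(config$seed, paste0("svm_cv_rep_", rep)),
              stratified_folds(y, config$cv_folds))
  })
  oof_all <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    oof_scores <- matrix(NA_real_, length(y), config$cv_repeats)
    for (rep in seq_len(config$cv_repeats)) {
      folds <- fold_plan[[rep]]
      sc <- rep(NA_real_, length(y))
      for (k in seq_len(config$cv_folds)) {
        tr <- folds != k
        scorer <- fit_svm_scorer(X[tr, , drop = FALSE], y[tr], positive,
                                 config, grid$cost[g], grid$gamma[g])
        sc[!tr] <- score_svm(scorer, X[!tr, , drop = FALSE])
      }
      oof_scores[, rep] <- sc
      cv_scores[g, rep] <- roc_auc(sc, y == positive)$auc
    }
    oof_all[[g]] <- oof_scores
  }
  mean_auc <- rowMeans(cv_scores)
  best <- which.max(mean_auc)  # ties: first (smallest cost/gamma)
  final <- fit_svm_scorer(X, y, positive, config, grid$cost[best], grid$gamma[best])
  structure(
    list(scorer = final, cv_auc = mean_auc[best],
         best = grid[best, , drop = FALSE],
         oof = list(score = rowMeans(oof_all[[best]]), label = y),
         positive = positive, config = config),
    class = "svm_scorer")
}

#' Score samples with a fitted scorer
#'
#' @param model an `svm_scorer` (or `calibrated_classifier`).
#' @param X matrix containing all the model's feature columns.
#' @return numeric decision scores; larger means more cancer-like.
#' @export
score_samples <- function(model, X) {
  if (inherits(model, "calibrated_classifier")) model <- model$model
  score_svm(model$scorer, X)
}

#' Calibrate a decision threshold to a target specificity
#'
#' Given decision scores of calibration controls, returns the smallest
#' threshold such that the fraction of controls scoring at or above it is at
#' most `1 - target_specificity` (a sample is called positive when
#' `score >= threshold`). The threshold is placed just above the relevant
#' order statistic, stepping past ties to the next distinct score, so the
#' achieved calibration specificity is >= the target by construction. When
#' the target is unreachable with `n` controls other than by excluding all of
#' them (`1 - target < 1/n`), the threshold lands above the maximum control
#' score (specificity 1) with a warning.
#'
#' @param control_scores numeric scores of the calibration controls.
#' @param target_specificity target in (0, 1].
#' @return list of class `score_threshold`: `threshold`,
#'   `achieved_specificity` (on the calibration controls),
#'   `target_specificity`, `n_controls`.
#' @export
calibrate_threshold <- function(control_scores, target_specificity) {
  stopifnot(length(control_scores) >= 1, target_specificity > 0,
            target_specificity <= 1)
  n <- length(control_scores)
  m <- floor(n * (1 - target_specificity))  # allowed exceedances
  s <- sort(control_scores, decreasing = TRUE)
  if (m >= n) m <- n - 1L
  if (m < 1 && 1 - target_specificity < 1 / n && target_specificity < 1) {
    warning("target specificity ", target_specificity, " unreachable with ",
            n, " controls except by excluding all; threshold set above the maximum")
  }
  anchor <- s[m + 1L]  # largest score that must fall below the threshold
  above <- s[s > anchor]
  threshold <- if (length(above)) {
    (anchor + min(above)) / 2  # midpoint to the next distinct score
  } else {
    anchor + max(1e-8, abs(anchor) * 1e-8)
  }
  structure(list(threshold = threshold,
                 achieved_specificity = mean(control_scores < threshold),
                 target_specificity = target_specificity, n_controls = n),
            class = "score_threshold")
}

#' Bundle a scorer with a calibrated operating point
#'
#' @param model an `svm_scorer`.
#' @param control_scores decision scores of discovery controls.
#' @param target_specificity operating specificity (e.g. 0.95, 0.99).
#' @return an object of class `calibrated_classifier`.
#' @export
calibrated_classifier <- function(model, control_scores, target_specificity) {
  thr <- calibrate_threshold(control_scores, target_specificity)
  structure(list(model = model, threshold = thr$threshold,
                 target_specificity = target_specificity,
                 achieved_specificity = thr$achieved_specificity),
            class = "calibrated_classifier")
}

#' Stage-stratified detection rates at the calibrated operating point
#'
#' For each tumor stage (and overall), the fraction of cancer samples scoring
#' at or above the calibrated threshold — the detection rate (sensitivity) at
#' the fixed specificity — with an exact (Clopper-Pearson) binomial 95% CI.
#' Non-cancer samples are excluded; an empty stage stratum is reported as
#' `NA`, not zero.
#'
#' @param calibrated a [calibrated_classifier()].
#' @param X validation feature matrix (all panel features present).
#' @param metadata metadata for the rows of `X` (`group`, `stage`).
#' @param cancer_groups groups counted as cancer.
#' @return data.frame: stage, n, n_detected, detection_rate, ci_lower,
#'   ci_upper.
#' @export
detection_rate_by_stage <- function(calibrated, X, metadata,
                                    cancer_groups = c("LC", "GC", "CRC")) {
  stopifnot(nrow(X) == nrow(metadata))
  is_cancer <- metadata$group %in% cancer_groups
  scores <- score_samples(calibrated, X[is_cancer, , drop = FALSE])
  stage <- metadata$stage[is_cancer]
  detected <- scores >= calibrated$threshold
  strata <- c("I", "II", "III", "IV", "unknown", "overall")
  rows <- lapply(strata, function(st) {
    sel <- if (st == "overall") rep(TRUE, length(stage)) else stage == st
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(stage = st, n = 0L, n_detected = NA_integer_,
                        detection_rate = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, stringsAsFactors = FALSE))
    }
    k <- sum(detected[sel])
    ci <- stats::binom.test(k, n)$conf.int
    data.frame(stage = st, n = n, n_detected = k, detection_rate = k / n,
               ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Age-confounding check
#'
#' Pearson correlation between model prediction scores and participant age,
#' with a two-sided p-value: a screening score should not be a surrogate for
#' age.
#'
#' @param scores prediction scores.
#' @param ages ages in years, same length.
#' @return list with `r` and `p_value`.
#' @export
age_confound_check <- function(scores, ages) {
  stopifnot(length(scores) == length(ages), length(scores) >= 3)
  if (stats::sd(scores) == 0 || stats::sd(ages) == 0) {
    stop("constant scores or ages: correlation undefined")
  }
  ct <- stats::cor.test(scores, ages, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
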