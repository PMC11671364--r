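#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney concordance probability: the chance that a random
#' positive outscores a random negative, with ties counted 1/2 (computed via
#' mid-ranks). The curve sweeps thresholds over the distinct score values
#' (plus the two trivial endpoints) under the convention that
#' `score >= threshold` predicts positive; it starts at (0,0), ends at (1,1)
#' and both coordinates are non-decreasing.
#'
#' @param scores numeric decision scores.
#' @param labels positive-class indicator (logical, 0/1, or two-level factor
#'   whose second level is positive).
#' @return list of class `roc_result`: `auc`, `curve` (data.frame fpr/tpr in
#'   threshold order), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)  # mid-ranks handle ties as 1/2
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thresholds,
    fpr = vapply(thresholds, function(t) mean(scores[!pos] >= t), 0),
    tpr = vapply(thresholds, function(t) mean(scores[pos] >= t), 0))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(labels == 1)
  }
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("labels must be binary")
  f == levels(f)[2L]
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile interval from `n_boot` bootstrap resamples drawn within each
#' class (stratified, so every resample keeps both classes). Deterministic
#' given `seed`.
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_boot number of resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list: `auc`, `ci_lower`, `ci_upper`, `n_boot`, `level`.
#' @export
auc_bootstrap_ci <- function(scores, labels, n_boot = 2000L, level = 0.95,
                             seed = 1L) {
  pos <- as_positive(labels)
  if (sum(pos) < 2L || sum(!pos) < 2L) stop("need >= 2 samples per class")
  point <- roc_auc(scores, pos)$auc
  ip <- which(pos); im <- which(!pos)
  boots <- with_seed(derive_seed(seed, "auc_boot"), {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ip, length(ip), replace = TRUE),
               sample(im, length(im), replace = TRUE))
      roc_auc(scores[idx], pos[idx])$auc
    }, 0)
  })
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(auc = point, ci_lower = qs[1], ci_upper = qs[2],
       n_boot = n_boot, level = level)
}

#' Confusion matrix with per-class recall
#'
#' @param predicted predicted class labels.
#' @param truth true class labels.
#' @param classes class order for rows (truth) and columns (prediction).
#' @return list of class `confusion_matrix`: `counts` (truth x predicted),
#'   `recall` (per-class detection rate, diagonal over row sum), `accuracy`.
#' @export
confusion_matrix <- function(predicted, truth, classes = sort(unique(truth))) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(truth) == 0L) stop("empty inputs")
  unknown <- setdiff(unique(c(predicted, truth)), classes)
  if (length(unknown)) stop("label(s) outside class order: ",
                            paste(unknown, collapse = ", "))
  counts <- table(factor(truth, classes), factor(predicted, classes))
  counts <- matrix(as.integer(counts), nrow(counts),
                   dimnames = list(truth = classes, predicted = classes))
  recall <- diag(counts) / rowSums(counts)
  structure(list(counts = counts, recall = recall,
                 accuracy = sum(diag(counts)) / length(truth)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  cat(sprintf("accuracy: %.3f | recall: %s\n", x$accuracy,
              paste(sprintf("%s %.2f", names(x$recall), x$recall), collapse = ", ")))
  invisible(x)
}
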