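#' Ensemble-LASSO selection configuration
#'
#' @param n_rounds number of recurring random data splits (default 100).
#' @param subsample_fraction fraction of each class drawn (without
#'   replacement) per round.
#' @param lambda_rule `"cv-1se"` (default; sparser) or `"cv-min"`: which
#'   cross-validated penalty each round's L1 logistic fit uses.
#' @param frequency_threshold minimum selection frequency for panel
#'   membership, in (0, 1].
#' @param class_balance `"weighted"` (inverse-frequency observation weights,
#'   default) or `"none"`.
#' @param cv_folds folds of the internal lambda-selection CV.
#' @param target_size optional integer: instead of thresholding, keep the
#'   top-k features by frequency (reproduces fixed-size panels).
#' @param seed RNG seed; round r uses a seed derived from it.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(n_rounds = 100L, subsample_fraction = 0.8,
                             lambda_rule = c("cv-1se", "cv-min"),
                             frequency_threshold = 0.8,
                             class_balance = c("weighted", "none"),
                             cv_folds = 5L, target_size = NULL, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  class_balance <- match.arg(class_balance)
  stopifnot(n_rounds >= 1, subsample_fraction > 0, subsample_fraction < 1,
            frequency_threshold > 0, frequency_threshold <= 1, cv_folds >= 3)
  structure(list(n_rounds = as.integer(n_rounds),
                 subsample_fraction = subsample_fraction,
                 lambda_rule = lambda_rule,
                 frequency_threshold = frequency_threshold,
                 class_balance = class_balance, cv_folds = as.integer(cv_folds),
                 target_size = target_size, seed = as.integer(seed)),
            class = "selection_config")
}

new_panel <- function(entries, label) {
  stopifnot(is.data.frame(entries),
            all(c("feature_id", "platform", "frequency", "sign") %in% names(entries)))
  if (anyDuplicated(entries$feature_id)) stop("panel has duplicate feature ids")
  # order: frequency desc, then |mean coefficient| desc, then feature_id
  o <- order(-entries$frequency, -abs(entries$mean_coef %||% 0), entries$feature_id)
  structure(list(entries = entries[o, , drop = FALSE], label = label),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel> %s: %d features\n", x$label, nrow(x$entries)))
  print(utils::head(x$entries, 10), row.names = FALSE)
  invisible(x)
}

panel_features <- function(panel) panel$entries$feature_id

#' Ensemble LASSO feature selection
#'
#' Stability-style selection: for each of `n_rounds` seeded stratified
#' subsamples (the recurring random data splits), an L1-penalized logistic
#' model is fitted with the penalty chosen by internal cross-validation; a
#' feature's selection frequency is the fraction of rounds in which its
#' coefficient is nonzero. The panel is the set of features at or above
#' `frequency_threshold` (or the top `target_size` by frequency), ordered by
#' frequency, ties broken by larger mean absolute coefficient then feature
#' id. Deterministic given the config seed, and invariant to the column order
#' of `X` (rows are subsampled and folded by index, never columns).
#'
#' @param X preprocessed numeric matrix (samples x features).
#' @param y binary labels (two levels; factor, character or 0/1).
#' @param config a [selection_config()].
#' @param exclude feature ids removed before fitting (for disjoint panels).
#' @param platform_of optional named platform per feature for tagging.
#' @param label panel name.
#' @return a `panel` object; entries carry `feature_id`, `platform`,
#'   `frequency`, `sign` (sign of the mean nonzero coefficient) and
#'   `mean_coef`.
#' @export
ensemble_lasso_select <- function(X, y, config = selection_config(),
                                  exclude = character(0),
                                  platform_of = NULL, label = "panel") {
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes")
  keep <- setdiff(colnames(X), exclude)
  if (!length(keep)) stop("exclusion set covers all features")
  X <- X[, keep, drop = FALSE]
  yb <- as.numeric(y == levels(y)[2L])

  n_sel <- stats::setNames(numeric(ncol(X)), colnames(X))
  coef_sum <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (r in seq_len(config$n_rounds)) {
    with_seed(derive_seed(config$seed, paste0("lasso_round_", r)), {
      idx <- sort(stratified_subsample(yb, config$subsample_fraction))
      w <- if (config$class_balance == "weighted") {
        balanced_weights(yb[idx])[as.character(yb[idx])]
      } else rep(1, length(idx))
      foldid <- stratified_folds(yb[idx], config$cv_folds)
      # lambda path floored at 1% of lambda_max: the separable fits that occur
      # with strong planted effects diverge below that and never win the CV
      fit <- glmnet::cv.glmnet(X[idx, , drop = FALSE], yb[idx],
                               family = "binomial", weights = as.numeric(w),
                               foldid = foldid, standardize = FALSE,
                               lambda.min.ratio = 0.01)
      s <- if (config$lambda_rule == "cv-min") fit$lambda.min else fit$lambda.1se
      beta <- as.numeric(stats::coef(fit, s = s))[-1L]  # drop intercept
      nz <- beta != 0
      n_sel[nz] <- n_sel[nz] + 1
      coef_sum <- coef_sum + beta
    })
  }
  freq <- n_sel / config$n_rounds
  mean_coef <- ifelse(n_sel > 0, coef_sum / pmax(n_sel, 1), 0)
  entries <- data.frame(
    feature_id = colnames(X),
    platform = if (is.null(platform_of)) NA_character_ else unname(platform_of[colnames(X)]),
    frequency = unname(freq),
    sign = sign(mean_coef),
    mean_coef = unname(mean_coef),
    stringsAsFactors = FALSE)
  selected <- if (!is.null(config$target_size)) {
    o <- order(-entries$frequency, -abs(entries$mean_coef), entries$feature_id)
    entries[o, ][seq_len(min(config$target_size, nrow(entries))), ]
  } else {
    entries[entries$frequency >= config$frequency_threshold, ]
  }
  selected <- selected[selected$frequency > 0, , drop = FALSE]
  new_panel(selected, label)
}

#' Per-platform selection and integration
#'
#' Runs [ensemble_lasso_select()] independently on each platform's feature
#' block, then concatenates the per-platform panels into one, tagging each
#' feature with its platform of origin.
#'
#' @param X combined preprocessed matrix (samples x features).
#' @param platform_of named character: platform per feature of `X`.
#' @param y binary labels aligned to rows of `X`.
#' @param config a [selection_config()].
#' @param exclude feature ids excluded from all platforms.
#' @param label merged panel name.
#' @return a `panel`.
#' @export
select_per_platform_and_merge <- function(X, platform_of, y,
                                          config = selection_config(),
                                          exclude = character(0),
                                          label = "panel") {
  stopifnot(all(colnames(X) %in% names(platform_of)))
  parts <- lapply(unique(platform_of[colnames(X)]), function(p) {
    feats <- colnames(X)[platform_of[colnames(X)] == p]
    if (all(feats %in% exclude)) return(NULL)
    ensemble_lasso_select(X[, feats, drop = FALSE], y, config,
                          exclude = exclude, platform_of = platform_of,
                          label = paste0(label, ":", p))$entries
  })
  entries <- do.call(rbind, parts)
  if (is.null(entries)) {
    entries <- data.frame(feature_id = character(0), platform = character(0),
                          frequency = numeric(0), sign = numeric(0),
                          mean_coef = numeric(0), stringsAsFactors = FALSE)
  }
  new_panel(entries, label)
}

#' Remove one panel's features from another
#'
#' Set difference used to force disjoint biomarker panels (the second-stage
#' origin panel must not reuse first-stage features). The selection pipeline
#' normally achieves this by passing the first panel as `exclude`, so
#' disjointness holds by construction; this operation enforces/checks it.
#'
#' @param candidate the panel to prune.
#' @param reference the panel whose features are removed.
#' @return the pruned `panel`.
#' @export
make_disjoint <- function(candidate, reference) {
  drop <- panel_features(candidate) %in% panel_features(reference)
  if (all(drop)) {
    stop("all candidate features overlap the reference panel; ",
         "lower the frequency threshold or widen the candidate set")
  }
  new_panel(candidate$entries[!drop, , drop = FALSE], candidate$label)
}

#' Read/write a panel as TSV
#'
#' Columns: feature_id, platform, frequency, sign, mean_coef.
#'
#' @param panel a `panel`.
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @param label panel name for the read object.
#' @export
read_panel <- function(path, label = basename(path)) {
  entries <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_panel(entries, label)
}
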