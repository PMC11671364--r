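#!/usr/bin/env Rscript

# Step 4: train, calibrate and evaluate the pan-cancer screening model.
#
# Class-balanced SVM on the pan-cancer panel, hyperparameters tuned by
# 5-fold CV repeated 5 times on the discovery cohort; decision thresholds
# calibrated on discovery controls at 95% and 99% target specificity;
# evaluated on the held-out validation cohort: AUC with stratified bootstrap
# 95% CI (vs healthy controls and vs all non-cancer), stage-stratified
# detection rates at both operating points, and the age-confounding check on
# validation controls.
#
# Writes results/screening/: detection tables and a metrics JSON.

suppressPackageStartupMessages(library(metaboscreen))

seed <- 20240901
X_df <- utils::read.delim(file.path("scratch", "processed", "X.tsv"),
                          check.names = FALSE)
X <- as.matrix(X_df[, -1]); rownames(X) <- X_df[[1]]
meta <- read_sample_metadata(file.path("scratch", "cohort", "metadata.tsv"))
panel <- read_panel(file.path("results", "panels", "panel_pan_cancer.tsv"))
pf <- panel$entries$feature_id

disc <- meta$cohort == "discovery"
y <- ifelse(meta$group %in% c("LC", "GC", "CRC"), "cancer", "control")

model <- train_screening_model(X[disc, pf, drop = FALSE], y[disc],
                               train_config(seed = derive_seed(seed, "train")),
                               positive = "cancer")
cat(sprintf("SVM tuned: cost = %g, mean CV AUC = %.3f\n",
            model$best$cost, model$cv_auc))

disc_scores <- score_samples(model, X[disc, pf, drop = FALSE])
val_scores <- score_samples(model, X[!disc, pf, drop = FALSE])
ctrl_scores <- disc_scores[y[disc] == "control"]

out <- file.path("results", "screening")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hc_mask <- meta$group[!disc] %in% c("LC", "GC", "CRC", "HC")
auc_hc <- auc_bootstrap_ci(val_scores[hc_mask], y[!disc][hc_mask] == "cancer",
                           seed = derive_seed(seed, "ci_hc"))
auc_nc <- auc_bootstrap_ci(val_scores, y[!disc] == "cancer",
                           seed = derive_seed(seed, "ci_nc"))
cat(sprintf("validation AUC cancer vs HC:         %.3f (95%% CI %.3f-%.3f)\n",
            auc_hc$auc, auc_hc$ci_lower, auc_hc$ci_upper))
cat(sprintf("validation AUC cancer vs non-cancer: %.3f (95%% CI %.3f-%.3f)\n",
            auc_nc$auc, auc_nc$ci_lower, auc_nc$ci_upper))

metrics <- list(panel_size = length(pf), cv_auc = model$cv_auc,
                auc_vs_hc = auc_hc, auc_vs_noncancer = auc_nc)
for (target in c(0.95, 0.99)) {
  cal <- calibrated_classifier(model, ctrl_scores, target)
  tab <- detection_rate_by_stage(cal, X[!disc, pf, drop = FALSE],
                                 meta[!disc, , drop = FALSE])
  utils::write.table(tab, file.path(out, sprintf("detection_spec%g.tsv",
                                                 100 * target)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("detection at %g%% specificity: %s\n", 100 * target,
              paste(sprintf("%s %.1f%%", tab$stage, 100 * tab$detection_rate),
                    collapse = ", ")))
  metrics[[sprintf("detection_spec%g", 100 * target)]] <-
    stats::setNames(as.list(tab$detection_rate), tab$stage)
}

ctrl_val <- !disc & y == "control"
age <- age_confound_check(score_samples(model, X[ctrl_val, pf, drop = FALSE]),
                          meta$age[ctrl_val])
cat(sprintf("age confounding (validation controls): R = %.3f, p = %.3g\n",
            age$r, age$p_value))
metrics$age_confounding <- age

jsonlite::write_json(metrics, file.path(out, "screening_metrics.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("metrics ->", file.path(out, "screening_metrics.json"), "\n")
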