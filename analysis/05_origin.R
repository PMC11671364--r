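#!/usr/bin/env Rscript

# Step 5: two-stage tumor-origin model on the cancer samples.
#
# Stage 1 scores LC vs non-LC on panel A; stage 2 scores GC vs CRC on the
# disjoint panel B; class probabilities compose hierarchically as
# P(LC), (1-P(LC))P(GC|non-LC), (1-P(LC))(1-P(GC|non-LC)). Trained on
# discovery cancers, evaluated on validation cancers: per-class one-vs-rest
# AUC, confusion matrix, accuracy and per-class recall (detection rate).
#
# Writes results/origin/.

suppressPackageStartupMessages(library(metaboscreen))

seed <- 20240901
X_df <- utils::read.delim(file.path("scratch", "processed", "X.tsv"),
                          check.names = FALSE)
X <- as.matrix(X_df[, -1]); rownames(X) <- X_df[[1]]
plat <- utils::read.delim(file.path("scratch", "processed", "platforms.tsv"))
platform_of <- stats::setNames(plat$platform, plat$feature_id)
meta <- read_sample_metadata(file.path("scratch", "cohort", "metadata.tsv"))

is_cancer <- meta$group %in% c("LC", "GC", "CRC")
disc <- meta$cohort == "discovery" & is_cancer
valid <- meta$cohort == "validation" & is_cancer

model <- train_origin_model(
  X[disc, ], meta$group[disc], platform_of,
  selection_config(seed = derive_seed(seed, "origin_sel")),
  train_config(seed = derive_seed(seed, "origin_svm")))
cat(sprintf("panel A (LC vs non-LC): %d features; panel B (GC vs CRC): %d; overlap %d\n",
            nrow(model$panel_a$entries), nrow(model$panel_b$entries),
            length(intersect(model$panel_a$entries$feature_id,
                             model$panel_b$entries$feature_id))))

pred <- predict_origin(model, X[valid, ])
truth <- meta$group[valid]
cm <- confusion_matrix(pred$labels, truth, classes = model$classes)
auc <- per_class_auc(pred$probabilities, truth)

cat(sprintf("validation accuracy: %.3f\n", cm$accuracy))
cat("per-class recall:", sprintf("%s %.2f", names(cm$recall), cm$recall), "\n")
cat("one-vs-rest AUC:  ", sprintf("%s %.2f", names(auc), auc), "\n")
print(cm)

out <- file.path("results", "origin")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
utils::write.table(as.data.frame.matrix(cm$counts),
                   file.path(out, "confusion.tsv"), sep = "\t", quote = FALSE)
jsonlite::write_json(
  list(accuracy = cm$accuracy, recall = as.list(cm$recall),
       per_class_auc = as.list(auc),
       panel_a = model$panel_a$entries$feature_id,
       panel_b = model$panel_b$entries$feature_id),
  file.path(out, "origin_metrics.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("metrics ->", file.path(out, "origin_metrics.json"), "\n")
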