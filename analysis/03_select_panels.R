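#!/usr/bin/env Rscript

# Step 3: ensemble-LASSO biomarker panel selection on the discovery cohort.
#
# Three panels, each selected per platform and merged:
#   pan-cancer : cancer (LC+GC+CRC) vs non-cancer (NCD+HC)
#   panel A    : LC vs non-LC (GC+CRC), cancers only
#   panel B    : GC vs CRC, with panel A excluded (disjoint by construction)
# Each selection runs 100 recurring random 80% splits; a feature enters a
# panel when its L1-logistic coefficient (penalty chosen by 5-fold CV, 1-SE
# rule) is nonzero in >= 80% of splits.
#
# Reads scratch/processed/, writes the three panel TSVs to results/panels/.

suppressPackageStartupMessages(library(metaboscreen))

seed <- 20240901
X_df <- utils::read.delim(file.path("scratch", "processed", "X.tsv"),
                          check.names = FALSE)
X <- as.matrix(X_df[, -1]); rownames(X) <- X_df[[1]]
plat <- utils::read.delim(file.path("scratch", "processed", "platforms.tsv"))
platform_of <- stats::setNames(plat$platform, plat$feature_id)
meta <- read_sample_metadata(file.path("scratch", "cohort", "metadata.tsv"))
stopifnot(identical(meta$sample_id, rownames(X)))

disc <- meta$cohort == "discovery"
is_cancer <- meta$group %in% c("LC", "GC", "CRC")
sel_cfg <- selection_config(seed = derive_seed(seed, "select"))

pan <- select_per_platform_and_merge(
  X[disc, ], platform_of,
  factor(ifelse(is_cancer[disc], "cancer", "control"),
         levels = c("control", "cancer")),  # cancer-directed signs
  sel_cfg, label = "pan-cancer")

disc_cancer <- disc & is_cancer
panel_a <- select_per_platform_and_merge(
  X[disc_cancer, ], platform_of,
  factor(ifelse(meta$group[disc_cancer] == "LC", "LC", "nonLC"),
         levels = c("nonLC", "LC")),
  sel_cfg, label = "LC-vs-nonLC")

gc_crc <- disc & meta$group %in% c("GC", "CRC")
panel_b <- select_per_platform_and_merge(
  X[gc_crc, ], platform_of, meta$group[gc_crc],
  sel_cfg, exclude = panel_a$entries$feature_id, label = "GC-vs-CRC")
panel_b <- make_disjoint(panel_b, panel_a)  # assert disjointness

out <- file.path("results", "panels")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_panel(pan, file.path(out, "panel_pan_cancer.tsv"))
write_panel(panel_a, file.path(out, "panel_lc_vs_nonlc.tsv"))
write_panel(panel_b, file.path(out, "panel_gc_vs_crc.tsv"))

truth <- jsonlite::read_json(file.path("scratch", "cohort", "truth.json"),
                             simplifyVector = TRUE)
planted <- truth$planted
for (p in list(pan, panel_a, panel_b)) {
  got <- p$entries$feature_id
  hit <- intersect(got, planted$feature_id)
  cat(sprintf("%-12s %2d features (planted recovered: %d, by platform: %s)\n",
              p$label, length(got), length(hit),
              paste(sprintf("%s=%d", names(table(p$entries$platform)),
                            as.integer(table(p$entries$platform))),
                    collapse = ", ")))
}
cat("panel A/B overlap:",
    length(intersect(panel_a$entries$feature_id, panel_b$entries$feature_id)),
    "\n")
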