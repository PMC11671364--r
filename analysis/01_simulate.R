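#!/usr/bin/env Rscript

# Step 1: generate the synthetic multi-platform urinary-metabolomics cohort.
#
# Five clinical groups (LC/GC/CRC cancers, NCD benign controls, HC healthy
# controls) at the study's enrolment sizes, three MS platforms with
# 125/13/222 metabolites, four acquisition batches with three pooled QC
# injections each, per-sample urine dilution, per-batch feature shifts,
# log-normal measurement noise, intensity-dependent missingness, and planted
# marker structure: 18 pan-cancer, 17 LC-vs-non-LC and 21 GC-vs-CRC
# metabolites with stage-dependent effect sizes (muted at stage I, partly
# reversed at IV). Subjects are split 77/23 into discovery and validation,
# stratified by group.
#
# Writes per-platform feature tables, metadata and the ground-truth record to
# scratch/cohort/.

suppressPackageStartupMessages(library(metaboscreen))

seed <- 20240901
cfg <- cohort_config(seed = derive_seed(seed, "cohort"))
cohort <- generate_cohort(cfg)

out <- file.path("scratch", "cohort")
write_cohort(cohort, out)

meta <- cohort$metadata
cat("cohort written to", out, "\n")
cat(sprintf("  %d subjects (%d discovery / %d validation)\n", nrow(meta),
            sum(meta$cohort == "discovery"), sum(meta$cohort == "validation")))
print(table(meta$group, meta$cohort))
for (p in names(cohort$matrices)) {
  fm <- cohort$matrices[[p]]
  cat(sprintf("  %-6s %3d features, %2d QC rows, %.1f%% missing\n", p,
              ncol(fm$intensities), sum(fm$is_qc),
              100 * mean(is.na(fm$intensities))))
}
cat(sprintf("  %d planted marker effects\n", nrow(cohort$truth$planted)))
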