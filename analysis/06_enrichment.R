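#!/usr/bin/env Rscript

# Step 6: pathway over-representation of the selected panels.
#
# One-sided hypergeometric test of each panel against the bundled synthetic
# metabolite-to-pathway map (the background universe is restricted to the
# metabolites measured in this cohort), flagging pathways at raw p < 0.05
# with BH q-values reported alongside.
#
# Writes results/enrichment/.

suppressPackageStartupMessages(library(metaboscreen))

map <- read_pathway_map(system.file("extdata", "pathway_map_synthetic.tsv",
                                    package = "metaboscreen"))
plat <- utils::read.delim(file.path("scratch", "processed", "platforms.tsv"))
universe <- plat$feature_id

out <- file.path("results", "enrichment")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panels <- c(pan_cancer = "panel_pan_cancer.tsv",
            lc_vs_nonlc = "panel_lc_vs_nonlc.tsv",
            gc_vs_crc = "panel_gc_vs_crc.tsv")
for (nm in names(panels)) {
  panel <- read_panel(file.path("results", "panels", panels[[nm]]))
  res <- tryCatch(enrich(panel, map, alpha = 0.05, universe = universe),
                  error = function(e) NULL)
  if (is.null(res)) {
    cat(nm, ": no annotated panel metabolites; skipped\n")
    next
  }
  utils::write.table(as.data.frame(res),
                     file.path(out, paste0(nm, "_enrichment.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- res[res$significant, ]
  cat(sprintf("%s: %d of %d panel metabolites carry pathway annotation; %d pathway(s) at p < 0.05\n",
              nm, res$n[1] - attr(res, "n_unannotated"), res$n[1], nrow(sig)))
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %-10s %-48s k=%d/%d p=%.4f q=%.4f\n", sig$pathway_id[i],
                  sig$pathway_name[i], sig$k[i], sig$K[i], sig$p_value[i],
                  sig$q_value[i]))
    }
  }
}
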