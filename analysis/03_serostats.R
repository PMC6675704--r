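#!/usr/bin/env Rscript
# Stage 3: seropositivity statistics. Optimizes the per-peptide cut-off on
# the preoperative case/control SNR (maximum positive-rate difference),
# classifies all sera, tests each peptide with Fisher's exact test under
# Bonferroni correction, and selects the highly responsive peptides.

suppressPackageStartupMessages(library(pepscreen))

res_dir <- "results"
profiles <- read_profiles(file.path(res_dir, "snr_profiles.tsv"))
pre <- profiles[profiles$timepoint == "preoperative", ]

cutoffs <- panel_cutoffs(pre)
calls <- classify_calls(pre, cutoffs)
comparison <- compare_groups(calls, m = length(unique(pre$peptide)))
rendered <- render_comparison(comparison)
selected <- select_top_peptides(comparison, alpha = 0.05, k = 5)

utils::write.table(cutoffs, file.path(res_dir, "cutoffs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
calls_out <- calls
calls_out$cutoff <- signif(calls_out$cutoff, 7)
utils::write.table(calls_out, file.path(res_dir, "calls_preoperative.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(comparison, file.path(res_dir, "comparison.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(rendered, file.path(res_dir, "comparison_rendered.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(selected, file.path(res_dir, "selected_peptides.txt"))

cat("screening table (whole-percent rendering):\n")
print(rendered, row.names = FALSE)
cat(sprintf("\npeptides with Bonferroni-adjusted p < 0.05, top 5 by rate difference: %s\n",
            paste(selected, collapse = ", ")))
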