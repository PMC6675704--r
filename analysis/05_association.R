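#!/usr/bin/env Rscript
# Stage 5: serology vs protein expression. Collapses the selected peptides
# to one serostatus per subject (positive for >= 1 selected peptide),
# dichotomizes the IHC percentage (> 10% positive) and quantifies the
# association with the midrank Spearman coefficient (= phi for binary
# pairs).

suppressPackageStartupMessages(library(pepscreen))

res_dir <- "results"
study_dir <- "scratch/study"
calls <- utils::read.delim(file.path(res_dir, "calls_preoperative.tsv"))
clinical <- utils::read.csv(file.path(study_dir, "clinical.csv"))
selected <- readLines(file.path(res_dir, "selected_peptides.txt"))

res <- serology_ihc_association(calls, clinical, peptides = selected)
utils::write.table(res$serostatus, file.path(res_dir, "association_subjects.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(r = res$r, p_value = res$p_value, n = res$n),
                   file.path(res_dir, "association.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

print(res$table)
cat(sprintf("Spearman r = %.3f, two-sided p = %.4g (n = %d, %s)\n",
            res$r, res$p_value, res$n, res$p_method))
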