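#!/usr/bin/env Rscript
# Stage 4: longitudinal coverage. Holds the preoperative cut-offs fixed
# and tracks seropositive coverage per peptide across preoperative,
# day-30 and recurrence samples, plus per-patient SNR trajectories with
# seroreversion/seroconversion transitions.

suppressPackageStartupMessages(library(pepscreen))

res_dir <- "results"
profiles <- read_profiles(file.path(res_dir, "snr_profiles.tsv"))
cutoffs <- utils::read.delim(file.path(res_dir, "cutoffs.tsv"))
selected <- readLines(file.path(res_dir, "selected_peptides.txt"))

lng <- longitudinal_coverage(profiles, cutoffs)
utils::write.table(lng$coverage, file.path(res_dir, "coverage_by_timepoint.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(lng$trajectories, file.path(res_dir, "trajectories.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cov <- lng$coverage[lng$coverage$group == "glioma" &
                      lng$coverage$peptide %in% selected, ]
cat("case coverage of the selected peptides by timepoint:\n")
print(cov, row.names = FALSE)
rev_n <- sum(lng$trajectories$transition == "seroreversion", na.rm = TRUE)
con_n <- sum(lng$trajectories$transition == "seroconversion", na.rm = TRUE)
cat(sprintf("\ntransitions in followed patients: %d seroreversions, %d seroconversions\n",
            rev_n, con_n))
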