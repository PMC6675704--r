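#!/usr/bin/env Rscript
# Stage 2: spot quantification. Parses the layout and every intensity
# file, computes per-block blank background and per-spot SNR, applies
# control-based QC, and averages replicate arrays into one reactivity
# profile per serum and timepoint.

suppressPackageStartupMessages(library(pepscreen))

study_dir <- "scratch/study"
res_dir <- "results"
dir.create(res_dir, showWarnings = FALSE)

panel <- mgmt_peptide_table()$name
layout <- parse_layout(file.path(study_dir, "layout.tsv"), panel = panel)
manifest <- read_manifest(file.path(study_dir, "manifest.csv"))
sig <- build_profiles(manifest, layout, panel, dir = file.path(study_dir, "arrays"))

profiles <- sig$profiles
profiles$snr <- signif(profiles$snr, 7)  # keeps the table compact on disk
write_profiles(profiles, file.path(res_dir, "snr_profiles.tsv"))
utils::write.table(sig$qc, file.path(res_dir, "array_qc.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("quantified %d arrays; %d failed QC\n", nrow(sig$qc), sum(!sig$qc$pass)))
cat(sprintf("profiles: %d sera x %d peptides -> %s/snr_profiles.tsv\n",
            length(unique(sig$profiles$serum_id)), length(panel), res_dir))
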