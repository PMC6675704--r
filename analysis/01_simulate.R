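#!/usr/bin/env Rscript
# Stage 1: simulate the study. A stylized emulation of the screening
# design: 67 glioma vs 311 healthy sera against the 20-peptide MGMT panel,
# two replicate arrays per serum, day-30 and recurrence follow-up samples,
# clinical covariates, IHC percentages and recurrence-free survival.
# Inputs are written in the pipeline's on-disk formats so the downstream
# stages exercise the same readers a real study would.

suppressPackageStartupMessages(library(pepscreen))

study_dir <- "scratch/study"
seed <- 20260919L

cfg <- preset_config("study", seed = seed)
cohort <- generate_cohort(cfg)
cohort <- generate_longitudinal(cohort)
cohort <- generate_survival(cohort, n_ihc = 21)
unlink(study_dir, recursive = TRUE)
write_cohort(cohort, study_dir)

cat(sprintf("cohort: %d cases / %d controls, %d arrays (%d sera x %d replicates + follow-up)\n",
            cfg$n_case, cfg$n_control, nrow(cohort$manifest),
            length(unique(cohort$manifest$serum_id)), cfg$replicates_per_serum))
cat(sprintf("day-30 samples: %d, recurrence samples: %d\n",
            length(cohort$longitudinal$postop_ids),
            length(cohort$longitudinal$recurrence_ids)))
cat(sprintf("events among cases: %d of %d\n",
            sum(cohort$clinical$event), nrow(cohort$clinical)))
cat(sprintf("study written to %s\n", study_dir))
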