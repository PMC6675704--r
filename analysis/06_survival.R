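#!/usr/bin/env Rscript
# Stage 6: recurrence-free survival. RFS from the clinical dates,
# Kaplan-Meier curves by serostatus for the top-ranked peptide, log-rank
# comparison, univariable Cox per candidate covariate and multivariable
# Cox with forward selection (likelihood-ratio entry at p < 0.05).

suppressPackageStartupMessages(library(pepscreen))

res_dir <- "results"
study_dir <- "scratch/study"
calls <- utils::read.delim(file.path(res_dir, "calls_preoperative.tsv"))
clinical <- utils::read.csv(file.path(study_dir, "clinical.csv"))
selected <- readLines(file.path(res_dir, "selected_peptides.txt"))
target <- selected[1]

rfs <- compute_rfs(clinical$surgery_date, clinical$recurrence_date,
                   clinical$last_followup_date)
dat <- cbind(clinical, rfs)
tcalls <- calls[calls$peptide == target, ]
dat$serostatus <- as.integer(tcalls$positive[match(dat$subject_id, tcalls$serum_id)])
dat$ki67_high <- as.integer(ihc_call(dat$ki67_pct, "Ki67") == "high")
dat <- dat[!is.na(dat$serostatus), ]

for (g in c(0, 1)) {
  km <- km_estimate(dat$time[dat$serostatus == g], dat$event[dat$serostatus == g])
  utils::write.table(km, file.path(res_dir, sprintf("km_serostatus_%d.tsv", g)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
lr <- logrank_test(dat$time, dat$event, dat$serostatus)
cat(sprintf("%s serostatus log-rank: chi-square %.2f, p = %.4g\n",
            target, lr$statistic, lr$p_value))

candidates <- c("serostatus", "age_ge65", "sex_male", "grade_high", "ki67_high")
uni <- do.call(rbind, lapply(candidates, function(v) {
  tryCatch(cox_fit(dat, v)$coefficients, error = function(e) NULL)
}))
utils::write.table(uni, file.path(res_dir, "cox_univariable.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nunivariable Cox (HR, 95% CI, Wald p):\n")
print(uni[, c("covariate", "hr", "ci_lower", "ci_upper", "p_value")],
      row.names = FALSE)

fs <- forward_selection(dat, candidates, entry_p = 0.05)
utils::write.table(fs$steps, file.path(res_dir, "forward_selection_steps.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
if (!is.null(fs$fit)) {
  utils::write.table(fs$fit$coefficients, file.path(res_dir, "cox_multivariable.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("\nforward selection entered: %s\n", paste(fs$selected, collapse = ", ")))
  print(fs$fit$coefficients[, c("covariate", "hr", "ci_lower", "ci_upper", "p_value")],
        row.names = FALSE)
} else {
  cat("\nforward selection entered no covariate at p < 0.05\n")
}
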