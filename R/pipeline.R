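#' Pipeline configuration
#'
#' Collects every tunable of the analysis with the package defaults:
#' QC thresholds, cut-off search mode, Bonferroni family size, the rule
#' selecting the highly responsive peptides, and the survival options.
#'
#' @param min_pos_snr,max_neg_snr array QC thresholds (see [qc_array()]).
#' @param cutoff_mode `"observed"` (candidates = observed pooled SNR
#'   values, exact) or `"grid"` (fixed-step grid for sensitivity analysis).
#' @param grid_step grid step when `cutoff_mode = "grid"` (default 0.1).
#' @param panel_m Bonferroni family size; NULL = number of panel peptides.
#' @param select_alpha,select_k rule for the highly responsive peptides
#'   (adjusted p < alpha, top k by rate difference).
#' @param ties Cox tie handling, `"breslow"` or `"efron"`.
#' @param entry_p forward-selection entry threshold.
#' @param case_group,control_group group labels in the manifest/clinical
#'   tables.
#' @param seed seed recorded in the run manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(min_pos_snr = 2, max_neg_snr = 1,
                            cutoff_mode = c("observed", "grid"),
                            grid_step = 0.1, panel_m = NULL,
                            select_alpha = 0.05, select_k = 5L,
                            ties = "breslow", entry_p = 0.05,
                            case_group = "glioma", control_group = "healthy",
                            seed = 1L) {
  cfg <- list(min_pos_snr = min_pos_snr, max_neg_snr = max_neg_snr,
              cutoff_mode = match.arg(cutoff_mode), grid_step = grid_step,
              panel_m = panel_m, select_alpha = select_alpha,
              select_k = as.integer(select_k), ties = ties, entry_p = entry_p,
              case_group = case_group, control_group = control_group,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

# grid-mode cut-off search: fixed-step grid spanning the pooled values
grid_cutoffs <- function(profiles, step, case_group, control_group) {
  peptides <- unique(profiles$peptide)
  rows <- lapply(peptides, function(p) {
    sub <- profiles[profiles$peptide == p, ]
    case <- sub$snr[sub$group == case_group & !is.na(sub$snr)]
    ctrl <- sub$snr[sub$group == control_group & !is.na(sub$snr)]
    lo <- floor(min(case, ctrl) / step) * step
    hi <- ceiling(max(case, ctrl) / step) * step
    cand <- seq(lo, hi, by = step)
    obj <- vapply(cand, function(c) mean(case >= c) - mean(ctrl >= c), numeric(1))
    best <- which.max(obj)
    data.frame(peptide = p, cutoff = cand[best], max_difference = obj[best],
               candidates_evaluated = length(cand), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full serology analysis pipeline
#'
#' Sequences the analysis stages over a study directory (or an in-memory
#' synthetic cohort): layout parsing, per-array SNR quantification and QC,
#' replicate aggregation, preoperative cut-off optimization, case-control
#' comparison (screening-table style), coverage per timepoint with
#' per-patient trajectories, serology-IHC association (when the clinical
#' table carries an IHC column), and recurrence-free survival analysis
#' (Kaplan-Meier per serostatus group, log-rank, univariable Cox per
#' candidate and multivariable Cox with forward selection) when the
#' clinical table carries `rfs_days`/`event`. Every output table is written
#' as TSV under `out_dir` together with a JSON run manifest of all
#' parameters, counts and the seed.
#'
#' @param input either a directory written by [write_cohort()] (containing
#'   `layout.tsv`, `arrays/`, `manifest.csv`, optionally `clinical.csv`)
#'   or a `synthetic_cohort` object.
#' @param out_dir output directory, created if needed.
#' @param config a [pipeline_config()].
#' @param panel peptide panel; defaults to the peptide probes found in the
#'   layout.
#' @return invisibly, a list with every stage result (`profiles`, `qc`,
#'   `cutoffs`, `comparison`, `selected`, `coverage`, `trajectories`,
#'   `association`, `survival`, `manifest`).
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config(),
                         panel = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_ps("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if (inherits(input, "synthetic_cohort")) {
    layout <- input$layout; manifest <- input$manifest
    arrays <- input$arrays; dir <- NULL
    clinical <- input$clinical
  } else {
    layout <- stage("layout", parse_layout(file.path(input, "layout.tsv")))
    manifest <- stage("manifest", read_manifest(file.path(input, "manifest.csv")))
    arrays <- NULL; dir <- file.path(input, "arrays")
    clin_path <- file.path(input, "clinical.csv")
    clinical <- if (file.exists(clin_path)) {
      utils::read.csv(clin_path, stringsAsFactors = FALSE)
    } else NULL
  }
  panel <- panel %||% unique(layout$probe_id[layout$spot_type == "peptide"])
  layout <- parse_layout(layout, panel = panel)

  sig <- stage("signal", build_profiles(manifest, layout, panel, dir = dir,
                                        arrays = arrays,
                                        min_pos_snr = config$min_pos_snr,
                                        max_neg_snr = config$max_neg_snr))
  profiles <- sig$profiles
  pre <- profiles[profiles$timepoint == "preoperative", ]

  cutoffs <- stage("cutoffs", {
    if (config$cutoff_mode == "observed") {
      panel_cutoffs(pre, config$case_group, config$control_group)
    } else {
      grid_cutoffs(pre, config$grid_step, config$case_group, config$control_group)
    }
  })

  m <- config$panel_m %||% length(panel)
  calls_pre <- stage("classify", classify_calls(pre, cutoffs))
  comparison <- stage("compare", compare_groups(calls_pre, config$case_group,
                                                config$control_group, m = m))
  selected <- select_top_peptides(comparison, config$select_alpha, config$select_k)
  longit <- stage("coverage", longitudinal_coverage(profiles, cutoffs))

  association <- NULL
  association_note <- NULL
  if (!is.null(clinical) && "mgmt_ihc_pct" %in% names(clinical) &&
      any(!is.na(clinical$mgmt_ihc_pct)) && length(selected) > 0L) {
    # a constant serostatus/IHC vector (e.g. every IHC subject seropositive)
    # leaves the correlation undefined; that is a property of the sample,
    # so it is logged and the stage skipped rather than aborting the run
    association <- tryCatch(
      serology_ihc_association(calls_pre, clinical, peptides = selected),
      error = function(e) {
        if (grepl("constant vector", conditionMessage(e))) {
          association_note <<- conditionMessage(e)
          NULL
        } else {
          stop_ps("pipeline stage 'association' failed: %s", conditionMessage(e))
        }
      })
  }

  surv <- NULL
  if (!is.null(clinical) && all(c("rfs_days", "event") %in% names(clinical)) &&
      length(selected) > 0L && sum(clinical$event) > 0) {
    surv <- stage("survival", {
      target <- selected[1]
      tcalls <- calls_pre[calls_pre$peptide == target, ]
      dat <- clinical
      dat$serostatus <- as.integer(
        tcalls$positive[match(dat$subject_id, tcalls$serum_id)])
      dat <- dat[!is.na(dat$serostatus), ]
      dat$time <- dat$rfs_days
      candidates <- intersect(
        c("serostatus", "age_ge65", "sex_male", "grade_high", "ki67_high"),
        names(dat))
      if (!("ki67_high" %in% names(dat)) && "ki67_pct" %in% names(dat)) {
        dat$ki67_high <- as.integer(ihc_call(dat$ki67_pct, "Ki67") == "high")
        candidates <- c(candidates, "ki67_high")
      }
      km <- lapply(split(dat, dat$serostatus), function(g) {
        km_estimate(g$time, g$event)
      })
      lr <- if (length(unique(dat$serostatus)) == 2L) {
        logrank_test(dat$time, dat$event, dat$serostatus)
      } else NULL
      uni <- lapply(candidates, function(v) {
        tryCatch(cox_fit(dat, v, ties = config$ties)$coefficients,
                 error = function(e) NULL)
      })
      uni <- do.call(rbind, Filter(Negate(is.null), uni))
      fs <- forward_selection(dat, candidates, entry_p = config$entry_p,
                              ties = config$ties)
      list(target_peptide = target, data = dat, km = km, logrank = lr,
           univariable = uni, selection = fs)
    })
  }

  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_profiles(profiles, file.path(out_dir, "snr_profiles.tsv"))
  write_tsv(sig$qc, "array_qc.tsv")
  write_tsv(cutoffs, "cutoffs.tsv")
  write_tsv(calls_pre, "calls_preoperative.tsv")
  write_tsv(comparison, "comparison.tsv")
  write_tsv(render_comparison(comparison), "comparison_rendered.tsv")
  write_tsv(longit$coverage, "coverage_by_timepoint.tsv")
  write_tsv(longit$trajectories, "trajectories.tsv")
  if (!is.null(association)) {
    write_tsv(association$serostatus, "association_subjects.tsv")
    write_tsv(data.frame(r = association$r, p_value = association$p_value,
                         n = association$n), "association.tsv")
  }
  if (!is.null(surv)) {
    for (g in names(surv$km)) {
      write_tsv(surv$km[[g]], sprintf("km_serostatus_%s.tsv", g))
    }
    if (!is.null(surv$univariable)) write_tsv(surv$univariable, "cox_univariable.tsv")
    if (!is.null(surv$selection$fit)) {
      write_tsv(surv$selection$fit$coefficients, "cox_multivariable.tsv")
    }
    write_tsv(surv$selection$steps, "forward_selection_steps.tsv")
  }

  run_manifest <- list(
    config = unclass(config), panel = panel, panel_m = m,
    n_arrays = nrow(manifest), n_arrays_failed_qc = sum(!sig$qc$pass),
    n_sera = length(unique(manifest$serum_id)),
    selected_peptides = as.list(selected),
    survival_target = if (!is.null(surv)) surv$target_peptide else NULL,
    association_note = association_note,
    stages = c("signal", "cutoffs", "classify", "compare", "coverage",
               if (!is.null(association)) "association",
               if (!is.null(surv)) "survival")
  )
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  invisible(list(profiles = profiles, qc = sig$qc, cutoffs = cutoffs,
                 calls = calls_pre, comparison = comparison, selected = selected,
                 coverage = longit$coverage, trajectories = longit$trajectories,
                 association = association, survival = surv,
                 manifest = run_manifest))
}
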