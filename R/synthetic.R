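#' Simulation configuration for a synthetic serology study
#'
#' Defines the seeded study conditions the generator emulates: a
#' case-control cohort screened against a peptide panel on replicate
#' arrays, with optional postoperative and recurrence timepoints and
#' recurrence-free survival outcomes. Per-serum latent SNR for a peptide is
#' drawn from a two-component log-normal mixture: sera truly seropositive
#' for the peptide draw from the high component, the rest from the low
#' component (SNR is a positively skewed ratio, hence log-normal).
#'
#' @param seed integer RNG seed; every draw in the generator is
#'   reproducible from it.
#' @param n_case,n_control cohort sizes (default 100 / 300).
#' @param panel peptide names; defaults to the 20-peptide MGMT panel.
#' @param prevalence_case,prevalence_control per-peptide true
#'   seropositivity probabilities; scalar (recycled) or named vector over
#'   the panel. Defaults 0.45 / 0.06, the contrast scale of the strongest
#'   published peptide.
#' @param snr_neg,snr_pos `c(meanlog, sdlog)` of the seronegative /
#'   seropositive latent SNR components (defaults: median 0.5, sdlog 0.6;
#'   median 6, sdlog 0.4).
#' @param background_mean,background_cv blank background level (arbitrary
#'   units) and its between-block coefficient of variation.
#' @param spot_cv multiplicative per-spot intensity noise (CV).
#' @param replicates_per_serum arrays per serum (default 2).
#' @param pos_control_snr true SNR of positive-control spots (default 8).
#' @param postop_decay multiplicative latent-SNR decay at day 30 (< 1).
#' @param recurrence_rebound multiplicative factor restoring seropositive
#'   peptides to (approximately) preoperative level at recurrence.
#' @param postop_fraction,recurrence_fraction fractions of cases sampled at
#'   day 30 / at recurrence (study-design defaults 52/67 and 11/67).
#' @param baseline_hazard daily recurrence hazard of seronegative patients
#'   (default 1/365).
#' @param log_hr true log hazard ratio of seropositivity for the target
#'   peptide (default log 2).
#' @param censoring_rate target fraction of censored cases (default 0.3).
#' @param target_peptide peptide whose serostatus drives the hazard
#'   (default the second panel peptide, the MGMT-02 analogue).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L, n_case = 100L, n_control = 300L,
                       panel = mgmt_peptide_table()$name,
                       prevalence_case = 0.45, prevalence_control = 0.06,
                       snr_neg = c(meanlog = log(0.5), sdlog = 0.6),
                       snr_pos = c(meanlog = log(6), sdlog = 0.4),
                       background_mean = 500, background_cv = 0.1,
                       spot_cv = 0.08, replicates_per_serum = 2L,
                       pos_control_snr = 8,
                       postop_decay = 0.3, recurrence_rebound = 1.0,
                       postop_fraction = 52 / 67, recurrence_fraction = 11 / 67,
                       baseline_hazard = 1 / 365, log_hr = log(2),
                       censoring_rate = 0.3, target_peptide = NULL) {
  expand <- function(p, what) {
    if (length(p) == 1L && is.null(names(p))) {
      p <- stats::setNames(rep(p, length(panel)), panel)
    }
    if (is.null(names(p))) names(p) <- panel
    if (!all(panel %in% names(p))) stop_ps("%s must cover every panel peptide", what)
    p <- p[panel]
    if (any(p < 0) || any(p > 1)) stop_ps("%s must lie in [0, 1]", what)
    p
  }
  cfg <- list(
    seed = as.integer(seed), n_case = as.integer(n_case),
    n_control = as.integer(n_control), panel = panel,
    prevalence_case = expand(prevalence_case, "prevalence_case"),
    prevalence_control = expand(prevalence_control, "prevalence_control"),
    snr_neg = snr_neg, snr_pos = snr_pos,
    background_mean = background_mean, background_cv = background_cv,
    spot_cv = spot_cv, replicates_per_serum = as.integer(replicates_per_serum),
    pos_control_snr = pos_control_snr,
    postop_decay = postop_decay, recurrence_rebound = recurrence_rebound,
    postop_fraction = postop_fraction, recurrence_fraction = recurrence_fraction,
    baseline_hazard = baseline_hazard, log_hr = log_hr,
    censoring_rate = censoring_rate,
    target_peptide = target_peptide %||% panel[min(2L, length(panel))]
  )
  if (any(c(cfg$snr_neg["sdlog"], cfg$snr_pos["sdlog"]) <= 0)) {
    stop_ps("SNR component scales must be positive")
  }
  if (cfg$snr_pos["meanlog"] <= cfg$snr_neg["meanlog"]) {
    stop_ps("seropositive SNR location must exceed the seronegative location")
  }
  if (cfg$postop_decay <= 0 || cfg$recurrence_rebound <= 0) {
    stop_ps("longitudinal factors must be positive")
  }
  if (cfg$baseline_hazard <= 0) stop_ps("baseline hazard must be positive")
  if (cfg$background_mean <= 0 || cfg$background_cv < 0 || cfg$spot_cv < 0) {
    stop_ps("noise parameters out of range")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Preset simulation configurations
#'
#' `"default"`: 100 cases / 300 controls with uniform 0.45 vs 0.06
#' prevalences (the well-separated configuration used by the end-to-end
#' recovery checks). `"study"`: a stylized emulation of the published study
#' shape — 67 glioma vs 311 healthy sera, five elevated peptides at the
#' published preoperative rates (0.45/0.27/0.21/0.13/0.24 vs
#' 0.06/0.05/0.02/0.01/0.05), a low background prevalence elsewhere —
#' provided for demo runs, not as a claim about the real sera. `"demo"`: a
#' small 20/60 cohort for fast smoke tests.
#'
#' @param preset `"default"`, `"study"` or `"demo"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
preset_config <- function(preset = c("default", "study", "demo"), seed = 1L, ...) {
  preset <- match.arg(preset)
  panel <- mgmt_peptide_table()$name
  if (preset == "study") {
    elevated <- panel[c(2, 4, 7, 10, 18)]
    pc <- stats::setNames(rep(0.07, length(panel)), panel)
    pc[elevated] <- c(0.45, 0.27, 0.21, 0.13, 0.24)
    ph <- stats::setNames(rep(0.02, length(panel)), panel)
    ph[elevated] <- c(0.06, 0.05, 0.02, 0.01, 0.05)
    sim_config(seed = seed, n_case = 67L, n_control = 311L, panel = panel,
               prevalence_case = pc, prevalence_control = ph, ...)
  } else if (preset == "demo") {
    sim_config(seed = seed, n_case = 20L, n_control = 60L, panel = panel, ...)
  } else {
    sim_config(seed = seed, panel = panel, ...)
  }
}

# one simulated array (one 9x9 block) for a serum with given latent SNRs
simulate_array <- function(config, layout, latent_snr) {
  bg <- config$background_mean * exp(stats::rnorm(1, 0, config$background_cv))
  noise <- 1 + stats::rnorm(nrow(layout), 0, config$spot_cv)
  true_snr <- numeric(nrow(layout))
  pep <- layout$spot_type == "peptide"
  true_snr[pep] <- latent_snr[layout$probe_id[pep]]
  true_snr[layout$spot_type == "positive_control"] <- config$pos_control_snr
  # negative controls and blanks sit at the background level (SNR 0)
  intensity <- pmax(0, bg * (1 + true_snr) * noise)
  data.frame(block = layout$block, row = layout$row, column = layout$column,
             probe_id = layout$probe_id, intensity = intensity,
             stringsAsFactors = FALSE)
}

draw_latent <- function(config, status) {
  n <- length(status)
  out <- numeric(n)
  out[!status] <- stats::rlnorm(sum(!status), config$snr_neg["meanlog"],
                                config$snr_neg["sdlog"])
  out[status] <- stats::rlnorm(sum(status), config$snr_pos["meanlog"],
                               config$snr_pos["sdlog"])
  out
}

#' Generate a seeded synthetic case-control cohort
#'
#' Draws true per-serum per-peptide serostatus from the configured
#' prevalences, latent SNR from the status-specific log-normal component,
#' and per-replicate arrays with block-level background and multiplicative
#' spot noise (`intensity = background * (1 + SNR) * (1 + noise)`; blanks
#' and negative controls at background, positive controls at a high fixed
#' SNR). Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_cohort` list: `config`, `layout`, `manifest`,
#'   `arrays` (named list of spot tables keyed by manifest `file`),
#'   `truth` (`serum_id`, `group`, `timepoint`, `peptide`, `status`,
#'   `latent_snr`), `subjects`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- default_layout(config$panel)
  subjects <- data.frame(
    serum_id = c(sprintf("case_%03d", seq_len(config$n_case)),
                 sprintf("ctrl_%03d", seq_len(config$n_control))),
    group = rep(c("glioma", "healthy"), c(config$n_case, config$n_control)),
    stringsAsFactors = FALSE
  )
  truth <- list(); manifest <- list(); arrays <- list()
  for (i in seq_len(nrow(subjects))) {
    pv <- if (subjects$group[i] == "glioma") config$prevalence_case else
      config$prevalence_control
    status <- stats::runif(length(config$panel)) < pv
    latent <- stats::setNames(draw_latent(config, status), config$panel)
    truth[[i]] <- data.frame(
      serum_id = subjects$serum_id[i], group = subjects$group[i],
      timepoint = "preoperative", peptide = config$panel,
      status = status, latent_snr = unname(latent), stringsAsFactors = FALSE
    )
    for (r in seq_len(config$replicates_per_serum)) {
      file <- sprintf("%s_pre_r%d.tsv", subjects$serum_id[i], r)
      arrays[[file]] <- simulate_array(config, layout, latent)
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = file, serum_id = subjects$serum_id[i], replicate = r,
        group = subjects$group[i], timepoint = "preoperative",
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(
    config = config, layout = layout,
    manifest = do.call(rbind, manifest),
    arrays = arrays, truth = do.call(rbind, truth), subjects = subjects
  ), class = "synthetic_cohort")
}

#' Extend a cohort with postoperative and recurrence timepoints
#'
#' A seeded subset of cases is re-sampled at day 30 with latent SNR decayed
#' by `postop_decay` (antigen removal after resection lowers the antibody
#' level); a smaller subset is sampled at recurrence, where peptides the
#' patient was truly seropositive for rebound to `recurrence_rebound` times
#' the preoperative level while seronegative peptides keep their low level.
#' New arrays and manifest/truth rows are appended; uses its own seed
#' stream (`config$seed + 1`) so the preoperative draw is unchanged.
#'
#' @param cohort a `synthetic_cohort`.
#' @return the extended cohort; the day-30 and recurrence serum subsets are
#'   recorded in `cohort$longitudinal`.
#' @export
generate_longitudinal <- function(cohort) {
  config <- cohort$config
  set.seed(config$seed + 1L)
  cases <- cohort$subjects$serum_id[cohort$subjects$group == "glioma"]
  if (length(cases) == 0L) stop_ps("cohort has no preoperative cases")
  n_post <- round(config$postop_fraction * length(cases))
  n_rec <- round(config$recurrence_fraction * length(cases))
  postop_ids <- sort(sample(cases, n_post))
  recur_ids <- sort(sample(cases, n_rec))
  pre <- cohort$truth[cohort$truth$timepoint == "preoperative", ]
  add_tp <- function(ids, timepoint, code, factor_fun) {
    for (id in ids) {
      tr <- pre[pre$serum_id == id, ]
      latent <- stats::setNames(factor_fun(tr$latent_snr, tr$status), tr$peptide)
      cohort$truth <<- rbind(cohort$truth, data.frame(
        serum_id = id, group = "glioma", timepoint = timepoint,
        peptide = tr$peptide, status = tr$status, latent_snr = unname(latent),
        stringsAsFactors = FALSE
      ))
      for (r in seq_len(config$replicates_per_serum)) {
        file <- sprintf("%s_%s_r%d.tsv", id, code, r)
        cohort$arrays[[file]] <<- simulate_array(config, cohort$layout, latent)
        cohort$manifest <<- rbind(cohort$manifest, data.frame(
          file = file, serum_id = id, replicate = r, group = "glioma",
          timepoint = timepoint, stringsAsFactors = FALSE
        ))
      }
    }
  }
  add_tp(postop_ids, "postop_day30", "d30",
         function(snr, status) snr * config$postop_decay)
  add_tp(recur_ids, "recurrence", "rec",
         function(snr, status) ifelse(status, snr * config$recurrence_rebound, snr))
  cohort$longitudinal <- list(postop_ids = postop_ids, recurrence_ids = recur_ids)
  cohort
}

#' Generate clinical and recurrence-free survival data for the cases
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hr * serostatus)` where serostatus is the
#' subject's true preoperative status for `config$target_peptide`;
#' independent exponential censoring is calibrated so the expected censored
#' fraction equals `censoring_rate`. Clinical covariates (age group, sex,
#' WHO grade, Ki-67, and an IHC percentage correlated with serostatus) are
#' drawn from fixed marginals. Uses seed stream `config$seed + 2`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param n_ihc number of cases given an IHC percentage (default 21).
#' @return the cohort with a `clinical` `data.frame` attached: one row per
#'   case with `subject_id`, serostatus truth, covariates,
#'   `surgery_date`, `recurrence_date`, `last_followup_date`, `rfs_days`,
#'   `event`.
#' @export
generate_survival <- function(cohort, n_ihc = 21L) {
  config <- cohort$config
  set.seed(config$seed + 2L)
  cases <- cohort$subjects$serum_id[cohort$subjects$group == "glioma"]
  if (length(cases) == 0L) stop_ps("cohort has no cases")
  pre <- cohort$truth[cohort$truth$timepoint == "preoperative" &
                        cohort$truth$peptide == config$target_peptide, ]
  status <- stats::setNames(pre$status, pre$serum_id)[cases]
  n <- length(cases)
  lambda <- config$baseline_hazard * exp(config$log_hr * as.numeric(status))
  t_event <- stats::rexp(n, rate = lambda)
  if (config$censoring_rate >= 1) {
    time <- pmax(1, ceiling(stats::rexp(n, rate = config$baseline_hazard)))
    event <- rep(0L, n)
  } else if (config$censoring_rate <= 0) {
    time <- pmax(1, ceiling(t_event)); event <- rep(1L, n)
  } else {
    mu <- lambda * config$censoring_rate / (1 - config$censoring_rate)
    t_cens <- stats::rexp(n, rate = mu)
    event <- as.integer(t_event <= t_cens)
    time <- pmax(1, ceiling(pmin(t_event, t_cens)))
  }
  age <- round(pmin(85, pmax(18, stats::rnorm(n, 52, 12))))
  ki67_high <- stats::runif(n) < 0.5
  ihc_pos_prob <- ifelse(status, 0.7, 0.1)
  ihc_idx <- sort(sample(n, min(n_ihc, n)))
  mgmt_pct <- rep(NA_real_, n)
  ihc_pos <- stats::runif(n) < ihc_pos_prob
  mgmt_pct[ihc_idx] <- ifelse(ihc_pos[ihc_idx],
                              stats::runif(length(ihc_idx), 15, 90),
                              stats::runif(length(ihc_idx), 0, 10))
  surgery <- as.Date("2012-01-01") + sample(0:1400, n, replace = TRUE)
  clinical <- data.frame(
    subject_id = cases,
    group = "glioma",
    serostatus_true = as.logical(status),
    age = age,
    age_ge65 = as.integer(age >= 65),
    sex_male = as.integer(stats::runif(n) < 0.55),
    grade_high = as.integer(stats::runif(n) < 0.76),
    ki67_pct = round(ifelse(ki67_high, stats::runif(n, 21, 80),
                            stats::runif(n, 1, 20)), 1),
    mgmt_ihc_pct = round(mgmt_pct, 1),
    surgery_date = surgery,
    recurrence_date = as.Date(ifelse(event == 1, surgery + time, NA),
                              origin = "1970-01-01"),
    last_followup_date = surgery + time,
    rfs_days = time,
    event = event,
    stringsAsFactors = FALSE
  )
  cohort$clinical <- clinical
  cohort
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits `layout.tsv`, one intensity TSV per array under `arrays/`,
#' `manifest.csv`, `clinical.csv` (when present), `truth.tsv` and
#' `config.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "arrays"), recursive = TRUE, showWarnings = FALSE)
  write_layout(cohort$layout, file.path(dir, "layout.tsv"))
  for (f in names(cohort$arrays)) {
    utils::write.table(cohort$arrays[[f]], file.path(dir, "arrays", f),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$clinical)) {
    utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
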