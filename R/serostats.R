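#' Data-driven seropositivity cut-off for one peptide
#'
#' The cut-off is the SNR threshold that maximizes the difference in
#' positive response rate between the case (glioma) and control (healthy)
#' groups, where a serum counts as positive when its SNR is greater than or
#' equal to the threshold. The candidate set is the sorted unique pooled
#' SNR values, which makes the search exact: the objective is piecewise
#' constant between observed values, so an observed value always attains
#' the maximum. Ties are broken toward the smallest maximizing candidate
#' (maximal sensitivity at equal discrimination).
#'
#' @param case_snr numeric vector of case SNR values (NA dropped).
#' @param control_snr numeric vector of control SNR values (NA dropped).
#' @return list with `cutoff`, `max_difference` (case rate minus control
#'   rate at the cut-off), and `candidates_evaluated`.
#' @export
optimize_cutoff <- function(case_snr, control_snr) {
  case_snr <- case_snr[!is.na(case_snr)]
  control_snr <- control_snr[!is.na(control_snr)]
  if (length(case_snr) == 0L || length(control_snr) == 0L) {
    stop_ps("both groups must be non-empty to optimize a cut-off")
  }
  candidates <- sort(unique(c(case_snr, control_snr)))
  n1 <- length(case_snr)
  n2 <- length(control_snr)
  # exact integer arithmetic on the common denominator n1*n2, so ties in
  # the objective are true ties and the smallest-candidate tie-break is
  # immune to floating-point noise in the rate difference
  obj_int <- vapply(candidates, function(c) {
    sum(case_snr >= c) * n2 - sum(control_snr >= c) * n1
  }, numeric(1))
  best <- which.max(obj_int)  # which.max returns the first (= smallest) maximizer
  obj <- obj_int / (n1 * n2)
  if (length(candidates) == 1L) {
    warn_ps("degenerate cut-off search: all SNR values identical (%g)",
            candidates[1])
  }
  list(cutoff = candidates[best], max_difference = obj[best],
       candidates_evaluated = length(candidates))
}

#' Per-peptide cut-offs from preoperative case/control profiles
#'
#' @param profiles long profile `data.frame` (`serum_id`, `group`,
#'   `peptide`, `snr`); only rows of the two named groups are used.
#' @param case_group,control_group group labels (defaults "glioma",
#'   "healthy").
#' @return `data.frame` with one row per peptide: `peptide`, `cutoff`,
#'   `max_difference`, `candidates_evaluated`.
#' @export
panel_cutoffs <- function(profiles, case_group = "glioma",
                          control_group = "healthy") {
  peptides <- unique(profiles$peptide)
  rows <- lapply(peptides, function(p) {
    sub <- profiles[profiles$peptide == p, ]
    res <- optimize_cutoff(sub$snr[sub$group == case_group],
                           sub$snr[sub$group == control_group])
    data.frame(peptide = p, cutoff = res$cutoff,
               max_difference = res$max_difference,
               candidates_evaluated = res$candidates_evaluated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify sera against per-peptide cut-offs
#'
#' A serum is seropositive for a peptide when its aggregated SNR is greater
#' than or equal to that peptide's cut-off (boundary inclusive). Profiles
#' with missing SNR produce no call.
#'
#' @param profiles long profile `data.frame` (`serum_id`, `peptide`, `snr`,
#'   plus any label columns, carried through).
#' @param cutoffs cut-off `data.frame` from [panel_cutoffs()] (columns
#'   `peptide`, `cutoff`).
#' @return calls `data.frame`: the profile columns plus `cutoff` and
#'   logical `positive`.
#' @export
classify_calls <- function(profiles, cutoffs) {
  m <- match(profiles$peptide, cutoffs$peptide)
  if (anyNA(m)) {
    stop_ps("no cut-off for peptide '%s'", profiles$peptide[which(is.na(m))[1]])
  }
  calls <- profiles
  calls$cutoff <- cutoffs$cutoff[m]
  calls <- calls[!is.na(calls$snr), , drop = FALSE]
  calls$positive <- calls$snr >= calls$cutoff
  rownames(calls) <- NULL
  calls
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value for independence in the table `(a, b; c, d)` with fixed
#' margins: the sum of hypergeometric probabilities of all tables whose
#' probability does not exceed that of the observed table
#' (minimum-likelihood two-sided convention). A small relative tolerance
#' guards the inclusion boundary against floating-point noise.
#'
#' @param a,b,c,d non-negative integer counts: case-positive, case-negative,
#'   control-positive, control-negative.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_ps("counts must be non-negative integers")
  }
  m <- a + b          # row 1 margin (cases)
  n_ <- c + d         # row 2 margin (controls)
  k <- a + c          # column margin (positives)
  if (m + n_ == 0L || (k == 0L && b + d == 0L)) {
    warn_ps("empty table margins: p = 1 by convention")
    return(1)
  }
  if (k == 0L || b + d == 0L || m == 0L || n_ == 0L) {
    # a zero margin fixes the table completely: no evidence either way
    warn_ps("degenerate 2x2 margin: p = 1")
    return(1)
  }
  support <- max(0L, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Bonferroni adjustment against a fixed panel size
#'
#' `p_adj = min(1, m * p)` with the family size `m` given explicitly (the
#' peptide panel size), so the correction does not silently shrink when a
#' subset of peptides is tested.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param m family size; must be at least `length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_ps("p-values must lie in [0, 1]")
  }
  if (m < length(p)) stop_ps("family size m (%d) < number of tests (%d)", m, length(p))
  pmin(1, m * p)
}

#' Case-control comparison of seropositivity rates per peptide
#'
#' Builds the per-peptide 2x2 table from classified calls, computes the
#' positive response rate in each group, their difference (case minus
#' control), the two-sided Fisher exact p and its Bonferroni adjustment
#' against the panel size.
#'
#' @param calls calls `data.frame` from [classify_calls()] with a `group`
#'   column.
#' @param case_group,control_group group labels.
#' @param m Bonferroni family size; defaults to the number of peptides in
#'   `calls`.
#' @return `data.frame`: `peptide`, `cutoff`, counts `a`,`b`,`c`,`d`,
#'   `case_n`, `control_n`, `case_rate`, `control_rate`, `difference`,
#'   `p_value`, `p_adjusted`.
#' @export
compare_groups <- function(calls, case_group = "glioma",
                           control_group = "healthy", m = NULL) {
  peptides <- unique(calls$peptide)
  m <- m %||% length(peptides)
  rows <- lapply(peptides, function(p) {
    sub <- calls[calls$peptide == p, ]
    ca <- sub[sub$group == case_group, ]
    co <- sub[sub$group == control_group, ]
    if (nrow(ca) == 0L || nrow(co) == 0L) {
      stop_ps("peptide '%s': empty case or control group", p)
    }
    a <- sum(ca$positive); b <- sum(!ca$positive)
    c_ <- sum(co$positive); d <- sum(!co$positive)
    data.frame(
      peptide = p, cutoff = sub$cutoff[1],
      a = a, b = b, c = c_, d = d,
      case_n = a + b, control_n = c_ + d,
      case_rate = a / (a + b), control_rate = c_ / (c_ + d),
      difference = a / (a + b) - c_ / (c_ + d),
      p_value = fisher_exact_2x2(a, b, c_, d),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_adjust(out$p_value, m)
  rownames(out) <- NULL
  out
}

#' Render a group comparison as a report table
#'
#' Whole-percent rendering (half away from zero) of rates and rate
#' differences, with counts as `"n (rate%)"` strings — the layout used in
#' published screening tables.
#'
#' @param comparison `data.frame` from [compare_groups()].
#' @return `data.frame` with columns `peptide`, `cutoff`, `difference_pct`,
#'   `case`, `control`, `p_value`, `p_adjusted`.
#' @export
render_comparison <- function(comparison) {
  data.frame(
    peptide = comparison$peptide,
    cutoff = comparison$cutoff,
    difference_pct = percent_round(comparison$difference),
    case = sprintf("%d (%d%%)", comparison$a, percent_round(comparison$case_rate)),
    control = sprintf("%d (%d%%)", comparison$c, percent_round(comparison$control_rate)),
    p_value = signif(comparison$p_value, 3),
    p_adjusted = signif(comparison$p_adjusted, 3),
    stringsAsFactors = FALSE
  )
}

#' Seropositive coverage of a peptide in a serum set
#'
#' Coverage = seropositive sera / total sera in the set.
#'
#' @param positive logical vector of calls for one peptide in one set.
#' @return list with `n_positive`, `n_total`, `coverage`.
#' @export
coverage <- function(positive) {
  positive <- positive[!is.na(positive)]
  if (length(positive) == 0L) stop_ps("coverage of an empty serum set is undefined")
  list(n_positive = sum(positive), n_total = length(positive),
       coverage = mean(positive))
}

#' Coverage per peptide and timepoint, with per-patient trajectories
#'
#' Classifies every profile (all timepoints) against cut-offs fixed from
#' the preoperative case-control comparison, tabulates coverage per
#' (peptide, timepoint), and emits per-patient SNR trajectories with
#' serostatus transitions (e.g. seroreversion at day 30, rebound at
#' recurrence) for sera measured at more than one timepoint.
#'
#' @param profiles long profile `data.frame` with a `timepoint` column.
#' @param cutoffs cut-off `data.frame` (columns `peptide`, `cutoff`).
#' @param timepoints allowed timepoint labels in chronological order.
#' @return list with `coverage` (`peptide`, `group`, `timepoint`, `n_positive`,
#'   `n_total`, `coverage`) and `trajectories` (`serum_id`, `peptide`,
#'   `timepoint`, `snr`, `positive`, `transition`), the latter empty when
#'   no serum has multiple timepoints.
#' @export
longitudinal_coverage <- function(profiles, cutoffs,
                                  timepoints = c("preoperative", "postop_day30",
                                                 "recurrence")) {
  unknown <- setdiff(unique(profiles$timepoint), timepoints)
  if (length(unknown) > 0L) {
    stop_ps("unknown timepoint label '%s'", unknown[1])
  }
  calls <- classify_calls(profiles, cutoffs)
  combos <- unique(calls[, c("peptide", "group", "timepoint")])
  cov_rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- calls[calls$peptide == combos$peptide[i] &
                   calls$group == combos$group[i] &
                   calls$timepoint == combos$timepoint[i], ]
    cv <- coverage(sub$positive)
    data.frame(peptide = combos$peptide[i], group = combos$group[i],
               timepoint = combos$timepoint[i],
               n_positive = cv$n_positive, n_total = cv$n_total,
               coverage = cv$coverage, stringsAsFactors = FALSE)
  })
  cov <- do.call(rbind, cov_rows)
  cov$timepoint <- factor(cov$timepoint, levels = timepoints)
  cov <- cov[order(cov$peptide, cov$group, cov$timepoint), ]
  rownames(cov) <- NULL

  multi <- names(which(tapply(calls$timepoint, calls$serum_id,
                              function(t) length(unique(t))) > 1))
  traj <- calls[calls$serum_id %in% multi,
                c("serum_id", "peptide", "timepoint", "snr", "cutoff", "positive")]
  if (nrow(traj) > 0L) {
    traj$timepoint <- factor(traj$timepoint, levels = timepoints)
    traj <- traj[order(traj$serum_id, traj$peptide, traj$timepoint), ]
    key <- paste(traj$serum_id, traj$peptide)
    prev <- ave(as.integer(traj$positive), key,
                FUN = function(x) c(NA, utils::head(x, -1)))
    traj$transition <- ifelse(
      is.na(prev), NA_character_,
      ifelse(prev == 1 & !traj$positive, "seroreversion",
             ifelse(prev == 0 & traj$positive, "seroconversion", "stable"))
    )
    rownames(traj) <- NULL
  } else {
    traj$transition <- character(0)
  }
  list(coverage = cov, trajectories = traj)
}

#' Select the highly responsive peptides
#'
#' Peptides with Bonferroni-adjusted p below `alpha`, ranked by descending
#' case-control rate difference, truncated to the top `k`.
#'
#' @param comparison `data.frame` from [compare_groups()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @param k maximum number of peptides returned (default 5).
#' @return character vector of selected peptide names (possibly shorter
#'   than `k`).
#' @export
select_top_peptides <- function(comparison, alpha = 0.05, k = 5L) {
  hit <- comparison[comparison$p_adjusted < alpha, ]
  hit <- hit[order(-hit$difference, hit$peptide), ]
  utils::head(hit$peptide, k)
}
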