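#' Recurrence-free survival from clinical dates
#'
#' RFS is the interval from surgery to recurrence (event observed) or to
#' the last follow-up (censored). Vectorized over subjects.
#'
#' @param surgery_date,recurrence_date,last_followup_date `Date` vectors
#'   (or strings coercible via `as.Date`); `recurrence_date` is NA for
#'   recurrence-free subjects.
#' @return `data.frame` with `time` (days, > 0) and `event` (1 recurrence,
#'   0 censored).
#' @export
compute_rfs <- function(surgery_date, recurrence_date, last_followup_date) {
  surgery_date <- as.Date(surgery_date)
  recurrence_date <- as.Date(recurrence_date)
  last_followup_date <- as.Date(last_followup_date)
  event <- !is.na(recurrence_date)
  bad <- which(event & recurrence_date < surgery_date)
  if (length(bad) > 0L) {
    stop_ps("recurrence before surgery for record %d", bad[1])
  }
  end <- ifelse(event, as.numeric(recurrence_date), as.numeric(last_followup_date))
  time <- end - as.numeric(surgery_date)
  if (any(is.na(time))) stop_ps("missing follow-up date for a censored record")
  zero <- which(time <= 0)
  if (length(zero) > 0L) {
    stop_ps("zero or negative follow-up interval for record %d", zero[1])
  }
  data.frame(time = time, event = as.integer(event))
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator via `survival::survfit`; subjects censored at an
#' event time are counted at risk at that time (the standard convention).
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (1 event, 0 censored).
#' @return `data.frame` with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` at each distinct observed time.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop_ps("no records for Kaplan-Meier estimation")
  if (any(time <= 0)) stop_ps("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop_ps("event indicator must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance, two-sided p
#' from the chi-square distribution with 1 degree of freedom (via
#' `survival::survdiff`).
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level grouping vector.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop_ps("log-rank test needs exactly two groups")
  if (min(table(group)) == 0L) stop_ps("both groups must be non-empty")
  if (sum(event) == 0) stop_ps("no events observed: log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(statistic = unname(sd$chisq), df = 1L, p_value = p)
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood fit (Breslow tie handling by default, Efron
#' available) with Wald confidence intervals `exp(coef +/- 1.96 * SE)`.
#' Monotone likelihood (perfect separation) is flagged as non-converged
#' with a diagnostic rather than silently reported.
#'
#' @param data `data.frame` holding the time, event and covariate columns.
#' @param covariates character vector of covariate column names; constants
#'   are rejected by name.
#' @param time_col,event_col column names (defaults `"time"`, `"event"`).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list with `coefficients` (`data.frame`: `covariate`, `coef`,
#'   `hr`, `se`, `ci_lower`, `ci_upper`, `p_value`), `loglik` (at the
#'   optimum), `loglik_null`, `converged`, `warnings`, and the underlying
#'   `coxph` object in `fit`.
#' @export
cox_fit <- function(data, covariates, time_col = "time", event_col = "event",
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  check_columns(data, c(time_col, event_col, covariates), "survival data")
  if (sum(data[[event_col]]) == 0) stop_ps("no events: Cox model undefined")
  for (v in covariates) {
    vals <- data[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2L) {
      stop_ps("covariate '%s' is constant across all records", v)
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (anyNA(stats::coef(fit))) {
    stop_ps("singular model matrix: covariate(s) %s aliased",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  s <- summary(fit)
  coefs <- data.frame(
    covariate = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = exp(s$coefficients[, "coef"]),
    se = s$coefficients[, "se(coef)"],
    ci_lower = exp(s$coefficients[, "coef"] - 1.96 * s$coefficients[, "se(coef)"]),
    ci_upper = exp(s$coefficients[, "coef"] + 1.96 * s$coefficients[, "se(coef)"]),
    p_value = s$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  separated <- any(grepl("infinite|did not converge|out of iterations",
                         warns, ignore.case = TRUE)) ||
    any(abs(coefs$coef) > 15)
  if (separated) {
    warn_ps("monotone partial likelihood suspected (covariate(s): %s); coefficients unreliable",
            paste(coefs$covariate[abs(coefs$coef) > 15], collapse = ", "))
  }
  list(coefficients = coefs, loglik = fit$loglik[2], loglik_null = fit$loglik[1],
       converged = !separated, warnings = warns, fit = fit)
}

#' Forward covariate selection for the Cox model
#'
#' Starting from the null model, repeatedly adds the candidate whose
#' likelihood-ratio test against the current model has the smallest p-value
#' below `entry_p`; stops when no candidate qualifies. Ties are broken by
#' candidate order, so the procedure is deterministic given the input.
#' Candidates that fail to fit (e.g. constant within the risk sets) are
#' skipped with a warning. There is no removal step.
#'
#' @inheritParams cox_fit
#' @param candidates candidate covariate names, in priority order.
#' @param entry_p likelihood-ratio entry threshold (default 0.05).
#' @return list with `selected` (ordered character vector, possibly
#'   empty), `steps` (`data.frame` of every evaluated candidate per round:
#'   `round`, `candidate`, `lrt_stat`, `p_value`, `entered`), and `fit`
#'   (final [cox_fit()] result, or NULL for the null model).
#' @export
forward_selection <- function(data, candidates, entry_p = 0.05,
                              time_col = "time", event_col = "event",
                              ties = "breslow") {
  selected <- character(0)
  steps <- list()
  current_ll <- NULL
  final_fit <- NULL
  round <- 0L
  repeat {
    round <- round + 1L
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    best <- NULL
    for (cand in remaining) {
      fit <- tryCatch(
        suppressWarnings(cox_fit(data, c(selected, cand), time_col, event_col,
                                 ties = ties)),
        error = function(e) {
          warn_ps("forward selection skipped '%s': %s", cand, conditionMessage(e))
          NULL
        }
      )
      if (is.null(fit)) next
      ll0 <- if (is.null(current_ll)) fit$loglik_null else current_ll
      lrt <- max(0, 2 * (fit$loglik - ll0))
      p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
      steps[[length(steps) + 1L]] <- data.frame(
        round = round, candidate = cand, lrt_stat = lrt, p_value = p,
        entered = FALSE, stringsAsFactors = FALSE
      )
      if (p < entry_p && (is.null(best) || p < best$p)) {
        best <- list(candidate = cand, p = p, fit = fit)
      }
    }
    if (is.null(best)) break
    selected <- c(selected, best$candidate)
    current_ll <- best$fit$loglik
    final_fit <- best$fit
    for (i in seq_along(steps)) {
      if (steps[[i]]$round == round && steps[[i]]$candidate == best$candidate) {
        steps[[i]]$entered <- TRUE
      }
    }
  }
  steps <- if (length(steps) > 0L) do.call(rbind, steps) else
    data.frame(round = integer(0), candidate = character(0),
               lrt_stat = numeric(0), p_value = numeric(0), entered = logical(0))
  list(selected = selected, steps = steps, fit = final_fit)
}
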