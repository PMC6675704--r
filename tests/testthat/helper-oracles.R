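# Independent brute-force oracles used to validate the analysis routines.
# These deliberately avoid the code paths (and where possible the library
# calls) of the implementations they check.

# exhaustive cut-off search: scan every pooled value, count exceedances by
# explicit comparison loops
oracle_cutoff <- function(case, control) {
  cand <- sort(unique(c(case, control)))
  best_c <- NA_real_
  best_num <- -Inf  # objective numerator on the exact n1*n2 denominator
  for (cc in cand) {
    n_case_pos <- 0L
    for (v in case) if (v >= cc) n_case_pos <- n_case_pos + 1L
    n_ctrl_pos <- 0L
    for (v in control) if (v >= cc) n_ctrl_pos <- n_ctrl_pos + 1L
    num <- n_case_pos * length(control) - n_ctrl_pos * length(case)
    if (num > best_num) {
      best_num <- num
      best_c <- cc
    }
  }
  list(cutoff = best_c,
       max_difference = best_num / (length(case) * length(control)))
}

# hypergeometric probability of table (a, m-a; k-a, n-k+a) via log-factorials
oracle_table_prob <- function(a, m, n, k) {
  N <- m + n
  exp(lfactorial(m) + lfactorial(n) + lfactorial(k) + lfactorial(N - k) -
        lfactorial(N) - lfactorial(a) - lfactorial(m - a) -
        lfactorial(k - a) - lfactorial(n - k + a))
}

# two-sided Fisher p by full enumeration of the fixed-margin support
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, oracle_table_prob, numeric(1), m = m, n = n, k = k)
  p_obs <- oracle_table_prob(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-written product-limit estimator (standard censoring convention)
oracle_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = times, survival = surv)
}

# Breslow partial log-likelihood for a single covariate, written from the
# definition (event-time loop over risk sets)
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- which(time >= t)
    dead <- which(time == t & event == 1)
    ll <- ll + sum(beta * x[dead]) -
      length(dead) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# grid-search maximizer of the Breslow partial likelihood; returns NA when
# the optimum sits on the grid boundary (monotone likelihood)
oracle_cox_grid <- function(time, event, x, lo = -8, hi = 8) {
  grid <- seq(lo, hi, by = 0.01)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time = time,
               event = event, x = x)
  i <- which.max(ll)
  if (i == 1L || i == length(grid)) return(NA_real_)
  fine <- seq(grid[i] - 0.01, grid[i] + 0.01, by = 1e-5)
  llf <- vapply(fine, oracle_cox_loglik, numeric(1), time = time,
                event = event, x = x)
  fine[which.max(llf)]
}

# random small survival instance with a binary covariate; both covariate
# levels present and at least one event
random_cox_instance <- function(n) {
  repeat {
    x <- rbinom(n, 1, 0.5)
    time <- round(rexp(n, 1 / 10) + 0.5, 1)
    event <- rbinom(n, 1, 0.7)
    if (length(unique(x)) == 2L && sum(event) >= 1L) {
      return(data.frame(time = time, event = event, x = x))
    }
  }
}

# quick profile builder for serostats tests: SNR values straight into the
# long profile format, bypassing the array stage
make_profiles <- function(case_snr, control_snr, peptide = "PEP-01") {
  data.frame(
    serum_id = c(sprintf("case_%03d", seq_along(case_snr)),
                 sprintf("ctrl_%03d", seq_along(control_snr))),
    group = rep(c("glioma", "healthy"), c(length(case_snr), length(control_snr))),
    timepoint = "preoperative",
    peptide = peptide,
    snr = c(case_snr, control_snr),
    n_replicates = 2L,
    stringsAsFactors = FALSE
  )
}

# calls table with a given number of positives per group, for the
# count-level worked examples
make_calls <- function(peptide, cutoff, n_case_pos, n_case, n_ctrl_pos, n_ctrl) {
  data.frame(
    serum_id = c(sprintf("case_%03d", seq_len(n_case)),
                 sprintf("ctrl_%03d", seq_len(n_ctrl))),
    group = rep(c("glioma", "healthy"), c(n_case, n_ctrl)),
    peptide = peptide,
    snr = NA_real_,
    cutoff = cutoff,
    positive = c(rep(c(TRUE, FALSE), c(n_case_pos, n_case - n_case_pos)),
                 rep(c(TRUE, FALSE), c(n_ctrl_pos, n_ctrl - n_ctrl_pos))),
    stringsAsFactors = FALSE
  )
}
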