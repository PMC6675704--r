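#' Dichotomize an immunohistochemistry percentage
#'
#' MGMT staining is called positive when more than 10% of cell nuclei
#' stain; Ki-67 is called high when more than 20% of cells stain. Boundary
#' values (exactly 10 / exactly 20) fall in the negative/low class.
#'
#' @param percent percent of positively stained cells, in \[0, 100\];
#'   vectorized.
#' @param marker `"MGMT"` or `"Ki67"`.
#' @return character vector: `"positive"`/`"negative"` for MGMT,
#'   `"high"`/`"low"` for Ki-67.
#' @export
ihc_call <- function(percent, marker = c("MGMT", "Ki67")) {
  marker <- match.arg(marker)
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent > 100)) {
    stop_ps("IHC percent must lie in [0, 100]")
  }
  if (marker == "MGMT") {
    ifelse(percent > 10, "positive", "negative")
  } else {
    ifelse(percent > 20, "high", "low")
  }
}

# exact permutation p for the Spearman statistic; for binary y the distinct
# permutations are the positions of the ones, enumerable far beyond n = 12
perm_spearman_p <- function(x, y) {
  n <- length(x)
  r_obs <- abs(stats::cor(x, y, method = "spearman"))
  if (length(unique(y)) == 2L) {
    lv <- sort(unique(y))
    k <- sum(y == lv[2])
    combos <- utils::combn(n, k)
    rs <- apply(combos, 2, function(idx) {
      yy <- rep(lv[1], n)
      yy[idx] <- lv[2]
      stats::cor(x, yy, method = "spearman")
    })
    # weight each support point by its multiplicity under full permutation:
    # every choice of positions is equally likely, so combinations are uniform
    mean(abs(rs) >= r_obs - 1e-12)
  } else {
    if (n > 8L) stop_ps("exact permutation for non-binary data limited to n <= 8")
    perms <- all_permutations(n)
    rs <- apply(perms, 1, function(idx) stats::cor(x, y[idx], method = "spearman"))
    mean(abs(rs) >= r_obs - 1e-12)
  }
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman association between two paired variables
#'
#' Spearman rank correlation with midranks for ties. For two binary
#' variables this equals the phi coefficient of the underlying 2x2 table,
#' phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)), which is how a published
#' serostatus-vs-IHC association table can be reproduced from its counts.
#' The two-sided p-value uses the t-approximation
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom; an exact
#' permutation p is available for small samples (binary vectors of any
#' modest n, general vectors up to n = 8).
#'
#' @param x,y paired vectors (numeric or two-level factors/characters) of
#'   equal length >= 3 with at least two distinct values each.
#' @param p_method `"tapprox"` (default) or `"permutation"`.
#' @return list with `r`, `p_value`, `n`, `p_method`, and `table` (the 2x2
#'   contingency table when both inputs are binary, else NULL).
#' @export
spearman_association <- function(x, y, p_method = c("tapprox", "permutation")) {
  p_method <- match.arg(p_method)
  to_num <- function(v) {
    if (is.numeric(v)) return(v)
    f <- factor(v)
    as.integer(f) - 1
  }
  x <- to_num(x); y <- to_num(y)
  if (length(x) != length(y)) stop_ps("x and y must be paired (equal length)")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_ps("need at least 3 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop_ps("correlation undefined for a constant vector")
  }
  r <- stats::cor(x, y, method = "spearman")
  if (p_method == "tapprox") {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    p <- perm_spearman_p(x, y)
  }
  tab <- NULL
  if (length(unique(x)) == 2L && length(unique(y)) == 2L) {
    tab <- table(x = factor(x, levels = sort(unique(x), decreasing = TRUE)),
                 y = factor(y, levels = sort(unique(y), decreasing = TRUE)))
  }
  list(r = r, p_value = min(1, p), n = n, p_method = p_method, table = tab)
}

#' Serostatus vs protein-expression association for a cohort
#'
#' Collapses per-peptide calls to one serostatus per subject (positive for
#' at least one peptide of `peptides` — the pooled rule for a multi-peptide
#' panel — or a single peptide), joins IHC calls, and runs
#' [spearman_association()].
#'
#' @param calls calls `data.frame` (`serum_id`, `peptide`, `positive`).
#' @param clinical clinical `data.frame` with `subject_id` and an IHC
#'   percent column.
#' @param peptides peptide name(s) defining serostatus.
#' @param ihc_column name of the IHC percent column (default
#'   `"mgmt_ihc_pct"`).
#' @param marker IHC marker for dichotomization (default `"MGMT"`).
#' @param p_method passed to [spearman_association()].
#' @return list as from [spearman_association()], plus `serostatus` (the
#'   per-subject merged table).
#' @export
serology_ihc_association <- function(calls, clinical, peptides,
                                     ihc_column = "mgmt_ihc_pct",
                                     marker = "MGMT",
                                     p_method = "tapprox") {
  check_columns(clinical, c("subject_id", ihc_column), "clinical table")
  sub <- calls[calls$peptide %in% peptides, ]
  if (nrow(sub) == 0L) stop_ps("no calls for peptide(s) %s", paste(peptides, collapse = ", "))
  sero <- tapply(sub$positive, sub$serum_id, any)
  clin <- clinical[!is.na(clinical[[ihc_column]]), ]
  clin <- clin[clin$subject_id %in% names(sero), ]
  if (nrow(clin) == 0L) stop_ps("no subjects with both serology and IHC data")
  merged <- data.frame(
    subject_id = clin$subject_id,
    seropositive = as.logical(sero[clin$subject_id]),
    ihc_percent = clin[[ihc_column]],
    ihc_call = ihc_call(clin[[ihc_column]], marker),
    stringsAsFactors = FALSE
  )
  res <- spearman_association(as.integer(merged$seropositive),
                              as.integer(merged$ihc_call %in% c("positive", "high")),
                              p_method = p_method)
  res$serostatus <- merged
  res
}
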