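test_that("cut-off optimization matches the worked examples", {
  sep <- optimize_cutoff(c(5, 6, 7), c(1, 2, 3))
  expect_equal(sep$cutoff, 5)
  expect_equal(sep$max_difference, 1.0)
  expect_equal(sep$candidates_evaluated, 6L)

  expect_warning(same <- optimize_cutoff(c(1, 1, 1), c(1, 1, 1)), "degenerate")
  expect_equal(same$cutoff, 1)
  expect_equal(same$max_difference, 0)

  inter <- optimize_cutoff(c(2, 4, 6), c(1, 3, 5))
  expect_equal(inter$max_difference, 1 / 3)
  expect_equal(inter$cutoff, 2)  # ties broken toward the smallest candidate

  expect_error(optimize_cutoff(numeric(0), c(1, 2)), "non-empty")
})

test_that("cut-off optimizer equals exhaustive search and the objective re-evaluates", {
  set.seed(101)
  for (i in 1:100) {
    case <- round(rlnorm(sample(3:40, 1), 0.5, 1), 2)
    ctrl <- round(rlnorm(sample(3:60, 1), 0, 1), 2)
    got <- optimize_cutoff(case, ctrl)
    ora <- oracle_cutoff(case, ctrl)
    expect_equal(got$cutoff, ora$cutoff)
    expect_equal(got$max_difference, ora$max_difference)
    # re-evaluating the objective at the returned cut-off reproduces it
    expect_equal(mean(case >= got$cutoff) - mean(ctrl >= got$cutoff),
                 got$max_difference)
    # swapping the groups negates the objective landscape
    swapped <- optimize_cutoff(ctrl, case)
    all_c <- sort(unique(c(case, ctrl)))
    min_obj <- min(vapply(all_c, function(c)
      mean(case >= c) - mean(ctrl >= c), numeric(1)))
    expect_equal(swapped$max_difference, -min_obj)
  }
})

test_that("classification is boundary-inclusive and skips missing SNR", {
  prof <- make_profiles(c(5.5, 5.49, NA), c(0.1), peptide = "PEP-01")
  cuts <- data.frame(peptide = "PEP-01", cutoff = 5.5)
  calls <- classify_calls(prof, cuts)
  expect_equal(nrow(calls), 3)  # the NA profile emits no call
  expect_equal(calls$positive[calls$serum_id == "case_001"], TRUE)
  expect_equal(calls$positive[calls$serum_id == "case_002"], FALSE)
  expect_error(classify_calls(transform(prof, peptide = "OTHER"), cuts),
               "no cut-off for peptide 'OTHER'")
})

test_that("Fisher exact p matches the published counts and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(2, 2, 2, 2), 1.0)
  # published screening-table rows: counts (positive, negative) per group
  expect_equal(fisher_exact_2x2(8, 59, 7, 304), 0.0015, tolerance = 1e-3)
  expect_equal(fisher_exact_2x2(30, 37, 19, 292), 9.29e-14, tolerance = 1e-2)
  expect_equal(fisher_exact_2x2(18, 49, 16, 295), 8.48e-07, tolerance = 1e-2)

  set.seed(77)
  for (i in 1:60) {
    tab <- as.vector(stats::rmultinom(1, size = sample(4:60, 1), prob = runif(4, 0.05, 1)))
    got <- suppressWarnings(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]))
    ora <- oracle_fisher(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got, ora, tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(got, min(1, ft), tolerance = 1e-7)
  }
  expect_warning(p0 <- fisher_exact_2x2(0, 5, 0, 7), "degenerate")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Bonferroni adjustment multiplies by the panel size and caps at 1", {
  expect_equal(bonferroni_adjust(0.001, m = 20), 0.02)
  expect_equal(bonferroni_adjust(0.1, m = 20), 1.0)
  expect_equal(bonferroni_adjust(rep(1, 3), m = 20), rep(1, 3))
  p <- c(0.04, 0.001, 0.5)
  adj <- bonferroni_adjust(p, m = 20)
  expect_equal(order(adj), order(p))     # order-preserving
  expect_true(all(adj >= p))             # never smaller than raw p
  expect_error(bonferroni_adjust(1.2, m = 2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(rep(0.1, 5), m = 3), "family size")
})

test_that("group comparison reproduces the published rate arithmetic", {
  # strongest peptide: 30/67 cases vs 19/311 controls
  calls <- rbind(make_calls("MGMT-02", 5.5, 30, 67, 19, 311),
                 make_calls("MGMT-04", 3.1, 18, 67, 16, 311),
                 make_calls("MGMT-18", 2.0, 16, 67, 15, 311))
  comp <- compare_groups(calls, m = 20)
  rendered <- render_comparison(comp)
  r02 <- rendered[rendered$peptide == "MGMT-02", ]
  expect_equal(r02$case, "30 (45%)")
  expect_equal(r02$control, "19 (6%)")
  expect_equal(r02$difference_pct, 39L)
  expect_equal(rendered$difference_pct[rendered$peptide == "MGMT-04"], 22L)
  expect_match(rendered$case[rendered$peptide == "MGMT-18"], "16 \\(24%\\)")
  expect_equal(comp$a + comp$b, rep(67L, 3))
  expect_equal(comp$c + comp$d, rep(311L, 3))
  expect_equal(comp$difference, comp$case_rate - comp$control_rate)
  expect_equal(comp$p_adjusted, pmin(1, 20 * comp$p_value))

  # identical groups: zero difference, p = 1
  null_calls <- make_calls("P", 1, 5, 20, 5, 20)
  nc <- compare_groups(null_calls)
  expect_equal(nc$difference, 0)
  expect_equal(nc$p_value, 1)
})

test_that("coverage is the seropositive fraction of the serum set", {
  cv <- coverage(rep(c(TRUE, FALSE), c(30, 37)))
  expect_equal(cv$coverage, 30 / 67, tolerance = 1e-12)
  expect_equal(coverage(rep(FALSE, 5))$coverage, 0)
  expect_equal(coverage(rep(TRUE, 4))$coverage, 1)
  expect_error(coverage(logical(0)), "empty")
})

test_that("longitudinal coverage drops after the simulated postoperative decay", {
  cfg <- sim_config(seed = 5, n_case = 60, n_control = 120,
                    postop_decay = 0.3, postop_fraction = 1)
  cohort <- generate_longitudinal(generate_cohort(cfg))
  prof <- build_profiles(cohort$manifest, cohort$layout, cfg$panel,
                         arrays = cohort$arrays)$profiles
  pre <- prof[prof$timepoint == "preoperative", ]
  cuts <- panel_cutoffs(pre)
  lng <- longitudinal_coverage(prof, cuts)
  cov <- lng$coverage[lng$coverage$group == "glioma", ]
  wide <- merge(cov[cov$timepoint == "preoperative", c("peptide", "coverage")],
                cov[cov$timepoint == "postop_day30", c("peptide", "coverage")],
                by = "peptide", suffixes = c("_pre", "_post"))
  expect_equal(nrow(wide), 20)
  # decay 0.3 pulls seropositive latent SNR well below the cut-offs
  expect_true(all(wide$coverage_post < wide$coverage_pre))
  expect_gt(mean(wide$coverage_pre - wide$coverage_post), 0.15)

  # trajectories exist for the multi-timepoint sera and flag seroreversion
  expect_gt(nrow(lng$trajectories), 0)
  expect_true("seroreversion" %in% lng$trajectories$transition)
  expect_error(longitudinal_coverage(transform(pre, timepoint = "weird"), cuts),
               "unknown timepoint")

  # single timepoint: coverage only, no trajectories
  single <- longitudinal_coverage(pre, cuts)
  expect_equal(nrow(single$trajectories), 0)
})

test_that("the highly responsive peptides are selected by adjusted p then difference", {
  comp <- data.frame(
    peptide = sprintf("P%02d", 1:6),
    difference = c(0.39, 0.22, 0.19, 0.12, 0.04, 0.19),
    p_adjusted = c(1e-10, 1e-5, 1e-4, 1e-3, 0.2, 1e-6)
  )
  expect_equal(select_top_peptides(comp, alpha = 0.05, k = 5),
               c("P01", "P02", "P03", "P06", "P04"))
  expect_equal(select_top_peptides(comp, alpha = 0.05, k = 2), c("P01", "P02"))
  expect_equal(select_top_peptides(comp, alpha = 1e-12), character(0))
})

test_that("recovered rates converge to the true prevalences as n grows", {
  cfg <- sim_config(seed = 9, n_case = 500, n_control = 500,
                    panel = c("PEP-A"), prevalence_case = 0.45,
                    prevalence_control = 0.06)
  cohort <- generate_cohort(cfg)
  prof <- build_profiles(cohort$manifest, cohort$layout, cfg$panel,
                         arrays = cohort$arrays)$profiles
  cuts <- panel_cutoffs(prof)
  comp <- compare_groups(classify_calls(prof, cuts), m = 1)
  expect_equal(comp$case_rate, 0.45, tolerance = 0.12)
  expect_equal(comp$control_rate, 0.06, tolerance = 0.5)
})
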