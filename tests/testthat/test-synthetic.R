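test_that("configuration validation rejects impossible study conditions", {
  expect_error(sim_config(prevalence_case = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(snr_pos = c(meanlog = log(0.4), sdlog = 0.4)),
               "must exceed")
  expect_error(sim_config(snr_neg = c(meanlog = 0, sdlog = -1)), "positive")
  expect_error(sim_config(postop_decay = 0), "positive")
  expect_error(sim_config(baseline_hazard = -1), "positive")
  expect_error(sim_config(prevalence_case = c(BAD = 0.5), panel = c("P1", "P2")),
               "cover every panel peptide")
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(seed = 99, n_case = 6, n_control = 8)
  a <- generate_survival(generate_longitudinal(generate_cohort(cfg)))
  b <- generate_survival(generate_longitudinal(generate_cohort(cfg)))
  expect_identical(a$truth, b$truth)
  expect_identical(a$arrays, b$arrays)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$clinical, b$clinical)
  c_ <- generate_cohort(sim_config(seed = 100, n_case = 6, n_control = 8))
  expect_false(identical(a$arrays, c_$arrays))
})

test_that("the cut-off objective on null data equals the one-sided KS statistic", {
  # with equal prevalences the case and control SNR distributions are
  # identical, so the maximized rate difference is exactly the one-sided
  # two-sample Kolmogorov-Smirnov statistic between the two SNR samples;
  # its Brownian-bridge expectation at n = m = 200 is sqrt(pi/8)/10 ~ 0.063
  diffs <- numeric(6)
  for (s in seq_len(6)) {
    cfg <- sim_config(seed = 200 + s, n_case = 200, n_control = 200,
                      panel = "PEP-A", prevalence_case = 0.2,
                      prevalence_control = 0.2)
    cohort <- generate_cohort(cfg)
    prof <- build_profiles(cohort$manifest, cohort$layout, cfg$panel,
                           arrays = cohort$arrays)$profiles
    case <- prof$snr[prof$group == "glioma"]
    ctrl <- prof$snr[prof$group == "healthy"]
    got <- optimize_cutoff(case, ctrl)
    ks <- max(vapply(sort(unique(c(case, ctrl))), function(c)
      mean(case >= c) - mean(ctrl >= c), numeric(1)))
    expect_equal(got$max_difference, ks)
    diffs[s] <- got$max_difference
  }
  expect_lt(mean(diffs), 0.12)
  expect_gt(mean(diffs), 0)
})

test_that("recovered coverage tracks the configured prevalences", {
  # averaged over seeds so the check measures recovery bias, not the
  # binomial noise of a single draw (sd ~ 0.022 per seed at n = 500)
  case_cov <- ctrl_cov <- numeric(3)
  for (s in 1:3) {
    cfg <- sim_config(seed = 40 + s, n_case = 500, n_control = 500,
                      panel = "PEP-A", prevalence_case = 0.45,
                      prevalence_control = 0.06)
    cohort <- generate_cohort(cfg)
    prof <- build_profiles(cohort$manifest, cohort$layout, cfg$panel,
                           arrays = cohort$arrays)$profiles
    calls <- classify_calls(prof, panel_cutoffs(prof))
    case_cov[s] <- coverage(calls$positive[calls$group == "glioma"])$coverage
    ctrl_cov[s] <- coverage(calls$positive[calls$group == "healthy"])$coverage
  }
  expect_lt(abs(mean(case_cov) - 0.45), 0.05)
  expect_lt(abs(mean(ctrl_cov) - 0.06), 0.05)
})

test_that("longitudinal dynamics rebound the truly seropositive peptides only", {
  cfg <- sim_config(seed = 55, n_case = 40, n_control = 40,
                    postop_fraction = 1, recurrence_fraction = 1,
                    postop_decay = 0.3, recurrence_rebound = 1.0)
  cohort <- generate_longitudinal(generate_cohort(cfg))
  tr <- cohort$truth
  pre <- tr[tr$timepoint == "preoperative", ]
  rec <- tr[tr$timepoint == "recurrence", ]
  m <- merge(pre, rec, by = c("serum_id", "peptide"), suffixes = c("_pre", "_rec"))
  pos <- m[m$status_pre, ]
  neg <- m[!m$status_pre, ]
  expect_equal(pos$latent_snr_rec, pos$latent_snr_pre)  # rebound factor 1
  expect_equal(neg$latent_snr_rec, neg$latent_snr_pre)  # low level unchanged
  d30 <- tr[tr$timepoint == "postop_day30", ]
  m2 <- merge(pre, d30, by = c("serum_id", "peptide"), suffixes = c("_pre", "_d30"))
  expect_equal(m2$latent_snr_d30, 0.3 * m2$latent_snr_pre)
  expect_error(generate_longitudinal(
    generate_cohort(sim_config(seed = 1, n_case = 0, n_control = 4))),
    "no preoperative cases")
})

test_that("survival generation respects the configured censoring regimes", {
  cfg_all <- sim_config(seed = 61, n_case = 30, n_control = 10,
                        censoring_rate = 1)
  all_cens <- generate_survival(generate_cohort(cfg_all))$clinical
  expect_true(all(all_cens$event == 0))
  # the survival module rejects an all-censored cohort, as specified
  expect_error(logrank_test(all_cens$rfs_days, all_cens$event,
                            all_cens$serostatus_true), "no events")
  expect_error(cox_fit(transform(all_cens, time = rfs_days),
                       "age_ge65"), "no events")

  cfg_none <- sim_config(seed = 62, n_case = 200, n_control = 10,
                         censoring_rate = 0)
  none <- generate_survival(generate_cohort(cfg_none))$clinical
  expect_true(all(none$event == 1))

  cfg_mid <- sim_config(seed = 63, n_case = 400, n_control = 10,
                        censoring_rate = 0.3)
  mid <- generate_survival(generate_cohort(cfg_mid))$clinical
  expect_lt(abs(mean(mid$event == 0) - 0.3), 0.08)
  # dates are consistent with the recorded RFS
  rfs <- compute_rfs(mid$surgery_date, mid$recurrence_date,
                     mid$last_followup_date)
  expect_equal(rfs$time, mid$rfs_days)
  expect_equal(rfs$event, mid$event)
})

test_that("seropositive cohorts generated with HR > 1 recur earlier", {
  cfg <- sim_config(seed = 71, n_case = 300, n_control = 10, log_hr = log(3))
  cl <- generate_survival(generate_cohort(cfg))$clinical
  km_pos <- km_estimate(cl$rfs_days[cl$serostatus_true],
                        cl$event[cl$serostatus_true])
  km_neg <- km_estimate(cl$rfs_days[!cl$serostatus_true],
                        cl$event[!cl$serostatus_true])
  # seronegative survival dominates seropositive survival at the median
  med <- function(km) km$time[which(km$survival <= 0.5)[1]]
  expect_gt(med(km_neg), med(km_pos))
  lr <- logrank_test(cl$rfs_days, cl$event, cl$serostatus_true)
  expect_lt(lr$p_value, 0.01)
})
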