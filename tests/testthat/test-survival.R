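test_that("RFS derives from surgery, recurrence and follow-up dates", {
  rec <- compute_rfs("2012-01-01", "2012-03-01", NA)
  expect_equal(rec$time, 60)
  expect_equal(rec$event, 1L)

  cens <- compute_rfs("2012-01-01", NA, "2013-01-01")
  expect_equal(cens$time, 366)   # 2012 is a leap year
  expect_equal(cens$event, 0L)

  expect_error(compute_rfs("2012-01-01", "2011-12-31", NA), "before surgery")
  expect_error(compute_rfs("2012-01-01", "2012-01-01", NA), "zero or negative")
  expect_error(compute_rfs("2012-01-01", NA, NA), "missing follow-up")
})

test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  all_cens <- km_estimate(c(3, 7, 12), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))

  # times {1 event, 2 censored, 3 event}: S(1) = 2/3, S(3) = 0
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)

  set.seed(21)
  time <- round(rexp(40, 1 / 10) + 0.5, 1)
  event <- rbinom(40, 1, 0.6)
  km1 <- km_estimate(time, event)
  ora <- oracle_km(time, event)
  got <- km1[km1$n_event > 0, c("time", "survival")]
  expect_equal(got$time, ora$time)
  expect_equal(got$survival, ora$survival, tolerance = 1e-12)

  # with no censoring KM equals the empirical survival function
  km2 <- km_estimate(time, rep(1, 40))
  expect_equal(km2$survival, 1 - ecdf(time)(km2$time), tolerance = 1e-12)

  # duplicating every record leaves the curve unchanged
  km3 <- km_estimate(rep(time, 2), rep(event, 2))
  expect_equal(unique(km3[km3$n_event > 0, c("time", "survival")]),
               got, ignore_attr = TRUE)

  expect_error(km_estimate(numeric(0), numeric(0)), "no records")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank test is symmetric, null on identical groups, powered under separation", {
  time <- c(2, 4, 6, 8, 10)
  event <- c(1, 1, 0, 1, 0)
  ident <- logrank_test(c(time, time), c(event, event), rep(c("A", "B"), each = 5))
  expect_equal(ident$statistic, 0, tolerance = 1e-10)
  expect_equal(ident$p_value, 1, tolerance = 1e-6)

  set.seed(3)
  early <- rexp(20, 1 / 5)
  late <- rexp(20, 1 / 50)
  sep <- logrank_test(c(early, late), rep(1, 40), rep(c("A", "B"), each = 20))
  expect_lt(sep$p_value, 0.05)
  swapped <- logrank_test(c(late, early), rep(1, 40), rep(c("A", "B"), each = 20))
  expect_equal(sep$statistic, swapped$statistic, tolerance = 1e-10)

  expect_error(logrank_test(time, rep(0, 5), c("A", "A", "B", "B", "B")),
               "no events")
  expect_error(logrank_test(time, event, rep("A", 5)), "two groups")
})

test_that("Cox fit matches the brute-force partial-likelihood maximizer on small data", {
  set.seed(17)
  compared <- 0
  while (compared < 25) {
    d <- random_cox_instance(sample(4:8, 1))
    beta_star <- oracle_cox_grid(d$time, d$event, d$x)
    if (is.na(beta_star)) next  # monotone likelihood: no finite maximizer
    fit <- tryCatch(suppressWarnings(cox_fit(d, "x")), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    expect_lt(abs(fit$coefficients$coef - beta_star), 1e-4)
    expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))
    expect_true(fit$coefficients$ci_lower < fit$coefficients$hr &&
                  fit$coefficients$hr < fit$coefficients$ci_upper)
    compared <- compared + 1
  }
})

test_that("Cox fit is null on exchangeable groups and rejects degenerate input", {
  # mirror-image data: the two covariate levels see identical outcomes
  d <- data.frame(time = rep(c(3, 5, 9, 14), 2),
                  event = rep(c(1, 0, 1, 1), 2),
                  x = rep(c(0, 1), each = 4))
  fit <- cox_fit(d, "x")
  expect_equal(fit$coefficients$coef, 0, tolerance = 1e-8)
  expect_equal(fit$coefficients$hr, 1, tolerance = 1e-8)

  expect_error(cox_fit(transform(d, x = 1), "x"), "constant")
  expect_error(cox_fit(transform(d, event = 0), "x"), "no events")

  # perfect separation is flagged, not silently reported
  ps <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                   event = c(1, 1, 1, 1, 1, 1),
                   x = c(1, 1, 1, 0, 0, 0))
  expect_warning(bad <- cox_fit(ps, "x"), "monotone")
  expect_false(bad$converged)
})

test_that("Breslow and Efron tie handling agree in the absence of ties", {
  set.seed(23)
  d <- data.frame(time = rexp(30) + 0.001, event = rbinom(30, 1, 0.7),
                  x = rbinom(30, 1, 0.5))
  d$time <- d$time + seq_len(30) * 1e-6  # guarantee unique times
  b <- cox_fit(d, "x", ties = "breslow")
  e <- cox_fit(d, "x", ties = "efron")
  expect_equal(b$coefficients$coef, e$coefficients$coef, tolerance = 1e-8)
})

test_that("forward selection finds the prognostic covariate and skips duplicates", {
  set.seed(29)
  n <- 150
  x_true <- rbinom(n, 1, 0.5)
  noise1 <- rbinom(n, 1, 0.5)
  noise2 <- rnorm(n)
  time <- rexp(n, rate = 0.01 * exp(log(3) * x_true))
  cens <- rexp(n, rate = 0.004)
  d <- data.frame(time = pmin(time, cens), event = as.integer(time <= cens),
                  biomarker = x_true, noise1 = noise1, noise2 = noise2)
  fs <- forward_selection(d, c("noise1", "biomarker", "noise2"))
  expect_equal(fs$selected[1], "biomarker")
  expect_true(all(fs$steps$p_value[fs$steps$entered] < 0.05))

  # a duplicated covariate column adds no likelihood: only one copy enters
  d$biomarker_copy <- d$biomarker
  expect_warning(fs2 <- forward_selection(d, c("biomarker", "biomarker_copy")),
                 "singular")
  expect_equal(fs2$selected, "biomarker")

  # constant candidates are skipped with a warning, not fatal
  d$flat <- 1
  w <- capture_warnings(fs3 <- forward_selection(d, c("flat", "biomarker")))
  expect_match(w, "skipped 'flat'", all = FALSE)
  expect_equal(fs3$selected, "biomarker")
})

test_that("all-noise candidates rarely enter the selection", {
  set.seed(37)
  entered <- 0L
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    n <- 60
    d <- data.frame(time = rexp(n, 0.02), event = rbinom(n, 1, 0.8),
                    z1 = rbinom(n, 1, 0.5), z2 = rnorm(n), z3 = rbinom(n, 1, 0.3))
    fs <- suppressWarnings(forward_selection(d, c("z1", "z2", "z3")))
    if (length(fs$selected) > 0) entered <- entered + 1L
  }
  # P(any of 3 null candidates enters) ~ 1 - 0.95^3 ~ 0.14
  expect_lt(entered / n_seeds, 0.4)
})
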