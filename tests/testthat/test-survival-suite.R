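test_that("Kaplan-Meier estimates match hand product-limit computations", {
  no_events <- km_estimate(tibble::tibble(time = c(5, 9, 12), event = FALSE))
  expect_true(all(no_events$surv == 1))

  two <- km_estimate(tibble::tibble(time = c(1, 2), event = TRUE))
  expect_equal(two$surv[two$time == 1], 0.5)
  expect_equal(two$surv[two$time == 2], 0)

  # event at 1, censor at 2, event at 3
  mix <- km_estimate(tibble::tibble(time = c(1, 2, 3), event = c(TRUE, FALSE, TRUE)))
  expect_equal(mix$surv[mix$time == 1], 2 / 3)
  expect_equal(mix$surv[mix$time == 3], 0)
  expect_equal(mix$cum_event, 1 - mix$surv)

  # against the independent oracle with censoring, random data
  set.seed(404)
  d <- tibble::tibble(time = sample(1:30, 25, replace = FALSE),
                      event = runif(25) < 0.6)
  km <- km_estimate(d)
  expect_equal(km$surv[km$n_event > 0],
               oracle_km_surv(d$time, d$event, km$time[km$n_event > 0]))

  # with no censoring KM equals the empirical survival function exactly
  d2 <- tibble::tibble(time = sample(1:40, 20), event = TRUE)
  km2 <- km_estimate(d2)
  emp <- vapply(km2$time, function(t0) mean(d2$time > t0), numeric(1))
  expect_equal(km2$surv, emp)
})

test_that("log-rank test matches observed-minus-expected arithmetic", {
  base <- tibble::tibble(time = c(2, 4, 6, 8), event = c(TRUE, TRUE, FALSE, TRUE),
                         group = "a")
  dup <- dplyr::bind_rows(base, base |> dplyr::mutate(group = "b"))
  lr <- logrank_test(dup)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$df, 1)

  # hand-worked two-group example
  d <- tibble::tibble(
    time = c(1, 3, 5, 7, 2, 4, 6, 8),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    group = rep(c("a", "b"), each = 4)
  )
  lr2 <- logrank_test(d)
  expect_equal(lr2$statistic,
               oracle_logrank_chisq(d$time, d$event, d$group),
               tolerance = 1e-8)
  expect_error(logrank_test(base), "two groups")
})

test_that("log-rank detects a threefold hazard difference", {
  set.seed(405)
  hits <- vapply(1:60, function(r) {
    d <- tibble::tibble(
      time = c(rexp(120, 1), rexp(120, 3)),
      event = TRUE,
      group = rep(c("a", "b"), each = 120)
    )
    logrank_test(d)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("event rates per 100 person-years are exact arithmetic", {
  expect_equal(round(event_rate_per_100py(582, 1496), 1), 38.9)
  expect_equal(event_rate_per_100py(0, 10), 0)
  expect_equal(event_rate_per_100py(10, 25), 40)
  expect_error(event_rate_per_100py(5, 0), "> 0")
})

test_that("Cox coefficients match brute-force partial-likelihood maximization", {
  set.seed(406)
  for (rep in 1:12) {
    # redraw degenerate designs whose partial likelihood has no interior
    # maximum (monotone likelihood / separation)
    repeat {
      n <- sample(4:8, 1)
      d <- random_small_cox_data(n, binary = rep %% 2 == 0)
      if (oracle_cox_identifiable(d)) break
    }
    fit <- fit_cox(d, ~x)
    expect_equal(fit$tidy$estimate, oracle_cox_coef(d$time, d$event, d$x),
                 tolerance = 1e-4)
  }
})

test_that("integer case weights are equivalent to row duplication", {
  set.seed(407)
  d <- random_small_cox_data(7)
  d$w <- sample(1:3, 7, replace = TRUE)
  dup <- d[rep(seq_len(7), d$w), ]
  # duplication creates event-time ties, so the exact equivalence is a
  # Breslow property; the weighted data itself has no ties
  fit_w <- fit_cox(d, ~x, weights = "w", ties = "breslow")
  fit_d <- fit_cox(dup, ~x, ties = "breslow")
  expect_equal(fit_w$tidy$estimate, fit_d$tidy$estimate, tolerance = 1e-8)
  # and the weighted fit also matches the weighted brute-force oracle
  expect_equal(fit_w$tidy$estimate, oracle_cox_coef(d$time, d$event, d$x, d$w),
               tolerance = 1e-4)
})

test_that("a permuted covariate carries no signal", {
  set.seed(408)
  n <- 500
  d <- tibble::tibble(time = rexp(n), event = runif(n) < 0.7, x = rnorm(n))
  d$x <- sample(d$x)
  fit <- fit_cox(d, ~x)
  expect_lt(abs(fit$tidy$estimate), 3 * fit$tidy$se)
})

test_that("robust and model SEs agree for independent single-row subjects", {
  set.seed(409)
  n <- 2000
  x <- rnorm(n)
  d <- tibble::tibble(id = 1:n, time = rexp(n, exp(0.3 * x)),
                      event = TRUE, x = x)
  fit <- fit_cox(d, ~x, cluster = "id")
  expect_lt(abs(fit$tidy$robust_se / fit$tidy$se - 1), 0.15)
})

test_that("models A-C expose the study's covariate structure", {
  sim <- generate_score_panel(truth_params(600, seed = 17))
  a <- fit_cox_model(sim$panel, "A")
  expect_equal(a$tidy$term, "mos10")
  b <- fit_cox_model(sim$panel, "B")
  expect_true(all(c("mos10", "age10") %in% b$tidy$term))
  expect_true(any(grepl("hfpsi_base", b$tidy$term)))
  expect_true(any(grepl("cci_cat", b$tidy$term)))
  cc <- fit_cox_model(sim$panel, "C")
  expect_true("lagcum10" %in% cc$tidy$term)
  expect_true(cc$robust)
  # HR/CI invariants
  expect_equal(cc$tidy$hr, exp(cc$tidy$estimate))
  expect_true(all(cc$tidy$conf_low <= cc$tidy$hr & cc$tidy$hr <= cc$tidy$conf_high))
})

test_that("model C recovers the truth when exposure is constant and unconfounded", {
  p <- truth_params(2000, titration_mean_pp = 0, titration_sd_pp = 0,
                    noise_sd_pp = 0, feedback_hfpsi_on_mos = 0,
                    feedback_mos_on_hfpsi = 0,
                    beta_hfpsi = c(0, 0, 0), beta_cci = c(0, 0),
                    beta_age_per10 = 0, seed = 23)
  panel <- generate_score_panel(p)$panel
  cc <- fit_cox_model(panel, "C")
  est <- cc$tidy[cc$tidy$term == "lagcum10", ]
  expect_lt(abs(est$estimate - p$beta_mos_per10), 2 * est$robust_se)
})

test_that("Schoenfeld residual check behaves at the boundaries", {
  set.seed(410)
  n <- 300
  d <- tibble::tibble(time = rexp(n), event = runif(n) < 0.8, x = rnorm(n))
  fit <- fit_cox(d, ~x)
  ph <- schoenfeld_ph_test(fit)
  expect_true(all(c("x", "GLOBAL") %in% ph$term))
  expect_true(all(ph$p_value >= 0 & ph$p_value <= 1))

  # a single-event dataset cannot support the residual regression (the fit
  # itself is degenerate and non-convergent, hence the suppression)
  single <- tibble::tibble(time = c(1, 2), event = c(TRUE, FALSE), x = c(0, 1))
  expect_error(schoenfeld_ph_test(suppressWarnings(fit_cox(single, ~x))),
               "at least 2 events")
})
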