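test_that("product-limit estimates match hand-worked tables", {
  # three deaths, no censoring
  km1 <- km_estimate(data.frame(os_months = c(10, 20, 30), event = 1))
  expect_equal(km1$curve$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km1$median, 20)

  # death at 5 and 10 with a censored patient at 7: risk set at 10 is 1
  km2 <- km_estimate(data.frame(os_months = c(5, 7, 10), event = c(1, 0, 1)))
  expect_equal(km2$curve$survival[km2$curve$time == 5], 2 / 3)
  expect_equal(km2$curve$survival[km2$curve$time == 10], 0)
  expect_equal(km2$median, 10)

  # tied deaths, interleaved censoring: S = 4/6, then 4/6 * 2/3 = 4/9, then 0
  km3 <- km_estimate(data.frame(
    os_months = c(6, 6, 7, 9, 11, 12),
    event = c(1, 1, 0, 1, 0, 1)
  ))
  expect_equal(km3$curve$survival[km3$curve$time == 6], 4 / 6)
  expect_equal(km3$curve$survival[km3$curve$time == 9], 4 / 9)
  expect_equal(km3$curve$survival[km3$curve$time == 12], 0)
  expect_equal(km3$median, 9)
})

test_that("the estimator agrees with an independent product-limit loop", {
  set.seed(99)
  time <- round(rexp(40, 0.05), 1)
  event <- rbinom(40, 1, 0.7)
  km <- km_estimate(data.frame(os_months = time, event = event))
  oracle <- manual_km(time, event)
  merged <- merge(km$curve, oracle, by = "time")
  expect_equal(merged$survival.x, merged$survival.y)
})

test_that("without censoring the curve is the empirical survival function", {
  set.seed(12)
  t <- sort(round(rexp(25, 0.04), 2))
  km <- km_estimate(data.frame(os_months = t, event = 1))
  emp <- vapply(km$curve$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$curve$survival, emp)
})

test_that("fully censored records keep survival at 1 with undefined median", {
  km <- km_estimate(data.frame(os_months = c(5, 10, 15), event = 0))
  expect_true(all(km$curve$survival == 1))
  expect_true(is.na(km$median))
  expect_error(km_estimate(data.frame(os_months = -1, event = 1)), "non-negative")
  expect_error(km_estimate(data.frame(os_months = 5, event = 2)), "event")
})

tertile_fixture <- function(g_values, ids = sprintf("p%02d", seq_along(g_values))) {
  rows <- lapply(seq_along(g_values), function(i) {
    fake_fit_row(ids[i], "fitted", "gx", g = g_values[i])
  })
  do.call(fake_fit_table, rows)
}

test_that("nine distinct growth rates split into tertiles of three", {
  g <- c(0.0001, 0.0002, 0.0003, 0.001, 0.002, 0.003, 0.01, 0.02, 0.03)
  fits <- tertile_fixture(g)
  surv <- data.frame(patient_id = fits$patient_id,
                     os_months = 50 - seq_along(g), event = 1)
  ta <- tertile_analysis(fits, surv)
  expect_equal(ta$summary$n, c(3, 3, 3))
  expect_equal(sort(ta$assignments$tertile), rep(1:3, each = 3))
  # Q1 holds the smallest g values
  expect_setequal(ta$assignments$patient_id[ta$assignments$tertile == 1],
                  fits$patient_id[order(g)[1:3]])
})

test_that("tertile membership is invariant to monotone transforms of g", {
  set.seed(44)
  g <- rlnorm(30, log(0.002), 1)
  fits1 <- tertile_fixture(g)
  fits2 <- tertile_fixture(exp(g))  # strictly monotone transform
  surv <- data.frame(patient_id = fits1$patient_id,
                     os_months = runif(30, 5, 60), event = 1)
  t1 <- tertile_analysis(fits1, surv)
  t2 <- tertile_analysis(fits2, surv)
  expect_equal(t1$assignments$tertile, t2$assignments$tertile)
})

test_that("equal growth rates fall back to a stable near-equal split", {
  fits <- tertile_fixture(rep(0.002, 7))
  surv <- data.frame(patient_id = fits$patient_id, os_months = 1:7, event = 1)
  ta <- tertile_analysis(fits, surv)
  expect_equal(sort(table(ta$assignments$tertile), decreasing = TRUE),
               sort(table(cut(1:7, 3, labels = FALSE)), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_true(all(1:3 %in% ta$assignments$tertile))
})

test_that("missing survival linkage is reported with the orphan ids", {
  fits <- tertile_fixture(c(0.001, 0.002, 0.003, 0.004))
  surv <- data.frame(patient_id = fits$patient_id[1:2],
                     os_months = c(10, 20), event = 1)
  expect_error(tertile_analysis(fits, surv), "p03.*p04|p03, p04")
})

test_that("dx patients overlay the best tertile; empty dx set is not an error", {
  set.seed(77)
  n <- 30
  g <- rlnorm(n, log(0.002), 1)
  rows <- lapply(1:n, function(i) fake_fit_row(sprintf("g%02d", i), "fitted", "gx", g = g[i]))
  dx_rows <- lapply(1:10, function(i) fake_fit_row(sprintf("d%02d", i), "fitted", "dx", d = 0.01))
  fits <- do.call(fake_fit_table, c(rows, dx_rows))
  surv <- data.frame(
    patient_id = fits$patient_id,
    os_months = pmin(rexp(n + 10, 1 / 30), 60),
    event = as.integer(rexp(n + 10, 1 / 30) <= 60)
  )
  surv$os_months <- pmin(rexp(n + 10, 1 / 30), 60)
  surv$event <- as.integer(surv$os_months < 60)
  ta <- tertile_analysis(fits, surv)
  ov <- dx_overlay(fits, surv, ta)
  expect_equal(ov$n_dx, 10)
  expect_true(is.finite(ov$logrank_chisq))
  expect_true(ov$logrank_p > 0 && ov$logrank_p <= 1)

  no_dx <- do.call(fake_fit_table, rows)
  ov0 <- dx_overlay(no_dx, surv, ta)
  expect_equal(ov0$n_dx, 0)
  expect_null(ov0$curve)
})

test_that("a planted positive log-hazard on log g makes fitted g and OS discordant", {
  trial <- simulate_trial(trial_config(n_experimental = 80, n_control = 40),
                          seed = 55)
  fits <- fit_cohort(trial$measurements)
  g <- collect_g(fits, impute_dx = FALSE)
  merged <- merge(g, trial$survival, by = "patient_id")
  merged <- merged[merged$event == 1, ]
  expect_gt(nrow(merged), 20)
  expect_lt(cor(merged$g, merged$os_months, method = "spearman"), 0)
})
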