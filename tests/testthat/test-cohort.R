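test_that("classification counts and denominators follow the table conventions", {
  fits <- fake_fit_table(
    fake_fit_row("a1", "insufficient_data"),
    fake_fit_row("a2", "insufficient_data"),
    fake_fit_row("a3", "fitted", "dx", d = 0.01),
    fake_fit_row("a4", "fitted", "dx", d = 0.02),
    fake_fit_row("a5", "fitted", "dx", d = 0.03),
    fake_fit_row("a6", "fitted", "gd", g = 0.001, d = 0.01),
    fake_fit_row("a7", "fitted", "gd", g = 0.002, d = 0.01),
    fake_fit_row("a8", "fitted", "gd", g = 0.003, d = 0.01),
    fake_fit_row("a9", "fitted", "gd", g = 0.004, d = 0.01),
    fake_fit_row("b1", "no_fit")
  )
  cs <- classify_cohort(fits)
  expect_equal(unname(cs$counts[, "all"]),
               c(2, 3, 0, 4, 0, 1))  # insufficient, dx, gd_theta, gd, gx, no_fit
  expect_equal(unname(cs$fractions$sufficiency[["all"]]), 8 / 10)
  expect_equal(unname(cs$fractions$total_fit[["all"]]), 7 / 8)
  expect_output(print(cs), "total fit")
})

test_that("classification handles empty input and rejects duplicate patients", {
  empty <- fake_fit_table(fake_fit_row("x", "fitted", "gx", g = 0.001))[0, ]
  class(empty) <- c("growth_fit_table", "data.frame")
  cs <- classify_cohort(empty)
  expect_true(all(cs$counts == 0))
  dup <- fake_fit_table(
    fake_fit_row("same", "fitted", "gx", g = 0.001),
    fake_fit_row("same", "no_fit")
  )
  expect_error(classify_cohort(dup), "duplicate patient_id.*same")
})

test_that("observed class fractions track generating probabilities", {
  probs <- c(insufficient = 0, dx = 0.2, gd_theta = 0.1, gd = 0.45,
             gx = 0.2, no_fit = 0.05)
  set.seed(404)
  n <- 400
  draws <- sample(names(probs), n, replace = TRUE, prob = probs)
  fits <- fake_fit_table(fake_fit_row("tmp", "no_fit"))[0, ]
  rows <- lapply(seq_len(n), function(i) {
    cl <- draws[i]
    if (cl == "no_fit") fake_fit_row(paste0("p", i), "no_fit")
    else fake_fit_row(paste0("p", i), "fitted", cl, g = 0.001, d = 0.01)
  })
  fits <- do.call(fake_fit_table, rows)
  cs <- classify_cohort(fits)
  for (cl in c("dx", "gd_theta", "gd", "gx", "no_fit")) {
    sd3 <- 3 * sqrt(probs[[cl]] * (1 - probs[[cl]]) / n)
    expect_lt(abs(cs$counts[cl, "all"] / n - probs[[cl]]), sd3 + 1e-12)
  }
})

test_that("g collection imputes dx tumors only when asked", {
  fits <- fake_fit_table(
    fake_fit_row("p1", "fitted", "dx", d = 0.01),
    fake_fit_row("p2", "fitted", "gd", g = 0.003, d = 0.01),
    fake_fit_row("p3", "fitted", "gx", g = 0.005),
    fake_fit_row("p4", "insufficient_data"),
    fake_fit_row("p5", "no_fit")
  )
  on <- collect_g(fits, impute_dx = TRUE)
  expect_equal(on$g[on$patient_id == "p1"], 1e-4)
  expect_equal(on$g[on$patient_id == "p2"], 0.003)
  expect_setequal(on$patient_id, c("p1", "p2", "p3"))
  off <- collect_g(fits, impute_dx = FALSE)
  expect_setequal(off$patient_id, c("p2", "p3"))
  expect_error(collect_g(fits, impute_value = -1), "positive")
})

test_that("imputation can only lower the median g", {
  fits <- fake_fit_table(
    fake_fit_row("p1", "fitted", "dx", d = 0.01),
    fake_fit_row("p2", "fitted", "dx", d = 0.02),
    fake_fit_row("p3", "fitted", "gd", g = 0.003, d = 0.01),
    fake_fit_row("p4", "fitted", "gx", g = 0.005),
    fake_fit_row("p5", "fitted", "gx", g = 0.001)
  )
  with_imp <- median(collect_g(fits, impute_dx = TRUE)$g)
  without <- median(collect_g(fits, impute_dx = FALSE)$g)
  expect_lte(with_imp, without)
})

test_that("rank-sum comparison matches brute-force enumeration and is symmetric", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)
  expect_equal(compare_groups(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  set.seed(11)
  for (i in 1:20) {
    a <- round(runif(3, 0, 100), 3)
    b <- round(runif(3, 0, 100), 3)
    cmp <- compare_groups(a, b)
    expect_equal(cmp$p_value, exact_ranksum_p(a, b))
    expect_equal(cmp$p_value, compare_groups(b, a)$p_value)
  }
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("large-sample comparison detects the planted arm effect", {
  set.seed(21)
  hits <- 0
  for (i in 1:50) {
    a <- rlnorm(180, log(0.0009), 1)
    b <- rlnorm(80, log(0.0023), 1)
    if (compare_groups(a, b)$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("null arm comparisons yield roughly uniform p-values", {
  set.seed(31)
  p <- replicate(300, {
    compare_groups(rlnorm(40, log(0.001), 1), rlnorm(20, log(0.001), 1))$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("subgroup comparisons test arms within each stratum and flag small cells", {
  set.seed(5)
  mk <- function(id, arm, visceral, g) {
    fake_fit_row(id, "fitted", "gx", g = g, arm = arm, visceral = visceral,
                 sensitivity = "sensitive")
  }
  rows <- list()
  for (i in 1:30) {
    # planted arm effect only in visceral disease
    rows[[length(rows) + 1]] <- mk(paste0("ev", i), "experimental", "yes",
                                   rlnorm(1, log(0.0005), 0.3))
    rows[[length(rows) + 1]] <- mk(paste0("cv", i), "control", "yes",
                                   rlnorm(1, log(0.004), 0.3))
    rows[[length(rows) + 1]] <- mk(paste0("en", i), "experimental", "no",
                                   rlnorm(1, log(0.002), 0.3))
    rows[[length(rows) + 1]] <- mk(paste0("cn", i), "control", "no",
                                   rlnorm(1, log(0.002), 0.3))
  }
  fits <- do.call(fake_fit_table, rows)
  out <- subgroup_comparisons(fits, strata = "visceral")
  yes_all <- out[out$stratum == "yes" & out$cohort == "all", ]
  no_all <- out[out$stratum == "no" & out$cohort == "all", ]
  expect_lt(yes_all$p_value, 0.001)
  expect_gt(no_all$p_value, 0.05)
  expect_error(subgroup_comparisons(fits, strata = "nonexistent"), "unknown stratum")

  # a cell below the minimum size is flagged, not tested
  small <- fits[fits$visceral == "yes" | fits$arm == "experimental", ]
  class(small) <- c("growth_fit_table", "data.frame")
  out2 <- subgroup_comparisons(small, strata = "visceral", min_n = 5)
  no_row <- out2[out2$stratum == "no" & out2$cohort == "all", ]
  expect_false(no_row$tested)
  expect_true(is.na(no_row$p_value))
})

test_that("doubling-time threshold fractions count and stay monotone", {
  out <- dt_threshold_fractions(c(0.001, 0.002, 0.003), thresholds = 0.0019)
  expect_equal(out$fraction, 1 / 3)
  defaults <- dt_threshold_fractions(c(0.001, 0.002, 0.003))
  expect_equal(defaults$doubling_days, log(2) / c(0.0019, 0.00095, 0.00063))
  expect_equal(round(defaults$doubling_days), c(365, 730, 1100))
  set.seed(8)
  g <- rlnorm(200, log(0.001), 1)
  fr <- dt_threshold_fractions(g, thresholds = sort(runif(5, 1e-4, 0.01)))
  expect_true(all(diff(fr$fraction) >= 0))  # larger threshold, larger fraction
  expect_equal(nrow(dt_threshold_fractions(numeric(0))), 0)
  expect_error(dt_threshold_fractions(g, thresholds = -1), "positive")
})
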