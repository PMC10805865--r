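test_that("sufficiency screen follows the two-scan 20% rule", {
  expect_equal(assess_sufficiency(numeric(0), numeric(0)), "insufficient")
  expect_equal(assess_sufficiency(0, 100), "insufficient")
  expect_equal(assess_sufficiency(c(0, 42), c(100, 115)), "insufficient")  # 15%
  expect_equal(assess_sufficiency(c(0, 42), c(100, 85)), "insufficient")   # -15%
  expect_equal(assess_sufficiency(c(0, 42), c(100, 125)), "sufficient")    # 25%
  expect_equal(assess_sufficiency(c(0, 42), c(100, 80)), "sufficient")     # exactly -20%
  expect_equal(assess_sufficiency(c(0, 42, 84), c(100, 99, 101)), "sufficient")
})

test_that("normalization divides by a positive baseline", {
  ns <- normalize_series(c(0, 42), c(100, 50))
  expect_equal(ns$f, c(1, 0.5))
  expect_equal(normalize_series(c(0, 42, 84), c(80, 80, 80))$f, c(1, 1, 1))
  expect_error(normalize_series(c(0, 42), c(0, 50)), "baseline")
  expect_error(normalize_series(c(0, 42), c(100, NA)), "non-finite")
  expect_error(normalize_series(c(0, 42, 42), c(100, 90, 80)), "increasing")
  expect_error(normalize_series(c(10, 42), c(100, 90)), "baseline")
})

test_that("each model recovers its own noiseless parameters to 1e-4", {
  cases <- list(
    list(kind = "dx", g = NULL, d = 0.005, theta = NULL),
    list(kind = "gx", g = 0.003, d = NULL, theta = NULL),
    list(kind = "gd", g = 0.002, d = 0.02, theta = NULL),
    list(kind = "gd_theta", g = 0.0025, d = 0.03, theta = 0.6)
  )
  for (cs in cases) {
    s <- make_series(cs$kind, g = cs$g, d = cs$d, theta = cs$theta)
    ns <- normalize_series(s$times, s$quantity)
    cand <- fit_single_model(ns$time, ns$f, cs$kind)
    expect_lte(cand$rss, 1e-10)
    truth <- c(g = cs$g, d = cs$d, theta = cs$theta)
    expect_equal(cand$params[names(truth)], truth, tolerance = 1e-4)
    # the composed pipeline also lands on the generating model
    fit <- growth_fit(s$times, s$quantity)
    expect_equal(fit$status, "fitted")
    expect_equal(fit$model, cs$kind)
  }
})

test_that("dx-only series with d = 0.005 at 6-weekly scans recovers d", {
  s <- make_series("dx", d = 0.005, times = seq(0, 210, by = 42))
  ns <- normalize_series(s$times, s$quantity)
  cand <- fit_single_model(ns$time, ns$f, "dx")
  expect_equal(unname(cand$params[["d"]]), 0.005, tolerance = 1e-4)
})

test_that("on monotone noiseless growth the richer gd candidate is inadmissible", {
  s <- make_series("gx", g = 0.004)
  fit <- growth_fit(s$times, s$quantity)
  expect_equal(fit$model, "gx")
  gd <- fit$candidates[["gd"]]
  expect_false(gd$admissible)
  # d is either pinned at its bound or not significant at the 0.1 gate
  expect_true(gd$boundary || gd$p_values[["d"]] >= 0.1)
})

test_that("too few points for a kind yields no candidate, not an error", {
  expect_null(fit_single_model(c(0, 42), c(1, 0.5), "gd"))
  expect_null(fit_single_model(c(0, 42, 84), c(1, 0.7, 0.6), "gd_theta"))
  expect_error(fit_single_model(c(0, 42, NA), c(1, 0.7, 0.6), "gd"),
               "non-finite")
})

test_that("selection keeps the admissible minimum-AIC candidate", {
  mk <- function(model, aic, admissible = TRUE) {
    list(model = model, aic = aic, admissible = admissible,
         params = c(g = 0.001), rss = 0.01)
  }
  expect_equal(select_model(list(mk("dx", -50), mk("gd", -48)))$model, "dx")
  expect_equal(select_model(list(mk("gd", -48, admissible = FALSE),
                                 mk("gx", -40)))$model, "gx")
  expect_null(select_model(list()))
  expect_null(select_model(list(mk("gd", -48, admissible = FALSE))))
  # AIC tie breaks to fewer parameters, then fixed model order
  expect_equal(select_model(list(mk("gd", -50), mk("gx", -50)))$model, "gx")
  expect_equal(select_model(list(mk("gx", -50), mk("dx", -50)))$model, "dx")
})

test_that("the per-patient pipeline short-circuits and classifies correctly", {
  insuf <- growth_fit(c(0, 42), c(100, 115))
  expect_equal(insuf$status, "insufficient_data")
  expect_null(insuf$model)

  s <- make_series("dx", d = 0.01)
  expect_equal(growth_fit(s$times, s$quantity)$model, "dx")

  # trendless noise around baseline: nothing should pass the gate
  set.seed(101)
  no_fit_count <- 0
  for (i in 1:10) {
    q <- 100 * c(1, exp(rnorm(4, 0, 0.15)))
    fit <- growth_fit(default_times(5), q)
    if (fit$status == "no_fit") no_fit_count <- no_fit_count + 1
  }
  expect_gte(no_fit_count, 7)
})

test_that("nested richer models are never selected on noiseless simpler data", {
  set.seed(7)
  richer_rank <- c(dx = 1, gx = 1, gd = 2, gd_theta = 3)
  for (i in 1:30) {
    kind <- sample(c("dx", "gx", "gd"), 1)
    g <- runif(1, 5e-4, 0.01)
    d <- runif(1, 0.003, 0.05)
    s <- switch(kind,
      dx = make_series("dx", d = d),
      gx = make_series("gx", g = g),
      gd = make_series("gd", g = g, d = d)
    )
    fit <- growth_fit(s$times, s$quantity)
    expect_equal(fit$status, "fitted")
    expect_lte(richer_rank[[fit$model]], richer_rank[[kind]])
  }
})

test_that("fits are invariant to the measurement scale", {
  s <- make_series("gd", g = 0.002, d = 0.02)
  f1 <- growth_fit(s$times, s$quantity)
  f2 <- growth_fit(s$times, s$quantity * 3.7)
  expect_equal(f1$model, f2$model)
  expect_equal(f1$params, f2$params)
  expect_equal(f1$aic, f2$aic)
})

test_that("relabeling days as weeks scales the rates by exactly 7", {
  s <- make_series("gd", g = 0.004, d = 0.03)
  fd <- growth_fit(s$times, s$quantity)
  fw <- growth_fit(s$times / 7, s$quantity)
  expect_equal(unname(fw$params[["g"]] / fd$params[["g"]]), 7, tolerance = 1e-6)
  expect_equal(unname(fw$params[["d"]] / fd$params[["d"]]), 7, tolerance = 1e-6)
})

test_that("AIC is -2 logLik + 2k and the gate uses two-sided Wald p-values", {
  set.seed(3)
  s <- make_series("gd", g = 0.003, d = 0.02)
  q <- s$quantity * exp(rnorm(length(s$quantity), 0, 0.08))
  fit <- growth_fit(s$times, q)
  expect_equal(fit$status, "fitted")
  k <- length(fit$params)
  expect_equal(fit$aic, -2 * fit$logLik + 2 * k)
  n <- fit$n_points
  expect_equal(fit$logLik, -(n / 2) * (log(2 * pi * fit$rss / n) + 1))
  z <- abs(fit$params) / fit$se
  expect_equal(unname(fit$p_values), unname(2 * pnorm(-z)))
  expect_true(all(fit$p_values < 0.1))
})

test_that("growth_fit accepts the formula interface and methods are coherent", {
  s <- make_series("gd", g = 0.002, d = 0.02)
  df <- data.frame(day = s$times, quantity = s$quantity)
  fit <- growth_fit(quantity ~ day, data = df)
  expect_equal(fit$model, "gd")
  expect_equal(coef(fit), fit$params)
  expect_equal(fitted(fit), s$quantity / s$quantity[1], tolerance = 1e-6)
  expect_equal(residuals(fit), rep(0, length(s$times)), tolerance = 1e-6)
  expect_equal(predict(fit, times = 0), 1, tolerance = 1e-8)
  expect_equal(AIC(fit), fit$aic)
  sim <- simulate(fit, nsim = 2, seed = 1, noise_sd = 0.1)
  expect_equal(nrow(sim), 2 * length(s$times))
  expect_output(print(summary(fit)), "Candidate models")
})
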