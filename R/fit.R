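# Per-patient fitting engine: sufficiency screen, baseline normalization,
# bounded multi-start nonlinear least squares for each candidate model,
# per-parameter Wald gate and AIC selection.

.RATE_LOWER <- 1e-6   # day^-1 bounds for g and d
.RATE_UPPER <- 0.5
.THETA_LOWER <- 0.01
.THETA_UPPER <- 0.99
.GATE_ALPHA <- 0.1    # per-parameter significance gate

#' Screen a measurement series for sufficiency
#'
#' A series is insufficient when it has no or only one measurement, or exactly
#' two measurements (baseline plus one) whose relative change from baseline is
#' below 20% in absolute value — too little signal to identify any kinetic
#' parameter. Everything else is sufficient.
#'
#' @param time days since baseline, first element 0, strictly increasing.
#' @param quantity tumor-quantity scalars, same length as `time`.
#' @return `"sufficient"` or `"insufficient"`.
#' @examples
#' assess_sufficiency(c(0, 42), c(100, 115))      # 15% change: insufficient
#' assess_sufficiency(c(0, 42, 84), c(100, 75, 60))
#' @export
assess_sufficiency <- function(time, quantity) {
  n <- length(time)
  if (length(quantity) != n) stop("time and quantity lengths differ", call. = FALSE)
  if (n <= 1L) return("insufficient")
  if (n == 2L && abs(quantity[2] - quantity[1]) < 0.20 * quantity[1]) {
    return("insufficient")
  }
  "sufficient"
}

#' Normalize a series to its baseline quantity
#'
#' @param time days since baseline.
#' @param quantity positive baseline quantity followed by later scans.
#' @return list with `time` and `f`, the relative tumor quantity
#'   (`quantity / quantity[1]`, so `f[1] == 1`).
#' @export
normalize_series <- function(time, quantity) {
  if (length(time) != length(quantity)) {
    stop("time and quantity lengths differ", call. = FALSE)
  }
  if (length(quantity) == 0L || !is.finite(quantity[1]) || quantity[1] <= 0) {
    stop("baseline quantity must be positive", call. = FALSE)
  }
  if (any(!is.finite(quantity)) || any(!is.finite(time))) {
    stop("non-finite measurement", call. = FALSE)
  }
  if (time[1] != 0) stop("first time must be 0 (baseline)", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(quantity < 0)) stop("quantities must be non-negative", call. = FALSE)
  list(time = as.numeric(time), f = as.numeric(quantity) / quantity[1])
}

# residual and jacobian for each model kind; par is a named vector
.model_residual <- function(kind, par, t, f) {
  switch(kind,
    dx = exp(-par[["d"]] * t) - f,
    gx = exp(par[["g"]] * t) - f,
    gd = exp(-par[["d"]] * t) + exp(par[["g"]] * t) - 1 - f,
    gd_theta = par[["theta"]] * exp(-par[["d"]] * t) +
      (1 - par[["theta"]]) * exp(par[["g"]] * t) - f
  )
}

.model_jacobian <- function(kind, par, t) {
  switch(kind,
    dx = cbind(d = -t * exp(-par[["d"]] * t)),
    gx = cbind(g = t * exp(par[["g"]] * t)),
    gd = cbind(
      g = t * exp(par[["g"]] * t),
      d = -t * exp(-par[["d"]] * t)
    ),
    gd_theta = cbind(
      g = (1 - par[["theta"]]) * t * exp(par[["g"]] * t),
      d = -par[["theta"]] * t * exp(-par[["d"]] * t),
      theta = exp(-par[["d"]] * t) - exp(par[["g"]] * t)
    )
  )
}

.model_bounds <- function(kind) {
  pars <- .MODEL_PARS[[kind]]
  lower <- ifelse(pars == "theta", .THETA_LOWER, .RATE_LOWER)
  upper <- ifelse(pars == "theta", .THETA_UPPER, .RATE_UPPER)
  names(lower) <- names(upper) <- pars
  list(lower = lower, upper = upper)
}

# log-spaced multi-start grid: 4 values for each rate, 3 for theta
.model_starts <- function(kind) {
  rate_grid <- 10^seq(-4, -1, length.out = 4)
  theta_grid <- c(0.2, 0.5, 0.8)
  switch(kind,
    dx = lapply(rate_grid, function(d) c(d = d)),
    gx = lapply(rate_grid, function(g) c(g = g)),
    gd = {
      grid <- expand.grid(g = rate_grid, d = rate_grid)
      lapply(seq_len(nrow(grid)), function(i) c(g = grid$g[i], d = grid$d[i]))
    },
    gd_theta = {
      grid <- expand.grid(g = rate_grid, d = rate_grid, theta = theta_grid)
      lapply(seq_len(nrow(grid)), function(i) {
        c(g = grid$g[i], d = grid$d[i], theta = grid$theta[i])
      })
    }
  )
}

#' Fit one kinetic model to a normalized series
#'
#' Bounded Levenberg–Marquardt least squares (g, d in `[1e-6, 0.5]` day^-1,
#' theta in `[0.01, 0.99]`) from a log-spaced multi-start grid; the start with
#' the lowest residual sum of squares wins. Per-parameter standard errors come
#' from the asymptotic covariance `sigma^2 (J'J)^-1` with
#' `sigma^2 = rss / (n - k)`, and p-values are two-sided Wald (normal). The
#' Gaussian log-likelihood is `-(n/2) (log(2 pi rss / n) + 1)` and
#' `AIC = -2 logLik + 2k` with `k` the number of kinetic parameters.
#'
#' A candidate is *admissible* only if the optimizer converged, no parameter
#' sits on a bound, and every p-value is below 0.1; `select_model()` enforces
#' this gate.
#'
#' @param time days since baseline (first 0).
#' @param f relative tumor quantity (first 1).
#' @param kind model kind, see [model_kinds()].
#' @return a list describing the candidate fit (`NULL` when the series has
#'   fewer than `n_params + 1` points): parameter estimates, `se`, `p_values`,
#'   `rss`, `logLik`, `aic`, `converged`, `boundary`, `admissible`.
#' @export
fit_single_model <- function(time, f, kind) {
  kind <- match_model_kind(kind)
  if (any(!is.finite(time)) || any(!is.finite(f))) {
    stop("non-finite measurement", call. = FALSE)
  }
  n <- length(time)
  k <- .MODEL_NPAR[[kind]]
  if (n < k + 1L) return(NULL)

  bounds <- .model_bounds(kind)
  best <- NULL
  for (start in .model_starts(kind)) {
    # maxiter warnings are expected for hopeless starts; the info code is
    # checked below instead
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = start,
        lower = bounds$lower, upper = bounds$upper,
        fn = function(p) .model_residual(kind, p, time, f),
        jac = function(p) .model_jacobian(kind, p, time),
        control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  if (is.null(best)) return(NULL)

  par <- stats::setNames(as.numeric(best$par), names(best$par))
  rss <- best_rss
  converged <- best$info %in% 1:4
  # relative tolerance: the rate floor 1e-6 needs a relative, not absolute, check
  boundary <- any(par <= bounds$lower * 1.001 | par >= bounds$upper * 0.999)

  J <- .model_jacobian(kind, par, time)
  se <- rep(NA_real_, k)
  names(se) <- names(par)
  if (n > k) {
    sigma2 <- rss / (n - k)
    JtJ <- crossprod(J)
    cov <- tryCatch(solve(JtJ) * sigma2, error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)
      se <- sqrt(pmax(dg, 0))
      names(se) <- names(par)
    }
  }
  z <- abs(par) / se
  p_values <- 2 * stats::pnorm(-z)
  p_values[rss == 0 & is.nan(z)] <- 0  # exact fit: parameters identified
  names(p_values) <- names(par)

  # below 1e-12 the residual is numerically exact (normalized scale ~1) and
  # the Gaussian log-likelihood is unbounded; pinning it keeps AIC selection
  # and scale invariance well defined, with ties resolved by parsimony
  logLik <- if (rss < 1e-12) Inf else -(n / 2) * (log(2 * pi * rss / n) + 1)
  aic <- -2 * logLik + 2 * k
  admissible <- isTRUE(converged) && !boundary &&
    all(is.finite(p_values)) && all(p_values < .GATE_ALPHA)

  list(
    model = kind, params = par, se = se, p_values = p_values,
    rss = rss, logLik = logLik, aic = aic, n_points = n,
    converged = converged, boundary = boundary, admissible = admissible
  )
}

#' Select the best admissible candidate model
#'
#' Candidates pass the gate only if every parameter's two-sided Wald p-value
#' is below 0.1, the optimizer converged and no parameter sits on a bound.
#' Among admissible candidates the minimum AIC wins; ties break to fewer
#' parameters, then to the fixed order dx < gx < gd < gd_theta.
#'
#' @param candidates list of candidate fits from [fit_single_model()]
#'   (`NULL` entries are dropped).
#' @return the winning candidate, or `NULL` when none is admissible.
#' @export
select_model <- function(candidates) {
  candidates <- Filter(Negate(is.null), candidates)
  admissible <- Filter(function(x) isTRUE(x$admissible), candidates)
  if (length(admissible) == 0L) return(NULL)
  aics <- vapply(admissible, function(x) x$aic, numeric(1))
  npars <- vapply(admissible, function(x) .MODEL_NPAR[[x$model]], integer(1))
  order_idx <- vapply(admissible, function(x) match(x$model, .MODEL_ORDER), integer(1))
  pick <- order(aics, npars, order_idx)[1]
  admissible[[pick]]
}

#' Fit the regression-growth model to one patient's tumor measurements
#'
#' The full per-patient pipeline: sufficiency screening, normalization to the
#' baseline quantity, fitting of all four kinetic models (dx, gx, gd,
#' gd_theta) by bounded multi-start least squares, per-parameter significance
#' gating at p < 0.1, and AIC selection among the admissible fits.
#'
#' @param formula either a formula `quantity ~ day` evaluated in `data`, or a
#'   numeric vector of times in days (first element 0).
#' @param data data frame holding the formula variables, or (when `formula`
#'   is numeric) the numeric vector of tumor quantities.
#' @param patient_id optional identifier carried into the result.
#' @return an object of class `growth_fit` with fields `status` (`"fitted"`,
#'   `"insufficient_data"` or `"no_fit"`), `model`, `params`, `se`,
#'   `p_values`, `rss`, `logLik`, `aic`, `n_points`, the (normalized) data
#'   and all candidate fits. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`, `logLik`, `simulate`.
#' @examples
#' t <- seq(0, 378, by = 42)
#' q <- 80 * evaluate_model("gd", t, g = 0.003, d = 0.02)
#' fit <- growth_fit(t, q)
#' coef(fit)
#' doubling_time(coef(fit)[["g"]])
#' @export
growth_fit <- function(formula, data = NULL, patient_id = NA_character_) {
  if (inherits(formula, "formula")) {
    mf <- stats::model.frame(formula, data)
    quantity <- mf[[1L]]
    time <- mf[[2L]]
  } else {
    time <- formula
    quantity <- data
  }
  if (!is.numeric(time) || !is.numeric(quantity)) {
    stop("time and quantity must be numeric", call. = FALSE)
  }
  out <- list(
    patient_id = patient_id, status = NA_character_, model = NULL,
    params = NULL, se = NULL, p_values = NULL,
    rss = NA_real_, logLik = NA_real_, aic = NA_real_,
    n_points = length(time), candidates = list(),
    data = list(time = as.numeric(time), quantity = as.numeric(quantity),
                f = NULL)
  )
  class(out) <- "growth_fit"

  if (assess_sufficiency(time, quantity) == "insufficient") {
    out$status <- "insufficient_data"
    return(out)
  }
  ns <- normalize_series(time, quantity)
  out$data$f <- ns$f
  cands <- lapply(.MODEL_ORDER, function(kind) {
    fit_single_model(ns$time, ns$f, kind)
  })
  names(cands) <- .MODEL_ORDER
  out$candidates <- Filter(Negate(is.null), cands)
  winner <- select_model(out$candidates)
  if (is.null(winner)) {
    out$status <- "no_fit"
    return(out)
  }
  out$status <- "fitted"
  out$model <- winner$model
  out$params <- winner$params
  out$se <- winner$se
  out$p_values <- winner$p_values
  out$rss <- winner$rss
  out$logLik <- winner$logLik
  out$aic <- winner$aic
  out
}
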