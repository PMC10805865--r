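# S3 methods for growth_fit objects.

#' @export
print.growth_fit <- function(x, ...) {
  cat("Regression-growth kinetic fit")
  if (!is.na(x$patient_id)) cat(" — patient ", x$patient_id, sep = "")
  cat("\n")
  cat("  measurements:", x$n_points, "\n")
  cat("  status:      ", x$status, "\n")
  if (x$status == "fitted") {
    cat("  model:       ", x$model, "\n")
    cat("  estimates:   ",
        paste(sprintf("%s = %.6g", names(x$params), x$params), collapse = ", "),
        "\n")
    if ("g" %in% names(x$params)) {
      cat("  doubling time:", sprintf("%.0f days", doubling_time(x$params[["g"]])), "\n")
    }
    cat("  AIC:         ", format(x$aic, digits = 6), "\n")
  }
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  out <- object
  if (object$status == "fitted") {
    out$coef_table <- cbind(
      Estimate = object$params,
      `Std. Error` = object$se,
      `z value` = object$params / object$se,
      `Pr(>|z|)` = object$p_values
    )
    cand <- object$candidates
    out$candidate_table <- data.frame(
      model = vapply(cand, function(c) c$model, character(1)),
      rss = vapply(cand, function(c) c$rss, numeric(1)),
      aic = vapply(cand, function(c) c$aic, numeric(1)),
      admissible = vapply(cand, function(c) c$admissible, logical(1)),
      row.names = NULL
    )
  }
  class(out) <- c("summary.growth_fit", class(object))
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  NextMethod()
  if (x$status == "fitted") {
    cat("\nCoefficients:\n")
    stats::printCoefmat(x$coef_table, P.values = TRUE, has.Pvalue = TRUE)
    cat("\nCandidate models:\n")
    print(x$candidate_table, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$params

#' @export
logLik.growth_fit <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- if (is.null(object$model)) 0L else .MODEL_NPAR[[object$model]]
  attr(val, "nobs") <- object$n_points
  class(val) <- "logLik"
  val
}

#' Predicted relative tumor quantity
#'
#' @param object a fitted `growth_fit`.
#' @param times days at which to evaluate the selected model; defaults to the
#'   observed scan times.
#' @param ... unused.
#' @export
predict.growth_fit <- function(object, times = object$data$time, ...) {
  if (object$status != "fitted") {
    stop("no model was fitted (status: ", object$status, ")", call. = FALSE)
  }
  p <- as.list(object$params)
  evaluate_model(object$model, times,
                 g = p$g, d = p$d, theta = p$theta)
}

#' @export
fitted.growth_fit <- function(object, ...) predict(object)

#' @export
residuals.growth_fit <- function(object, ...) {
  if (object$status != "fitted") {
    stop("no model was fitted (status: ", object$status, ")", call. = FALSE)
  }
  object$data$f - fitted(object)
}

#' Simulate noisy replicate series from a fitted kinetic model
#'
#' Draws multiplicative lognormal measurement noise around the fitted
#' trajectory at the observed scan times — the same error model the
#' synthetic-trial generator uses.
#'
#' @param object a fitted `growth_fit`.
#' @param nsim number of replicate series.
#' @param seed optional integer seed.
#' @param noise_sd standard deviation of log measurement error.
#' @param ... unused.
#' @return data frame with columns `sim`, `time`, `f`.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, noise_sd = 0.1, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  t <- object$data$time
  do.call(rbind, lapply(seq_len(nsim), function(i) {
    data.frame(sim = i, time = t,
               f = mu * exp(stats::rnorm(length(t), 0, noise_sd)))
  }))
}

#' Plot a per-patient kinetic fit
#'
#' Observed relative tumor quantities with the selected model's curve.
#'
#' @param x a `growth_fit`.
#' @param ... passed to `plot.default`.
#' @export
plot.growth_fit <- function(x, ...) {
  t <- x$data$time
  f <- if (is.null(x$data$f)) x$data$quantity / x$data$quantity[1] else x$data$f
  graphics::plot(t, f, xlab = "days since baseline",
                 ylab = "relative tumor quantity",
                 main = if (x$status == "fitted") {
                   sprintf("model %s", x$model)
                 } else x$status, ...)
  if (x$status == "fitted") {
    tt <- seq(min(t), max(t), length.out = 200)
    graphics::lines(tt, predict(x, times = tt), col = "steelblue", lwd = 2)
  }
  invisible(x)
}
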