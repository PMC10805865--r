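# Overall-survival analyses: Kaplan-Meier estimation, g-tertile biomarker
# analysis, and the overlay of dx (no-detectable-growth) patients on the
# best tertile.

#' Kaplan–Meier estimate of overall survival
#'
#' Product-limit estimator over a set of survival records. Censored times
#' reduce the risk set without a survival drop. The median is the first time
#' at which the survival estimate falls to 0.5 or below, and is `NA` when the
#' curve never reaches 0.5.
#'
#' @param records data frame with columns `os_months` (non-negative) and
#'   `event` (1 = death observed, 0 = censored); optional `patient_id`.
#' @return a `km_curve`: list with `curve` (data frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`), `median`, `n`, `events`.
#' @examples
#' km <- km_estimate(data.frame(os_months = c(10, 20, 30), event = 1))
#' km$median  # 20
#' @export
km_estimate <- function(records) {
  records <- check_survival(records)
  if (nrow(records) == 0L) stop("no survival records", call. = FALSE)
  sf <- survival::survfit(
    survival::Surv(os_months, event) ~ 1,
    data = records, conf.type = "none"
  )
  curve <- data.frame(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, survival = sf$surv
  )
  structure(
    list(curve = curve, median = km_median(curve),
         n = nrow(records), events = sum(records$event)),
    class = "km_curve"
  )
}

km_median <- function(curve) {
  idx <- which(curve$survival <= 0.5 + 1e-12 & curve$n_event > 0)
  if (length(idx) == 0L) NA_real_ else curve$time[idx[1L]]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, x$events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  t <- c(0, x$curve$time)
  s <- c(1, x$curve$survival)
  graphics::plot(t, s, type = "s", ylim = c(0, 1), xlab = "months",
                 ylab = "survival probability", ...)
  invisible(x)
}

check_survival <- function(records) {
  if (!is.data.frame(records)) stop("survival records must be a data frame", call. = FALSE)
  missing <- setdiff(c("os_months", "event"), names(records))
  if (length(missing) > 0L) {
    stop("survival table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(records$os_months)) || any(records$os_months < 0)) {
    stop("os_months must be finite and non-negative", call. = FALSE)
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  }
  if ("patient_id" %in% names(records)) {
    records$patient_id <- as.character(records$patient_id)
  }
  records
}

# tertile assignment: type-7 empirical quantile boundaries, ties on a
# boundary go to the lower tertile; degenerate boundaries fall back to a
# stable rank-based split into near-equal thirds.
assign_tertiles <- function(g) {
  qs <- stats::quantile(g, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  tert <- 1L + (g > qs[1]) + (g > qs[2])
  if (length(unique(tert)) < 3L) {
    ord <- order(g)  # stable: ties keep input order
    tert <- integer(length(g))
    tert[ord] <- cut(seq_along(g), 3L, labels = FALSE)
  }
  tert
}

#' Overall survival by tertile of the growth rate g
#'
#' Patients with a determined growth rate (models gx, gd, gd_theta — dx
#' tumors have no measurable growth and are excluded) are ranked by g and
#' split at the empirical 1/3 and 2/3 quantiles into Q1 (slowest-growing),
#' intermediate and Q3 (fastest-growing) tertiles; a Kaplan–Meier curve is
#' estimated per tertile.
#'
#' @param fits a `growth_fit_table`.
#' @param survival data frame with `patient_id`, `os_months`, `event`.
#' @return a `g_tertiles`: list with `assignments` (patient_id, g, tertile),
#'   `summary` (per tertile: n, events, median_g, median_os_months) and
#'   `curves` (list of `km_curve`).
#' @export
tertile_analysis <- function(fits, survival) {
  survival <- check_survival(survival)
  if (!"patient_id" %in% names(survival)) {
    stop("survival table needs a patient_id column", call. = FALSE)
  }
  gtab <- collect_g(fits, impute_dx = FALSE)
  if (nrow(gtab) < 3L) {
    stop("tertile analysis needs at least 3 patients with a determined g",
         call. = FALSE)
  }
  orphans <- setdiff(gtab$patient_id, survival$patient_id)
  if (length(orphans) > 0L) {
    stop("no survival record for patient(s): ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  gtab$tertile <- assign_tertiles(gtab$g)
  merged <- merge(gtab, survival, by = "patient_id", sort = FALSE)
  curves <- lapply(1:3, function(q) {
    km_estimate(merged[merged$tertile == q, c("os_months", "event")])
  })
  names(curves) <- c("Q1", "Q2", "Q3")
  summary <- data.frame(
    tertile = c("Q1", "Q2", "Q3"),
    n = vapply(1:3, function(q) sum(merged$tertile == q), integer(1)),
    events = vapply(curves, function(c) c$events, numeric(1)),
    median_g = vapply(1:3, function(q) stats::median(merged$g[merged$tertile == q]),
                      numeric(1)),
    median_os_months = vapply(curves, function(c) c$median, numeric(1)),
    row.names = NULL
  )
  structure(
    list(assignments = gtab[, c("patient_id", "g", "tertile")],
         summary = summary, curves = curves),
    class = "g_tertiles"
  )
}

#' @export
print.g_tertiles <- function(x, ...) {
  cat("Overall survival by tertile of g (Q1 = slowest-growing)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Overlay of patients without detectable growth on the best tertile
#'
#' Tumors best fit by the pure-decay model (dx) have no measurable growth;
#' their survival is expected to resemble the lowest-g tertile. This
#' estimates the dx population's Kaplan–Meier curve and quantifies the
#' overlap with Q1 by a logrank test.
#'
#' @param fits a `growth_fit_table`.
#' @param survival data frame with `patient_id`, `os_months`, `event`.
#' @param tertiles a `g_tertiles` from [tertile_analysis()].
#' @return a `dx_overlay`: list with `n_dx`, `curve` (km_curve or NULL),
#'   `median_dx`, `logrank_chisq`, `logrank_p` (against Q1). An empty dx set
#'   yields an empty result, not an error.
#' @export
dx_overlay <- function(fits, survival, tertiles) {
  survival <- check_survival(survival)
  dx_ids <- fits$patient_id[fits$status == "fitted" & fits$model == "dx"]
  dx_ids <- intersect(dx_ids, survival$patient_id)
  if (length(dx_ids) == 0L) {
    return(structure(
      list(n_dx = 0L, curve = NULL, median_dx = NA_real_,
           logrank_chisq = NA_real_, logrank_p = NA_real_),
      class = "dx_overlay"
    ))
  }
  dx_surv <- survival[survival$patient_id %in% dx_ids, , drop = FALSE]
  q1_ids <- tertiles$assignments$patient_id[tertiles$assignments$tertile == 1L]
  q1_surv <- survival[survival$patient_id %in% q1_ids, , drop = FALSE]
  pooled <- rbind(
    data.frame(os_months = dx_surv$os_months, event = dx_surv$event, group = "dx"),
    data.frame(os_months = q1_surv$os_months, event = q1_surv$event, group = "Q1")
  )
  chisq <- p <- NA_real_
  if (length(unique(pooled$group)) == 2L && sum(pooled$event) > 0) {
    sd <- survival::survdiff(
      survival::Surv(os_months, event) ~ group, data = pooled
    )
    chisq <- unname(sd$chisq)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  curve <- km_estimate(dx_surv[, c("os_months", "event")])
  structure(
    list(n_dx = length(dx_ids), curve = curve, median_dx = curve$median,
         logrank_chisq = chisq, logrank_p = p),
    class = "dx_overlay"
  )
}

#' @export
print.dx_overlay <- function(x, ...) {
  if (x$n_dx == 0L) {
    cat("No dx-classified patients.\n")
  } else {
    cat(sprintf("dx population: n = %d, median OS = %s months\n", x$n_dx,
                if (is.na(x$median_dx)) "not reached" else format(x$median_dx)))
    cat(sprintf("logrank vs best tertile (Q1): chisq = %.3g, p = %.4g\n",
                x$logrank_chisq, x$logrank_p))
  }
  invisible(x)
}
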