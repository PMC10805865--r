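# How early the two arms' g distributions separate: as a function of scans
# per patient, and of patients enrolled.

#' Arm separation as scans accumulate
#'
#' For each k from 3 to `max_points`, every patient's series is truncated to
#' its first k scans (patients with fewer scans contribute what they have —
#' cumulative inclusion), series with at least a baseline plus two further
#' scans are refitted, growth rates are collected with dx imputation, and the
#' arms are compared by the two-sided rank-sum test. The look sequence is
#' uncorrected for multiplicity and is exploratory.
#'
#' @param measurements long measurements table with `patient_id`, `day`,
#'   `quantity`, `arm`.
#' @param max_points largest number of scans per patient to consider (>= 3).
#' @param impute_value fixed low g assigned to dx tumors, day^-1.
#' @return an `accrual_result` with `axis = "scans"` and a `steps` data frame:
#'   `step`, `n_experimental`, `n_control`, `p_value`.
#' @export
scan_accrual <- function(measurements, max_points = 10L, impute_value = 1e-4) {
  if (!is.numeric(max_points) || max_points < 3L) {
    stop("max_points must be at least 3", call. = FALSE)
  }
  measurements <- check_measurements(measurements, require_meta = "arm")
  measurements <- measurements[order(measurements$patient_id, measurements$day), ]
  series <- split(measurements, measurements$patient_id)
  n_scans <- vapply(series, nrow, integer(1))

  # cache per-patient fits keyed on truncation length: a patient's fit only
  # changes between steps when the truncated length changes
  g_cache <- list()
  len_cache <- integer(length(series))
  arm <- vapply(series, function(s) as.character(s$arm[1]), character(1))

  rows <- list()
  for (k in seq.int(3L, max_points)) {
    for (i in seq_along(series)) {
      len_k <- min(k, n_scans[i])
      if (len_k < 3L) {
        g_cache[i] <- list(NULL)
        len_cache[i] <- len_k
        next
      }
      if (len_cache[i] == len_k && length(g_cache) >= i) next
      sub <- series[[i]][seq_len(len_k), , drop = FALSE]
      fit <- growth_fit(sub$day, sub$quantity, patient_id = sub$patient_id[1])
      g_cache[[i]] <- fit_g_value(fit, impute_value)
      len_cache[i] <- len_k
    }
    g_all <- unlist(g_cache[!vapply(g_cache, is.null, logical(1))])
    arm_all <- arm[!vapply(g_cache, is.null, logical(1))]
    keep <- !is.na(g_all)
    ge <- g_all[keep & arm_all == "experimental"]
    gc <- g_all[keep & arm_all == "control"]
    p <- if (length(ge) >= 2L && length(gc) >= 2L) {
      compare_groups(ge, gc)$p_value
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      step = k, n_experimental = length(ge), n_control = length(gc), p_value = p
    )
  }
  structure(
    list(axis = "scans", steps = do.call(rbind, rows)),
    class = "accrual_result"
  )
}

# the g a patient contributes to a rank test: estimate for gx/gd/gd_theta,
# the imputation constant for dx, NA otherwise
fit_g_value <- function(fit, impute_value) {
  if (fit$status != "fitted") return(NA_real_)
  if (fit$model == "dx") return(impute_value)
  fit$params[["g"]]
}

#' Arm separation as patients accrue
#'
#' Emulates looking at the trial early: every series is truncated to its
#' first `truncate_scans` scans (default 3 — baseline plus two follow-ups)
#' and fitted once; patients are then added in enrollment order and after
#' each addition, once both arms carry at least `min_evaluable` evaluable
#' growth rates, the arms are rank-tested. Looks are sequential and
#' uncorrected; the trajectory is exploratory, not confirmatory.
#'
#' @param measurements long measurements table with `patient_id`, `day`,
#'   `quantity`, `arm`, `enrollment_rank`.
#' @param truncate_scans scans per patient available at the look (>= 3).
#' @param alpha crossing threshold for the reported first crossing.
#' @param min_evaluable minimum evaluable g per arm before testing starts.
#' @param impute_value fixed low g for dx tumors, day^-1.
#' @return an `accrual_result` with `axis = "patients"`, a `steps` data frame
#'   (`step` = patients enrolled, `n_experimental`, `n_control`, `p_value`)
#'   and `first_crossing`, the smallest number of patients enrolled with
#'   p < alpha (NA when never crossed).
#' @export
patient_accrual <- function(measurements, truncate_scans = 3L, alpha = 0.05,
                            min_evaluable = 3L, impute_value = 1e-4) {
  measurements <- check_measurements(measurements,
                                     require_meta = c("arm", "enrollment_rank"))
  if (any(is.na(measurements$enrollment_rank))) {
    stop("enrollment_rank missing for some patients", call. = FALSE)
  }
  if (truncate_scans < 3L) stop("truncate_scans must be at least 3", call. = FALSE)
  measurements <- measurements[order(measurements$patient_id, measurements$day), ]
  series <- split(measurements, measurements$patient_id)
  arm <- vapply(series, function(s) as.character(s$arm[1]), character(1))
  if (length(unique(arm)) < 2L) {
    stop("both arms are required for an accrual comparison", call. = FALSE)
  }
  rank <- vapply(series, function(s) as.numeric(s$enrollment_rank[1]), numeric(1))
  g <- vapply(series, function(s) {
    sub <- s[seq_len(min(truncate_scans, nrow(s))), , drop = FALSE]
    fit <- growth_fit(sub$day, sub$quantity, patient_id = sub$patient_id[1])
    val <- fit_g_value(fit, impute_value)
    if (is.null(val)) NA_real_ else val
  }, numeric(1))

  ord <- order(rank)
  rows <- list()
  first_crossing <- NA_integer_
  for (m in seq_along(ord)) {
    idx <- ord[seq_len(m)]
    ge <- g[idx][arm[idx] == "experimental"]
    gc <- g[idx][arm[idx] == "control"]
    ge <- ge[!is.na(ge)]
    gc <- gc[!is.na(gc)]
    if (length(ge) < min_evaluable || length(gc) < min_evaluable) next
    p <- compare_groups(ge, gc)$p_value
    rows[[length(rows) + 1L]] <- data.frame(
      step = m, n_experimental = length(ge), n_control = length(gc), p_value = p
    )
    if (is.na(first_crossing) && p < alpha) first_crossing <- m
  }
  structure(
    list(axis = "patients",
         steps = if (length(rows)) do.call(rbind, rows) else
           data.frame(step = integer(0), n_experimental = integer(0),
                      n_control = integer(0), p_value = numeric(0)),
         first_crossing = first_crossing, alpha = alpha),
    class = "accrual_result"
  )
}

#' @export
print.accrual_result <- function(x, ...) {
  cat(sprintf("Accrual separation analysis (axis: %s)\n", x$axis))
  cat("Note: sequential looks are uncorrected; the trajectory is exploratory.\n")
  if (x$axis == "patients") {
    cat(sprintf("First crossing below alpha = %g: %s patients\n", x$alpha,
                if (is.na(x$first_crossing)) "never" else x$first_crossing))
  }
  print(utils::head(x$steps, 12), row.names = FALSE)
  if (nrow(x$steps) > 12) cat("...", nrow(x$steps) - 12, "more steps\n")
  invisible(x)
}
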