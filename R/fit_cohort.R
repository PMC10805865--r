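# Batch fitting over a long measurements table.

.META_COLS <- c("arm", "sensitivity", "visceral", "age_group", "enrollment_rank")

#' Fit every patient in a measurements table
#'
#' Applies [growth_fit()] to each patient's series in a long measurements
#' table (one row per scan) and returns one row per patient with the selected
#' model, estimates, standard errors, p-values, fit statistics and any
#' per-patient metadata columns (`arm`, `sensitivity`, `visceral`,
#' `age_group`, `enrollment_rank`) found in the input.
#'
#' @param measurements data frame with columns `patient_id`, `day`,
#'   `quantity` and optional metadata columns; `day` starts at 0 per patient
#'   and increases strictly.
#' @param progress print a dot every 50 patients.
#' @return a `growth_fit_table`: a data frame with columns `patient_id`,
#'   `status`, `model`, `g`, `d`, `theta`, `se_g`, `se_d`, `se_theta`, `p_g`,
#'   `p_d`, `p_theta`, `rss`, `aic`, `n_points` plus metadata.
#' @examples
#' trial <- simulate_trial(trial_config(n_experimental = 6, n_control = 3), seed = 1)
#' fits <- fit_cohort(trial$measurements)
#' table(fits$status)
#' @export
fit_cohort <- function(measurements, progress = FALSE) {
  measurements <- check_measurements(measurements)
  ids <- unique(measurements$patient_id)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- measurements[measurements$patient_id == ids[i], , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    fit <- growth_fit(sub$day, sub$quantity, patient_id = ids[i])
    rows[[i]] <- fit_row(fit, sub[1L, intersect(.META_COLS, names(sub)), drop = FALSE])
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("growth_fit_table", "data.frame")
  out
}

fit_row <- function(fit, meta) {
  g <- d <- theta <- se_g <- se_d <- se_theta <- p_g <- p_d <- p_theta <- NA_real_
  if (fit$status == "fitted") {
    p <- fit$params
    if ("g" %in% names(p)) {
      g <- p[["g"]]; se_g <- fit$se[["g"]]; p_g <- fit$p_values[["g"]]
    }
    if ("d" %in% names(p)) {
      d <- p[["d"]]; se_d <- fit$se[["d"]]; p_d <- fit$p_values[["d"]]
    }
    if ("theta" %in% names(p)) {
      theta <- p[["theta"]]; se_theta <- fit$se[["theta"]]
      p_theta <- fit$p_values[["theta"]]
    }
  }
  row <- data.frame(
    patient_id = fit$patient_id,
    status = fit$status,
    model = if (is.null(fit$model)) NA_character_ else fit$model,
    g = g, d = d, theta = theta,
    se_g = se_g, se_d = se_d, se_theta = se_theta,
    p_g = p_g, p_d = p_d, p_theta = p_theta,
    rss = fit$rss, aic = fit$aic, n_points = fit$n_points,
    stringsAsFactors = FALSE
  )
  if (ncol(meta) > 0L) row <- cbind(row, meta, row.names = NULL)
  row
}

# shared input checks for a long measurements table
check_measurements <- function(measurements, require_meta = character(0)) {
  if (!is.data.frame(measurements)) {
    stop("measurements must be a data frame", call. = FALSE)
  }
  required <- c("patient_id", "day", "quantity", require_meta)
  missing <- setdiff(required, names(measurements))
  if (length(missing) > 0L) {
    stop("measurements table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(measurements) == 0L) stop("measurements table is empty", call. = FALSE)
  measurements$patient_id <- as.character(measurements$patient_id)
  measurements
}

#' @export
print.growth_fit_table <- function(x, ...) {
  cat("Per-patient regression-growth fits:", nrow(x), "patients\n")
  print(table(status = x$status))
  fitted <- x[x$status == "fitted", , drop = FALSE]
  if (nrow(fitted) > 0L) {
    cat("\nSelected models:\n")
    print(table(model = fitted$model))
  }
  invisible(x)
}
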