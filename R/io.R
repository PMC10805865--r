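# CSV schemas, input validation, and the end-to-end pipeline driver.

#' Read a measurements table
#'
#' Expects the long scan schema: one row per scan with columns `patient_id`,
#' `day`, `quantity` and optional `arm`, `sensitivity`, `visceral`,
#' `age_group`, `enrollment_rank`.
#'
#' @param path CSV file path.
#' @return data frame in the measurements schema.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("patient_id", "day", "quantity"), names(df))
  if (length(missing) > 0L) {
    stop("measurement file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Read a survival table
#'
#' Expects columns `patient_id`, `os_months`, `event` (0/1).
#'
#' @param path CSV file path.
#' @return data frame in the survival schema.
#' @export
read_survival <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("patient_id", "os_months", "event"), names(df))
  if (length(missing) > 0L) {
    stop("survival file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Validate measurement and survival tables without running analyses
#'
#' Checks the series invariants (baseline day 0, strictly increasing days,
#' non-negative quantities, positive baseline, single arm label per patient)
#' and the survival invariants (non-negative times, 0/1 events), and reports
#' findings rather than raising errors.
#'
#' @param measurements data frame or CSV path in the measurements schema.
#' @param survival optional data frame or CSV path in the survival schema.
#' @return data frame of findings (`patient_id`, `row`, `field`, `message`);
#'   zero rows when everything is well-formed.
#' @export
validate_inputs <- function(measurements, survival = NULL) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  findings <- list()
  add <- function(patient_id, row, field, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      patient_id = patient_id, row = row, field = field, message = message,
      stringsAsFactors = FALSE
    )
  }
  for (id in unique(measurements$patient_id)) {
    idx <- which(measurements$patient_id == id)
    sub <- measurements[idx, , drop = FALSE]
    ord <- order(sub$day)
    sub <- sub[ord, , drop = FALSE]
    idx <- idx[ord]
    if (any(!is.finite(sub$day))) {
      add(id, idx[!is.finite(sub$day)][1], "day", "non-finite day")
      next
    }
    if (sub$day[1] != 0) add(id, idx[1], "day", "first scan must be at day 0")
    if (anyDuplicated(sub$day)) {
      add(id, idx[duplicated(sub$day)][1], "day", "days not strictly increasing")
    }
    bad_q <- which(!is.finite(sub$quantity) | sub$quantity < 0)
    if (length(bad_q) > 0L) {
      add(id, idx[bad_q[1]], "quantity", "negative or non-finite quantity")
    }
    if (is.finite(sub$quantity[1]) && sub$quantity[1] <= 0) {
      add(id, idx[1], "quantity", "baseline quantity must be positive")
    }
    if ("arm" %in% names(sub)) {
      arms <- unique(as.character(sub$arm))
      if (length(arms) > 1L) add(id, idx[1], "arm", "conflicting arm labels")
      if (!all(arms %in% c("experimental", "control"))) {
        add(id, idx[1], "arm", paste0("unknown arm label: ",
                                      paste(setdiff(arms, c("experimental", "control")),
                                            collapse = ", ")))
      }
    }
  }
  if (!is.null(survival)) {
    if (is.character(survival)) survival <- read_survival(survival)
    bad_t <- which(!is.finite(survival$os_months) | survival$os_months < 0)
    for (r in bad_t) {
      add(survival$patient_id[r], r, "os_months", "negative or non-finite OS time")
    }
    bad_e <- which(!survival$event %in% c(0, 1))
    for (r in bad_e) add(survival$patient_id[r], r, "event", "event must be 0 or 1")
    orphans <- setdiff(survival$patient_id, measurements$patient_id)
    for (id in orphans) {
      add(id, which(survival$patient_id == id)[1], "patient_id",
          "survival record without measurements")
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(patient_id = character(0), row = integer(0),
                      field = character(0), message = character(0)))
  }
  do.call(rbind, findings)
}

#' Write a per-patient fits table
#'
#' One row per patient in the fit-output schema; absent values are written
#' as empty fields.
#'
#' @param fits a `growth_fit_table`.
#' @param path output CSV path.
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic trial to CSV files
#'
#' Writes `measurements.csv`, `survival.csv` and `truth.csv` (the ground
#' truth is a separate file never read by the analysis path).
#'
#' @param trial a `synthetic_trial`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(trial$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(trial$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Executes fit, cohort classification, arm and subgroup comparisons,
#' doubling-time thresholds, tertile survival analysis, dx overlay, and both
#' accrual analyses, writing every output table plus a run manifest to
#' `out_dir`. Identical inputs and seed produce byte-identical outputs.
#'
#' @param measurements data frame or CSV path in the measurements schema
#'   (needs `arm`; `sensitivity` and `enrollment_rank` unlock the subgroup
#'   and patient-accrual stages).
#' @param survival data frame or CSV path in the survival schema; survival
#'   records without a measured patient are skipped with a warning.
#' @param out_dir output directory.
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters when the caller also simulates).
#' @param impute_value fixed low g for dx tumors, day^-1.
#' @param dt_thresholds doubling-time g thresholds, day^-1.
#' @param max_points scan-accrual horizon.
#' @param alpha accrual crossing threshold.
#' @param strata stratifier columns for subgroup comparisons (used when
#'   present in the measurements).
#' @return (invisibly) a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_full_pipeline <- function(measurements, survival = NULL, out_dir,
                              seed = 1L, impute_value = 1e-4,
                              dt_thresholds = c(0.0019, 0.00095, 0.00063),
                              max_points = 10L, alpha = 0.05,
                              strata = c("visceral", "age_group")) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(survival) && length(survival) == 1L) {
    survival <- read_survival(survival)
  }
  findings <- validate_inputs(measurements, survival)
  hard <- findings[findings$field != "patient_id", , drop = FALSE]
  if (nrow(hard) > 0L) {
    stop("input validation failed:\n",
         paste(sprintf("  %s (row %s, %s): %s", hard$patient_id, hard$row,
                       hard$field, hard$message), collapse = "\n"),
         call. = FALSE)
  }
  warnings <- character(0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))

  fits <- fit_cohort(measurements)
  write_fits(fits, file.path(out_dir, "fits.csv"))

  by <- intersect(c("arm", "sensitivity"), names(fits))
  summary <- classify_cohort(fits, by = if (length(by)) by else NULL)
  counts_df <- as.data.frame.matrix(summary$counts)
  counts_df <- cbind(category = rownames(summary$counts), counts_df)
  utils::write.csv(counts_df, file.path(out_dir, "cohort_counts.csv"),
                   row.names = FALSE)

  comparisons <- list()
  gtab <- collect_g(fits, impute_dx = TRUE, impute_value = impute_value)
  if ("arm" %in% names(gtab) &&
      all(c("experimental", "control") %in% gtab$arm)) {
    comparisons$arm_all <- compare_groups(
      gtab$g[gtab$arm == "experimental"], gtab$g[gtab$arm == "control"],
      "experimental", "control"
    )
    if ("sensitivity" %in% names(gtab)) {
      for (coh in sort(unique(gtab$sensitivity))) {
        sub <- gtab[gtab$sensitivity == coh, , drop = FALSE]
        if (all(c("experimental", "control") %in% sub$arm)) {
          comparisons[[paste0("arm_", coh)]] <- compare_groups(
            sub$g[sub$arm == "experimental"], sub$g[sub$arm == "control"],
            "experimental", "control"
          )
        }
      }
    }
  }
  subgroups <- NULL
  strata_present <- intersect(strata, names(fits))
  if (length(strata_present) > 0L && "arm" %in% names(fits)) {
    subgroups <- subgroup_comparisons(fits, strata = strata_present,
                                      impute_value = impute_value)
    utils::write.csv(as.data.frame(subgroups),
                     file.path(out_dir, "subgroup_comparisons.csv"),
                     row.names = FALSE)
    skipped <- sum(!subgroups$tested)
    if (skipped > 0L) {
      warnings <- c(warnings, sprintf("%d subgroup(s) below minimum size, not tested",
                                      skipped))
    }
  }
  jsonlite::write_json(
    lapply(comparisons, unclass),
    file.path(out_dir, "comparisons.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  dt <- dt_threshold_fractions(gtab$g, dt_thresholds)
  utils::write.csv(dt, file.path(out_dir, "dt_fractions.csv"), row.names = FALSE)

  tertiles <- NULL
  overlay <- NULL
  n_surv <- 0L
  if (!is.null(survival)) {
    orphans <- setdiff(survival$patient_id, fits$patient_id)
    if (length(orphans) > 0L) {
      warnings <- c(warnings, paste0("survival records without measurements skipped: ",
                                     paste(orphans, collapse = ", ")))
      survival <- survival[!survival$patient_id %in% orphans, , drop = FALSE]
    }
    n_surv <- nrow(survival)
    n_determined <- nrow(collect_g(fits, impute_dx = FALSE))
    if (n_determined >= 3L) {
      tertiles <- tertile_analysis(fits, survival)
      utils::write.csv(tertiles$summary, file.path(out_dir, "tertiles.csv"),
                       row.names = FALSE)
      km_points <- do.call(rbind, lapply(names(tertiles$curves), function(q) {
        cbind(tertile = q, tertiles$curves[[q]]$curve)
      }))
      utils::write.csv(km_points, file.path(out_dir, "km_curves.csv"),
                       row.names = FALSE)
      overlay <- dx_overlay(fits, survival, tertiles)
      jsonlite::write_json(
        list(n_dx = overlay$n_dx, median_dx = overlay$median_dx,
             logrank_chisq = overlay$logrank_chisq, logrank_p = overlay$logrank_p),
        file.path(out_dir, "dx_overlay.json"),
        auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
      )
    } else {
      warnings <- c(warnings, "fewer than 3 determined g values; tertile stage skipped")
    }
  }

  accrual_scans <- NULL
  accrual_patients <- NULL
  if ("arm" %in% names(measurements) &&
      all(c("experimental", "control") %in% measurements$arm)) {
    accrual_scans <- scan_accrual(measurements, max_points = max_points,
                                  impute_value = impute_value)
    utils::write.csv(accrual_scans$steps, file.path(out_dir, "accrual_scans.csv"),
                     row.names = FALSE)
    if ("enrollment_rank" %in% names(measurements) &&
        !any(is.na(measurements$enrollment_rank))) {
      accrual_patients <- patient_accrual(measurements, alpha = alpha,
                                          impute_value = impute_value)
      utils::write.csv(accrual_patients$steps,
                       file.path(out_dir, "accrual_patients.csv"),
                       row.names = FALSE)
    }
  }

  n_patients <- length(unique(measurements$patient_id))
  manifest <- list(
    package = "regrowth",
    version = as.character(utils::packageVersion("regrowth")),
    seed = as.integer(seed),
    settings = list(impute_value = impute_value, dt_thresholds = dt_thresholds,
                    max_points = as.integer(max_points), alpha = alpha),
    counts = list(
      patients = n_patients,
      scans = nrow(measurements),
      survival_records = n_surv,
      insufficient = sum(fits$status == "insufficient_data"),
      fitted = sum(fits$status == "fitted"),
      no_fit = sum(fits$status == "no_fit")
    ),
    warnings = warnings
  )
  stopifnot(with(manifest$counts, insufficient + fitted + no_fit == patients))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(warnings) > 0L) {
    for (w in warnings) warning(w, call. = FALSE)
  }
  invisible(list(
    fits = fits, summary = summary, comparisons = comparisons,
    subgroups = subgroups, dt_fractions = dt, tertiles = tertiles,
    dx_overlay = overlay, accrual_scans = accrual_scans,
    accrual_patients = accrual_patients, manifest = manifest
  ))
}
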