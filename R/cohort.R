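# Cohort-level aggregation: classification tables, g collection with dx
# imputation, rank-sum arm/subgroup comparisons, doubling-time thresholds.

.FIT_CATEGORIES <- c("insufficient", "dx", "gd_theta", "gd", "gx", "no_fit")

fit_category <- function(status, model) {
  ifelse(status == "insufficient_data", "insufficient",
    ifelse(status == "no_fit", "no_fit", model))
}

#' Classify a cohort of per-patient fits
#'
#' Tabulates the kinetic classification of every patient — insufficient data,
#' one of the four models, or no admissible fit — overall and within groups.
#' Fraction conventions: the sufficiency fraction is of all patients in the
#' group; model fractions are of patients with sufficient data; the total-fit
#' fraction is (dx + gd_theta + gd + gx) / sufficient.
#'
#' @param fits a `growth_fit_table` from [fit_cohort()].
#' @param by character vector of grouping columns present in `fits`
#'   (e.g. `c("arm", "sensitivity")`); `NULL` for a single overall group.
#' @return a `cohort_summary`: list with `counts` (categories x groups matrix,
#'   first column `all`), `fractions` and `group_totals`.
#' @export
classify_cohort <- function(fits, by = NULL) {
  if (anyDuplicated(fits$patient_id)) {
    stop("duplicate patient_id in fits: ",
         paste(unique(fits$patient_id[duplicated(fits$patient_id)]), collapse = ", "),
         call. = FALSE)
  }
  missing_by <- setdiff(by, names(fits))
  if (length(missing_by) > 0L) {
    stop("grouping column(s) not found: ", paste(missing_by, collapse = ", "),
         call. = FALSE)
  }
  cat_vec <- factor(fit_category(fits$status, fits$model), levels = .FIT_CATEGORIES)
  groups <- if (is.null(by) || nrow(fits) == 0L) {
    factor(rep("all", nrow(fits)))
  } else {
    interaction(fits[by], sep = ":", drop = TRUE)
  }
  counts <- table(category = cat_vec, group = groups)
  counts <- cbind(all = rowSums(counts), counts)
  totals <- colSums(counts)
  sufficient <- totals - counts["insufficient", ]
  fitted_n <- colSums(counts[c("dx", "gd_theta", "gd", "gx"), , drop = FALSE])
  fractions <- list(
    sufficiency = sufficient / pmax(totals, 1),
    model = sweep(counts[c("dx", "gd_theta", "gd", "gx", "no_fit"), , drop = FALSE],
                  2, pmax(sufficient, 1), "/"),
    total_fit = fitted_n / pmax(sufficient, 1)
  )
  structure(
    list(counts = counts, fractions = fractions, group_totals = totals, by = by),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort kinetic classification\n")
  tot <- x$group_totals
  suf <- tot - x$counts["insufficient", ]
  header <- rbind(
    `patients` = tot,
    `sufficient data` = sprintf("%d (%.1f%%)", suf, 100 * x$fractions$sufficiency)
  )
  body <- t(vapply(c("dx", "gd_theta", "gd", "gx"), function(cat) {
    sprintf("%d (%.1f%%)", x$counts[cat, ], 100 * x$fractions$model[cat, ])
  }, character(ncol(x$counts))))
  rownames(body) <- c("dx", "gd_theta", "gd", "gx")
  fitted_n <- colSums(x$counts[c("dx", "gd_theta", "gd", "gx"), , drop = FALSE])
  footer <- rbind(
    `total fit` = sprintf("%d (%.1f%%)", fitted_n, 100 * x$fractions$total_fit),
    `no fit` = sprintf("%d (%.1f%%)", x$counts["no_fit", ],
                       100 * x$fractions$model["no_fit", ])
  )
  print(rbind(header, body, footer), quote = FALSE, right = TRUE)
  invisible(x)
}

#' Collect per-patient growth rates, optionally imputing dx tumors
#'
#' Patients whose selected model carries a growth rate (gx, gd, gd_theta)
#' contribute their estimate; tumors best fit by pure decay (dx) have no
#' measurable growth and are either assigned a fixed low value (default 1e-4
#' day^-1) or omitted. Patients with insufficient data or no admissible fit
#' are always omitted.
#'
#' @param fits a `growth_fit_table`.
#' @param impute_dx include dx patients at `impute_value`?
#' @param impute_value fixed low g for dx tumors, day^-1.
#' @return data frame with `patient_id`, `g`, `imputed` and any metadata
#'   columns carried by `fits`.
#' @export
collect_g <- function(fits, impute_dx = TRUE, impute_value = 1e-4) {
  if (!is.numeric(impute_value) || length(impute_value) != 1L || impute_value <= 0) {
    stop("impute_value must be a positive number", call. = FALSE)
  }
  cat_vec <- fit_category(fits$status, fits$model)
  keep_g <- !is.na(cat_vec) & cat_vec %in% c("gx", "gd", "gd_theta")
  keep_dx <- !is.na(cat_vec) & cat_vec == "dx" & impute_dx
  out <- fits[keep_g | keep_dx, , drop = FALSE]
  out$imputed <- fit_category(out$status, out$model) == "dx"
  out$g[out$imputed] <- impute_value
  cols <- c("patient_id", "g", "imputed", intersect(.META_COLS, names(fits)))
  out <- out[, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two growth-rate distributions
#'
#' Two-sided Wilcoxon rank-sum (Mann–Whitney) comparison of two g vectors:
#' exact enumeration when both samples have at most 20 untied values, normal
#' approximation with tie correction otherwise. Medians of the vectors as
#' compared (i.e. after any imputation) are reported alongside.
#'
#' @param a,b numeric vectors of growth rates (day^-1), non-empty.
#' @param label_a,label_b group labels for reporting.
#' @return a `g_comparison`: list with labels, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `statistic` (Mann–Whitney U for the first sample), `p_value`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$p_value  # exact two-sided: 0.1
#' @export
compare_groups <- function(a, b, label_a = "a", label_b = "b") {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- length(a) <= 20L && length(b) <= 20L && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  structure(
    list(
      label_a = label_a, label_b = label_b,
      n_a = length(a), n_b = length(b),
      median_a = stats::median(a), median_b = stats::median(b),
      statistic = unname(wt$statistic), p_value = wt$p.value,
      exact = exact
    ),
    class = "g_comparison"
  )
}

#' @export
print.g_comparison <- function(x, ...) {
  cat(sprintf("Rank-sum comparison of g: %s (n=%d, median %.4g) vs %s (n=%d, median %.4g)\n",
              x$label_a, x$n_a, x$median_a, x$label_b, x$n_b, x$median_b))
  cat(sprintf("  W = %g, two-sided p = %.4g (%s)\n", x$statistic, x$p_value,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' Arm-versus-arm comparisons within subgroups
#'
#' For each value of each stratifier, crossed with the endocrine-sensitivity
#' cohorts (all / sensitive / resistant), compares the g distribution of the
#' experimental arm against the control arm. Subgroups with fewer than
#' `min_n` patients per arm are reported descriptively but not tested.
#' Nominal p-values, no multiplicity correction; `n_tests` counts the tests
#' actually performed.
#'
#' @param fits a `growth_fit_table` with an `arm` column.
#' @param strata stratifier column names (default `visceral` and `age_group`).
#' @param impute_dx,impute_value passed to [collect_g()].
#' @param min_n minimum patients per arm for a test.
#' @return data frame (class `subgroup_comparisons`) with one row per
#'   stratifier value x sensitivity cohort: group sizes, medians, `p_value`
#'   (NA when skipped) and `tested`.
#' @export
subgroup_comparisons <- function(fits, strata = c("visceral", "age_group"),
                                 impute_dx = TRUE, impute_value = 1e-4,
                                 min_n = 5L) {
  if (!"arm" %in% names(fits)) stop("fits must carry an 'arm' column", call. = FALSE)
  unknown <- setdiff(strata, names(fits))
  if (length(unknown) > 0L) {
    stop("unknown stratum column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  gtab <- collect_g(fits, impute_dx = impute_dx, impute_value = impute_value)
  arms <- sort(unique(as.character(gtab$arm)))
  if (!all(c("control", "experimental") %in% arms)) {
    stop("fits must contain both 'experimental' and 'control' arms", call. = FALSE)
  }
  cohorts <- "all"
  if ("sensitivity" %in% names(gtab)) {
    cohorts <- c("all", sort(unique(as.character(gtab$sensitivity))))
  }
  rows <- list()
  for (st in strata) {
    for (val in sort(unique(as.character(gtab[[st]])))) {
      for (coh in cohorts) {
        sub <- gtab[as.character(gtab[[st]]) == val, , drop = FALSE]
        if (coh != "all") {
          sub <- sub[as.character(sub$sensitivity) == coh, , drop = FALSE]
        }
        ge <- sub$g[sub$arm == "experimental"]
        gc <- sub$g[sub$arm == "control"]
        tested <- length(ge) >= min_n && length(gc) >= min_n
        p <- NA_real_
        if (tested) {
          p <- compare_groups(ge, gc)$p_value
        }
        rows[[length(rows) + 1L]] <- data.frame(
          stratifier = st, stratum = val, cohort = coh,
          n_experimental = length(ge), n_control = length(gc),
          median_experimental = if (length(ge)) stats::median(ge) else NA_real_,
          median_control = if (length(gc)) stats::median(gc) else NA_real_,
          p_value = p, tested = tested,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- sum(out$tested)
  class(out) <- c("subgroup_comparisons", "data.frame")
  out
}

#' Fractions of patients at or below doubling-time thresholds
#'
#' Growth-rate thresholds translate to doubling times via
#' \eqn{T_d = \ln(2)/g}; the defaults 0.0019, 0.00095 and 0.00063 day^-1
#' correspond to doubling times of about 1, 2 and 3 years. For each
#' threshold the fraction of patients with \eqn{g \le g^*} is reported.
#'
#' @param g numeric vector of growth rates (day^-1).
#' @param thresholds positive thresholds, day^-1.
#' @return data frame with `threshold_g`, `doubling_days`, `n_at_or_below`,
#'   `fraction`; zero rows when `g` is empty.
#' @export
dt_threshold_fractions <- function(g, thresholds = c(0.0019, 0.00095, 0.00063)) {
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    stop("thresholds must be positive", call. = FALSE)
  }
  if (length(g) == 0L) {
    return(data.frame(threshold_g = numeric(0), doubling_days = numeric(0),
                      n_at_or_below = integer(0), fraction = numeric(0)))
  }
  data.frame(
    threshold_g = thresholds,
    doubling_days = doubling_time(thresholds),
    n_at_or_below = vapply(thresholds, function(th) sum(g <= th), integer(1)),
    fraction = vapply(thresholds, function(th) mean(g <= th), numeric(1))
  )
}
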