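# Synthetic two-arm trial generator. Emulates the structure the analysis
# assumes — 2:1 randomization, endocrine-sensitivity strata, ~6-weekly scans,
# a per-arm mixture of kinetic classes, lognormal growth/decay rates,
# multiplicative measurement noise, and overall survival whose hazard rises
# with g — and exports the generating ground truth for recovery tests.

.CLASS_LEVELS <- c("insufficient", "dx", "gd_theta", "gd", "gx", "no_fit")

#' Configuration of a synthetic two-arm trial
#'
#' Defaults reproduce the structure of a 393-patient 2:1 trial: arm sizes
#' 261/132, sensitivity split and per-arm kinetic-class mixtures taken from
#' the classification table of such a trial, per-arm median growth rates
#' 0.0009 (experimental) and 0.0023 (control) day^-1 with log-sd 1, scans
#' every 42 days up to 10 scans, 10% multiplicative lognormal measurement
#' noise, and an overall-survival hazard h0 * g^beta per month calibrated so
#' the slowest- and fastest-growing tertiles have medians near 48 and 18
#' months.
#'
#' @param n_experimental,n_control patients per arm.
#' @param sensitivity_split named fractions of endocrine-sensitive patients
#'   per arm.
#' @param class_probs nested list `arm -> sensitivity -> named probabilities`
#'   over the classes `insufficient, dx, gd_theta, gd, gx, no_fit`.
#' @param g_median named per-arm median of the lognormal growth-rate law
#'   (day^-1); `g_sdlog` its log-sd.
#' @param d_median,d_sdlog lognormal decay-rate law (day^-1).
#' @param theta_range range of the uniform sensitive-fraction law.
#' @param noise_sd sd of log measurement error (multiplicative noise).
#' @param scan_interval days between scans; `max_scans` includes baseline.
#' @param dropout_rate per-scan dropout intensity; the per-scan dropout
#'   probability is `1 - exp(-dropout_rate * f)` at current relative burden f,
#'   applied from the third scan on (earlier discontinuation is modelled by
#'   the `insufficient` class).
#' @param os_h0,os_beta overall-survival link: hazard `os_h0 * g^os_beta`
#'   per month, with g floored at `dx_floor` for tumors without detectable
#'   growth.
#' @param os_horizon administrative censoring horizon, months; the default
#'   matches a mature trial readout (median follow-up beyond the slowest
#'   tertile's median survival).
#' @param dx_floor effective g (day^-1) used in the OS link for dx patients.
#' @param baseline_median,baseline_sdlog lognormal law of the baseline tumor
#'   quantity (arbitrary positive units).
#' @param visceral_prob,age_lt65_prob marginal stratifier frequencies (no
#'   kinetic effect by default).
#' @return a `trial_config` list.
#' @export
trial_config <- function(
    n_experimental = 261L, n_control = 132L,
    sensitivity_split = c(experimental = 205 / 261, control = 101 / 132),
    class_probs = default_class_probs(),
    g_median = c(experimental = 0.0009, control = 0.0023), g_sdlog = 1.0,
    d_median = 0.008, d_sdlog = 0.8,
    theta_range = c(0.2, 0.8),
    noise_sd = 0.10,
    scan_interval = 42, max_scans = 10L,
    dropout_rate = 0.02,
    os_h0 = 0.6, os_beta = 0.5, os_horizon = 73, dx_floor = 1e-4,
    baseline_median = 50, baseline_sdlog = 0.5,
    visceral_prob = 0.6, age_lt65_prob = 0.7) {
  cfg <- list(
    n_experimental = as.integer(n_experimental),
    n_control = as.integer(n_control),
    sensitivity_split = sensitivity_split,
    class_probs = class_probs,
    g_median = g_median, g_sdlog = g_sdlog,
    d_median = d_median, d_sdlog = d_sdlog,
    theta_range = theta_range,
    noise_sd = noise_sd,
    scan_interval = scan_interval, max_scans = as.integer(max_scans),
    dropout_rate = dropout_rate,
    os_h0 = os_h0, os_beta = os_beta, os_horizon = os_horizon,
    dx_floor = dx_floor,
    baseline_median = baseline_median, baseline_sdlog = baseline_sdlog,
    visceral_prob = visceral_prob, age_lt65_prob = age_lt65_prob
  )
  class(cfg) <- "trial_config"
  problems <- validate_config(cfg)
  if (length(problems) > 0L) {
    stop("invalid trial configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

#' @rdname trial_config
#' @export
default_class_probs <- function() {
  list(
    experimental = list(
      sensitive = c(insufficient = 24, dx = 43, gd_theta = 12,
                    gd = 85, gx = 27, no_fit = 14) / 205,
      resistant = c(insufficient = 9, dx = 7, gd_theta = 9,
                    gd = 20, gx = 8, no_fit = 3) / 56
    ),
    control = list(
      sensitive = c(insufficient = 18, dx = 12, gd_theta = 5,
                    gd = 31, gx = 27, no_fit = 8) / 101,
      resistant = c(insufficient = 7, dx = 1, gd_theta = 3,
                    gd = 10, gx = 6, no_fit = 4) / 31
    )
  )
}

validate_config <- function(cfg) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (cfg$n_experimental < 1L || cfg$n_control < 1L) add("arm sizes must be positive")
  for (arm in c("experimental", "control")) {
    sp <- cfg$sensitivity_split[[arm]]
    if (is.null(sp) || sp < 0 || sp > 1) {
      add(paste0("sensitivity_split['", arm, "'] must lie in [0, 1]"))
    }
    for (sens in c("sensitive", "resistant")) {
      pr <- cfg$class_probs[[arm]][[sens]]
      if (is.null(pr) || !setequal(names(pr), .CLASS_LEVELS)) {
        add(paste0("class_probs$", arm, "$", sens,
                   " must name the classes ", paste(.CLASS_LEVELS, collapse = ", ")))
      } else if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
        add(paste0("class_probs$", arm, "$", sens, " must be non-negative and sum to 1"))
      }
    }
    if (is.null(cfg$g_median[[arm]]) || cfg$g_median[[arm]] <= 0) {
      add(paste0("g_median['", arm, "'] must be positive"))
    }
  }
  if (cfg$noise_sd < 0) add("noise_sd must be non-negative")
  if (cfg$d_median <= 0) add("d_median must be positive")
  if (cfg$scan_interval <= 0) add("scan_interval must be positive")
  if (cfg$max_scans < 1L) add("max_scans must be at least 1")
  if (cfg$theta_range[1] <= 0 || cfg$theta_range[2] >= 1 ||
      cfg$theta_range[1] >= cfg$theta_range[2]) {
    add("theta_range must be an increasing interval inside (0, 1)")
  }
  if (cfg$dropout_rate < 0) add("dropout_rate must be non-negative")
  if (cfg$os_h0 <= 0 || cfg$os_horizon <= 0) add("os_h0 and os_horizon must be positive")
  if (cfg$dx_floor <= 0) add("dx_floor must be positive")
  problems
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf("Synthetic trial configuration: %d experimental + %d control patients\n",
              x$n_experimental, x$n_control))
  cat(sprintf("  g medians: %.4g (experimental) vs %.4g (control), log-sd %.2g\n",
              x$g_median[["experimental"]], x$g_median[["control"]], x$g_sdlog))
  cat(sprintf("  scans every %g days, up to %d; noise sd %.2g\n",
              x$scan_interval, x$max_scans, x$noise_sd))
  cat(sprintf("  OS hazard %.3g * g^%.2g per month, censored at %g months\n",
              x$os_h0, x$os_beta, x$os_horizon))
  invisible(x)
}

#' Generate a synthetic two-arm trial
#'
#' Draws, per patient: arm (fixed counts), endocrine sensitivity, stratifiers,
#' a kinetic class, class parameters (g, d, theta), a noiseless trajectory at
#' the scan schedule with multiplicative lognormal measurement noise, dropout,
#' and an overall-survival time from an exponential law whose hazard rises
#' with the (true or floored) growth rate, administratively censored at the
#' horizon. Enrollment order is a random permutation. All randomness derives
#' from `seed` through per-patient substreams.
#'
#' @param config a [trial_config()].
#' @param seed integer seed.
#' @return a `synthetic_trial`: list with `measurements` (long scan table),
#'   `survival` (per-patient OS records) and `truth` (per-patient generating
#'   class and parameters; never consumed by the analysis path).
#' @export
simulate_trial <- function(config = trial_config(), seed = 1L) {
  problems <- validate_config(config)
  if (length(problems) > 0L) {
    stop("invalid trial configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  n <- config$n_experimental + config$n_control
  arms <- rep(c("experimental", "control"),
              c(config$n_experimental, config$n_control))
  ids <- sprintf("pt%04d", seq_len(n))
  base_seed <- as.integer(seed) %% 100000L

  meas <- vector("list", n)
  truth <- vector("list", n)
  surv <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((base_seed * 1009L + i * 101L) %% 2147483587L)
    p <- simulate_patient(ids[i], arms[i], config)
    meas[[i]] <- p$measurements
    truth[[i]] <- p$truth
    surv[[i]] <- p$survival
  }
  set.seed((base_seed * 1009L + (n + 1L) * 101L) %% 2147483587L)
  enrollment <- sample.int(n)

  truth <- do.call(rbind, truth)
  surv <- do.call(rbind, surv)
  meta <- data.frame(
    patient_id = ids, arm = arms,
    sensitivity = truth$sensitivity, visceral = truth$visceral,
    age_group = truth$age_group, enrollment_rank = enrollment,
    stringsAsFactors = FALSE
  )
  measurements <- do.call(rbind, meas)
  measurements <- merge(measurements, meta, by = "patient_id", sort = FALSE)
  measurements <- measurements[order(match(measurements$patient_id, ids),
                                     measurements$day), ]
  rownames(measurements) <- NULL
  truth$enrollment_rank <- enrollment
  structure(
    list(measurements = measurements, survival = surv, truth = truth,
         config = config, seed = seed),
    class = "synthetic_trial"
  )
}

simulate_patient <- function(id, arm, cfg) {
  sens <- if (stats::runif(1) < cfg$sensitivity_split[[arm]]) "sensitive" else "resistant"
  visceral <- if (stats::runif(1) < cfg$visceral_prob) "yes" else "no"
  age_group <- if (stats::runif(1) < cfg$age_lt65_prob) "<65" else ">=65"
  cls <- sample(.CLASS_LEVELS, 1L, prob = cfg$class_probs[[arm]][[sens]])

  g <- d <- theta <- NA_real_
  if (cls %in% c("gx", "gd", "gd_theta")) {
    g <- stats::rlnorm(1, log(cfg$g_median[[arm]]), cfg$g_sdlog)
    g <- min(g, 0.4)  # keep inside the fitting bounds
  }
  if (cls %in% c("dx", "gd", "gd_theta")) {
    d <- stats::rlnorm(1, log(cfg$d_median), cfg$d_sdlog)
    d <- min(d, 0.4)
  }
  if (cls == "gd_theta") {
    theta <- stats::runif(1, cfg$theta_range[1], cfg$theta_range[2])
  }

  q0 <- stats::rlnorm(1, log(cfg$baseline_median), cfg$baseline_sdlog)
  times <- cfg$scan_interval * (seq_len(cfg$max_scans) - 1L)

  if (cls == "insufficient") {
    n_scans <- if (stats::runif(1) < 0.5) 1L else 2L
    quantity <- q0
    if (n_scans == 2L) {
      quantity <- c(q0, q0 * (1 + stats::runif(1, -0.19, 0.19)))
    }
    times <- times[seq_len(n_scans)]
  } else {
    f_true <- switch(cls,
      dx = evaluate_model("dx", times, d = d),
      gx = evaluate_model("gx", times, g = g),
      gd = evaluate_model("gd", times, g = g, d = d),
      gd_theta = evaluate_model("gd_theta", times, g = g, d = d, theta = theta),
      no_fit = c(1, exp(stats::rnorm(length(times) - 1L, 0, 0.3)))
    )
    keep <- length(times)
    if (cfg$dropout_rate > 0) {
      for (j in seq_along(times)) {
        if (j <= 3L) next  # early discontinuation is the insufficient class
        p_drop <- 1 - exp(-cfg$dropout_rate * f_true[j])
        if (stats::runif(1) < p_drop) {
          keep <- j - 1L
          break
        }
      }
    }
    times <- times[seq_len(keep)]
    f_true <- f_true[seq_len(keep)]
    noise <- exp(stats::rnorm(length(times), 0, cfg$noise_sd))
    quantity <- q0 * f_true * noise
  }

  g_os <- if (cls %in% c("gx", "gd", "gd_theta")) {
    g
  } else if (cls == "dx") {
    cfg$dx_floor
  } else {
    # latent growth rate used only for the OS link: keeps survival of
    # insufficient/no-fit patients unexceptional for their arm
    stats::rlnorm(1, log(cfg$g_median[[arm]]), cfg$g_sdlog)
  }
  hazard <- cfg$os_h0 * g_os^cfg$os_beta
  os_true <- stats::rexp(1, rate = hazard)
  event <- as.integer(os_true <= cfg$os_horizon)
  os_months <- min(os_true, cfg$os_horizon)

  list(
    measurements = data.frame(
      patient_id = id, day = times, quantity = quantity,
      stringsAsFactors = FALSE
    ),
    survival = data.frame(
      patient_id = id, os_months = os_months, event = event,
      stringsAsFactors = FALSE
    ),
    truth = data.frame(
      patient_id = id, arm = arm, sensitivity = sens,
      visceral = visceral, age_group = age_group, class = cls,
      g = g, d = d, theta = theta, g_os = g_os, os_true = os_true,
      stringsAsFactors = FALSE
    )
  )
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("Synthetic trial: %d patients, %d scans, seed %s\n",
              nrow(x$truth), nrow(x$measurements), format(x$seed)))
  print(table(arm = x$truth$arm, class = x$truth$class))
  invisible(x)
}

#' Parameter-recovery report against generating ground truth
#'
#' Joins the generator's ground truth with the fitted results and summarizes,
#' per kinetic class, how often the selected model matches the generating
#' class and how accurately the rate constants are recovered among matches.
#'
#' @param trial a `synthetic_trial`.
#' @param fits a `growth_fit_table` fitted to `trial$measurements`.
#' @return data frame: per class (plus `overall` across the four kinetic
#'   classes) `n`, `match_fraction`, `median_rel_err_g`, `median_rel_err_d`.
#' @export
recovery_report <- function(trial, fits) {
  truth <- trial$truth
  if (!setequal(truth$patient_id, fits$patient_id)) {
    stop("fits and ground truth cover different patient sets", call. = FALSE)
  }
  merged <- merge(truth, fits, by = "patient_id", suffixes = c("_true", "_fit"))
  merged$category <- fit_category(merged$status, merged$model)
  kinetic <- c("dx", "gx", "gd", "gd_theta")
  one_class <- function(sub) {
    match <- sub$category == sub$class
    rel_g <- abs(sub$g_fit[match] - sub$g_true[match]) / sub$g_true[match]
    rel_d <- abs(sub$d_fit[match] - sub$d_true[match]) / sub$d_true[match]
    data.frame(
      n = nrow(sub),
      match_fraction = mean(match),
      median_rel_err_g = stats::median(rel_g, na.rm = TRUE),
      median_rel_err_d = stats::median(rel_d, na.rm = TRUE)
    )
  }
  rows <- lapply(kinetic, function(cl) {
    sub <- merged[merged$class == cl, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(n = 0L, match_fraction = NA_real_,
                        median_rel_err_g = NA_real_, median_rel_err_d = NA_real_))
    }
    one_class(sub)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, one_class(merged[merged$class %in% kinetic, , drop = FALSE]))
  out <- cbind(class = c(kinetic, "overall"), out)
  rownames(out) <- NULL
  out
}
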