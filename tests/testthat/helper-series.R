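# Shared fixtures: noiseless series builders, an independent Wilcoxon
# enumeration oracle, and a hand-computable product-limit oracle.

default_times <- function(n = 10, interval = 42) interval * (seq_len(n) - 1)

# noiseless series generated straight from a kinetic model
make_series <- function(kind, g = NULL, d = NULL, theta = NULL,
                        times = default_times(), q0 = 100) {
  list(times = times,
       quantity = q0 * evaluate_model(kind, times, g = g, d = d, theta = theta))
}

# long measurements table from a list of per-patient series
make_measurements <- function(series_list, arms = NULL, meta = NULL) {
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    df <- data.frame(patient_id = sprintf("p%03d", i), day = s$times,
                     quantity = s$quantity, stringsAsFactors = FALSE)
    if (!is.null(arms)) df$arm <- arms[i]
    if (!is.null(meta)) df <- cbind(df, meta[i, , drop = FALSE], row.names = NULL)
    df
  })
  do.call(rbind, rows)
}

# a minimal growth_fit_table row built by hand (for cohort-level tests that
# do not need the fitting engine)
fake_fit_row <- function(patient_id, status, model = NA_character_,
                         g = NA_real_, d = NA_real_, ...) {
  extra <- list(...)
  row <- data.frame(
    patient_id = patient_id, status = status, model = model,
    g = g, d = d, theta = NA_real_,
    se_g = NA_real_, se_d = NA_real_, se_theta = NA_real_,
    p_g = NA_real_, p_d = NA_real_, p_theta = NA_real_,
    rss = NA_real_, aic = NA_real_, n_points = 5L,
    stringsAsFactors = FALSE
  )
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

fake_fit_table <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("growth_fit_table", "data.frame")
  out
}

# Independent oracle: exact two-sided Mann-Whitney p by brute-force
# enumeration of every assignment of the pooled ranks to group a.
exact_ranksum_p <- function(a, b) {
  n_a <- length(a)
  pooled <- rank(c(a, b))
  u_obs <- sum(pooled[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  u_all <- apply(combos, 2, function(idx) {
    sum(pooled[idx]) - n_a * (n_a + 1) / 2
  })
  # same doubling convention as the exact two-sided rank-sum test
  if (u_obs > n_a * length(b) / 2) {
    p <- mean(u_all >= u_obs)
  } else {
    p <- mean(u_all <= u_obs)
  }
  min(1, 2 * p)
}

# Independent oracle: product-limit estimator computed directly from its
# definition (loop over distinct times, no survival-package code).
manual_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  times <- sort(unique(time))
  s <- 1
  out <- data.frame(time = numeric(0), survival = numeric(0),
                    n_risk = numeric(0), n_event = numeric(0))
  for (t in times) {
    n_risk <- sum(time >= t)
    n_event <- sum(time == t & event == 1)
    if (n_event > 0) s <- s * (1 - n_event / n_risk)
    out <- rbind(out, data.frame(time = t, survival = s,
                                 n_risk = n_risk, n_event = n_event))
  }
  out
}
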