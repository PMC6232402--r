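#' Contingency table of composite versus gold vital status
#'
#' Cross-classifies every patient by presence of a composite death date and
#' the gold-standard vital-status call: true positives `A` (dead in both),
#' false positives `B` (composite only), false negatives `C` (gold only),
#' true negatives `D` (neither).
#'
#' @param composite Composite tibble covering the cohort (`patient_id`,
#'   `death_date`).
#' @param calls Vital-status calls from [classify_gold_matches()].
#' @return A one-row tibble of class `"mort_contingency"` with columns
#'   `A`, `B`, `C`, `D`, `n`.
#' @export
contingency <- function(composite, calls) {
  require_columns(composite, c("patient_id", "death_date"), "composite")
  require_columns(calls, c("patient_id", "status"), "calls")
  if (!setequal(composite$patient_id, calls$patient_id) ||
      anyDuplicated(composite$patient_id) || anyDuplicated(calls$patient_id)) {
    abort("contingency: composite and vital-status calls must cover the same cohort exactly once",
          class = "mortcomp_coverage_error")
  }
  j <- inner_join(composite, calls, by = "patient_id")
  comp_dead <- !is.na(j$death_date)
  gold_dead <- j$status == "dead"
  new_contingency(A = sum(comp_dead & gold_dead),
                  B = sum(comp_dead & !gold_dead),
                  C = sum(!comp_dead & gold_dead),
                  D = sum(!comp_dead & !gold_dead))
}

new_contingency <- function(A, B, C, D) {
  out <- tibble(A = as.integer(A), B = as.integer(B), C = as.integer(C),
                D = as.integer(D), n = as.integer(A + B + C + D))
  class(out) <- c("mort_contingency", class(out))
  out
}

#' Diagnostic accuracy metrics from a contingency table
#'
#' Sensitivity `A/(A+C)`, specificity `D/(B+D)`, positive predictive value
#' `A/(A+B)` and negative predictive value `D/(C+D)`, each with a Wald
#' normal-approximation confidence interval
#' \eqn{p \pm z \sqrt{p(1-p)/m}} truncated to `[0, 1]`, where `m` is the
#' metric's denominator. A metric with zero denominator is undefined and
#' reported as `NA`, never as 0. An exact Clopper-Pearson interval is
#' available as an option.
#'
#' @param x A `"mort_contingency"` table (e.g. from [contingency()] or
#'   [reconstruct_contingency()]).
#' @param conf_level Confidence level.
#' @param ci_method `"wald"` (default) or `"clopper-pearson"`.
#' @return Tibble with one row per metric: `metric`, `estimate`,
#'   `conf.low`, `conf.high`, `numerator`, `denominator`.
#' @export
metrics <- function(x, conf_level = 0.95,
                    ci_method = c("wald", "clopper-pearson")) {
  stopifnot(inherits(x, "mort_contingency"))
  ci_method <- match.arg(ci_method)
  num <- c(sensitivity = x$A, specificity = x$D, ppv = x$A, npv = x$D)
  den <- c(sensitivity = x$A + x$C, specificity = x$B + x$D,
           ppv = x$A + x$B, npv = x$C + x$D)
  p <- ifelse(den > 0, num / den, NA_real_)
  if (ci_method == "wald") {
    z <- qnorm(1 - (1 - conf_level) / 2)
    hw <- z * sqrt(p * (1 - p) / den)
    lo <- pmax(0, p - hw)
    hi <- pmin(1, p + hw)
  } else {
    cp <- function(k, m) {
      if (is.na(m) || m == 0) return(c(NA_real_, NA_real_))
      stats::binom.test(k, m, conf.level = conf_level)$conf.int
    }
    ci <- mapply(cp, num, den)
    lo <- ci[1, ]; hi <- ci[2, ]
  }
  tibble(metric = names(num), estimate = unname(p),
         conf.low = unname(lo), conf.high = unname(hi),
         numerator = unname(num), denominator = unname(den))
}

#' Windowed death-date agreement
#'
#' Among patients carrying a composite death date, the proportion whose
#' gold-standard death date exists and lies within `window_days` of the
#' composite date (inclusive). Composite deaths without a gold death —
#' false positives — count as disagreements; the denominator is all
#' composite deaths (`A + B`).
#'
#' @param composite Composite tibble.
#' @param calls Vital-status calls (with `gold_death_date`).
#' @param window_days Agreement window in days (0 for exact agreement).
#' @return A single proportion (`NA` when no composite deaths exist).
#' @export
date_agreement <- function(composite, calls, window_days = 0) {
  stopifnot(window_days >= 0)
  require_columns(calls, c("patient_id", "status", "gold_death_date"),
                  "calls")
  j <- composite %>%
    filter(!is.na(.data$death_date)) %>%
    inner_join(calls, by = "patient_id")
  if (nrow(j) == 0) return(NA_real_)
  agree <- j$status == "dead" & !is.na(j$gold_death_date) &
    abs(as.numeric(j$death_date - j$gold_death_date)) <= window_days
  mean(agree)
}

#' Full validation report for one composite dataset version
#'
#' Combines the contingency table, the four accuracy metrics with
#' confidence intervals, and exact/windowed date agreement into a single
#' benchmark result.
#'
#' @param composite Composite tibble for one version.
#' @param calls Vital-status calls.
#' @param windows Agreement windows in days.
#' @param label Optional version label.
#' @param conf_level Confidence level for metric intervals.
#' @return An object of class `"mort_validation"`; see [tidy()] and
#'   [glance()] methods.
#' @export
validation_report <- function(composite, calls, windows = c(0, 15, 30),
                              label = NULL, conf_level = 0.95) {
  ct <- contingency(composite, calls)
  agr <- tibble(window_days = windows,
                agreement = vapply(windows, function(w)
                  date_agreement(composite, calls, w), numeric(1)))
  structure(list(label = label %||% "composite",
                 contingency = ct,
                 metrics = metrics(ct, conf_level = conf_level),
                 agreement = agr),
            class = "mort_validation")
}

#' @export
print.mort_validation <- function(x, ...) {
  ct <- x$contingency
  cat(sprintf("<mort_validation> %s (n = %d; A=%d B=%d C=%d D=%d)\n",
              x$label, ct$n, ct$A, ct$B, ct$C, ct$D))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %6.2f%% (%5.2f%%, %5.2f%%)\n", m$metric[i],
                100 * m$estimate[i], 100 * m$conf.low[i],
                100 * m$conf.high[i]))
  }
  for (i in seq_len(nrow(x$agreement))) {
    cat(sprintf("  date agreement (+/-%d d): %.2f%%\n",
                x$agreement$window_days[i], 100 * x$agreement$agreement[i]))
  }
  invisible(x)
}

#' Benchmark every composite dataset version
#'
#' Computes the full validation surface — accuracy metrics with confidence
#' intervals and windowed date agreement — for each stepwise dataset
#' version, one row per version in development order.
#'
#' @param versions Tibble from [build_dataset_versions()].
#' @param calls Vital-status calls.
#' @param windows Agreement windows in days.
#' @return Tibble with one row per version: contingency counts, the four
#'   metrics with `.low`/`.high` interval bounds, and one
#'   `date_agreement_<w>` column per window (all proportions).
#' @export
benchmark_versions <- function(versions, calls, windows = c(0, 15, 30)) {
  versions %>%
    group_by(.data$version) %>%
    dplyr::group_map(function(comp, key) {
      glance(validation_report(comp, calls, windows = windows,
                               label = as.character(key$version)))
    }) %>%
    bind_rows() %>%
    mutate(version = factor(.data$version, levels = version_labels)) %>%
    arrange(.data$version)
}

#' Per-practice sensitivity summary
#'
#' Sensitivity of the composite computed separately within each practice,
#' restricted to practices with at least `min_patients` patients so that
#' small practices with a handful of deaths do not dominate the spread.
#' Boxplot statistics use type-7 quantiles with whiskers at the most
#' extreme values within 1.5 IQR of the hinges.
#'
#' @param composite Composite tibble.
#' @param calls Vital-status calls.
#' @param cohort Cohort tibble carrying `practice_id`.
#' @param min_patients Minimum practice size for inclusion.
#' @return An object of class `"mort_practice_summary"`: list with
#'   `per_practice` (practice, n, gold deaths, sensitivity) and `stats`
#'   (median, hinges, whiskers, outliers).
#' @export
per_practice_sensitivity <- function(composite, calls, cohort,
                                     min_patients = 100) {
  require_columns(cohort, c("patient_id", "practice_id"), "cohort")
  per <- cohort %>%
    select("patient_id", "practice_id") %>%
    inner_join(composite, by = "patient_id") %>%
    inner_join(calls, by = "patient_id") %>%
    group_by(.data$practice_id) %>%
    summarise(n_patients = n(),
              n_gold_deaths = sum(.data$status == "dead"),
              .n_tp = sum(.data$status == "dead" & !is.na(.data$death_date)),
              .groups = "drop") %>%
    mutate(sensitivity = if_else(.data$n_gold_deaths > 0,
                                 .data$.n_tp / .data$n_gold_deaths,
                                 NA_real_)) %>%
    select(-".n_tp") %>%
    filter(.data$n_patients >= min_patients, !is.na(.data$sensitivity))
  if (nrow(per) == 0) {
    warn(sprintf("per_practice_sensitivity: no practice with >= %d patients",
                 min_patients))
    stats <- tibble(median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                    whisker_low = NA_real_, whisker_high = NA_real_)
    outliers <- numeric(0)
  } else {
    s <- per$sensitivity
    q <- quantile(s, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    in_lo <- s[s >= q[1] - 1.5 * iqr]
    in_hi <- s[s <= q[3] + 1.5 * iqr]
    stats <- tibble(median = q[2], q25 = q[1], q75 = q[3],
                    whisker_low = if (length(in_lo)) min(in_lo) else NA_real_,
                    whisker_high = if (length(in_hi)) max(in_hi) else NA_real_)
    outliers <- s[s < stats$whisker_low | s > stats$whisker_high]
  }
  structure(list(per_practice = per, stats = stats, outliers = outliers,
                 min_patients = min_patients),
            class = "mort_practice_summary")
}

#' @export
print.mort_practice_summary <- function(x, ...) {
  cat(sprintf("<mort_practice_summary> %d practice(s) with >= %d patients\n",
              nrow(x$per_practice), x$min_patients))
  if (nrow(x$per_practice)) {
    with(x$stats, cat(sprintf(
      "  sensitivity median %.3f, hinges [%.3f, %.3f], whiskers [%.3f, %.3f], %d outlier(s)\n",
      median, q25, q75, whisker_low, whisker_high, length(x$outliers))))
  }
  invisible(x)
}

#' Reconstruct a contingency table from rounded published metrics
#'
#' Recovers the integer 2x2 table behind a published row of accuracy
#' metrics. Given the total `n` and the printed specificity, PPV and NPV
#' (proportions rounded to the printed precision), it searches non-negative
#' integer tables `A + B + C + D = n` minimising the summed absolute
#' deviation of the three recomputed metrics from the inputs, and returns
#' the minimiser — from which the unpublished sensitivity (or any cell)
#' can be read off.
#'
#' The search is exact but bounded: since each printed value differs from
#' the true metric by at most half a unit of printed precision, only
#' candidates with every per-metric deviation below `tol` can contain the
#' minimiser. Ties are broken by smallest `B`, then smallest `C`, then
#' smallest `D`. An `NA` input metric is unconstrained. If no table lies
#' within tolerance the inputs are inconsistent and an error of class
#' `"mortcomp_infeasible"` is thrown.
#'
#' @param specificity,ppv,npv Printed metrics as proportions (e.g. 0.9706
#'   for 97.06%); `NA` to leave unconstrained.
#' @param n Total number of patients.
#' @param tol Per-metric feasibility bound; the default 2e-4 covers values
#'   printed to two decimals in percent with margin.
#' @return A `"mort_contingency"` tibble with attribute `"deviation"`.
#' @export
reconstruct_contingency <- function(specificity, ppv, npv, n, tol = 2e-4) {
  stopifnot(length(n) == 1, n >= 0)
  n <- as.integer(n)
  # candidate (A, B) pairs from the PPV constraint
  if (!is.na(ppv) && ppv < 1) {
    B <- 0:n
    A_lo <- pmax(0, ceiling(B * (ppv - tol) / (1 - ppv + tol)))
    A_hi <- pmin(n - B, floor(B * (ppv + tol) / max(1 - ppv - tol, 1e-12)))
    keep <- which(A_hi - A_lo >= 0)
    Av <- unlist(mapply(seq, A_lo[keep], A_hi[keep], SIMPLIFY = FALSE),
                 use.names = FALSE)
    Bv <- rep(B[keep], A_hi[keep] - A_lo[keep] + 1L)
  } else if (!is.na(ppv)) {  # ppv == 1 forces B = 0
    Bv <- rep(0L, n + 1L); Av <- 0:n
  } else {
    g <- expand.grid(A = 0:n, B = 0:n)
    g <- g[g$A + g$B <= n, ]
    Av <- g$A; Bv <- g$B
  }
  # candidate D from the NPV constraint
  rem <- n - Av - Bv
  if (!is.na(npv)) {
    D_lo <- pmax(0, ceiling(rem * (npv - tol)))
    D_hi <- pmin(rem, floor(rem * (npv + tol)))
  } else {
    D_lo <- rep(0, length(rem)); D_hi <- rem
  }
  keep <- which(D_hi - D_lo >= 0)
  if (!length(keep)) {
    abort("reconstruct_contingency: no integer table within rounding tolerance of the inputs",
          class = "mortcomp_infeasible")
  }
  A <- rep(Av[keep], D_hi[keep] - D_lo[keep] + 1L)
  B <- rep(Bv[keep], D_hi[keep] - D_lo[keep] + 1L)
  D <- unlist(mapply(seq, D_lo[keep], D_hi[keep], SIMPLIFY = FALSE),
              use.names = FALSE)
  C <- n - A - B - D
  dev_term <- function(est, target) {
    if (is.na(target)) return(rep(0, length(est)))
    ifelse(is.na(est), Inf, abs(est - target))
  }
  dev <- dev_term(ifelse(B + D > 0, D / (B + D), NA), specificity) +
    dev_term(ifelse(A + B > 0, A / (A + B), NA), ppv) +
    dev_term(ifelse(C + D > 0, D / (C + D), NA), npv)
  feas <- which(is.finite(dev) & dev <= 3 * tol)
  if (!length(feas)) {
    abort("reconstruct_contingency: no integer table within rounding tolerance of the inputs",
          class = "mortcomp_infeasible")
  }
  o <- feas[order(dev[feas], B[feas], C[feas], D[feas])][1]
  out <- new_contingency(A[o], B[o], C[o], D[o])
  attr(out, "deviation") <- dev[o]
  out
}
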