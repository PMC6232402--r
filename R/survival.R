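#' Build survival-analysis inputs from a composite mortality table
#'
#' Converts a composite table into right-censored time-to-event records
#' with the advanced-diagnosis date as time origin. Patients with a
#' composite death date contribute an event at that date; others are
#' censored at their last activity capped at the study cutoff
#' (`censor = "last_activity"`, the EHR convention) or at the cutoff itself
#' (`censor = "cutoff"`, appropriate for a gold standard assumed complete).
#' Patients whose event would precede the time origin are excluded with a
#' warning — upstream plausibility filtering normally removes them.
#'
#' @param composite Composite tibble (`patient_id`, `death_date`); to build
#'   the gold-standard curve, pass the vital-status calls with
#'   `gold_death_date` renamed to `death_date`.
#' @param cohort Cohort tibble with `advanced_diagnosis_date` and
#'   `last_activity_date`.
#' @param cutoff Study cutoff date.
#' @param censor Censoring convention for patients without an event.
#' @return Tibble: `patient_id`, `time` (days from diagnosis), `event`
#'   (1 death, 0 censored).
#' @export
survival_input <- function(composite, cohort, cutoff,
                           censor = c("last_activity", "cutoff")) {
  censor <- match.arg(censor)
  cutoff <- as.Date(cutoff)
  require_columns(cohort,
                  c("patient_id", "advanced_diagnosis_date",
                    "last_activity_date"), "cohort")
  out <- composite %>%
    select("patient_id", "death_date") %>%
    inner_join(cohort %>%
                 select("patient_id", "advanced_diagnosis_date",
                        "last_activity_date"),
               by = "patient_id") %>%
    mutate(
      censor_date = if (censor == "cutoff") cutoff
                    else pmin(.data$last_activity_date, cutoff),
      event = as.integer(!is.na(.data$death_date)),
      end_date = if_else(.data$event == 1L, .data$death_date,
                         .data$censor_date),
      time = as.numeric(.data$end_date - .data$advanced_diagnosis_date)
    )
  neg <- out$time < 0
  if (any(neg)) {
    warn(sprintf("survival_input: excluding %d patient(s) with event or censoring before diagnosis",
                 sum(neg)))
    out <- out[!neg, , drop = FALSE]
  }
  out %>% select("patient_id", "time", "event")
}

#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' over the distinct event times, with censorings at an event time leaving
#' the risk set after the event (events first). Fitting is delegated to
#' [survival::survfit()].
#'
#' @param inputs Tibble from [survival_input()].
#' @return A tibble of class `"mort_km"`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, with attributes `n` (subjects) and `median`
#'   (median survival in days, `NA` if never reached).
#' @export
km_estimate <- function(inputs) {
  require_columns(inputs, c("time", "event"), "inputs")
  if (nrow(inputs) == 0) abort("km_estimate: no subjects")
  if (all(inputs$event == 0)) {
    warn("km_estimate: no events observed; survival curve is identically 1")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = inputs, conf.type = "none")
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, surv = fit$surv)
  class(out) <- c("mort_km", class(out))
  attr(out, "n") <- fit$n
  med <- unname(summary(fit)$table["median"])
  attr(out, "median") <- if (is.na(med)) NA_real_ else as.numeric(med)
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function evaluation: `S(t)` is the estimate after the last event
#' time at or before `t`, and 1 before the first event.
#'
#' @param km A `"mort_km"` curve.
#' @param times Numeric vector of times (days).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, times) {
  ev <- km %>% filter(.data$n_event > 0)
  if (nrow(ev) == 0) return(rep(1, length(times)))
  stats::approx(x = ev$time, y = ev$surv, xout = times, method = "constant",
                f = 0, yleft = 1, rule = 2)$y
}

#' Compare version survival curves against the gold-standard curve
#'
#' For each composite dataset version: median survival, survival at each
#' requested horizon, and the largest horizon-wise excess over the
#' gold-standard curve. Positive excess flags survival overestimation —
#' the signature of missed deaths masquerading as censorings.
#'
#' @param curves Named list of `"mort_km"` curves, one per version.
#' @param gold_curve The gold-standard `"mort_km"` curve.
#' @param horizons Numeric vector of horizons in days (may be empty, in
#'   which case only medians are reported).
#' @return Tibble: `version`, `median_days` (`NA` = not reached), one
#'   `surv_<h>d` column per horizon, and `max_overestimate`.
#' @export
compare_curves <- function(curves, gold_curve, horizons = c(365, 730)) {
  stopifnot(inherits(gold_curve, "mort_km"))
  gold_s <- km_surv_at(gold_curve, horizons)
  purrr::imap(curves, function(cv, label) {
    s <- km_surv_at(cv, horizons)
    row <- tibble(version = label,
                  median_days = attr(cv, "median") %||% NA_real_)
    if (length(horizons)) {
      row <- dplyr::bind_cols(
        row, setNames(as.list(s), sprintf("surv_%dd", horizons)))
      row$max_overestimate <- max(s - gold_s)
    }
    row
  }) %>%
    bind_rows()
}
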