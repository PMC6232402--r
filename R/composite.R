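version_labels <- c("EHR_only", "SSDI_only", "EHR_CDD1", "EHR_CDD1_SSDI",
                    "EHR_CDD1_SSDI_ABS")

version_sources <- list(
  EHR_only = "EHR",
  SSDI_only = "SSDI",
  EHR_CDD1 = c("EHR", "CDD1"),
  EHR_CDD1_SSDI = c("EHR", "CDD1", "SSDI"),
  EHR_CDD1_SSDI_ABS = c("EHR", "CDD1", "SSDI")  # ABS enters via gap fill only
)

#' Resolve per-patient death dates from multiple source assertions
#'
#' Amalgamates linked death assertions into one date per patient. When two
#' or more sources assert the same date, that date wins regardless of
#' source order. When all asserted dates conflict, the source hierarchy
#' decides: SSDI is preferred (most reliable against the gold standard),
#' then commercial death data, then the structured EHR field. A single
#' assertion is taken as is. Duplicate assertions from one source are
#' collapsed to that source's earliest date before resolution.
#'
#' @param assertions Tibble with `patient_id`, `source_id`, `death_date`
#'   (rows with missing dates are ignored).
#' @param hierarchy Character vector of source ids in decreasing priority,
#'   used when asserted dates conflict (and, defensively, to break ties
#'   between equally supported dates).
#' @return Tibble with one row per patient holding a date: `patient_id`,
#'   `death_date`, `contributing_sources` (sources asserting the chosen
#'   date, `"+"`-joined), `resolution` (`"single_source"`,
#'   `"two_or_more_agree"`, or `"hierarchy_<source>"`).
#' @export
resolve_death_dates <- function(assertions,
                                hierarchy = c("SSDI", "CDD1", "EHR")) {
  require_columns(assertions, c("patient_id", "source_id", "death_date"),
                  "assertions")
  kept <- assertions %>%
    filter(!is.na(.data$death_date), !is.na(.data$patient_id))
  if (nrow(kept) == 0) {
    return(tibble(patient_id = character(0),
                  death_date = as.Date(character(0)),
                  contributing_sources = character(0),
                  resolution = character(0)))
  }
  asr <- kept %>%
    group_by(.data$patient_id, .data$source_id) %>%
    summarise(death_date = min(.data$death_date), .groups = "drop") %>%
    mutate(.pri = match(.data$source_id, hierarchy,
                        nomatch = length(hierarchy) + 1L))

  totals <- asr %>% count(.data$patient_id, name = ".n_assert")

  asr %>%
    group_by(.data$patient_id, .data$death_date) %>%
    summarise(.n_support = n(),
              .best_pri = min(.data$.pri),
              contributing_sources = paste(
                .data$source_id[order(.data$.pri)], collapse = "+"),
              .groups = "drop_last") %>%
    arrange(dplyr::desc(.data$.n_support), .data$.best_pri, .data$death_date,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    left_join(totals, by = "patient_id") %>%
    mutate(resolution = dplyr::case_when(
      .data$.n_assert == 1 ~ "single_source",
      .data$.n_support >= 2 ~ "two_or_more_agree",
      TRUE ~ paste0("hierarchy_",
                    sub("\\+.*$", "", .data$contributing_sources))
    )) %>%
    select("patient_id", "death_date", "contributing_sources", "resolution")
}

#' @keywords internal
#' Extend a resolved table to cover every cohort patient.
complete_composite <- function(resolved, cohort) {
  cohort %>%
    select("patient_id") %>%
    left_join(resolved, by = "patient_id") %>%
    mutate(contributing_sources = dplyr::coalesce(.data$contributing_sources,
                                                  ""),
           resolution = dplyr::coalesce(.data$resolution, "none"))
}

#' Remove implausible death dates
#'
#' Clears any composite death date falling strictly before the patient's
#' advanced-diagnosis date — a known error mode of source data — and flags
#' the row `removed_implausible`. A death on the diagnosis date itself is
#' retained.
#'
#' @param composite Composite tibble (full cohort coverage).
#' @param cohort Cohort tibble carrying `advanced_diagnosis_date`.
#' @return The composite tibble with implausible dates cleared.
#' @export
plausibility_filter <- function(composite, cohort) {
  require_columns(cohort, c("patient_id", "advanced_diagnosis_date"), "cohort")
  composite %>%
    left_join(cohort %>% select("patient_id", "advanced_diagnosis_date"),
              by = "patient_id") %>%
    mutate(
      .bad = !is.na(.data$death_date) &
        .data$death_date < .data$advanced_diagnosis_date,
      death_date = if_else(.data$.bad, as.Date(NA), .data$death_date),
      contributing_sources = if_else(.data$.bad, "",
                                     .data$contributing_sources),
      resolution = if_else(.data$.bad, "removed_implausible",
                           .data$resolution)
    ) %>%
    select(-".bad", -"advanced_diagnosis_date")
}

#' Fill composite gaps from chart abstraction
#'
#' Chart-abstracted death dates never participate in conflict resolution:
#' they only fill gaps. A patient receives an abstracted date only when the
#' composite has no date for them and their last recorded activity is more
#' than `recency_days` before `reference_date` — recently active patients
#' are presumed alive and are never filled.
#'
#' @param composite Composite tibble (full cohort coverage).
#' @param abs_assertions Tibble of linked abstraction assertions
#'   (`patient_id`, `death_date`).
#' @param cohort Cohort tibble carrying `last_activity_date`.
#' @param recency_days Activity recency window (days).
#' @param reference_date Date the recency window is measured from; defaults
#'   to the latest last-activity date in the cohort (use the study cutoff
#'   in pipeline runs).
#' @return The composite tibble with eligible gaps filled
#'   (`resolution = "abs_fill"`).
#' @export
abs_fill <- function(composite, abs_assertions, cohort, recency_days = 60,
                     reference_date = NULL) {
  require_columns(cohort, c("patient_id", "last_activity_date"), "cohort")
  if (is.null(reference_date)) {
    reference_date <- max(cohort$last_activity_date)
  }
  reference_date <- as.Date(reference_date)
  kept <- abs_assertions %>%
    filter(!is.na(.data$patient_id), !is.na(.data$death_date))
  abs_dates <- if (nrow(kept) == 0) {
    tibble(patient_id = character(0), .abs_date = as.Date(character(0)))
  } else {
    kept %>%
      group_by(.data$patient_id) %>%
      summarise(.abs_date = min(.data$death_date), .groups = "drop")
  }
  composite %>%
    left_join(abs_dates, by = "patient_id") %>%
    left_join(cohort %>% select("patient_id", "last_activity_date"),
              by = "patient_id") %>%
    mutate(
      .fill = is.na(.data$death_date) & !is.na(.data$.abs_date) &
        .data$last_activity_date < reference_date - recency_days,
      death_date = if_else(.data$.fill, .data$.abs_date, .data$death_date),
      contributing_sources = if_else(.data$.fill, "ABS",
                                     .data$contributing_sources),
      resolution = if_else(.data$.fill, "abs_fill", .data$resolution)
    ) %>%
    select(-".abs_date", -".fill", -"last_activity_date")
}

#' Build the stepwise composite dataset versions
#'
#' Reproduces the sequential development of the composite mortality
#' variable: structured EHR alone, SSDI alone, EHR plus commercial death
#' data, EHR-CDD1 plus SSDI, and the final version adding chart-abstracted
#' dates as gap fill. Every version passes through the plausibility filter;
#' the final version applies abstraction fill before filtering.
#'
#' @param cohort Cohort tibble.
#' @param assertions Long tibble of linked assertions across all sources
#'   (`patient_id`, `source_id`, `death_date`).
#' @param reference_date Recency reference for abstraction fill (study
#'   cutoff in pipeline runs).
#' @param recency_days Activity recency window for abstraction fill.
#' @return A tibble with a `version` factor column (ordered as above) and
#'   the composite columns, covering every cohort patient in every version.
#' @export
build_dataset_versions <- function(cohort, assertions, reference_date = NULL,
                                   recency_days = 60) {
  purrr::imap(version_sources, function(srcs, label) {
    comp <- assertions %>%
      filter(.data$source_id %in% srcs) %>%
      resolve_death_dates() %>%
      complete_composite(cohort)
    if (label == "EHR_CDD1_SSDI_ABS") {
      comp <- abs_fill(comp,
                       assertions %>% filter(.data$source_id == "ABS"),
                       cohort, recency_days = recency_days,
                       reference_date = reference_date)
    }
    comp %>%
      plausibility_filter(cohort) %>%
      mutate(version = label, .before = 1)
  }) %>%
    bind_rows() %>%
    mutate(version = factor(.data$version, levels = version_labels))
}
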