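#' @keywords internal
#' Day/month-swapped birth date, NA where the swap is not a valid date.
swap_day_month <- function(d) {
  lt <- as.POSIXlt(d)
  ok <- !is.na(d) & lt$mday <= 12
  out <- rep(as.Date(NA), length(d))
  out[ok] <- as.Date(sprintf("%04d-%02d-%02d", lt$year[ok] + 1900,
                             lt$mday[ok], lt$mon[ok] + 1))
  out
}

norm_name <- function(x) stringr::str_trim(tolower(x))

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing identifier column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "mortcomp_schema_error")
  }
}

#' Match external records to cohort patients
#'
#' Deterministic multi-pass linkage on patient identifiers. A record is
#' tried against the cohort in three passes of decreasing stringency, and
#' the first pass that identifies exactly one patient wins:
#'
#' 1. `exact` — last name, first name and birth date all agree;
#' 2. `name_dob` — last name and birth date agree and the first name is
#'    within Levenshtein distance `max_name_edit` (a single typo);
#' 3. `name_state` — last and first name and state agree and the birth
#'    dates are related by a day/month field swap.
#'
#' Name comparison is case-insensitive and whitespace-trimmed. If two or
#' more patients tie within a pass the record is left unmatched rather than
#' guessed: misidentification is costlier than a missed link.
#'
#' @param cohort Cohort tibble carrying `patient_id`, `first_name`,
#'   `last_name`, `birth_date`, `state`.
#' @param records Record tibble carrying `record_id` and the same
#'   identifier fields.
#' @param max_name_edit Maximum Levenshtein distance for the fuzzy
#'   first-name pass.
#' @return Tibble with one row per record: `record_id`, `patient_id` (`NA`
#'   if unmatched), `match_pass` (`"exact"`, `"name_dob"`, `"name_state"`,
#'   or `NA`), and ordinal `score` (3 best, 0 unmatched).
#' @export
match_records <- function(cohort, records, max_name_edit = 1) {
  id_cols <- c("first_name", "last_name", "birth_date", "state")
  require_columns(cohort, c("patient_id", id_cols), "cohort")
  require_columns(records, c("record_id", id_cols), "records")

  cht <- cohort %>%
    dplyr::transmute(patient_id = .data$patient_id,
                     c_first = norm_name(.data$first_name),
                     c_last = norm_name(.data$last_name),
                     c_dob = .data$birth_date,
                     c_dob_swap = swap_day_month(.data$birth_date),
                     c_state = .data$state)
  rec <- records %>%
    dplyr::transmute(record_id = .data$record_id,
                     r_first = norm_name(.data$first_name),
                     r_last = norm_name(.data$last_name),
                     r_dob = .data$birth_date,
                     r_dob_swap = swap_day_month(.data$birth_date),
                     r_state = .data$state)

  # A record with >= 2 candidate patients in a pass is finally unmatched:
  # guessing risks misidentification. `settled` collects record ids that are
  # either matched or ambiguous, so later passes never see them.
  settled <- character(0)
  unique_hits <- function(pairs) {
    cand <- pairs %>% distinct(.data$record_id, .data$patient_id)
    counts <- cand %>% count(.data$record_id)
    settled <<- c(settled, counts$record_id)
    cand %>% semi_join(counts %>% filter(.data$n == 1), by = "record_id")
  }

  # pass 1: exact on (last, first, dob)
  p1 <- rec %>%
    inner_join(cht, by = c(r_last = "c_last", r_first = "c_first",
                           r_dob = "c_dob")) %>%
    unique_hits() %>%
    mutate(match_pass = "exact", score = 3L)

  rec2 <- rec %>% filter(!.data$record_id %in% settled)
  # pass 2: (last, dob) with fuzzy first name
  p2 <- rec2 %>%
    inner_join(cht, by = c(r_last = "c_last", r_dob = "c_dob"),
               relationship = "many-to-many") %>%
    filter(purrr::map2_int(.data$r_first, .data$c_first,
                           ~ as.integer(adist(.x, .y))) <= max_name_edit) %>%
    unique_hits() %>%
    mutate(match_pass = "name_dob", score = 2L)

  rec3 <- rec2 %>% filter(!.data$record_id %in% settled)
  # pass 3: (last, first, state) with day/month-swapped birth date
  p3 <- rec3 %>%
    inner_join(cht, by = c(r_last = "c_last", r_first = "c_first",
                           r_state = "c_state"),
               relationship = "many-to-many") %>%
    filter((!is.na(.data$r_dob_swap) & .data$r_dob_swap == .data$c_dob) |
             (!is.na(.data$c_dob_swap) & .data$r_dob == .data$c_dob_swap)) %>%
    unique_hits() %>%
    mutate(match_pass = "name_state", score = 1L)

  hits <- bind_rows(p1, p2, p3) %>%
    select("record_id", "patient_id", "match_pass", "score")
  rec %>%
    select("record_id") %>%
    left_join(hits, by = "record_id") %>%
    mutate(score = dplyr::coalesce(.data$score, 0L))
}

#' Classify gold-index matches into vital-status calls
#'
#' Applies the conservative vital-status rules of gold-standard
#' benchmarking: a patient with no linked gold record is alive
#' (`no_gold_record`); a gold death record annotated as an `exact` or
#' `probable` match makes the patient dead; records flagged as likely false
#' matches or unclassifiable leave the patient alive. Every cohort patient
#' receives exactly one call. The observed class fractions are attached as
#' the `"class_fractions"` attribute for run logging.
#'
#' @param cohort Cohort tibble.
#' @param gold_records Gold record tibble from [generate_gold()] (needs
#'   `record_id`, `death_date`, `match_quality`).
#' @param matches Match table from [match_records()] run on the gold
#'   records.
#' @return Tibble with one row per patient: `patient_id`, `status`
#'   (`"dead"`/`"alive"`), `reason`, `gold_death_date` (`NA` unless dead).
#' @export
classify_gold_matches <- function(cohort, gold_records, matches) {
  require_columns(gold_records, c("record_id", "death_date", "match_quality"),
                  "gold_records")
  bad <- !is.na(gold_records$death_date) & is.na(gold_records$match_quality)
  if (any(bad)) {
    abort(sprintf(
      "classify_gold_matches: %d gold death record(s) carry no match_quality",
      sum(bad)), class = "mortcomp_data_error")
  }
  linked <- gold_records %>%
    inner_join(matches %>% filter(!is.na(.data$patient_id)),
               by = "record_id") %>%
    mutate(.pri = match(.data$match_quality,
                        c("exact", "probable", "likely_false",
                          "unclassifiable"))) %>%
    group_by(.data$patient_id) %>%
    arrange(.data$.pri, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()

  calls <- cohort %>%
    select("patient_id") %>%
    left_join(linked %>% select("patient_id", "death_date", "match_quality"),
              by = "patient_id") %>%
    mutate(
      reason = dplyr::case_when(
        is.na(.data$match_quality) ~ "no_gold_record",
        .data$match_quality == "exact" ~ "exact_match",
        .data$match_quality == "probable" ~ "probable_match",
        .data$match_quality == "likely_false" ~ "likely_false_match",
        TRUE ~ "unclassifiable"
      ),
      status = if_else(.data$reason %in% c("exact_match", "probable_match"),
                       "dead", "alive"),
      gold_death_date = if_else(.data$status == "dead", .data$death_date,
                                as.Date(NA))
    ) %>%
    select("patient_id", "status", "reason", "gold_death_date")

  fr <- calls %>% count(.data$reason) %>%
    mutate(fraction = .data$n / sum(.data$n))
  attr(calls, "class_fractions") <- fr
  calls
}
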