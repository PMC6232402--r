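# Small, fully in-code fixtures shared across test files.

# A compact config for fast end-to-end runs.
tiny_config <- function(n = 300, seed = 7, ...) {
  sim_config(n_patients = n, n_practices = 5, seed = seed, ...)
}

# Error-free study conditions: every source complete and exact, no identifier
# corruption, no spurious records, no loss to follow-up, perfect gold index.
perfect_config <- function(n = 500, seed = 11) {
  perfect <- function(id) {
    source_spec(id, capture_prob = 1, false_record_prob = 0,
                date_exact_prob = 1, year_typo_prob = 0,
                id_corruption_rate = 0)
  }
  sim_config(
    n_patients = n, n_practices = 4, seed = seed,
    practice_heterogeneity = Inf, ltfu_prob = 0,
    source_specs = lapply(
      setNames(nm = c("EHR", "CDD1", "SSDI", "ABS")), perfect),
    gold_spec = gold_spec(capture_prob = 1,
                          class_probs = c(exact = 1, probable = 0,
                                          unclassifiable = 0),
                          likely_false_rate = 0, id_corruption_rate = 0)
  )
}

# Three distinguishable patients for hand-checkable linkage fixtures.
linkage_cohort <- function() {
  tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    first_name = c("Maria", "Jonas", "Elena"),
    last_name = c("Varga", "Holt", "Prenn"),
    birth_date = as.Date(c("1950-03-04", "1962-11-07", "1947-06-02")),
    state = c("NY", "CA", "TX")
  )
}

# Assertions helper: quick long-format death assertions.
asrt <- function(...) {
  rows <- list(...)
  tibble::tibble(
    patient_id = vapply(rows, `[[`, "", 1),
    source_id = vapply(rows, `[[`, "", 2),
    death_date = as.Date(vapply(rows, `[[`, "", 3))
  )
}

# Link source records to patients through the generator's hidden truth link,
# bypassing identifier matching (used where linkage is not under test).
truth_linked_assertions <- function(study) {
  dplyr::bind_rows(lapply(study$sources, function(s) {
    tibble::tibble(patient_id = s$.truth_patient_id,
                   source_id = s$source_id,
                   death_date = s$death_date)
  }))
}

# Vital-status calls straight from ground truth (perfect gold).
truth_calls <- function(cohort) {
  tibble::tibble(
    patient_id = cohort$patient_id,
    status = ifelse(is.na(cohort$true_death_date), "alive", "dead"),
    reason = ifelse(is.na(cohort$true_death_date), "no_gold_record",
                    "exact_match"),
    gold_death_date = cohort$true_death_date
  )
}
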