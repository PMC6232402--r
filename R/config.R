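#' Specification of one mortality data source
#'
#' A `source_spec` describes the error model of a single mortality source:
#' how often a true death yields a record (`capture_prob`), how often an
#' alive patient acquires a spurious death record (`false_record_prob`),
#' and how recorded dates and identifiers are degraded.
#'
#' Recorded dates are exact with probability `date_exact_prob`; otherwise
#' they receive a small Gaussian offset (sd `small_offset_sd_days`, rounded
#' to whole days, never zero) or, with probability `year_typo_prob`, a
#' +/-365-day shift emulating a mistyped year of death.
#'
#' `internal` marks sources whose records live inside the EHR system and
#' therefore carry the patient id directly (structured EHR fields, chart
#' abstraction); external sources (commercial death data, SSDI) must be
#' linked back to the cohort through identifier matching, and only their
#' identifiers are subject to corruption.
#'
#' @param source_id One of `"EHR"`, `"CDD1"`, `"SSDI"`, `"ABS"`.
#' @param capture_prob Probability a true death is recorded by this source.
#' @param false_record_prob Probability an alive patient gets a spurious
#'   death record.
#' @param date_exact_prob Probability a captured death date is exact.
#' @param small_offset_sd_days Standard deviation (days) of small date errors.
#' @param year_typo_prob Probability a captured date is shifted by exactly
#'   +/-365 days.
#' @param id_corruption_rate Probability each identifier field of a record is
#'   perturbed (external sources only).
#' @param internal Logical; records carry the patient id directly.
#' @return An object of class `"mort_source_spec"`.
#' @export
source_spec <- function(source_id = c("EHR", "CDD1", "SSDI", "ABS"),
                        capture_prob,
                        false_record_prob = 0.001,
                        date_exact_prob = 0.95,
                        small_offset_sd_days = 7,
                        year_typo_prob = 0.005,
                        id_corruption_rate = 0,
                        internal = source_id %in% c("EHR", "ABS")) {
  source_id <- match.arg(source_id)
  probs <- c(capture_prob = capture_prob, false_record_prob = false_record_prob,
             date_exact_prob = date_exact_prob, year_typo_prob = year_typo_prob,
             id_corruption_rate = id_corruption_rate)
  if (any(probs < 0 | probs > 1)) {
    abort(sprintf("source_spec('%s'): probabilities must lie in [0, 1] (got %s)",
                  source_id,
                  paste(names(probs)[probs < 0 | probs > 1], collapse = ", ")))
  }
  if (small_offset_sd_days < 0) {
    abort("source_spec: `small_offset_sd_days` must be >= 0")
  }
  structure(
    list(source_id = source_id, capture_prob = capture_prob,
         false_record_prob = false_record_prob,
         date_exact_prob = date_exact_prob,
         small_offset_sd_days = small_offset_sd_days,
         year_typo_prob = year_typo_prob,
         id_corruption_rate = id_corruption_rate,
         internal = isTRUE(internal)),
    class = "mort_source_spec"
  )
}

#' Default source specifications
#'
#' Capture probabilities are calibrated so that, under independent capture,
#' the stepwise union sensitivities of the composite versions reach the
#' published benchmarks for advanced NSCLC: 0.66 for structured EHR alone,
#' 0.84 after adding commercial death data, 0.89 after adding the SSDI and
#' 0.91 after chart abstraction. Solving
#' \eqn{1 - \prod_k (1 - p_k)} for each step gives the marginal capture
#' probabilities used here. Date-exactness defaults mirror the published
#' exact date agreement of each source (structured EHR about 89%, SSDI about
#' 97%).
#'
#' @return Named list of [source_spec()] objects (`EHR`, `CDD1`, `SSDI`,
#'   `ABS`).
#' @export
default_source_specs <- function() {
  list(
    EHR  = source_spec("EHR",  capture_prob = 0.66,
                       date_exact_prob = 0.89),
    CDD1 = source_spec("CDD1", capture_prob = 1 - (1 - 0.84) / (1 - 0.66),
                       date_exact_prob = 0.93, id_corruption_rate = 0.01),
    SSDI = source_spec("SSDI", capture_prob = 1 - (1 - 0.89) / (1 - 0.84),
                       date_exact_prob = 0.97, id_corruption_rate = 0.01),
    ABS  = source_spec("ABS",  capture_prob = 1 - (1 - 0.91) / (1 - 0.89),
                       date_exact_prob = 0.95)
  )
}

#' Specification of the gold-standard death index
#'
#' The gold standard emulates a national death index: near-complete capture
#' of true deaths with exact dates, a match-quality class attached to every
#' death record, and "likely false" death records attached to a fraction of
#' alive patients to exercise the conservative vital-status classifier.
#'
#' @param capture_prob Probability a true death appears in the index.
#' @param class_probs Named probabilities over match-quality classes assigned
#'   to true death records: `exact`, `probable`, `unclassifiable`. Must sum
#'   to 1.
#' @param likely_false_rate Probability an alive patient carries a death
#'   record flagged as a likely false match.
#' @param id_corruption_rate Identifier corruption rate for gold records.
#' @return An object of class `"mort_gold_spec"`.
#' @export
gold_spec <- function(capture_prob = 0.99,
                      class_probs = c(exact = 0.88, probable = 0.10,
                                      unclassifiable = 0.02),
                      likely_false_rate = 0.35,
                      id_corruption_rate = 0.005) {
  if (capture_prob < 0 || capture_prob > 1 ||
      likely_false_rate < 0 || likely_false_rate > 1 ||
      id_corruption_rate < 0 || id_corruption_rate > 1) {
    abort("gold_spec: probabilities must lie in [0, 1]")
  }
  wanted <- c("exact", "probable", "unclassifiable")
  if (!all(wanted %in% names(class_probs)) ||
      any(class_probs < 0) || abs(sum(class_probs) - 1) > 1e-8) {
    abort("gold_spec: `class_probs` needs exact/probable/unclassifiable summing to 1")
  }
  structure(
    list(capture_prob = capture_prob, class_probs = class_probs[wanted],
         likely_false_rate = likely_false_rate,
         id_corruption_rate = id_corruption_rate),
    class = "mort_gold_spec"
  )
}

#' Simulation configuration for a synthetic multi-source mortality study
#'
#' Defines the full study conditions for the synthetic cohort: size, tumor
#' mix, per-tumor survival model, enrollment windows and study cutoff,
#' practice structure, loss to follow-up, and the error model of every
#' mortality source plus the gold standard. A single `seed` determines
#' every random draw downstream.
#'
#' Defaults emulate a multi-tumor advanced-cancer cohort observed through a
#' fixed cutoff aligned with gold-standard availability: the tumor mix is
#' proportional to the published cohort sizes, enrollment is uniform over a
#' 2011-2015 window for advanced NSCLC and 2013-2015 for the other tumor
#' types, and survival is exponential with tumor-specific medians spanning
#' short (advanced NSCLC) to long (metastatic breast cancer) survival.
#'
#' @param n_patients Number of patients.
#' @param tumor_mix Named proportions over
#'   `c("advNSCLC","advMelanoma","mCRC","mBC")`; normalised to sum to 1.
#' @param median_survival_months Named per-tumor median survival (months).
#' @param survival_shape Weibull shape parameter; 1 gives the exponential
#'   model.
#' @param enrollment_start Named per-tumor first enrollment date.
#' @param enrollment_end Last enrollment date (all tumor types).
#' @param study_cutoff Fixed cutoff; deaths after it are unobserved and the
#'   patient counts as alive.
#' @param n_practices Number of practices patients are spread over.
#' @param practice_size_sdlog Log-sd of the lognormal practice-size weights.
#' @param practice_heterogeneity Concentration of the Beta distribution from
#'   which per-practice EHR capture probabilities are drawn (mean equal to
#'   the EHR `capture_prob`); `Inf` disables heterogeneity.
#' @param ltfu_prob Probability an alive patient is lost to follow-up before
#'   the cutoff (last activity uniform between diagnosis and cutoff).
#' @param abs_recency_days Patients with activity within this many days of
#'   the cutoff are never targeted for chart abstraction.
#' @param source_specs Named list of [source_spec()] objects.
#' @param gold_spec A [gold_spec()] object.
#' @param seed Integer seed determining all randomness.
#' @return An object of class `"mort_sim_config"`.
#' @export
sim_config <- function(n_patients = 10000,
                       tumor_mix = c(advNSCLC = 10195, advMelanoma = 1622,
                                     mCRC = 7325, mBC = 3792),
                       median_survival_months = c(advNSCLC = 12,
                                                  advMelanoma = 20,
                                                  mCRC = 28, mBC = 36),
                       survival_shape = 1,
                       enrollment_start = c(advNSCLC = "2011-01-01",
                                            advMelanoma = "2013-01-01",
                                            mCRC = "2013-01-01",
                                            mBC = "2013-01-01"),
                       enrollment_end = "2015-12-31",
                       study_cutoff = "2015-12-31",
                       n_practices = 40,
                       practice_size_sdlog = 1,
                       practice_heterogeneity = 12,
                       ltfu_prob = 0.08,
                       abs_recency_days = 60,
                       source_specs = default_source_specs(),
                       gold_spec = mortcomp::gold_spec(),
                       seed = 1L) {
  tumors <- c("advNSCLC", "advMelanoma", "mCRC", "mBC")
  if (n_patients < 0) abort("sim_config: `n_patients` must be >= 0")
  tumor_mix <- tumor_mix[intersect(tumors, names(tumor_mix))]
  if (!length(tumor_mix) || any(tumor_mix < 0) || sum(tumor_mix) <= 0) {
    abort("sim_config: `tumor_mix` must give non-negative weight to at least one known tumor type")
  }
  tumor_mix <- tumor_mix / sum(tumor_mix)
  enrollment_start <- as.Date(enrollment_start[names(enrollment_start) %in% tumors])
  enrollment_end <- as.Date(enrollment_end)
  study_cutoff <- as.Date(study_cutoff)
  if (any(is.na(enrollment_start)) || is.na(enrollment_end) || is.na(study_cutoff)) {
    abort("sim_config: enrollment and cutoff dates must parse as ISO dates")
  }
  if (study_cutoff < max(enrollment_start) || enrollment_end < max(enrollment_start)) {
    abort(sprintf(
      "sim_config: invalid enrollment window: study cutoff (%s) or enrollment end (%s) precedes enrollment start (%s)",
      study_cutoff, enrollment_end, max(enrollment_start)))
  }
  missing_med <- setdiff(names(tumor_mix)[tumor_mix > 0],
                         names(median_survival_months))
  if (length(missing_med)) {
    abort(sprintf("sim_config: no median survival given for %s",
                  paste(missing_med, collapse = ", ")))
  }
  if (any(median_survival_months < 0)) {
    abort("sim_config: median survival must be >= 0")
  }
  stopifnot(is.list(source_specs),
            all(vapply(source_specs, inherits, TRUE, "mort_source_spec")),
            inherits(gold_spec, "mort_gold_spec"))
  names(source_specs) <- vapply(source_specs, `[[`, "", "source_id")
  structure(
    list(n_patients = as.integer(n_patients),
         tumor_mix = tumor_mix,
         median_survival_months = median_survival_months,
         survival_shape = survival_shape,
         enrollment_start = enrollment_start,
         enrollment_end = enrollment_end,
         study_cutoff = study_cutoff,
         n_practices = as.integer(n_practices),
         practice_size_sdlog = practice_size_sdlog,
         practice_heterogeneity = practice_heterogeneity,
         ltfu_prob = ltfu_prob,
         abs_recency_days = abs_recency_days,
         source_specs = source_specs,
         gold_spec = gold_spec,
         seed = as.integer(seed)),
    class = "mort_sim_config"
  )
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [sim_config()]; `source_specs` is
#' a mapping from source id to [source_spec()] fields and `gold_spec` a
#' mapping of [gold_spec()] fields. Keys omitted from the file keep their
#' defaults.
#'
#' @param path Path to a YAML config file.
#' @return A `"mort_sim_config"` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), c("source_specs", "gold_spec"))]
  for (nm in c("tumor_mix", "median_survival_months", "enrollment_start")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  if (!is.null(raw$source_specs)) {
    args$source_specs <- purrr::imap(raw$source_specs, function(fields, id) {
      do.call(source_spec, c(list(source_id = id), fields))
    })
  }
  if (!is.null(raw$gold_spec)) {
    gs <- raw$gold_spec
    if (!is.null(gs$class_probs)) gs$class_probs <- unlist(gs$class_probs)
    args$gold_spec <- do.call(gold_spec, gs)
  }
  do.call(sim_config, args)
}

#' @export
print.mort_sim_config <- function(x, ...) {
  cat("<mort_sim_config>\n")
  cat(sprintf("  patients: %d over %d practices, seed %d\n",
              x$n_patients, x$n_practices, x$seed))
  cat(sprintf("  tumor mix: %s\n",
              paste(sprintf("%s %.1f%%", names(x$tumor_mix), 100 * x$tumor_mix),
                    collapse = ", ")))
  cat(sprintf("  enrollment through %s, study cutoff %s\n",
              x$enrollment_end, x$study_cutoff))
  cat(sprintf("  sources: %s\n", paste(names(x$source_specs), collapse = ", ")))
  invisible(x)
}
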