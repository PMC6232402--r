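#' @keywords internal
#' Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @keywords internal
#' Deterministic per-stage seed below 2^31, derived from the master seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + offset)
}

# Pronounceable synthetic names: two/three syllables from a fixed inventory.
# The inventory is deliberately large enough that exact (first, last, dob)
# collisions are vanishingly rare at cohort sizes used here.
.syllables <- c("an", "bel", "cor", "dan", "el", "fen", "gar", "hol", "ira",
                "jan", "kel", "lor", "mar", "nor", "ol", "per", "quin", "ros",
                "sam", "tor", "ul", "ver", "win", "xan", "yar", "zel", "bri",
                "cal", "dor", "eth", "fay", "gil", "hart", "ing", "joss", "kim")

random_names <- function(n, n_syllables = 2) {
  if (n == 0) return(character(0))
  parts <- replicate(n_syllables, sample(.syllables, n, replace = TRUE))
  parts <- if (is.matrix(parts)) apply(parts, 1, paste0, collapse = "") else parts
  stringr::str_to_title(parts)
}

random_dates <- function(n, from, to) {
  as.Date(round(runif(n, as.numeric(as.Date(from)), as.numeric(as.Date(to)))),
          origin = "1970-01-01")
}

#' Generate a synthetic patient cohort with ground-truth mortality
#'
#' Simulates a cohort of advanced-cancer patients: identifiers, practice
#' membership, tumor type, an advanced-diagnosis date uniform over the
#' tumor-specific enrollment window, a Weibull (default exponential)
#' time to death from diagnosis, and a last-activity date. Deaths occurring
#' after the study cutoff are unobservable and stored as missing: such
#' patients count as alive at cutoff. Last activity equals the death date
#' for deceased patients and the cutoff for alive patients unless they are
#' lost to follow-up, in which case it falls uniformly between diagnosis
#' and cutoff.
#'
#' When the configuration requests practice-level heterogeneity, each
#' practice receives its own structured-EHR capture probability drawn from a
#' Beta distribution with mean equal to the EHR source's `capture_prob`;
#' the draw is stored in the hidden column `.ehr_capture_prob` and used by
#' [generate_source()] for the EHR source only.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per patient: `patient_id`, `first_name`,
#'   `last_name`, `birth_date`, `state`, `practice_id`, `tumor_type`,
#'   `advanced_diagnosis_date`, `last_activity_date`, `true_death_date`
#'   (`NA` when alive at cutoff), plus the hidden `.ehr_capture_prob`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "mort_sim_config"))
  n <- config$n_patients
  with_seed(config$seed, {
    tumor <- sample(names(config$tumor_mix), n, replace = TRUE,
                    prob = config$tumor_mix)
    practice_ids <- sprintf("PR%03d", seq_len(config$n_practices))
    practice_w <- stats::rlnorm(config$n_practices, 0, config$practice_size_sdlog)
    practice <- sample(practice_ids, n, replace = TRUE, prob = practice_w)

    start <- config$enrollment_start[tumor]
    start[is.na(start)] <- max(config$enrollment_start)
    dx <- as.Date(round(runif(n, as.numeric(start),
                              as.numeric(config$enrollment_end))),
                  origin = "1970-01-01")

    med_days <- config$median_survival_months[tumor] * 30.4375
    shape <- config$survival_shape
    scale <- med_days / log(2)^(1 / shape)
    t_death <- round(rweibull(n, shape = shape, scale = scale))
    death <- dx + t_death
    true_death <- dplyr::if_else(death <= config$study_cutoff, death,
                                 as.Date(NA))

    lost <- is.na(true_death) & runif(n) < config$ltfu_prob
    lost_dates <- as.Date(round(runif(n, as.numeric(dx),
                                      as.numeric(config$study_cutoff))),
                          origin = "1970-01-01")
    last_activity <- dplyr::if_else(
      !is.na(true_death), true_death,
      dplyr::if_else(lost, lost_dates, rep(config$study_cutoff, n)))

    ehr_mu <- if (!is.null(config$source_specs$EHR))
      config$source_specs$EHR$capture_prob else NA_real_
    kappa <- config$practice_heterogeneity
    practice_capture <- if (is.na(ehr_mu) || !is.finite(kappa)) {
      setNames(rep(ehr_mu, config$n_practices), practice_ids)
    } else {
      setNames(rbeta(config$n_practices, ehr_mu * kappa, (1 - ehr_mu) * kappa),
               practice_ids)
    }

    tibble(
      patient_id = sprintf("PT%06d", seq_len(n)),
      first_name = random_names(n, 2),
      last_name = random_names(n, 3),
      birth_date = random_dates(n, "1930-01-01", "1975-12-31"),
      state = if (n) sample(datasets::state.abb, n, replace = TRUE) else character(0),
      practice_id = practice,
      tumor_type = tumor,
      advanced_diagnosis_date = dx,
      last_activity_date = last_activity,
      true_death_date = true_death,
      .ehr_capture_prob = unname(practice_capture[practice])
    )
  })
}

#' @keywords internal
#' Perturb identifier fields of records at a per-field corruption rate.
corrupt_identifiers <- function(df, rate) {
  if (rate <= 0 || nrow(df) == 0) return(df)
  edit_name <- function(x, hit) {
    idx <- which(hit & nchar(x) > 0)
    if (!length(idx)) return(x)
    pos <- ceiling(runif(length(idx)) * nchar(x[idx]))
    substr(x[idx], pos, pos) <- sample(letters, length(idx), replace = TRUE)
    x
  }
  df$first_name <- edit_name(df$first_name, runif(nrow(df)) < rate)
  df$last_name <- edit_name(df$last_name, runif(nrow(df)) < rate)
  hit <- runif(nrow(df)) < rate
  if (any(hit)) {
    d <- as.POSIXlt(df$birth_date[hit])
    swappable <- d$mday <= 12
    new_day <- ifelse(swappable, d$mon + 1, pmax(1, d$mday - 1))
    new_mon <- ifelse(swappable, d$mday, d$mon + 1)
    df$birth_date[hit] <- as.Date(sprintf("%04d-%02d-%02d",
                                          d$year + 1900, new_mon, new_day))
  }
  hit <- runif(nrow(df)) < rate
  if (any(hit)) {
    df$state[hit] <- sample(datasets::state.abb, sum(hit), replace = TRUE)
  }
  df
}

#' @keywords internal
#' Apply the source date-error model to a vector of true dates.
perturb_dates <- function(dates, spec) {
  n <- length(dates)
  if (n == 0) return(dates)
  u <- runif(n)
  out <- dates
  typo <- u >= spec$date_exact_prob &
    u < spec$date_exact_prob + spec$year_typo_prob
  small <- u >= spec$date_exact_prob + spec$year_typo_prob
  if (any(typo)) {
    out[typo] <- dates[typo] + sample(c(-365, 365), sum(typo), replace = TRUE)
  }
  if (any(small)) {
    off <- round(rnorm(sum(small), 0, max(spec$small_offset_sd_days, 1e-9)))
    off[off == 0] <- sample(c(-1L, 1L), sum(off == 0), replace = TRUE)
    out[small] <- dates[small] + off
  }
  out
}

#' Generate one synthetic mortality source
#'
#' Emits the records of a single mortality source for a cohort generated by
#' [generate_cohort()]. Each deceased patient is captured with the source's
#' `capture_prob` (for the EHR source, modulated by the per-practice capture
#' probability when present); captured dates pass through the error model of
#' [source_spec()]. Alive patients acquire a spurious record with
#' `false_record_prob`. External sources report only identifiers — possibly
#' corrupted — while internal sources carry the patient id directly.
#'
#' For the chart-abstraction source (`ABS`), pass `other_captured` (patient
#' ids already holding a record in any other source) together with
#' `reference_date` and `recency_days`: abstraction targets only patients
#' with no other record and no activity within `recency_days` of
#' `reference_date`, mirroring how chart review is commissioned.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param spec A [source_spec()].
#' @param seed Integer seed for this source's draws.
#' @param other_captured Optional character vector of patient ids covered by
#'   other sources (ABS targeting).
#' @param reference_date Recency reference for ABS targeting; defaults to
#'   the latest last-activity date.
#' @param recency_days Recency window (days) for ABS targeting.
#' @return Tibble of source assertions: `record_id`, `source_id`,
#'   `patient_id` (`NA` for external sources), identifier fields,
#'   `death_date`, and the hidden oracle link `.truth_patient_id`.
#' @export
generate_source <- function(cohort, spec, seed,
                            other_captured = NULL,
                            reference_date = NULL,
                            recency_days = 60) {
  stopifnot(inherits(spec, "mort_source_spec"))
  if (spec$date_exact_prob + spec$year_typo_prob > 1) {
    abort("generate_source: date_exact_prob + year_typo_prob must not exceed 1")
  }
  with_seed(seed, {
    dead <- dplyr::filter(cohort, !is.na(.data$true_death_date))
    alive <- dplyr::filter(cohort, is.na(.data$true_death_date))

    if (spec$source_id == "ABS" && !is.null(other_captured)) {
      if (is.null(reference_date)) {
        reference_date <- max(cohort$last_activity_date, na.rm = TRUE)
      }
      eligible <- function(df) {
        dplyr::filter(df,
                      !(.data$patient_id %in% other_captured),
                      .data$last_activity_date <
                        as.Date(reference_date) - recency_days)
      }
      dead <- eligible(dead)
      alive <- eligible(alive)
    }

    p_cap <- if (spec$source_id == "EHR" && ".ehr_capture_prob" %in% names(dead) &&
                 !anyNA(dead$.ehr_capture_prob)) {
      dead$.ehr_capture_prob
    } else {
      rep(spec$capture_prob, nrow(dead))
    }
    captured <- dead[runif(nrow(dead)) < p_cap, , drop = FALSE]
    captured_dates <- perturb_dates(captured$true_death_date, spec)

    spurious <- alive[runif(nrow(alive)) < spec$false_record_prob, , drop = FALSE]
    spurious_dates <- random_dates(nrow(spurious), min(cohort$advanced_diagnosis_date %||%
                                                        Sys.Date()),
                                   max(cohort$last_activity_date %||% Sys.Date()))

    out <- bind_rows(
      dplyr::transmute(captured,
                       .truth_patient_id = .data$patient_id,
                       first_name = .data$first_name,
                       last_name = .data$last_name,
                       birth_date = .data$birth_date,
                       state = .data$state) %>%
        mutate(death_date = captured_dates),
      dplyr::transmute(spurious,
                       .truth_patient_id = .data$patient_id,
                       first_name = .data$first_name,
                       last_name = .data$last_name,
                       birth_date = .data$birth_date,
                       state = .data$state) %>%
        mutate(death_date = spurious_dates)
    )
    if (!spec$internal) {
      out <- corrupt_identifiers(out, spec$id_corruption_rate)
    }
    out %>%
      mutate(record_id = sprintf("%s-%06d", spec$source_id, row_number()),
             source_id = spec$source_id,
             patient_id = if (spec$internal) .data$.truth_patient_id
                          else NA_character_) %>%
      select("record_id", "source_id", "patient_id", "first_name",
             "last_name", "birth_date", "state", "death_date",
             ".truth_patient_id")
  })
}

#' Generate the gold-standard death index
#'
#' Emulates a national death index over the synthetic cohort: true deaths
#' are captured near-completely with exact dates and annotated with a
#' match-quality class (`exact`, `probable`, or `unclassifiable`), and a
#' fraction of alive patients carry a death record flagged `likely_false`
#' — these exercise the conservative classifier, which treats them as
#' alive. Identifiers may be lightly corrupted to exercise linkage.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param spec A [gold_spec()].
#' @param seed Integer seed.
#' @return Tibble of gold records: `record_id`, identifier fields,
#'   `death_date`, `match_quality`, and hidden `.truth_patient_id`.
#' @export
generate_gold <- function(cohort, spec, seed) {
  stopifnot(inherits(spec, "mort_gold_spec"))
  with_seed(seed, {
    dead <- dplyr::filter(cohort, !is.na(.data$true_death_date))
    alive <- dplyr::filter(cohort, is.na(.data$true_death_date))
    captured <- dead[runif(nrow(dead)) < spec$capture_prob, , drop = FALSE]
    classes <- if (nrow(captured))
      sample(names(spec$class_probs), nrow(captured), replace = TRUE,
             prob = spec$class_probs) else character(0)
    lf <- alive[runif(nrow(alive)) < spec$likely_false_rate, , drop = FALSE]
    lf_dates <- random_dates(nrow(lf),
                             min(cohort$advanced_diagnosis_date %||% Sys.Date()),
                             max(cohort$last_activity_date %||% Sys.Date()))
    out <- bind_rows(
      dplyr::transmute(captured,
                       .truth_patient_id = .data$patient_id,
                       first_name = .data$first_name,
                       last_name = .data$last_name,
                       birth_date = .data$birth_date,
                       state = .data$state,
                       death_date = .data$true_death_date) %>%
        mutate(match_quality = classes),
      dplyr::transmute(lf,
                       .truth_patient_id = .data$patient_id,
                       first_name = .data$first_name,
                       last_name = .data$last_name,
                       birth_date = .data$birth_date,
                       state = .data$state) %>%
        mutate(death_date = lf_dates, match_quality = "likely_false")
    )
    out <- corrupt_identifiers(out, spec$id_corruption_rate)
    out %>%
      mutate(record_id = sprintf("NDI-%06d", row_number())) %>%
      select("record_id", "first_name", "last_name", "birth_date", "state",
             "death_date", "match_quality", ".truth_patient_id")
  })
}

#' Simulate a complete multi-source mortality study
#'
#' Generates the cohort, the four mortality sources and the gold-standard
#' index from one configuration. The chart-abstraction source is generated
#' last so that its targeting rule (no record in any other source, no recent
#' activity) can be applied. All randomness derives from `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `"mort_study"`: a list with `cohort`,
#'   `sources` (named list of source tibbles) and `gold`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "mort_sim_config"))
  cohort <- generate_cohort(config)
  specs <- config$source_specs
  sources <- list()
  k <- 1L
  for (id in setdiff(names(specs), "ABS")) {
    sources[[id]] <- generate_source(cohort, specs[[id]],
                                     seed = derive_seed(config$seed, k))
    k <- k + 1L
  }
  if (!is.null(specs$ABS)) {
    covered <- unique(c(character(0),
                        unlist(lapply(sources, function(s) s$.truth_patient_id))))
    sources$ABS <- generate_source(cohort, specs$ABS,
                                   seed = derive_seed(config$seed, k),
                                   other_captured = covered,
                                   reference_date = config$study_cutoff,
                                   recency_days = config$abs_recency_days)
    k <- k + 1L
  }
  gold <- generate_gold(cohort, config$gold_spec,
                        seed = derive_seed(config$seed, 99L))
  structure(list(cohort = cohort, sources = sources, gold = gold,
                 config = config),
            class = "mort_study")
}

#' @export
print.mort_study <- function(x, ...) {
  cat("<mort_study>\n")
  cat(sprintf("  cohort: %d patients (%d deceased by cutoff %s)\n",
              nrow(x$cohort), sum(!is.na(x$cohort$true_death_date)),
              x$config$study_cutoff))
  for (id in names(x$sources)) {
    cat(sprintf("  source %-4s: %d records\n", id, nrow(x$sources[[id]])))
  }
  cat(sprintf("  gold index: %d records\n", nrow(x$gold)))
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 0)) y else x
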