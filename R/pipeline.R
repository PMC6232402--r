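#' Link every mortality source and the gold index to the cohort
#'
#' Internal sources (structured EHR, chart abstraction) already carry the
#' patient id; external sources (commercial death data, SSDI) and the gold
#' index are linked through [match_records()]. Gold matches are classified
#' into conservative vital-status calls.
#'
#' @param study A `"mort_study"` from [simulate_study()].
#' @return An object of class `"mort_linked"`: `assertions` (long tibble of
#'   linked death assertions: `patient_id`, `source_id`, `death_date`),
#'   `audit` (per-record match audit across external sources and gold),
#'   and `calls` (vital-status calls).
#' @export
link_study <- function(study) {
  stopifnot(inherits(study, "mort_study"))
  cohort <- study$cohort
  audits <- list()
  assertions <- purrr::imap(study$sources, function(src, id) {
    internal <- isTRUE(study$config$source_specs[[id]]$internal)
    if (internal) {
      src %>% select("patient_id", "source_id", "death_date")
    } else {
      m <- match_records(cohort, src)
      audits[[id]] <<- m %>% mutate(source_id = id, .before = 1)
      src %>%
        select("record_id", "source_id", "death_date") %>%
        inner_join(m %>% filter(!is.na(.data$patient_id)), by = "record_id") %>%
        select("patient_id", "source_id", "death_date")
    }
  }) %>% bind_rows()

  gold_matches <- match_records(cohort, study$gold)
  audits[["gold"]] <- gold_matches %>% mutate(source_id = "GOLD", .before = 1)
  calls <- classify_gold_matches(cohort, study$gold, gold_matches)

  structure(list(assertions = assertions, audit = bind_rows(audits),
                 calls = calls),
            class = "mort_linked")
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[mortcomp] ", fmt), ...))
}

drop_hidden <- function(df) df[, !startsWith(names(df), "."), drop = FALSE]

#' Run the full simulate-link-compose-benchmark-survive pipeline
#'
#' End-to-end orchestration: simulate the multi-source study, link every
#' source and the gold index, build the stepwise composite dataset
#' versions, benchmark each against the gold standard, and estimate
#' Kaplan-Meier curves per version alongside the gold-based curve. All
#' stage outputs are written as headered comma-delimited files with ISO
#' dates, plus a JSON manifest recording the configuration, seed, and the
#' row count and MD5 checksum of every file. Reruns with the same
#' configuration and seed produce identical outputs.
#'
#' @param config A [sim_config()] object or path to a YAML config file.
#' @param outdir Output directory (created if needed).
#' @param windows Date-agreement windows in days.
#' @param horizons Survival-comparison horizons in days.
#' @param min_patients Practice-size threshold for the per-practice
#'   summary.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the in-memory stage outputs (`study`,
#'   `linked`, `versions`, `report`, `practice`, `curves`, `comparison`)
#'   and the `manifest`.
#' @export
run_pipeline <- function(config, outdir, windows = c(0, 15, 30),
                         horizons = c(183, 365, 730), min_patients = 100,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "mort_sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    readr::write_csv(drop_hidden(df), path, na = "")
    files[[name]] <<- path
    path
  }

  study <- simulate_study(config)
  log_stage(quiet, "simulate: %d patients, %d deceased by cutoff %s",
            nrow(study$cohort), sum(!is.na(study$cohort$true_death_date)),
            config$study_cutoff)
  emit(study$cohort, "cohort.csv")
  for (id in names(study$sources)) {
    log_stage(quiet, "simulate: source %s -> %d records", id,
              nrow(study$sources[[id]]))
    emit(study$sources[[id]], sprintf("source_%s.csv", id))
  }
  emit(study$gold, "gold.csv")

  linked <- link_study(study)
  n_matched <- sum(!is.na(linked$audit$patient_id))
  log_stage(quiet, "link: %d/%d external+gold records matched",
            n_matched, nrow(linked$audit))
  fr <- attr(linked$calls, "class_fractions")
  log_stage(quiet, "link: vital-status classes: %s",
            paste(sprintf("%s %.1f%%", fr$reason, 100 * fr$fraction),
                  collapse = ", "))
  emit(linked$audit, "match_audit.csv")
  emit(linked$calls, "vital_status.csv")

  versions <- build_dataset_versions(study$cohort, linked$assertions,
                                     reference_date = config$study_cutoff,
                                     recency_days = config$abs_recency_days)
  for (v in levels(versions$version)) {
    comp <- versions %>% filter(.data$version == v)
    log_stage(quiet, "compose: %s -> %d deaths (%d removed as implausible)",
              v, sum(!is.na(comp$death_date)),
              sum(comp$resolution == "removed_implausible"))
    emit(comp, sprintf("composite_%s.csv", v))
  }

  report <- benchmark_versions(versions, linked$calls, windows = windows)
  emit(report, "report.csv")
  log_stage(quiet, "benchmark: sensitivity %s",
            paste(sprintf("%s %.1f%%", report$version,
                          100 * report$sensitivity), collapse = ", "))

  practice <- versions %>%
    group_by(.data$version) %>%
    dplyr::group_map(function(comp, key) {
      s <- per_practice_sensitivity(comp, linked$calls, study$cohort,
                                    min_patients = min_patients)
      tidy(s) %>% mutate(version = as.character(key$version), .before = 1)
    }) %>%
    bind_rows()
  emit(practice, "practice_summary.csv")

  curves <- list()
  for (v in levels(versions$version)) {
    si <- survival_input(versions %>% filter(.data$version == v),
                         study$cohort, cutoff = config$study_cutoff)
    curves[[v]] <- km_estimate(si)
    emit(curves[[v]], sprintf("km_%s.csv", v))
  }
  gold_si <- survival_input(
    linked$calls %>% dplyr::transmute(patient_id = .data$patient_id,
                                      death_date = .data$gold_death_date),
    study$cohort, cutoff = config$study_cutoff, censor = "cutoff")
  gold_curve <- km_estimate(gold_si)
  emit(gold_curve, "km_gold.csv")
  comparison <- compare_curves(curves, gold_curve, horizons = horizons)
  emit(comparison, "survival_comparison.csv")
  log_stage(quiet, "survive: max overestimate vs gold: %s",
            paste(sprintf("%s %+.3f", comparison$version,
                          comparison$max_overestimate), collapse = ", "))

  snapshot <- config
  snapshot[c("enrollment_start", "enrollment_end", "study_cutoff")] <-
    lapply(snapshot[c("enrollment_start", "enrollment_end", "study_cutoff")],
           as.character)
  manifest <- list(
    seed = config$seed,
    config = unclass(snapshot),
    files = purrr::imap(files, function(path, name) {
      list(path = name,
           rows = length(readr::read_lines(path)) - 1L,
           md5 = unname(tools::md5sum(path)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  log_stage(quiet, "done: %d files in %s", length(files) + 1L, outdir)

  invisible(list(study = study, linked = linked, versions = versions,
                 report = report, practice = practice, curves = curves,
                 gold_curve = gold_curve, comparison = comparison,
                 manifest = manifest))
}

#' Compare a benchmark report against expected values
#'
#' Cell-by-cell comparison of a report from [benchmark_versions()] with a
#' table of expected values at a stated absolute tolerance — the harness
#' used to check pipeline output against published benchmark rows.
#'
#' @param report Report tibble (proportions) from [benchmark_versions()].
#' @param expected Tibble with a `version` column and a subset of the
#'   report's numeric columns, on the same scale.
#' @param tolerance Absolute tolerance applied to every compared cell.
#' @return Tibble with one row per compared cell: `version`, `metric`,
#'   `expected`, `actual`, `tolerance`, `pass`; attribute `"all_pass"`.
#' @export
validate_against_table <- function(report, expected, tolerance = 0.0015) {
  if (!"version" %in% names(expected)) {
    abort("validate_against_table: `expected` needs a `version` column",
          class = "mortcomp_schema_error")
  }
  metric_cols <- setdiff(names(expected), "version")
  missing <- setdiff(metric_cols, names(report))
  if (length(missing)) {
    abort(sprintf("validate_against_table: report lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "mortcomp_schema_error")
  }
  missing_v <- setdiff(as.character(expected$version),
                       as.character(report$version))
  if (length(missing_v)) {
    abort(sprintf("validate_against_table: report lacks version(s): %s",
                  paste(missing_v, collapse = ", ")),
          class = "mortcomp_schema_error")
  }
  out <- expected %>%
    mutate(version = as.character(.data$version)) %>%
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric",
                        values_to = "expected") %>%
    left_join(report %>%
                mutate(version = as.character(.data$version)) %>%
                tidyr::pivot_longer(dplyr::all_of(metric_cols),
                                    names_to = "metric",
                                    values_to = "actual") %>%
                select("version", "metric", "actual"),
              by = c("version", "metric")) %>%
    mutate(tolerance = tolerance,
           pass = abs(.data$actual - .data$expected) <= tolerance)
  attr(out, "all_pass") <- all(out$pass)
  out
}
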