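test_that("date resolution follows agreement first, then the source hierarchy", {
  # any two identical dates win, regardless of the third
  r <- resolve_death_dates(asrt(list("P1", "SSDI", "2015-03-01"),
                                list("P1", "CDD1", "2015-03-01"),
                                list("P1", "EHR", "2015-04-01")))
  expect_equal(r$death_date, as.Date("2015-03-01"))
  expect_equal(r$resolution, "two_or_more_agree")
  expect_equal(r$contributing_sources, "SSDI+CDD1")

  # full conflict: SSDI > CDD1 > EHR
  r <- resolve_death_dates(asrt(list("P1", "SSDI", "2015-03-01"),
                                list("P1", "CDD1", "2015-02-27"),
                                list("P1", "EHR", "2015-03-05")))
  expect_equal(r$death_date, as.Date("2015-03-01"))
  expect_equal(r$resolution, "hierarchy_SSDI")

  r <- resolve_death_dates(asrt(list("P1", "CDD1", "2015-02-27"),
                                list("P1", "EHR", "2015-03-05")))
  expect_equal(r$resolution, "hierarchy_CDD1")

  # single assertion is taken as is
  r <- resolve_death_dates(asrt(list("P1", "EHR", "2014-01-01")))
  expect_equal(r$death_date, as.Date("2014-01-01"))
  expect_equal(r$resolution, "single_source")

  # empty input -> empty resolved table
  expect_equal(nrow(resolve_death_dates(asrt())), 0)
})

test_that("agreement outcomes are invariant to the hierarchy order", {
  a <- asrt(list("P1", "SSDI", "2015-03-01"),
            list("P1", "CDD1", "2015-03-01"),
            list("P1", "EHR", "2015-04-01"),
            list("P2", "EHR", "2015-05-01"),
            list("P2", "CDD1", "2015-05-01"))
  perms <- list(c("SSDI", "CDD1", "EHR"), c("EHR", "SSDI", "CDD1"),
                c("CDD1", "EHR", "SSDI"))
  dates <- lapply(perms, function(h) {
    resolve_death_dates(a, hierarchy = h) %>%
      dplyr::arrange(patient_id) %>% dplyr::pull(death_date)
  })
  expect_equal(dates[[1]], dates[[2]])
  expect_equal(dates[[1]], dates[[3]])
})

test_that("resolution is idempotent", {
  a <- asrt(list("P1", "SSDI", "2015-03-01"), list("P1", "EHR", "2015-03-05"),
            list("P2", "EHR", "2014-08-01"))
  once <- resolve_death_dates(a)
  again <- resolve_death_dates(
    once %>% dplyr::transmute(patient_id, source_id = "SSDI", death_date))
  expect_equal(again$death_date[match(once$patient_id, again$patient_id)],
               once$death_date)
})

test_that("plausibility filter clears only dates strictly before diagnosis", {
  cohort <- tibble::tibble(patient_id = c("P1", "P2", "P3"),
                           advanced_diagnosis_date = as.Date("2015-01-01"))
  comp <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    death_date = as.Date(c("2014-06-01", "2015-01-01", NA)),
    contributing_sources = c("EHR", "EHR", ""),
    resolution = c("single_source", "single_source", "none"))
  out <- plausibility_filter(comp, cohort)
  expect_true(is.na(out$death_date[1]))
  expect_equal(out$resolution[1], "removed_implausible")
  expect_equal(out$death_date[2], as.Date("2015-01-01"))   # boundary retained
  expect_equal(out$resolution[3], "none")                  # no date unchanged
})

test_that("abstraction fills only inactive gap patients", {
  cutoff <- as.Date("2015-12-31")
  cohort <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    advanced_diagnosis_date = as.Date("2014-01-01"),
    last_activity_date = cutoff - c(90, 10, 90))
  comp <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    death_date = as.Date(c(NA, NA, "2015-05-05")),
    contributing_sources = c("", "", "EHR"),
    resolution = c("none", "none", "single_source"))
  abs_a <- asrt(list("P1", "ABS", "2015-10-15"),
                list("P2", "ABS", "2015-12-25"),
                list("P3", "ABS", "2015-06-06"))
  out <- abs_fill(comp, abs_a, cohort, recency_days = 60,
                  reference_date = cutoff)
  expect_equal(out$death_date[1], as.Date("2015-10-15"))   # filled
  expect_equal(out$resolution[1], "abs_fill")
  expect_true(is.na(out$death_date[2]))                    # recent activity
  expect_equal(out$death_date[3], as.Date("2015-05-05"))   # date kept
})

test_that("a degenerate source collapses versions onto each other", {
  cfg <- tiny_config(n = 400, seed = 23)
  study <- simulate_study(cfg)
  a <- truth_linked_assertions(study) %>%
    dplyr::filter(source_id != "CDD1")  # CDD1 contributed nothing
  versions <- build_dataset_versions(study$cohort, a,
                                     reference_date = cfg$study_cutoff)
  ehr <- versions %>% dplyr::filter(version == "EHR_only") %>%
    dplyr::select(-version)
  both <- versions %>% dplyr::filter(version == "EHR_CDD1") %>%
    dplyr::select(-version)
  expect_equal(as.data.frame(both), as.data.frame(ehr))
})

test_that("adding sources never removes a death before plausibility filtering", {
  cfg <- tiny_config(n = 500, seed = 29)
  study <- simulate_study(cfg)
  a <- truth_linked_assertions(study)
  subsets <- list("EHR", c("EHR", "CDD1"), c("EHR", "CDD1", "SSDI"))
  dead_sets <- lapply(subsets, function(srcs) {
    resolve_death_dates(a %>% dplyr::filter(source_id %in% srcs))$patient_id
  })
  expect_true(all(dead_sets[[1]] %in% dead_sets[[2]]))
  expect_true(all(dead_sets[[2]] %in% dead_sets[[3]]))
})

test_that("dataset versions use exactly their labeled sources", {
  cfg <- tiny_config(n = 400, seed = 37)
  study <- simulate_study(cfg)
  versions <- build_dataset_versions(study$cohort,
                                     truth_linked_assertions(study),
                                     reference_date = cfg$study_cutoff)
  expect_equal(levels(versions$version),
               c("EHR_only", "SSDI_only", "EHR_CDD1", "EHR_CDD1_SSDI",
                 "EHR_CDD1_SSDI_ABS"))
  used <- function(v) {
    versions %>% dplyr::filter(version == v, contributing_sources != "") %>%
      dplyr::pull(contributing_sources) %>%
      strsplit("\\+") %>% unlist() %>% unique()
  }
  expect_true(all(used("EHR_only") == "EHR"))
  expect_true(all(used("SSDI_only") == "SSDI"))
  expect_true(all(used("EHR_CDD1") %in% c("EHR", "CDD1")))
  expect_true(all(used("EHR_CDD1_SSDI") %in% c("EHR", "CDD1", "SSDI")))
  # ABS appears only as gap fill in the final version
  final <- versions %>% dplyr::filter(version == "EHR_CDD1_SSDI_ABS")
  expect_true(all(final$resolution[final$contributing_sources == "ABS"] ==
                    "abs_fill"))
  # every version covers the whole cohort exactly once
  expect_true(all(table(versions$version) == nrow(study$cohort)))
})
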