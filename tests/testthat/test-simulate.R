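test_that("degenerate cohort configurations behave as limits", {
  empty <- generate_cohort(tiny_config(n = 0))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("patient_id", "tumor_type", "advanced_diagnosis_date",
                    "last_activity_date", "true_death_date") %in% names(empty)))

  instant <- generate_cohort(
    tiny_config(n = 50, median_survival_months = c(advNSCLC = 0,
                                                   advMelanoma = 0,
                                                   mCRC = 0, mBC = 0)))
  expect_true(all(!is.na(instant$true_death_date)))
  expect_true(all(instant$true_death_date == instant$advanced_diagnosis_date))
})

test_that("cohort invariants hold and the config validates windows", {
  cohort <- generate_cohort(tiny_config(n = 400))
  expect_true(all(cohort$last_activity_date >= cohort$advanced_diagnosis_date))
  dead <- !is.na(cohort$true_death_date)
  expect_true(all(cohort$true_death_date[dead] >=
                    cohort$advanced_diagnosis_date[dead]))
  expect_true(all(cohort$true_death_date[dead] <= as.Date("2015-12-31")))
  starts <- as.Date(c(advNSCLC = "2011-01-01", advMelanoma = "2013-01-01",
                      mCRC = "2013-01-01", mBC = "2013-01-01"))
  expect_true(all(cohort$advanced_diagnosis_date >=
                    starts[cohort$tumor_type]))

  expect_error(sim_config(study_cutoff = "2010-01-01"), "invalid enrollment")
})

test_that("death fraction matches the closed-form exponential integral", {
  # Uniform enrollment over a window of W days, exponential survival with
  # rate lambda, observation to the end of the window:
  #   P(death observed) = 1 - (1 - exp(-lambda * W)) / (lambda * W)
  cfg <- sim_config(n_patients = 10000, tumor_mix = c(advNSCLC = 1),
                    median_survival_months = c(advNSCLC = 12),
                    enrollment_start = c(advNSCLC = "2013-01-01"),
                    seed = 123)
  cohort <- generate_cohort(cfg)
  W <- as.numeric(as.Date("2015-12-31") - as.Date("2013-01-01"))
  lambda <- log(2) / (12 * 30.4375)
  p <- 1 - (1 - exp(-lambda * W)) / (lambda * W)
  obs <- mean(!is.na(cohort$true_death_date))
  se <- sqrt(p * (1 - p) / nrow(cohort))
  expect_lt(abs(obs - p), 3 * se)
})

test_that("identical config and seed reproduce every table byte-for-byte", {
  cfg <- tiny_config(n = 200, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$sources, s2$sources)
  expect_identical(s1$gold, s2$gold)
})

test_that("a perfect source reproduces the true deaths exactly", {
  cfg <- perfect_config(n = 300, seed = 5)
  cohort <- generate_cohort(cfg)
  src <- generate_source(cohort, cfg$source_specs$EHR, seed = 1)
  dead <- cohort[!is.na(cohort$true_death_date), ]
  expect_setequal(src$.truth_patient_id, dead$patient_id)
  got <- setNames(src$death_date, src$.truth_patient_id)
  expect_equal(unname(got[dead$patient_id]), dead$true_death_date)
})

test_that("capture probability governs the captured count", {
  cfg <- tiny_config(
    n = 1000, seed = 21,
    median_survival_months = c(advNSCLC = 0, advMelanoma = 0, mCRC = 0,
                               mBC = 0))  # everyone dies: 1000 true deaths
  cohort <- generate_cohort(cfg)
  none <- generate_source(cohort, source_spec("CDD1", capture_prob = 0,
                                              false_record_prob = 0),
                          seed = 2)
  expect_equal(nrow(none), 0)
  some <- generate_source(cohort, source_spec("CDD1", capture_prob = 0.7,
                                              false_record_prob = 0),
                          seed = 3)
  # 3-sigma binomial interval around 700
  expect_gte(nrow(some), 666)
  expect_lte(nrow(some), 734)
})

test_that("date errors follow the exact / small-offset / year-typo mixture", {
  cfg <- tiny_config(n = 2000, seed = 31, median_survival_months =
                       c(advNSCLC = 6, advMelanoma = 6, mCRC = 6, mBC = 6))
  cohort <- generate_cohort(cfg)
  spec <- source_spec("CDD1", capture_prob = 1, false_record_prob = 0,
                      date_exact_prob = 0.8, year_typo_prob = 0.05,
                      small_offset_sd_days = 7, id_corruption_rate = 0)
  src <- generate_source(cohort, spec, seed = 4)
  truth <- setNames(cohort$true_death_date, cohort$patient_id)
  delta <- as.numeric(src$death_date - truth[src$.truth_patient_id])
  p_exact <- mean(delta == 0)
  p_typo <- mean(abs(delta) == 365)
  expect_lt(abs(p_exact - 0.8), 3 * sqrt(0.8 * 0.2 / length(delta)))
  expect_lt(abs(p_typo - 0.05), 3 * sqrt(0.05 * 0.95 / length(delta)))
  expect_true(all(delta[abs(delta) != 365] %in% -60:60))
})

test_that("perfect gold equals ground truth and classes drive the classifier", {
  cfg <- perfect_config(n = 300, seed = 13)
  cohort <- generate_cohort(cfg)
  gold <- generate_gold(cohort, cfg$gold_spec, seed = 9)
  dead <- cohort[!is.na(cohort$true_death_date), ]
  expect_setequal(gold$.truth_patient_id, dead$patient_id)
  expect_true(all(gold$match_quality == "exact"))
  got <- setNames(gold$death_date, gold$.truth_patient_id)
  expect_equal(unname(got[dead$patient_id]), dead$true_death_date)

  # every gold death record classified dead when all classes are exact
  calls <- classify_gold_matches(cohort, gold, match_records(cohort, gold))
  expect_equal(sum(calls$status == "dead"), nrow(dead))
})

test_that("likely-false gold records leave the alive fraction intact", {
  cfg <- tiny_config(n = 1500, seed = 17,
                     gold_spec = gold_spec(capture_prob = 1,
                                           class_probs = c(exact = 1,
                                                           probable = 0,
                                                           unclassifiable = 0),
                                           likely_false_rate = 0.05,
                                           id_corruption_rate = 0))
  cohort <- generate_cohort(cfg)
  gold <- generate_gold(cohort, cfg$gold_spec, seed = 8)
  calls <- classify_gold_matches(cohort, gold, match_records(cohort, gold))
  true_alive <- mean(is.na(cohort$true_death_date))
  got_alive <- mean(calls$status == "alive")
  expect_lt(abs(got_alive - true_alive),
            3 * sqrt(true_alive * (1 - true_alive) / nrow(cohort)))
})
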