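mini_calls <- function(status, gold_dates = NULL) {
  n <- length(status)
  tibble::tibble(
    patient_id = paste0("P", seq_len(n)),
    status = status,
    reason = ifelse(status == "dead", "exact_match", "no_gold_record"),
    gold_death_date = if (is.null(gold_dates)) {
      dplyr::if_else(status == "dead", as.Date("2015-06-01"), as.Date(NA))
    } else as.Date(gold_dates))
}

mini_composite <- function(death_dates) {
  n <- length(death_dates)
  tibble::tibble(patient_id = paste0("P", seq_len(n)),
                 death_date = as.Date(death_dates),
                 contributing_sources = ifelse(is.na(death_dates), "", "EHR"),
                 resolution = ifelse(is.na(death_dates), "none",
                                     "single_source"))
}

test_that("contingency counts every disagreement type correctly", {
  # all dead in both
  ct <- contingency(mini_composite(rep("2015-06-01", 4)),
                    mini_calls(rep("dead", 4)))
  expect_equal(unlist(ct[, c("A", "B", "C", "D")]), c(A = 4, B = 0, C = 0, D = 0))

  # composite empty, gold has k deaths
  ct <- contingency(mini_composite(rep(NA_character_, 5)),
                    mini_calls(c("dead", "dead", "alive", "alive", "alive")))
  expect_equal(unlist(ct[, c("A", "B", "C", "D")]), c(A = 0, B = 0, C = 2, D = 3))

  # hand-built fixture with one of each disagreement type
  comp <- mini_composite(c("2015-01-01", "2015-02-01", NA, NA,
                           "2015-03-01", NA))
  calls <- mini_calls(c("dead", "alive", "dead", "alive", "dead", "alive"))
  ct <- contingency(comp, calls)
  expect_equal(unlist(ct[, c("A", "B", "C", "D")]), c(A = 2, B = 1, C = 1, D = 2))
  expect_equal(ct$n, 6)
})

test_that("mismatched cohort coverage is a coverage error", {
  comp <- mini_composite(c("2015-01-01", NA))
  calls <- mini_calls(c("dead", "alive", "alive"))
  expect_error(contingency(comp, calls), class = "mortcomp_coverage_error")
})

test_that("metric definitions and Wald intervals are exact", {
  ct <- mortcomp:::new_contingency(8, 2, 2, 8)
  m <- metrics(ct)
  expect_equal(m$estimate, rep(0.8, 4))

  ct <- mortcomp:::new_contingency(1, 0, 0, 1)
  m <- metrics(ct)
  expect_equal(m$estimate, rep(1, 4))
  expect_equal(m$conf.high, rep(1, 4))  # truncated at 1

  # closed-form half-width: 1.96 * sqrt(0.25 / 100) = 0.098
  ct <- mortcomp:::new_contingency(50, 0, 50, 0)
  m <- metrics(ct)
  sens <- m[m$metric == "sensitivity", ]
  expect_equal(sens$estimate, 0.5)
  expect_equal(sens$conf.high - sens$estimate, 0.098, tolerance = 1e-3)

  # zero denominator -> undefined, not 0
  ct <- mortcomp:::new_contingency(0, 0, 0, 10)
  m <- metrics(ct)
  expect_true(is.na(m$estimate[m$metric == "sensitivity"]))
  expect_true(is.na(m$estimate[m$metric == "ppv"]))
  expect_equal(m$estimate[m$metric == "specificity"], 1)
})

test_that("definitional identities hold on computed contingency tables", {
  set.seed(42)
  for (i in 1:20) {
    cells <- as.integer(rmultinom(1, sample(20:400, 1), runif(4)))
    ct <- mortcomp:::new_contingency(cells[1], cells[2], cells[3], cells[4])
    m <- metrics(ct)
    est <- setNames(m$estimate, m$metric)
    if (!is.na(est["sensitivity"]))
      expect_equal(est[["sensitivity"]] * (ct$A + ct$C), ct$A)
    if (!is.na(est["specificity"]))
      expect_equal(est[["specificity"]] * (ct$B + ct$D), ct$D)
    if (!is.na(est["ppv"]))
      expect_equal(est[["ppv"]] * (ct$A + ct$B), ct$A)
    if (!is.na(est["npv"]))
      expect_equal(est[["npv"]] * (ct$C + ct$D), ct$D)
  }
})

test_that("date agreement counts false positives as disagreement and respects windows", {
  # all exact, no false positives
  comp <- mini_composite(rep("2015-06-01", 3))
  calls <- mini_calls(rep("dead", 3))
  expect_equal(date_agreement(comp, calls, 0), 1)

  # 9 exact + 1 false positive -> 0.9
  comp <- mini_composite(rep("2015-06-01", 10))
  calls <- mini_calls(c(rep("dead", 9), "alive"))
  expect_equal(date_agreement(comp, calls, 0), 0.9)

  # 13-day discrepancy: disagrees exactly at window 0, agrees at 15 and 30
  comp <- mini_composite("2015-01-14")
  calls <- mini_calls("dead", gold_dates = "2015-01-01")
  expect_equal(date_agreement(comp, calls, 0), 0)
  expect_equal(date_agreement(comp, calls, 15), 1)
  expect_equal(date_agreement(comp, calls, 30), 1)

  # window comparison is inclusive
  comp <- mini_composite("2015-01-16")
  expect_equal(date_agreement(comp, calls, 15), 1)
})

test_that("per-practice sensitivity respects the size threshold and boxplot stats", {
  # single perfect practice
  cohort <- tibble::tibble(patient_id = paste0("P", 1:120),
                           practice_id = "PR1")
  comp <- mini_composite(rep("2015-06-01", 120))
  calls <- mini_calls(rep("dead", 120))
  s <- per_practice_sensitivity(comp, calls, cohort, min_patients = 100)
  expect_equal(nrow(s$per_practice), 1)
  expect_equal(s$stats$median, 1)
  expect_equal(s$stats$q75 - s$stats$q25, 0)

  # practice below the threshold is excluded
  cohort2 <- tibble::tibble(patient_id = paste0("P", 1:120),
                            practice_id = rep(c("PR1", "PR2"), c(99, 21)))
  s2 <- suppressWarnings(
    per_practice_sensitivity(comp, calls, cohort2, min_patients = 100))
  expect_equal(nrow(s2$per_practice), 0)
  expect_warning(per_practice_sensitivity(comp, calls, cohort2,
                                          min_patients = 100),
                 "no practice")
})

test_that("per-practice sensitivity recovers practice-specific capture rates", {
  set.seed(77)
  n <- 2000
  cohort <- tibble::tibble(patient_id = paste0("P", seq_len(n)),
                           practice_id = rep(c("PR1", "PR2"), each = n / 2))
  calls <- mini_calls(rep("dead", n))
  p_cap <- ifelse(cohort$practice_id == "PR1", 0.5, 0.9)
  captured <- runif(n) < p_cap
  comp <- mini_composite(ifelse(captured, "2015-06-01", NA))
  s <- per_practice_sensitivity(comp, calls, cohort, min_patients = 100)
  got <- setNames(s$per_practice$sensitivity, s$per_practice$practice_id)
  se <- sqrt(c(0.5 * 0.5, 0.9 * 0.1) / (n / 2))
  expect_lt(abs(got[["PR1"]] - 0.5), 3 * se[1])
  expect_lt(abs(got[["PR2"]] - 0.9), 3 * se[2])
})

test_that("contingency reconstruction round-trips and handles degenerate input", {
  ct <- mortcomp:::new_contingency(80, 20, 20, 80)
  m <- setNames(metrics(ct)$estimate, metrics(ct)$metric)
  rec <- reconstruct_contingency(m[["specificity"]], m[["ppv"]], m[["npv"]],
                                 n = 200)
  expect_equal(unlist(rec[, c("A", "B", "C", "D")]),
               c(A = 80L, B = 20L, C = 20L, D = 80L))

  # all-dead table: only PPV is defined
  rec <- reconstruct_contingency(NA, 1, NA, n = 4)
  expect_equal(unlist(rec[, c("A", "B", "C", "D")]),
               c(A = 4L, B = 0L, C = 0L, D = 0L))

  expect_error(reconstruct_contingency(0.5, 0.999, 0.999, n = 20),
               class = "mortcomp_infeasible")
})
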