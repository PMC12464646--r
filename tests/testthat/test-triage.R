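test_that("predicates evaluate against the record and return evidence", {
  p <- patient_record("p1", age = 72,
                      medications = data.frame(
                        name = c("Clozapine", "paracetamol"),
                        regular = TRUE, missed_doses = c(0, 2)),
                      labs = data.frame(name = "eGFR", value = 40,
                                        units = "mL/min",
                                        date = "2026-01-02"),
                      flags = "seclusion")
  expect_equal(evaluate_predicate(p, predicate("medication_name_in",
                                               names = "clozapine")),
               "medication: Clozapine")
  expect_equal(evaluate_predicate(p, predicate("lab_compare", lab = "eGFR",
                                               op = "between", lo = 30,
                                               hi = 44, units = "mL/min")),
               "eGFR 40 mL/min")
  expect_match(evaluate_predicate(p, predicate("missed_dose_of", any = TRUE)),
               "2 missed dose")
  expect_equal(evaluate_predicate(p, predicate("age_compare", op = "gt",
                                               value = 70)),
               "age 72 years")
  expect_null(evaluate_predicate(p, predicate("age_compare", op = "gt",
                                              value = 80)))
  expect_equal(evaluate_predicate(p, predicate("flag_present",
                                               flag = "seclusion")),
               "flag: seclusion")
  expect_null(evaluate_predicate(p, predicate("manual")))
})

test_that("polypharmacy threshold is inclusive at the printed boundary", {
  meds <- function(n) data.frame(name = sprintf("m%02d", 1:n), regular = TRUE)
  ge10 <- predicate("regular_med_count_ge", count = 10)
  expect_null(evaluate_predicate(patient_record("p", medications = meds(9)),
                                 ge10))
  expect_equal(evaluate_predicate(patient_record("p", medications = meds(10)),
                                  ge10),
               "10 regular medications")
})

test_that("lab unit mismatches error rather than silently converting", {
  p <- patient_record("p1", labs = data.frame(name = "eGFR", value = 40,
                                              units = "mL/min/1.73m2"))
  expect_error(evaluate_predicate(p, predicate("lab_compare", lab = "eGFR",
                                               op = "lt", value = 60,
                                               units = "mL/min")),
               class = "delphitriage_unit_mismatch")
})

test_that("lab comparison uses the most recent result", {
  p <- patient_record("p1", labs = data.frame(
    name = "eGFR", value = c(35, 80), units = "mL/min",
    date = c("2026-01-01", "2026-02-01")))
  expect_null(evaluate_predicate(p, predicate("lab_compare", lab = "eGFR",
                                              op = "lt", value = 60,
                                              units = "mL/min")))
})

test_that("matching is exhaustive, flag-injectable and excludes merged ids", {
  catalog <- mini_catalog()
  empty <- patient_record("p0")
  expect_equal(nrow(match_indicators(empty, catalog)), 0)
  # a lithium patient with a toxic-level flag matches both indicators
  p <- patient_record("p1", age = 40,
                      medications = data.frame(name = "lithium"),
                      flags = "toxic_lithium_level")
  m <- match_indicators(p, catalog)
  expect_setequal(m$indicator_id, c("lithium", "toxic-lithium-levels"))
  expect_true(all(m$mode == "auto"))
  expect_true(all(nzchar(m$evidence)))
  # manual flag injects a match
  m2 <- match_indicators(p, catalog, manual_flags = "sig-interaction")
  expect_true("sig-interaction" %in% m2$indicator_id)
  expect_equal(m2$mode[m2$indicator_id == "sig-interaction"], "manual")
  # manual flags must name known, manual-predicate indicators
  expect_error(match_indicators(p, catalog, manual_flags = "nope"), "unknown")
  expect_error(match_indicators(p, catalog, manual_flags = "lithium"),
               "non-manual")
  # merged indicators never match
  merged <- apply_merge_plan(catalog,
                             tibble::tibble(id = "lithium", into = "clozapine"))
  m3 <- match_indicators(p, merged)
  expect_false("lithium" %in% m3$indicator_id)
})

test_that("unassigned-tier matches fall back to amber with a warning", {
  catalog <- indicator_catalog(tibble::tibble(
    id = "seclusion", text = "x", group = "hospital_related",
    tier = "unassigned",
    predicate = '{"type":"flag_present","flag":"seclusion"}'))
  p <- patient_record("p1", flags = "seclusion")
  expect_warning(m <- match_indicators(p, catalog), "amber")
  expect_equal(m$tier, "amber")
})

test_that("classification follows the red / escalation / amber / green rule", {
  red1 <- tibble::tibble(indicator_id = c("clozapine", "a1", "a2"),
                         tier = c("red", "amber", "amber"))
  r <- classify(red1)
  expect_equal(r$tier, "red")
  expect_false(r$escalated)
  # more than four ambers escalate
  r5 <- classify(amber_only_matches(5))
  expect_equal(r5$tier, "red")
  expect_true(r5$escalated)
  expect_equal(classify(amber_only_matches(4))$tier, "amber")
  expect_equal(classify(tibble::tibble(indicator_id = character(),
                                       tier = character()))$tier, "green")
  g <- glance(r5)
  expect_equal(g$n_amber, 5)
})

test_that("escalation boundary holds for every threshold 1..6", {
  for (k in 1:6) {
    pol <- triage_policy(amber_escalation_threshold = k)
    at <- classify(amber_only_matches(k), pol)
    above <- classify(amber_only_matches(k + 1), pol)
    expect_equal(at$tier, "amber")
    expect_false(at$escalated)
    expect_equal(above$tier, "red")
    expect_true(above$escalated)
  }
})

test_that("classification is order-invariant and monotone in matches", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(0:8, 1)
    m <- tibble::tibble(indicator_id = sprintf("i%d", seq_len(n)),
                        tier = sample(c("red", "amber", "green"), n,
                                      replace = TRUE))
    base <- classify(m)
    shuffled <- classify(m[sample(nrow(m)), ])
    expect_equal(shuffled$tier, base$tier)
    # adding one match never lowers severity
    extra <- tibble::tibble(indicator_id = "extra",
                            tier = sample(c("red", "amber", "green"), 1))
    grown <- classify(dplyr::bind_rows(m, extra))
    expect_true(tier_severity(grown$tier) >= tier_severity(base$tier))
  }
})

test_that("overrides demand authority and a non-empty comment", {
  r <- classify(amber_only_matches(1), patient_id = "p1")
  over <- apply_override(r, "red", "new rapid titration", author = "rx1")
  expect_equal(over$tier, "red")
  expect_equal(over$override$original_tier, "amber")
  expect_equal(over$override$comment, "new rapid titration")
  expect_equal(over$override$author, "rx1")
  expect_error(apply_override(r, "red", "   ", author = "rx1"),
               class = "delphitriage_override_comment")
  no <- triage_policy(allow_override = FALSE)
  expect_error(apply_override(classify(amber_only_matches(1), no),
                              "red", "why", "rx1"),
               "disallowed")
  relaxed <- triage_policy(require_override_comment = FALSE)
  expect_no_error(apply_override(classify(amber_only_matches(1), relaxed),
                                 "green", "", "rx1"))
})

test_that("patient cohorts round-trip through JSON and CSV", {
  cohort <- dplyr::bind_rows(
    patient_record("p1", age = 81, ward = "acute", admitted = "2026-01-01",
                   last_review = "2026-01-10",
                   medications = data.frame(name = c("clozapine", "senna"),
                                            class = c("antipsychotic", "other"),
                                            route = "oral", regular = TRUE,
                                            start = "2025-12-01",
                                            missed_doses = c(1, 0)),
                   labs = data.frame(name = "eGFR", value = 40,
                                     units = "mL/min", date = "2026-01-05"),
                   flags = c("seclusion", "covert_administration"),
                   manual_flags = "sig-interaction"),
    patient_record("p2", age = 30))
  for (ext in c(".json", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_patients(cohort, path)
    back <- read_patients(path)
    expect_equal(back$patient_id, cohort$patient_id)
    expect_equal(back$age, cohort$age)
    expect_equal(back$flags, cohort$flags)
    expect_equal(back$medications[[1]]$name, cohort$medications[[1]]$name)
    expect_equal(as.numeric(back$medications[[1]]$missed_doses),
                 cohort$medications[[1]]$missed_doses)
    expect_equal(back$labs[[1]]$value, cohort$labs[[1]]$value)
    expect_equal(back$last_review, cohort$last_review)
  }
})

test_that("triage_cohort produces one tidy row per patient", {
  catalog <- mini_catalog()
  cohort <- dplyr::bind_rows(
    patient_record("p1", medications = data.frame(name = "clozapine")),
    patient_record("p2", flags = "seclusion"),
    patient_record("p3"))
  res <- triage_cohort(cohort, catalog)
  expect_equal(res$tier, c("red", "amber", "green"))
  expect_equal(res$matched_ids[[1]], "clozapine")
  path <- withr::local_tempfile(fileext = ".csv")
  write_triage(res, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(out$tier, res$tier)
})
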