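test_that("exact-count panels reproduce their specified counts exactly", {
  spec <- panel_spec(n_panellists = 29, dropout = 0, seed = 11,
                     items = list(a = score_counts(c(0, 0, 0, 0, 0, 14, 15)),
                                  b = score_counts(c(1, 2, 3, 4, 5, 6, 7)),
                                  c = score_counts(c(0, 0, 0, 29, 0, 0, 0))))
  s <- summarize_ratings(generate_panel(spec))
  expect_equal(unname(unlist(s[s$item == "a", paste0("n", 1:7)])),
               c(0L, 0L, 0L, 0L, 0L, 14L, 15L))
  expect_equal(s[s$item == "a", ]$pct_6_7, 100)
  expect_equal(s[s$item == "a", ]$median, 7)
  expect_equal(unname(unlist(s[s$item == "b", paste0("n", 1:7)])),
               1:7)
  # panellists beyond the counted ones answered outside their expertise
  expect_equal(s[s$item == "b", ]$n_valid, 28L)
  expect_equal(s[s$item == "c", ]$median, 4)
})

test_that("a panel emulating the full-consensus indicator is included and red", {
  # 29 completers all rating importance 7 and risk 6-7
  spec <- panel_spec(n_panellists = 29, dropout = 0, seed = 4,
                     items = list(cloz = score_counts(c(0, 0, 0, 0, 0, 0, 29))))
  imp <- summarize_ratings(generate_panel(spec, dimension = "importance"))
  risk <- summarize_ratings(generate_panel(spec, dimension = "risk"))
  expect_true(include_indicator(imp))
  expect_equal(assign_tier(risk), "red")
})

test_that("distribution-mode percentages converge to the target", {
  spec <- panel_spec(n_panellists = 2000, dropout = 0, oe_prob = 0.1, seed = 42,
                     items = list(x = score_probs(c(0, 0, 0.05, 0.05, 0.1,
                                                    0.4, 0.4))))
  s <- summarize_ratings(generate_panel(spec))
  expect_lt(abs(s$pct_6_7 - 80), 3)
  expect_gt(s$n_valid, 1600)  # ~10% outside-expertise
})

test_that("panel generation is seeded, reproducible and leaves the RNG alone", {
  spec <- panel_spec(n_panellists = 10, dropout = 3, seed = 7,
                     items = list(x = score_probs(rep(1 / 7, 7))))
  r1 <- generate_panel(spec)
  set.seed(123); noise <- runif(1)
  r2 <- generate_panel(spec)
  expect_identical(r1, r2)
  # global RNG stream unaffected by the generator
  set.seed(123)
  expect_identical(runif(1), noise)
  # round 2 drops the configured number of panellists, reproducibly
  r2a <- generate_panel(spec, round = 2)
  r2b <- generate_panel(spec, round = 2)
  expect_identical(r2a, r2b)
  expect_equal(dplyr::n_distinct(r2a$panellist), 7)
  expect_true(all(r2a$panellist %in% r1$panellist))
})

test_that("infeasible exact counts are rejected", {
  expect_error(panel_spec(n_panellists = 5, dropout = 0,
                          items = list(x = score_counts(c(0, 0, 0, 0, 0, 3, 3)))),
               "exceed the panel")
  expect_error(score_counts(c(1, 2, 3)), "7 non-negative")
  expect_error(score_probs(rep(0, 7)), "probabilities")
})

test_that("planted cohorts are satisfiable and exactly recovered", {
  catalog <- mini_catalog()
  spec <- cohort_spec(n_patients = 3,
                      plant = list("clozapine", c("seclusion", "ckd-3b"),
                                   character()),
                      seed = 6)
  gen <- generate_cohort(spec, catalog)
  expect_equal(nrow(gen$cohort), 3)
  # patient 1 carries clozapine; match_indicators returns exactly that match
  m1 <- match_indicators(gen$cohort[1, ], catalog)
  expect_equal(m1$indicator_id, "clozapine")
  truth1 <- gen$ground_truth[gen$ground_truth$patient_id == "PT0001", ]
  expect_equal(truth1$indicator_id, "clozapine")
  # patient 2: lab value constructed inside the eGFR 30-44 band
  egfr <- gen$cohort$labs[[2]]
  expect_true(any(egfr$name == "eGFR" & egfr$value >= 30 & egfr$value <= 44))
  # patient 3: empty plant, no matches
  expect_false("PT0003" %in% gen$ground_truth$patient_id)
})

test_that("five planted ambers escalate to red under the default policy", {
  catalog <- indicator_catalog(tibble::tibble(
    id = paste0("amber", 1:5), text = "x", group = "patient_related",
    tier = "amber",
    predicate = sprintf('{"type":"flag_present","flag":"f%d"}', 1:5)))
  spec <- cohort_spec(n_patients = 1, plant = list(paste0("amber", 1:5)),
                      seed = 2)
  gen <- generate_cohort(spec, catalog)
  res <- triage_cohort(gen$cohort, catalog)
  expect_equal(res$tier, "red")
  expect_true(res$escalated)
  expect_equal(res$n_amber, 5)
})

test_that("a 500-patient random cohort matches its ground truth exactly", {
  catalog <- mini_catalog()
  auto_ids <- setdiff(active_indicators(catalog)$id, "sig-interaction")
  probs <- rlang::set_names(rep(0.15, length(auto_ids)), auto_ids)
  spec <- cohort_spec(n_patients = 500, plant = probs, seed = 17)
  gen <- generate_cohort(spec, catalog)
  expect_equal(nrow(gen$cohort), 500)
  found <- purrr::map(seq_len(500), function(i) {
    sort(match_indicators(gen$cohort[i, ], catalog)$indicator_id)
  })
  truth <- split(gen$ground_truth$indicator_id, gen$ground_truth$patient_id)
  for (i in seq_len(500)) {
    pid <- gen$cohort$patient_id[i]
    expect_identical(found[[i]], sort(truth[[pid]] %||% character()))
  }
  # planted indicators are always a subset of the ground truth
  expect_true(all(gen$ground_truth$planted |
                    gen$ground_truth$indicator_id %in% auto_ids))
})

test_that("cohort generation is bit-reproducible for a fixed seed", {
  catalog <- mini_catalog()
  spec <- cohort_spec(n_patients = 20,
                      plant = rlang::set_names(rep(0.3, 3),
                                               c("clozapine", "seclusion",
                                                 "age-over-80")),
                      seed = 33)
  g1 <- generate_cohort(spec, catalog)
  g2 <- generate_cohort(spec, catalog)
  expect_identical(g1, g2)
  # serialised form is bit-stable too
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_patients(g1$cohort, p1)
  write_patients(g2$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the cohort
  g3 <- generate_cohort(cohort_spec(n_patients = 20,
                                    plant = spec$plant, seed = 34), catalog)
  expect_false(identical(g1$cohort, g3$cohort))
})

test_that("manual indicators need the explicit flag channel", {
  catalog <- mini_catalog()
  expect_error(generate_cohort(cohort_spec(1, plant = list("sig-interaction")),
                               catalog),
               "manual_channel")
  spec <- cohort_spec(1, plant = list("sig-interaction"), manual_channel = TRUE,
                      seed = 8)
  gen <- generate_cohort(spec, catalog)
  expect_equal(gen$cohort$manual_flags[[1]], "sig-interaction")
  m <- match_indicators(gen$cohort[1, ], catalog)
  expect_equal(m$mode, "manual")
  expect_equal(gen$ground_truth$indicator_id, "sig-interaction")
})

test_that("implied matches are reported in ground truth, not hidden", {
  catalog <- indicator_catalog(tibble::tibble(
    id = c("poly5", "poly10"), text = "x", group = "drug_related",
    tier = "amber",
    predicate = c('{"type":"regular_med_count_ge","count":5}',
                  '{"type":"regular_med_count_ge","count":10}')))
  gen <- generate_cohort(cohort_spec(1, plant = list("poly10"), seed = 3),
                         catalog)
  truth <- gen$ground_truth
  expect_setequal(truth$indicator_id, c("poly5", "poly10"))
  expect_true(truth$planted[truth$indicator_id == "poly10"])
  expect_false(truth$planted[truth$indicator_id == "poly5"])
})
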