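test_that("catalogs round-trip through JSON and CSV", {
  cat0 <- indicator_catalog(tibble::tibble(
    id = c("clozapine", "seclusion"),
    text = c("Clozapine", "Patients in seclusion"),
    group = c("high_risk_medicine", "hospital_related"),
    tier = c("red", "amber"),
    predicate = c('{"type":"medication_name_in","names":["clozapine"]}',
                  "manual")),
    version = "v1", created = as.Date("2026-01-01"))
  for (ext in c(".json", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_catalog(cat0, path)
    back <- read_catalog(path)
    expect_equal(as.data.frame(back), as.data.frame(cat0),
                 ignore_attr = TRUE)
    if (ext == ".json") {
      # catalog metadata survives only in JSON
      expect_equal(attr(back, "version"), "v1")
      expect_equal(attr(back, "created"), as.Date("2026-01-01"))
    }
    # write(read(write(x))) is byte-identical
    path2 <- withr::local_tempfile(fileext = ext)
    write_catalog(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("duplicate ids and schema violations are distinct errors", {
  dup <- tibble::tibble(id = c("clozapine", "clozapine"), text = "Clozapine",
                        group = "high_risk_medicine")
  expect_error(indicator_catalog(dup), class = "delphitriage_duplicate_id")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(id = "a", text = "A"), path)
  expect_error(read_catalog(path), "missing column")
})

test_that("invariants are enforced: merge targets, tier assignment", {
  base <- tibble::tibble(id = c("a", "b"), text = c("A", "B"),
                         group = "patient_related")
  bad_target <- dplyr::mutate(base,
                              status = c("merged_into:zzz", "active"))
  expect_error(indicator_catalog(bad_target), "merge target")
  bad_tier <- dplyr::mutate(base, status = c("excluded", "active"),
                            tier = c("red", "unassigned"))
  expect_error(indicator_catalog(bad_tier), "tier assigned to non-active")
})

test_that("union of sources counts shared indicators once", {
  # the published collation: 48 + 415 with 3 shared -> 460
  a <- tibble::tibble(id = sprintf("lit%03d", 1:48), source = "systematic_review")
  b <- tibble::tibble(id = c(sprintf("lit%03d", 1:3), sprintf("svc%03d", 1:412)),
                      source = "practice_survey")
  u <- union_sources(a, b)
  expect_equal(n_active(u), 460)
  expect_equal(sort(u$source[u$id %in% sprintf("lit%03d", 1:3)]),
               rep("systematic_review;practice_survey", 3))
  # disjoint lists
  expect_equal(n_active(union_sources(tibble::tibble(id = c("x", "y")),
                                      tibble::tibble(id = c("p", "q", "r")))),
               5)
})

test_that("union count equals a brute-force pairwise overlap oracle", {
  set.seed(99)
  for (rep in 1:10) {
    na <- sample(5:40, 1); nb <- sample(5:40, 1)
    k <- sample(0:min(na, nb), 1)
    ids_a <- sprintf("A%03d", sample(500, na))
    shared <- sample(ids_a, k)
    ids_b <- c(shared, sprintf("B%03d", sample(500, nb - k)))
    # brute force: compare every pair
    overlap <- 0L
    for (x in ids_a) for (y in ids_b) if (x == y) overlap <- overlap + 1L
    u <- union_sources(tibble::tibble(id = ids_a), tibble::tibble(id = ids_b))
    expect_equal(n_active(u), na + nb - overlap)
    # commutative in the active count
    u2 <- union_sources(tibble::tibble(id = ids_b), tibble::tibble(id = ids_a))
    expect_equal(n_active(u2), n_active(u))
  }
})

test_that("merge plans absorb, exclude and audit; recount oracle agrees", {
  cat0 <- indicator_catalog(tibble::tibble(id = letters[1:10], text = letters[1:10],
                                           group = "drug_related", tier = "amber"))
  plan <- tibble::tibble(id = c("b", "c"), into = c("a", "a"))
  out <- apply_merge_plan(cat0, plan, exclusions = "j")
  expect_equal(n_active(out), 10 - 2 - 1)
  expect_equal(out$status[out$id == "b"], "merged_into:a")
  expect_equal(out$tier[out$id == "b"], "unassigned")
  expect_match(out$notes[out$id == "a"], "absorbed b")
  expect_equal(out$status[out$id == "j"], "excluded")
  # independent recount of the status column
  expect_equal(n_active(out), sum(out$status %in% c("active", "modified")))
  k <- catalog_counts(out)
  expect_equal(k$active + k$merged + k$excluded, k$total)
  # identity on the empty plan
  expect_equal(tibble::as_tibble(apply_merge_plan(cat0)),
               tibble::as_tibble(cat0))
  # absorbing an already-merged id fails
  expect_error(apply_merge_plan(out, tibble::tibble(id = "b", into = "d")),
               "non-active")
  expect_error(apply_merge_plan(cat0, tibble::tibble(id = c("b", "a"),
                                                     into = c("a", "d"))),
               "cannot itself be absorbed")
})

test_that("random merge plans keep counts consistent with a recount", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    cat0 <- indicator_catalog(tibble::tibble(id = sprintf("i%03d", 1:n),
                                             text = "t", group = "patient_related"))
    k_abs <- sample(0:(n %/% 3), 1)
    k_exc <- sample(0:(n %/% 4), 1)
    picked <- sample(cat0$id, k_abs + k_exc + 1)
    rep_id <- picked[1]
    absorbed <- picked[seq_len(k_abs) + 1]
    excluded <- setdiff(picked, c(rep_id, absorbed))
    out <- apply_merge_plan(cat0,
                            if (k_abs) tibble::tibble(id = absorbed, into = rep_id),
                            exclusions = excluded)
    expect_equal(n_active(out), n - k_abs - length(excluded))
    expect_equal(n_active(out), sum(out$status %in% c("active", "modified")))
  }
})

test_that("the packaged study catalog has the published shape", {
  full <- study_catalog(round = 2)
  expect_equal(nrow(full), 123)
  expect_equal(sum(full$source == "panel_round2_addition"), 14)
  expect_true(all(full$group %in% c("high_risk_medicine", "patient_related",
                                    "drug_related", "hospital_related")))
  # every indicator included in round 2 carries a red or amber tier: no
  # indicator reached the low-risk band and the fallback covers the rest
  b2 <- published_indicator_bands(round = 2, dimension = "importance")
  included <- b2$id[include_indicator(b2)]
  expect_equal(length(included), 82)
  expect_true(all(full$tier[full$id %in% included] %in% c("red", "amber")))
  expect_true(all(full$tier[!full$id %in% included] == "unassigned"))
})

test_that("the tool catalog reproduces the editorial refinement arithmetic", {
  tc <- tool_catalog()
  k <- catalog_counts(tc)
  expect_equal(k$total, 82)   # indicators that met round-2 consensus
  expect_equal(k$merged, 10)  # merged into representatives
  expect_equal(k$excluded, 1) # stakeholder exclusion
  expect_equal(k$active, 71)  # indicators in the final tool
  active <- active_indicators(tc)
  expect_true(all(active$tier %in% c("red", "amber")))
  expect_true(all(nzchar(active$predicate)))
  # predicates parse
  for (p in active$predicate) expect_no_error(parse_predicate(p))
  expect_equal(nrow(active_indicators(tool_catalog(keep_all = FALSE))), 71)
})
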