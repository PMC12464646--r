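with_preserved_seed <- function(seed, code) {
  if (seed < 0 || seed >= 2^31) abort("seed must be a non-negative integer < 2^31")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# one root seed drives every stream; sub-streams are derived by fixed offsets
# so that panel and cohort fixtures built from the same root seed are
# independent yet jointly reproducible
split_seed <- function(seed, stream) (as.integer(seed) * 1009L + stream) %% 2147483629L

#' Per-item score targets for the panel generator
#'
#' `score_counts()` declares exact per-score counts (the generator reproduces
#' them verbatim; panellists beyond the counted ones answer "outside my
#' expertise"); `score_probs()` declares a target distribution over the 1-7
#' scale that panellists sample independently.
#'
#' @param counts Integer vector of length 7 (scores 1..7).
#' @param probs Non-negative numeric vector of length 7; normalised to sum
#'   to 1.
#' @return A tagged item spec for [panel_spec()].
#' @examples
#' score_counts(c(0, 0, 0, 0, 0, 14, 15))
#' score_probs(c(0, 0, 0.05, 0.05, 0.1, 0.4, 0.4))
#' @export
score_counts <- function(counts) {
  if (length(counts) != 7 || any(is.na(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    abort("score_counts: need 7 non-negative integer counts")
  }
  structure(list(counts = as.integer(counts)), class = "score_counts")
}

#' @rdname score_counts
#' @export
score_probs <- function(probs) {
  if (length(probs) != 7 || any(is.na(probs)) || any(probs < 0) ||
      sum(probs) <= 0) {
    abort("score_probs: need 7 non-negative probabilities")
  }
  structure(list(probs = probs / sum(probs)), class = "score_probs")
}

#' Synthetic Delphi panel specification and generator
#'
#' Generates long-format rating matrices with controllable consensus
#' structure. Defaults emulate the development study's panel: 36 invited
#' panellists completing round 1 with 7 dropping out before round 2 (29
#' completers), and an "outside my expertise" option that panellists use with
#' a small probability in distribution mode. In exact-count mode,
#' [summarize_ratings()] on the output reproduces the specified counts
#' exactly; in distribution mode the band percentages converge to the target
#' as the panel grows. Output is fully determined by `seed`.
#'
#' @param n_panellists Panel size for round 1. Default 36.
#' @param items Named list of [score_counts()]/[score_probs()] specs, one per
#'   item.
#' @param oe_prob Probability of an "outside my expertise" response in
#'   distribution mode. Default 0.05.
#' @param dropout Number of panellists lost between rounds. Default 7.
#' @param seed Integer root seed.
#' @return `panel_spec()`: a spec list; `generate_panel()`: a ratings tibble.
#' @examples
#' spec <- panel_spec(items = list(cloz = score_counts(c(0, 0, 0, 0, 0, 0, 29))),
#'                    n_panellists = 29, dropout = 0)
#' summarize_ratings(generate_panel(spec))
#' @export
panel_spec <- function(n_panellists = 36, items = list(), oe_prob = 0.05,
                       dropout = 7, seed = 1) {
  if (n_panellists < 1) abort("panel_spec: need at least one panellist")
  if (oe_prob < 0 || oe_prob > 1) abort("panel_spec: oe_prob must be in [0, 1]")
  if (dropout < 0 || dropout >= n_panellists) {
    abort("panel_spec: dropout must be in [0, n_panellists)")
  }
  if (length(items) && is.null(names(items))) abort("panel_spec: items must be named")
  for (nm in names(items)) {
    it <- items[[nm]]
    if (!inherits(it, c("score_counts", "score_probs"))) {
      abort(paste0("panel_spec: item '", nm,
                   "' must be score_counts() or score_probs()"))
    }
    if (inherits(it, "score_counts") && sum(it$counts) > n_panellists) {
      abort(paste0("panel_spec: exact counts for item '", nm,
                   "' exceed the panel size"))
    }
  }
  structure(list(n_panellists = as.integer(n_panellists), items = items,
                 oe_prob = oe_prob, dropout = as.integer(dropout),
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' @rdname panel_spec
#' @param spec A `panel_spec`.
#' @param round Round to generate (1 or 2); round 2 drops `dropout`
#'   panellists chosen reproducibly from the root seed.
#' @param dimension Dimension label for the generated ratings.
#' @param study Optional study label.
#' @export
generate_panel <- function(spec, round = 1, dimension = "importance",
                           study = "synthetic") {
  if (!inherits(spec, "panel_spec")) abort("expected a panel_spec")
  panellists <- sprintf("P%03d", seq_len(spec$n_panellists))
  if (round == 2 && spec$dropout > 0) {
    drop <- with_preserved_seed(split_seed(spec$seed, 1L),
                                sample(panellists, spec$dropout))
    panellists <- setdiff(panellists, drop)
  }
  with_preserved_seed(split_seed(spec$seed, 10L + round), {
    rows <- purrr::imap(spec$items, function(it, nm) {
      resp <- if (inherits(it, "score_counts")) {
        scores <- rep(as.character(1:7), it$counts)
        extra <- rep("OE", length(panellists) - length(scores))
        sample(c(scores, extra))
      } else {
        oe <- runif(length(panellists)) < spec$oe_prob
        s <- sample(as.character(1:7), length(panellists), replace = TRUE,
                    prob = it$probs)
        ifelse(oe, "OE", s)
      }
      tibble(study = study, round = as.integer(round),
             panellist = panellists, item = nm, dimension = dimension,
             response = resp)
    })
    bind_rows(rows) |> arrange(.data$item, .data$panellist)
  })
}

default_formulary <- function() {
  tibble(name = c("paracetamol", "omeprazole", "senna", "atorvastatin",
                  "levothyroxine", "amlodipine", "salbutamol", "cetirizine",
                  "colecalciferol", "folic acid", "docusate", "lactulose"),
         class = "other")
}

#' Synthetic patient cohort specification and generator
#'
#' Generates patient cohorts with *planted* indicator matches against a
#' catalog: each planted indicator's predicate is made satisfiable by
#' construction (a matching medication, lab value, flag, age or review date),
#' while the unplanted record is drawn from ranges chosen not to trip any
#' catalog predicate (ages 25-65, at most `background_meds_max` neutral
#' formulary medications, no flags, a recent review). Accidental matches are
#' avoided by rejection sampling up to `retry_cap` resamples; logically
#' implied matches (e.g. ten regular medications necessarily satisfy the
#' five-medication polypharmacy indicator too) cannot be rejected away and
#' are then added to the returned ground truth rather than silently ignored.
#' The returned ground truth therefore always lists exactly the indicators
#' [match_indicators()] finds.
#'
#' Planting a manual-predicate indicator requires the explicit flag channel
#' (`manual_channel = TRUE`), which plants it as a per-patient clinical
#' judgement flag; otherwise it is an error, since manual indicators cannot
#' be matched from record data.
#'
#' @param n_patients Number of patients.
#' @param plant Either a named numeric vector of per-indicator planting
#'   probabilities, or a list of character vectors (exact planted set per
#'   patient, recycled to `n_patients`).
#' @param formulary Data frame of neutral background medications
#'   (`name`, `class`).
#' @param age_range Background age range (avoids the published age bands).
#' @param background_meds_max Maximum background medications per patient.
#' @param manual_channel Allow planting manual indicators as judgement flags.
#' @param retry_cap Rejection-sampling retries per patient. Default 25.
#' @param seed Integer root seed.
#' @return `cohort_spec()`: a spec list; `generate_cohort()`: a list with
#'   `cohort` (patient tibble) and `ground_truth`
#'   (`patient_id, indicator_id, planted`).
#' @examples
#' spec <- cohort_spec(n_patients = 2, plant = list("clozapine", "seclusion"))
#' gen <- generate_cohort(spec, tool_catalog())
#' gen$ground_truth
#' @export
cohort_spec <- function(n_patients, plant = list(character()),
                        formulary = default_formulary(),
                        age_range = c(25, 65), background_meds_max = 3,
                        manual_channel = FALSE, retry_cap = 25, seed = 1) {
  if (n_patients < 1) abort("cohort_spec: need at least one patient")
  if (is.numeric(plant)) {
    if (is.null(names(plant)) || any(plant < 0 | plant > 1)) {
      abort("cohort_spec: planting probabilities must be named and in [0, 1]")
    }
  } else if (!is.list(plant)) {
    abort("cohort_spec: `plant` must be a named probability vector or a list of id sets")
  }
  structure(list(n_patients = as.integer(n_patients), plant = plant,
                 formulary = as_tibble(formulary), age_range = age_range,
                 background_meds_max = as.integer(background_meds_max),
                 manual_channel = isTRUE(manual_channel),
                 retry_cap = as.integer(retry_cap), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec`.
#' @param catalog An [indicator_catalog()] with predicates.
#' @param today Reference date for time-based predicates.
#' @export
generate_cohort <- function(spec, catalog, today = Sys.Date()) {
  if (!inherits(spec, "cohort_spec")) abort("expected a cohort_spec")
  active <- active_indicators(catalog)
  specs <- rlang::set_names(lapply(active$predicate, parse_predicate),
                            active$id)
  plant_ids <- if (is.numeric(spec$plant)) names(spec$plant) else
    unique(unlist(spec$plant))
  unknown <- setdiff(plant_ids, active$id)
  if (length(unknown)) {
    abort(paste0("cohort_spec plants unknown/inactive indicator(s): ",
                 paste(unknown, collapse = ", ")))
  }
  manual_ids <- plant_ids[vapply(specs[plant_ids], function(s)
    identical(s$type, "manual"), logical(1))]
  if (length(manual_ids) && !spec$manual_channel) {
    abort(paste0("planting manual-predicate indicator(s) requires ",
                 "manual_channel = TRUE: ", paste(manual_ids, collapse = ", ")))
  }
  with_preserved_seed(split_seed(spec$seed, 20L), {
    planted_sets <- lapply(seq_len(spec$n_patients), function(i) {
      if (is.numeric(spec$plant)) {
        names(spec$plant)[runif(length(spec$plant)) < spec$plant]
      } else {
        spec$plant[[(i - 1L) %% length(spec$plant) + 1L]]
      }
    })
    patients <- vector("list", spec$n_patients)
    truth <- vector("list", spec$n_patients)
    for (i in seq_len(spec$n_patients)) {
      pid <- sprintf("PT%04d", i)
      planted <- planted_sets[[i]]
      for (attempt in seq_len(spec$retry_cap)) {
        rec <- build_planted_record(pid, planted, specs, spec, today)
        found <- match_indicators(rec, catalog, today = today)$indicator_id
        if (setequal(found, planted)) break
      }
      patients[[i]] <- rec
      truth[[i]] <- tibble(patient_id = pid,
                           indicator_id = sort(found),
                           planted = sort(found) %in% planted)
    }
    list(cohort = bind_rows(patients), ground_truth = bind_rows(truth))
  })
}

build_planted_record <- function(pid, planted, specs, spec, today) {
  meds <- tibble(name = character(), class = character(), route = character(),
                 regular = logical(), start = as.Date(character()),
                 missed_doses = numeric())
  add_med <- function(name, class = "other", missed = 0) {
    meds <<- bind_rows(meds, tibble(name = name, class = class,
                                    route = "oral", regular = TRUE,
                                    start = today - 30, missed_doses = missed))
  }
  labs <- tibble(name = character(), value = numeric(), units = character(),
                 date = as.Date(character()))
  flags <- character(); manual_flags <- character()
  age <- round(runif(1, spec$age_range[1], spec$age_range[2]))
  last_review <- today - 2
  want_regular <- 0L
  for (id in planted) {
    s <- specs[[id]]
    switch(s$type,
      manual = { manual_flags <- c(manual_flags, id) },
      medication_name_in = add_med(s$names[1]),
      medication_class_in = add_med(paste0("synthetic ", s$classes[1]),
                                    class = s$classes[1]),
      regular_med_count_ge = { want_regular <- max(want_regular, s$count) },
      missed_dose_of = {
        nm <- if (!is.null(s$names)) s$names[1] else
          if (!is.null(s$classes)) paste0("synthetic ", s$classes[1]) else
            spec$formulary$name[1]
        cl <- if (!is.null(s$classes) && is.null(s$names)) s$classes[1] else "other"
        add_med(nm, class = cl, missed = 2)
      },
      lab_compare = {
        value <- switch(s$op,
                        between = (s$lo + s$hi) / 2,
                        gt = s$value * 1.25 + 1, ge = s$value,
                        lt = max(s$value * 0.75 - 1, 0), le = s$value)
        labs <- bind_rows(labs, tibble(name = s$lab, value = value,
                                       units = s$units, date = today - 1))
      },
      age_compare = {
        age <- switch(s$op, gt = s$value + 3, ge = s$value,
                      lt = max(s$value - 3, 1), le = s$value)
      },
      flag_present = { flags <- c(flags, s$flag) },
      days_since_event_ge = {
        if (s$event == "last_review") last_review <- today - (s$days + 2)
      }
    )
  }
  n_background <- sample.int(spec$background_meds_max + 1L, 1L) - 1L
  if (want_regular > 0) {
    n_background <- max(0L, want_regular - nrow(meds))
  }
  if (n_background > 0) {
    picks <- spec$formulary[sample.int(nrow(spec$formulary),
                                       min(n_background,
                                           nrow(spec$formulary))), ]
    for (k in seq_len(nrow(picks))) add_med(picks$name[k], picks$class[k])
  }
  patient_record(pid, age = age, ward = "acute", admitted = today - 14,
                 last_review = last_review, medications = meds, labs = labs,
                 flags = unique(flags), manual_flags = unique(manual_flags))
}
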