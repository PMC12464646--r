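#' Match a patient against an indicator catalog
#'
#' Evaluates every active catalog indicator's predicate against the patient
#' record and returns one row per satisfied indicator. Manual-predicate
#' indicators (clinical-judgement criteria) never match automatically; they
#' are injected through `manual_flags`, which must name known,
#' manual-predicate, active indicators. Merged and excluded indicators never
#' match. Active indicators with an unassigned tier are treated as amber with
#' a warning, per the stakeholder fallback that criteria without a high- or
#' low-risk consensus count as medium risk.
#'
#' @param patient A patient record or one-row cohort tibble.
#' @param catalog An [indicator_catalog()] with predicates (e.g.
#'   [tool_catalog()]).
#' @param manual_flags Character vector of manual indicator ids asserted for
#'   this patient (defaults to the record's own `manual_flags`).
#' @param today Reference date for time-based predicates.
#' @return A tibble with columns `indicator_id`, `tier`, `evidence`, `mode`.
#' @examples
#' p <- patient_record("p1", age = 40,
#'                     medications = data.frame(name = "clozapine"))
#' match_indicators(p, tool_catalog())
#' @export
match_indicators <- function(patient, catalog, manual_flags = NULL,
                             today = Sys.Date()) {
  patient <- as_patient(patient)
  manual_flags <- as.character(manual_flags %||% patient$manual_flags)
  active <- active_indicators(catalog)
  if (length(manual_flags)) {
    unknown <- setdiff(manual_flags, active$id)
    if (length(unknown)) {
      abort(paste0("manual flag(s) for unknown or inactive indicator(s): ",
                   paste(unknown, collapse = ", ")))
    }
    types <- vapply(active$predicate[match(manual_flags, active$id)],
                    function(p) parse_predicate(p)$type %||% "none", "")
    bad <- manual_flags[types != "manual"]
    if (length(bad)) {
      abort(paste0("manual flag(s) for non-manual indicator(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  tier <- active$tier
  if (any(tier == "unassigned")) {
    hit_un <- FALSE
    for (k in which(tier == "unassigned")) {
      auto <- !is.null(evaluate_predicate(patient, active$predicate[k], today))
      if (auto || active$id[k] %in% manual_flags) hit_un <- TRUE
    }
    if (hit_un) {
      warn("matched indicator(s) with unassigned tier treated as amber (medium-risk fallback)")
    }
    tier[tier == "unassigned"] <- "amber"
  }
  rows <- purrr::map(seq_len(nrow(active)), function(k) {
    id <- active$id[k]
    if (id %in% manual_flags) {
      return(tibble(indicator_id = id, tier = tier[k],
                    evidence = "clinical judgement flag", mode = "manual"))
    }
    ev <- evaluate_predicate(patient, active$predicate[k], today)
    if (is.null(ev)) NULL else
      tibble(indicator_id = id, tier = tier[k], evidence = ev, mode = "auto")
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(indicator_id = character(), tier = character(),
                  evidence = character(), mode = character())
  }
  out
}

#' Traffic-light classification of a matched patient
#'
#' Classification is red when any red indicator matched; otherwise red with
#' `escalated = TRUE` when the number of amber matches exceeds the policy's
#' amber-escalation threshold (default: more than 4 ambers); otherwise amber
#' when any amber matched; otherwise green. The result is invariant to match
#' order, and adding a match can never lower the severity.
#'
#' @param matches A match tibble from [match_indicators()] (needs
#'   `indicator_id` and `tier` columns).
#' @param policy A [triage_policy()].
#' @param patient_id Optional id recorded in the result.
#' @return A `triage_result` with fields `tier`, `matches`, `n_red`,
#'   `n_amber`, `escalated`, `override` (NULL until [apply_override()]) and
#'   `evaluated_at`.
#' @examples
#' classify(data.frame(indicator_id = letters[1:5], tier = "amber"))
#' @export
classify <- function(matches, policy = triage_policy(), patient_id = NA) {
  matches <- as_tibble(matches)
  if (nrow(matches)) {
    need_cols(matches, c("indicator_id", "tier"), "classify")
    if (any(!matches$tier %in% c("red", "amber", "green"))) {
      abort("classify: every match must carry a red/amber/green tier")
    }
  } else {
    matches <- tibble(indicator_id = character(), tier = character())
  }
  n_red <- sum(matches$tier == "red")
  n_amber <- sum(matches$tier == "amber")
  escalated <- n_red == 0 & n_amber > policy$amber_escalation_threshold
  tier <- if (n_red > 0 || escalated) "red" else
    if (n_amber > 0) "amber" else "green"
  structure(list(patient_id = as.character(patient_id), tier = tier,
                 matches = matches, n_red = n_red, n_amber = n_amber,
                 escalated = escalated, override = NULL,
                 policy = policy, evaluated_at = Sys.time()),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result%s: %s%s; %d red + %d amber match(es)%s>\n",
              if (!is.na(x$patient_id)) paste0(" ", x$patient_id) else "",
              toupper(x$tier),
              if (x$escalated) " (amber escalation)" else "",
              x$n_red, x$n_amber,
              if (!is.null(x$override))
                sprintf("; override by %s from %s", x$override$author,
                        x$override$original_tier) else ""))
  invisible(x)
}

#' @export
tidy.triage_result <- function(x, ...) x$matches

#' @export
glance.triage_result <- function(x, ...) {
  tibble(patient_id = x$patient_id, tier = x$tier, n_red = x$n_red,
         n_amber = x$n_amber, escalated = x$escalated,
         override = !is.null(x$override))
}

#' Clinical-judgement override of a triage result
#'
#' Replaces the computed tier while keeping a full audit trail (original
#' tier, author, timestamp and the compulsory comment). The policy controls
#' whether overrides are allowed and whether the comment is required; an
#' empty or whitespace comment is rejected when required.
#'
#' @param result A `triage_result` from [classify()].
#' @param target Target tier (`"red"`, `"amber"`, `"green"`).
#' @param comment Free-text justification.
#' @param author Identifier of the overriding clinician.
#' @param policy A [triage_policy()]; defaults to the one used to classify.
#' @return The overridden `triage_result`.
#' @export
apply_override <- function(result, target, comment, author,
                           policy = result$policy) {
  if (!inherits(result, "triage_result")) abort("expected a triage_result")
  if (!policy$allow_override) {
    abort("overrides are disallowed by the triage policy")
  }
  target <- match.arg(target, c("red", "amber", "green"))
  if (policy$require_override_comment &&
      (length(comment) != 1 || is.na(comment) || !nzchar(trimws(comment)))) {
    abort("override rejected: a non-empty comment is compulsory",
          class = "delphitriage_override_comment")
  }
  result$override <- list(original_tier = result$tier, target = target,
                          comment = comment, author = as.character(author),
                          at = Sys.time())
  result$tier <- target
  result
}

#' Triage a cohort
#'
#' Matches and classifies every patient of a cohort, returning one tidy row
#' per patient. Each record's own `manual_flags` are applied.
#'
#' @param cohort A cohort tibble (see [patient_record()], [read_patients()],
#'   [generate_cohort()]).
#' @param catalog An [indicator_catalog()] with predicates.
#' @param policy A [triage_policy()].
#' @param today Reference date for time-based predicates.
#' @return A tibble with columns `patient_id, tier, n_red, n_amber,
#'   escalated, override, matched_ids` (list-column) plus a `matches`
#'   list-column of evidence tibbles.
#' @examples
#' cohort <- patient_record("p1", age = 85)
#' triage_cohort(cohort, tool_catalog())
#' @export
triage_cohort <- function(cohort, catalog, policy = triage_policy(),
                          today = Sys.Date()) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    p <- cohort[i, ]
    m <- match_indicators(p, catalog, today = today)
    r <- classify(m, policy, patient_id = p$patient_id)
    mutate(glance(r), matched_ids = list(sort(m$indicator_id)),
           matches = list(m))
  })
  bind_rows(rows)
}

#' Write cohort triage output
#'
#' One CSV row per patient: `patient_id, tier, n_red, n_amber, escalated,
#' override, matched_ids` with matched ids `;`-joined.
#'
#' @param results Output of [triage_cohort()].
#' @param path CSV path.
#' @export
write_triage <- function(results, path) {
  out <- results |>
    mutate(matched_ids = purrr::map_chr(.data$matched_ids, paste,
                                        collapse = ";")) |>
    select(all_of(c("patient_id", "tier", "n_red", "n_amber", "escalated",
                    "override", "matched_ids")))
  readr::write_csv(out, path, na = "")
  invisible(path)
}
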