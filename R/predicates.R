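predicate_types <- c("medication_name_in", "medication_class_in",
                     "regular_med_count_ge", "missed_dose_of", "lab_compare",
                     "age_compare", "flag_present", "days_since_event_ge",
                     "manual")

#' Matching predicates for risk indicators
#'
#' A small grammar of machine-checkable conditions linking catalog indicators
#' to patient records. Available types:
#'
#' * `medication_name_in(names)`: a current medication whose lower-cased name
#'   is in `names`.
#' * `medication_class_in(classes)`: likewise on the medication class.
#' * `regular_med_count_ge(count)`: at least `count` regular (non-PRN)
#'   medications -- the polypharmacy indicators (inclusive `>=`).
#' * `missed_dose_of(any/names/classes)`: a medication with a non-zero
#'   missed-dose count, optionally restricted by name or class list.
#' * `lab_compare(lab, op, value/lo..hi, units)`: the most recent result for
#'   `lab` compared with a threshold (`lt`, `le`, `gt`, `ge`) or an inclusive
#'   `between` range; units are declared and must match the record's units
#'   exactly -- a mismatch is an error, never a silent conversion.
#' * `age_compare(op, value)`: age in years against a bound. The published age
#'   indicators use strict bounds (>70, >80, <12, <18).
#' * `flag_present(flag)`: a keyed clinical flag is set (seclusion, covert
#'   administration, toxic drug levels, ...).
#' * `days_since_event_ge(event, days)`: at least `days` days since the
#'   record's `last_review` or `admitted` date; with no recorded date the
#'   elapsed time is unknown and the predicate does not match (an empty
#'   record matches nothing -- assert such indicators manually if needed).
#' * `manual`: requires clinical judgement or an external knowledge base
#'   (significant interaction, nonadherence, ...); never matched
#'   automatically, only via an explicit per-patient flag.
#'
#' @param type A predicate type string.
#' @param ... Type-specific parameters, as above.
#' @return A `predicate` list.
#' @examples
#' predicate("medication_name_in", names = "clozapine")
#' predicate("lab_compare", lab = "eGFR", op = "between", lo = 30, hi = 44,
#'           units = "mL/min")
#' @export
predicate <- function(type, ...) {
  type <- match.arg(type, predicate_types)
  p <- list(...)
  chk <- function(ok, msg) if (!ok) abort(paste0("predicate ", type, ": ", msg))
  switch(type,
    medication_name_in = chk(is.character(p$names) && length(p$names) > 0,
                             "needs non-empty `names`"),
    medication_class_in = chk(is.character(p$classes) && length(p$classes) > 0,
                              "needs non-empty `classes`"),
    regular_med_count_ge = chk(is.numeric(p$count) && length(p$count) == 1 &&
                                 p$count >= 1, "needs `count` >= 1"),
    missed_dose_of = chk(isTRUE(p$any) || is.character(p$names) ||
                           is.character(p$classes),
                         "needs `any = TRUE`, `names` or `classes`"),
    lab_compare = {
      chk(is.character(p$lab) && nzchar(p$lab), "needs `lab`")
      chk(is.character(p$units) && nzchar(p$units), "must declare `units`")
      chk(is.character(p$op) && p$op %in% c("lt", "le", "gt", "ge", "between"),
          "needs `op` in lt/le/gt/ge/between")
      if (p$op == "between") {
        chk(is.numeric(p$lo) && is.numeric(p$hi) && p$lo <= p$hi,
            "`between` needs lo <= hi")
      } else chk(is.numeric(p$value), "needs `value`")
    },
    age_compare = chk(is.character(p$op) && p$op %in% c("lt", "le", "gt", "ge") &&
                        is.numeric(p$value), "needs `op` and `value`"),
    flag_present = chk(is.character(p$flag) && nzchar(p$flag), "needs `flag`"),
    days_since_event_ge = chk(is.character(p$event) &&
                                p$event %in% c("last_review", "admitted") &&
                                is.numeric(p$days) && p$days >= 0,
                              "needs `event` (last_review/admitted) and `days`"),
    manual = chk(length(p) == 0, "carries no parameters")
  )
  structure(c(list(type = type), p), class = "predicate")
}

#' @rdname predicate
#' @param x A compact-JSON predicate string (as stored in a catalog's
#'   `predicate` column), the string `"manual"`, or blank.
#' @return `parse_predicate()`: a `predicate`, or `NULL` for blank input.
#' @export
parse_predicate <- function(x) {
  if (inherits(x, "predicate")) return(x)
  if (is.null(x) || is.na(x) || x == "") return(NULL)
  if (identical(x, "manual")) return(predicate("manual"))
  spec <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  if (is.null(spec$type)) abort("predicate JSON lacks a `type` field")
  do.call(predicate, spec)
}

#' @export
print.predicate <- function(x, ...) {
  params <- x[setdiff(names(x), "type")]
  cat(sprintf("<predicate %s%s>\n", x$type,
              if (length(params))
                paste0(": ", paste(names(params),
                                   vapply(params, function(v)
                                     paste(v, collapse = ","), ""),
                                   sep = "=", collapse = " "))
              else ""))
  invisible(x)
}

cmp_op <- function(op, x, value = NULL, lo = NULL, hi = NULL) {
  switch(op,
         lt = x < value, le = x <= value,
         gt = x > value, ge = x >= value,
         between = x >= lo & x <= hi)
}

#' Evaluate a predicate against a patient record
#'
#' Returns the satisfying datum (a human-readable evidence string) when the
#' predicate holds, or `NULL`. `manual` predicates always return `NULL`: they
#' match only through explicit flags passed to [match_indicators()].
#'
#' @param patient A patient record (see [patient_record()]) or a one-row
#'   cohort tibble.
#' @param spec A [predicate()] (or its compact-JSON string form).
#' @param today Reference date for `days_since_event_ge`.
#' @return Evidence string, or `NULL` when not satisfied.
#' @examples
#' p <- patient_record("p1", age = 44,
#'                     medications = data.frame(name = "Clozapine"))
#' evaluate_predicate(p, predicate("medication_name_in", names = "clozapine"))
#' @export
evaluate_predicate <- function(patient, spec, today = Sys.Date()) {
  patient <- as_patient(patient)
  spec <- parse_predicate(spec)
  if (is.null(spec)) return(NULL)
  meds <- patient$medications
  switch(spec$type,
    medication_name_in = {
      hit <- tolower(meds$name) %in% tolower(spec$names)
      if (any(hit)) paste0("medication: ", meds$name[which(hit)[1]])
    },
    medication_class_in = {
      hit <- tolower(meds$class) %in% tolower(spec$classes)
      if (any(hit)) paste0("medication class ", meds$class[which(hit)[1]],
                           ": ", meds$name[which(hit)[1]])
    },
    regular_med_count_ge = {
      k <- sum(meds$regular, na.rm = TRUE)
      if (k >= spec$count) paste0(k, " regular medications")
    },
    missed_dose_of = {
      missed <- !is.na(meds$missed_doses) & meds$missed_doses >= 1
      if (!isTRUE(spec$any)) {
        scoped <- rep(FALSE, nrow(meds))
        if (!is.null(spec$names))
          scoped <- scoped | tolower(meds$name) %in% tolower(spec$names)
        if (!is.null(spec$classes))
          scoped <- scoped | tolower(meds$class) %in% tolower(spec$classes)
        missed <- missed & scoped
      }
      if (any(missed)) {
        i <- which(missed)[1]
        paste0(meds$missed_doses[i], " missed dose(s) of ", meds$name[i])
      }
    },
    lab_compare = {
      labs <- patient$labs
      hit <- tolower(labs$name) == tolower(spec$lab)
      if (!any(hit)) return(NULL)
      labs <- labs[hit, ]
      units <- unique(labs$units)
      if (!all(units == spec$units)) {
        abort(paste0("unit mismatch for lab ", spec$lab, ": record has '",
                     paste(setdiff(units, spec$units), collapse = "', '"),
                     "', predicate declares '", spec$units,
                     "' (no silent conversion)"),
              class = "delphitriage_unit_mismatch")
      }
      latest <- labs[order(labs$date, na.last = FALSE), ][nrow(labs), ]
      if (isTRUE(cmp_op(spec$op, latest$value, spec$value, spec$lo, spec$hi)))
        paste0(spec$lab, " ", latest$value, " ", latest$units)
    },
    age_compare = {
      if (isTRUE(cmp_op(spec$op, patient$age, spec$value)))
        paste0("age ", patient$age, " years")
    },
    flag_present = {
      if (spec$flag %in% patient$flags) paste0("flag: ", spec$flag)
    },
    days_since_event_ge = {
      when <- patient[[spec$event]]
      if (!is.null(when) && !is.na(when)) {
        d <- as.numeric(as.Date(today) - as.Date(when))
        if (d >= spec$days) paste0(d, " days since ", spec$event)
      }
    },
    manual = NULL
  )
}
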