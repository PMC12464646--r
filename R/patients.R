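med_columns <- c("name", "class", "route", "regular", "start", "missed_doses")
lab_columns <- c("name", "value", "units", "date")

#' Patient records and cohorts
#'
#' A cohort is a tibble with one row per patient: scalar columns
#' `patient_id`, `age` (years), `ward`, `admitted` (date), `last_review`
#' (date), and list-columns `medications` (a tibble per patient with columns
#' `name, class, route, regular, start, missed_doses`), `labs`
#' (`name, value, units, date`), `flags` (character set of keyed clinical
#' flags) and `manual_flags` (ids of manual-predicate indicators asserted by
#' clinical judgement). `patient_record()` builds a one-row cohort; missing
#' medication/lab columns are completed with `NA`s.
#'
#' @param patient_id Patient identifier.
#' @param age Age in years (non-negative).
#' @param ward Ward type label.
#' @param admitted,last_review Dates (ISO-8601 strings accepted).
#' @param medications,labs Data frames (possibly empty).
#' @param flags Character vector of set flags.
#' @param manual_flags Character vector of manually asserted indicator ids.
#' @return A one-row cohort tibble.
#' @examples
#' patient_record("p1", age = 34,
#'                medications = data.frame(name = "clozapine"))
#' @export
patient_record <- function(patient_id, age = NA_real_, ward = NA_character_,
                           admitted = NA, last_review = NA,
                           medications = NULL, labs = NULL,
                           flags = character(), manual_flags = character()) {
  if (!is.na(age) && age < 0) abort("patient_record: age must be non-negative")
  tibble(patient_id = as.character(patient_id),
         age = as.numeric(age),
         ward = as.character(ward),
         admitted = as.Date(admitted),
         last_review = as.Date(last_review),
         medications = list(complete_frame(medications, med_columns,
                                           list(regular = TRUE,
                                                missed_doses = 0))),
         labs = list(complete_frame(labs, lab_columns)),
         flags = list(as.character(flags)),
         manual_flags = list(as.character(manual_flags)))
}

complete_frame <- function(x, columns, defaults = list()) {
  x <- as_tibble(x %||% tibble())
  for (nm in columns) {
    if (!nm %in% names(x)) {
      x[[nm]] <- if (nm %in% names(defaults)) {
        rep(defaults[[nm]], length.out = nrow(x))
      } else rep(NA, nrow(x))
    }
  }
  if ("value" %in% columns && nrow(x)) x$value <- as.numeric(x$value)
  if ("regular" %in% columns && nrow(x)) x$regular <- as.logical(x$regular)
  if ("missed_doses" %in% columns && nrow(x)) {
    x$missed_doses <- as.numeric(x$missed_doses)
  }
  x[columns]
}

as_patient <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort("expected a single patient (one-row cohort)")
    x <- as.list(x)
    for (nm in c("medications", "labs", "flags", "manual_flags")) {
      if (nm %in% names(x)) x[[nm]] <- x[[nm]][[1]]
    }
  }
  x$medications <- complete_frame(x$medications, med_columns,
                                  list(regular = TRUE, missed_doses = 0))
  x$labs <- complete_frame(x$labs, lab_columns)
  x$flags <- as.character(x$flags %||% character())
  x$manual_flags <- as.character(x$manual_flags %||% character())
  x
}

#' Read and write patient cohorts
#'
#' JSON cohorts are arrays of objects
#' `{"patient_id", "age", "ward", "admitted", "medications": [...],`
#' `"labs": [...], "flags": {...}, "last_review"}` (`flags` an object of
#' booleans; a single object is accepted for a single patient). The CSV
#' dialect has one row per patient with pipe-delimited list fields:
#' medications as `name;class;route;regular;start;missed_doses` entries
#' joined by `|`, labs as `name;value;units;date` entries, flags and
#' manual_flags joined by `|`.
#'
#' @param path File path (`.json` or `.csv`).
#' @return A cohort tibble.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) abort(paste0("patient file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!is.null(raw$patient_id)) raw <- list(raw)
    rows <- purrr::imap(raw, function(p, i) {
      if (is.null(p$patient_id)) {
        abort(paste0("patient entry ", i, ": missing patient_id field"))
      }
      flags <- names(Filter(isTRUE, p$flags %||% list()))
      patient_record(p$patient_id, age = p$age %||% NA_real_,
                     ward = p$ward %||% NA_character_,
                     admitted = p$admitted %||% NA,
                     last_review = p$last_review %||% NA,
                     medications = bind_listed(p$medications),
                     labs = bind_listed(p$labs),
                     flags = flags,
                     manual_flags = unlist(p$manual_flags) %||% character())
    })
    bind_rows(rows)
  } else {
    x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
    need_cols(x, c("patient_id", "age"), "read_patients")
    rows <- purrr::pmap(x, function(...) {
      p <- list(...)
      patient_record(p$patient_id, age = parse_printed(p$age),
                     ward = p$ward %||% NA_character_,
                     admitted = blank_na(p$admitted),
                     last_review = blank_na(p$last_review),
                     medications = split_entries(p$medications, med_columns),
                     labs = split_entries(p$labs, lab_columns),
                     flags = split_bar(p$flags),
                     manual_flags = split_bar(p$manual_flags))
    })
    bind_rows(rows)
  }
}

bind_listed <- function(x) {
  if (is.null(x) || length(x) == 0) return(NULL)
  bind_rows(lapply(x, function(e) as_tibble(purrr::compact(e))))
}

blank_na <- function(x) if (is.null(x) || is.na(x) || x == "") NA else x

split_bar <- function(x) {
  if (is.null(x) || is.na(x) || x == "") character() else
    strsplit(x, "|", fixed = TRUE)[[1]]
}

split_entries <- function(x, columns) {
  entries <- split_bar(x)
  if (length(entries) == 0) return(NULL)
  parts <- lapply(strsplit(entries, ";", fixed = TRUE), function(f) {
    f <- c(f, rep("", length(columns)))[seq_along(columns)]
    rlang::set_names(as.list(ifelse(f == "", NA, f)), columns)
  })
  bind_rows(parts)
}

#' @rdname read_patients
#' @param cohort A cohort tibble.
#' @export
write_patients <- function(cohort, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- purrr::map(seq_len(nrow(cohort)), function(i) {
      p <- as_patient(cohort[i, ])
      list(patient_id = p$patient_id, age = p$age, ward = p$ward,
           admitted = date_chr(p$admitted),
           medications = meds_json(p$medications),
           labs = labs_json(p$labs),
           flags = rlang::set_names(as.list(rep(TRUE, length(p$flags))),
                                    p$flags),
           last_review = date_chr(p$last_review),
           manual_flags = p$manual_flags)
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null", na = "null")
  } else {
    flat <- cohort |>
      mutate(medications = purrr::map_chr(.data$medications, join_entries),
             labs = purrr::map_chr(.data$labs, join_entries),
             flags = purrr::map_chr(.data$flags, paste, collapse = "|"),
             manual_flags = purrr::map_chr(.data$manual_flags, paste,
                                           collapse = "|"))
    readr::write_csv(flat, path, na = "")
  }
  invisible(path)
}

date_chr <- function(d) if (is.na(d)) NULL else format(as.Date(d))
meds_json <- function(m) purrr::pmap(m, function(...) purrr::compact(list(...)))
labs_json <- meds_json

join_entries <- function(df) {
  if (nrow(df) == 0) return("")
  paste(apply(df, 1, function(r) {
    paste(ifelse(is.na(r), "", trimws(as.character(r))), collapse = ";")
  }), collapse = "|")
}
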