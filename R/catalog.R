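catalog_columns <- c("id", "text", "group", "source", "status", "tier",
                     "predicate", "notes")
catalog_groups <- c("high_risk_medicine", "patient_related", "drug_related",
                    "hospital_related")
catalog_sources <- c("systematic_review", "practice_survey",
                     "panel_round2_addition", "stakeholder", "unrecorded")

#' Risk-indicator catalogs
#'
#' An indicator catalog is a tibble with one row per risk indicator and
#' columns `id` (stable slug), `text` (indicator wording), `group` (one of the
#' four collation groups: high-risk medicine, patient-, drug- or
#' hospital-related), `source` (provenance; `;`-joined when an indicator was
#' reported by several sources), `status` (`active`, `modified`,
#' `merged_into:<id>` or `excluded`), `tier` (`red`, `amber`, `green` or
#' `unassigned`), `predicate` (a compact-JSON predicate spec, `"manual"` for
#' judgement-only indicators, or blank) and free-text `notes`. `version` and
#' `created` metadata travel as attributes.
#'
#' `indicator_catalog()` validates the invariants: unique ids, enum fields,
#' merge targets that exist and are active, and tiers assigned only to active
#' (or modified) indicators.
#'
#' @param indicators Data frame of indicator rows; missing columns are filled
#'   with defaults (`status = "active"`, `tier = "unassigned"`).
#' @param version,created Catalog metadata.
#' @return A validated `indicator_catalog` tibble.
#' @examples
#' indicator_catalog(tibble::tibble(id = "clozapine", text = "Clozapine",
#'                                  group = "high_risk_medicine"))
#' @export
indicator_catalog <- function(indicators = NULL, version = "unversioned",
                              created = Sys.Date()) {
  x <- as_tibble(indicators %||% tibble(id = character()))
  if (!"id" %in% names(x)) abort("catalog: `id` column is required")
  defaults <- list(text = NA_character_, group = NA_character_,
                   source = "unrecorded", status = "active",
                   tier = "unassigned", predicate = "", notes = "")
  for (nm in names(defaults)) {
    if (!nm %in% names(x)) x[[nm]] <- defaults[[nm]]
    x[[nm]][is.na(x[[nm]])] <- defaults[[nm]]
  }
  x <- x[catalog_columns]
  out <- structure(x, class = c("indicator_catalog", class(tibble())),
                   version = as.character(version),
                   created = as.Date(created))
  validate_catalog(out)
}

validate_catalog <- function(x) {
  if (anyDuplicated(x$id)) {
    abort(paste0("catalog: duplicate indicator id(s): ",
                 paste(unique(x$id[duplicated(x$id)]), collapse = ", ")),
          class = "delphitriage_duplicate_id")
  }
  check_enum <- function(col, allowed, split = NULL) {
    vals <- x[[col]]
    if (!is.null(split)) vals <- unlist(strsplit(vals, split, fixed = TRUE))
    bad <- setdiff(unique(vals[!is.na(vals) & vals != ""]), allowed)
    if (length(bad)) {
      abort(paste0("catalog: invalid ", col, " value(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  check_enum("group", catalog_groups)
  check_enum("source", catalog_sources, split = ";")
  check_enum("tier", tiers())
  status_ok <- x$status %in% c("active", "modified", "excluded") |
    grepl("^merged_into:.+$", x$status)
  if (!all(status_ok)) {
    abort(paste0("catalog: invalid status value(s): ",
                 paste(unique(x$status[!status_ok]), collapse = ", ")))
  }
  targets <- sub("^merged_into:", "", x$status[grepl("^merged_into:", x$status)])
  live <- x$id[x$status %in% c("active", "modified")]
  if (!all(targets %in% live)) {
    abort(paste0("catalog: merge target(s) not an active indicator: ",
                 paste(setdiff(targets, live), collapse = ", ")))
  }
  misassigned <- x$tier != "unassigned" & !x$status %in% c("active", "modified")
  if (any(misassigned)) {
    abort(paste0("catalog: tier assigned to non-active indicator(s): ",
                 paste(x$id[misassigned], collapse = ", ")))
  }
  x
}

#' @rdname indicator_catalog
#' @param catalog An `indicator_catalog`.
#' @export
active_indicators <- function(catalog) {
  catalog[catalog$status %in% c("active", "modified"), ]
}

#' @rdname indicator_catalog
#' @export
n_active <- function(catalog) nrow(active_indicators(catalog))

#' @rdname indicator_catalog
#' @export
catalog_counts <- function(catalog) {
  tibble(active = n_active(catalog),
         merged = sum(grepl("^merged_into:", catalog$status)),
         excluded = sum(catalog$status == "excluded"),
         total = nrow(catalog))
}

#' @export
print.indicator_catalog <- function(x, ...) {
  k <- catalog_counts(x)
  cat(sprintf("<indicator_catalog '%s' (%s): %d indicators (%d active, %d merged, %d excluded)>\n",
              attr(x, "version"), format(attr(x, "created")), k$total,
              k$active, k$merged, k$excluded))
  NextMethod()
}

#' Read and write indicator catalogs
#'
#' The JSON layout is `{"version", "created", "indicators": [...]}` with one
#' object per indicator in canonical column order; the CSV dialect has
#' identical column names (catalog metadata is not representable in CSV and
#' defaults on read). `write_catalog()` followed by `read_catalog()` followed
#' by `write_catalog()` is byte-identical.
#'
#' @param path File path; format inferred from the `.json`/`.csv` extension
#'   unless given.
#' @param format `"json"` or `"csv"`.
#' @return `read_catalog()`: an [indicator_catalog()].
#' @export
read_catalog <- function(path, format = c("auto", "json", "csv")) {
  format <- guess_format(path, match.arg(format))
  if (!file.exists(path)) abort(paste0("catalog file not found: ", path))
  if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    miss <- setdiff(c("version", "created", "indicators"), names(raw))
    if (length(miss)) {
      abort(paste0("catalog JSON: missing field(s) ",
                   paste(miss, collapse = ", ")))
    }
    ind <- as_tibble(raw$indicators)
    if (nrow(ind)) check_catalog_schema(ind, path)
    indicator_catalog(ind, version = raw$version, created = raw$created)
  } else {
    ind <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE)
    check_catalog_schema(ind, path)
    indicator_catalog(ind)
  }
}

check_catalog_schema <- function(ind, path) {
  miss <- setdiff(catalog_columns, names(ind))
  if (length(miss)) {
    abort(paste0("catalog schema violation in ", path, ": missing column(s) ",
                 paste(miss, collapse = ", ")))
  }
  blank <- which(is.na(ind$id) | ind$id == "")
  if (length(blank)) {
    abort(paste0("catalog schema violation in ", path, ": blank id at row(s) ",
                 paste(head(blank, 5), collapse = ", ")))
  }
  invisible(ind)
}

#' @rdname read_catalog
#' @param catalog An [indicator_catalog()].
#' @export
write_catalog <- function(catalog, path, format = c("auto", "json", "csv")) {
  format <- guess_format(path, match.arg(format))
  catalog <- validate_catalog(catalog)
  if (format == "json") {
    payload <- list(version = attr(catalog, "version"),
                    created = format(attr(catalog, "created")),
                    indicators = as.data.frame(catalog)[catalog_columns])
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    readr::write_csv(as_tibble(catalog)[catalog_columns], path, na = "")
  }
  invisible(path)
}

guess_format <- function(path, format) {
  if (format != "auto") return(format)
  if (grepl("\\.json$", path, ignore.case = TRUE)) return("json")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return("csv")
  abort(paste0("cannot infer catalog format from path: ", path))
}

#' Union of two indicator source lists
#'
#' Combines indicator lists from two sources into one catalog, matching
#' entries by id. Indicators present in both keep both source annotations
#' (`;`-joined) and count once, so the active count is
#' `|a| + |b| - |shared|`. This is the collation step that turned 48
#' literature-derived and 415 practice-survey indicators with 3 in common into
#' a 460-indicator working list.
#'
#' @param a,b Indicator data frames (or catalogs) with at least an `id`
#'   column.
#' @param version,created Metadata for the resulting catalog.
#' @return An [indicator_catalog()].
#' @export
union_sources <- function(a, b, version = "union", created = Sys.Date()) {
  a <- indicator_catalog(a); b <- indicator_catalog(b)
  shared <- intersect(a$id, b$id)
  merged <- bind_rows(a, b[!b$id %in% shared, ])
  if (length(shared)) {
    b_src <- rlang::set_names(b$source, b$id)
    i <- merged$id %in% shared
    merged$source[i] <- paste_sources(merged$source[i], b_src[merged$id[i]])
  }
  indicator_catalog(merged, version = version, created = created)
}

paste_sources <- function(a, b) {
  purrr::map2_chr(strsplit(a, ";"), strsplit(b, ";"), function(x, y) {
    paste(unique(c(x, y)), collapse = ";")
  })
}

#' Apply an editorial merge plan to a catalog
#'
#' Merging is absorption: each absorbed indicator's status becomes
#' `merged_into:<representative>` (its tier reset to unassigned, an audit note
#' appended) and the active count drops by one per absorbed id; each excluded
#' id likewise drops the count by one. This is the only reading consistent
#' with the published refinement arithmetic, where 82 agreed indicators minus
#' 10 merged and 1 stakeholder-excluded left 71 in the tool.
#'
#' @param catalog An [indicator_catalog()].
#' @param plan Data frame with columns `id` (absorbed) and `into`
#'   (representative), or `NULL` for no merges.
#' @param exclusions Character vector of ids to exclude.
#' @return The updated catalog.
#' @examples
#' cat71 <- apply_merge_plan(study_catalog(round = 2),
#'                           plan = published_merge_plan())
#' @export
apply_merge_plan <- function(catalog, plan = NULL, exclusions = character()) {
  catalog <- validate_catalog(catalog)
  if (!is.null(plan)) {
    plan <- as_tibble(plan)
    if ("action" %in% names(plan)) {
      exclusions <- c(exclusions, plan$id[plan$action == "exclude"])
      plan <- plan[plan$action == "merge", ]
    }
    need_cols(plan, c("id", "into"), "apply_merge_plan")
  } else {
    plan <- tibble(id = character(), into = character())
  }
  live <- function() catalog$id[catalog$status %in% c("active", "modified")]
  refs <- c(plan$id, plan$into, exclusions)
  unknown <- setdiff(refs, catalog$id)
  if (length(unknown)) {
    abort(paste0("merge plan references unknown id(s): ",
                 paste(unknown, collapse = ", ")))
  }
  stale <- setdiff(refs, live())
  if (length(stale)) {
    abort(paste0("merge plan references non-active id(s): ",
                 paste(stale, collapse = ", ")))
  }
  if (any(plan$into %in% plan$id)) {
    abort("merge plan: a representative cannot itself be absorbed")
  }
  for (k in seq_len(nrow(plan))) {
    i <- match(plan$id[k], catalog$id)
    catalog$status[i] <- paste0("merged_into:", plan$into[k])
    catalog$tier[i] <- "unassigned"
    catalog$notes[i] <- append_note(catalog$notes[i],
                                    paste0("merged into ", plan$into[k]))
    j <- match(plan$into[k], catalog$id)
    catalog$notes[j] <- append_note(catalog$notes[j],
                                    paste0("absorbed ", plan$id[k]))
  }
  for (id in exclusions) {
    i <- match(id, catalog$id)
    catalog$status[i] <- "excluded"
    catalog$tier[i] <- "unassigned"
    catalog$notes[i] <- append_note(catalog$notes[i], "excluded")
  }
  validate_catalog(catalog)
}

append_note <- function(note, extra) {
  ifelse(is.na(note) | note == "", extra, paste(note, extra, sep = "; "))
}

#' The packaged study catalogs
#'
#' `study_catalog()` rebuilds the indicator catalog from the packaged
#' published aggregates: all 123 indicators rated across the two rounds, with
#' inclusion decided from the requested round's importance bands and risk
#' tiers assigned from that round's risk bands (non-included indicators stay
#' `unassigned`). The 14 indicators introduced in round 2 carry the
#' `panel_round2_addition` source; per-indicator provenance for the remainder
#' was not published, so they are marked `unrecorded`.
#'
#' `tool_catalog()` goes one step further and reproduces the final
#' prioritisation tool: round-2 inclusion (82 indicators), tier assignment
#' with the medium-risk majority fallback, the packaged 10-merge/1-exclusion
#' editorial plan (71 active indicators), and the packaged matching
#' predicates (indicators without a machine predicate are `manual`).
#'
#' @param round Round whose decisions to apply (default 2).
#' @param rule A [consensus_rule()].
#' @return An [indicator_catalog()].
#' @examples
#' n_active(tool_catalog())
#' @export
study_catalog <- function(round = 2, rule = consensus_rule()) {
  texts <- published_indicator_texts()
  imp <- published_indicator_bands(round = round, dimension = "importance")
  risk <- published_indicator_bands(round = round, dimension = "risk")
  r1 <- published_indicator_bands(round = 1, dimension = "importance")
  added_r2 <- r1$id[is.na(r1$pct_6_7)]
  inc <- rlang::set_names(include_indicator(imp, rule), imp$id)
  tier <- rlang::set_names(assign_tier(risk, rule), risk$id)
  ind <- texts |>
    mutate(source = if_else(.data$id %in% added_r2,
                            "panel_round2_addition", "unrecorded"),
           status = "active",
           tier = if_else(!is.na(inc[.data$id]) & inc[.data$id],
                          tier[.data$id], "unassigned"),
           predicate = "",
           notes = paste0("published row ", .data$row,
                          "; group assignment inferred from wording")) |>
    select(-"row")
  indicator_catalog(ind, version = paste0("study-round", round),
                    created = as.Date("2024-06-01"))
}

#' @rdname study_catalog
#' @param keep_all Keep non-included/merged/excluded rows (default `TRUE`;
#'   `FALSE` returns only the active tool indicators).
#' @export
tool_catalog <- function(rule = consensus_rule(), keep_all = TRUE) {
  full <- study_catalog(round = 2, rule = rule)
  imp <- published_indicator_bands(round = 2, dimension = "importance")
  included <- imp$id[include_indicator(imp, rule)]
  cat82 <- indicator_catalog(full[full$id %in% included, ],
                             version = "tool", created = attr(full, "created"))
  cat71 <- apply_merge_plan(cat82, plan = published_merge_plan())
  preds <- read_extdata_csv("predicates.csv", readr::cols(.default = "c"))
  i <- match(cat71$id, preds$id)
  cat71$predicate <- ifelse(is.na(i), "", preds$params[i])
  has_pred <- !is.na(i)
  active <- cat71$status %in% c("active", "modified")
  cat71$predicate[active & !has_pred] <- "manual"
  cat71$predicate[active & has_pred] <- purrr::map2_chr(
    preds$type[i[active & has_pred]], preds$params[i[active & has_pred]],
    function(type, params) {
      spec <- jsonlite::fromJSON(params, simplifyVector = TRUE)
      jsonlite::toJSON(c(list(type = type), spec), auto_unbox = TRUE,
                       digits = NA)
    })
  out <- validate_catalog(cat71)
  if (keep_all) out else indicator_catalog(active_indicators(out),
                                           version = "tool-active",
                                           created = attr(out, "created"))
}
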