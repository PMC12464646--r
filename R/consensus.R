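#' Read and write long-format panel ratings
#'
#' Ratings travel as one row per rating with columns
#' `study, round, panellist, item, dimension, response`, where `response` is
#' `"1"`..`"7"`, `"OE"` (outside my expertise) or empty (missing). The reader
#' validates the schema and the one-rating-per-cell invariant.
#'
#' @param path CSV file path.
#' @return A ratings tibble.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) abort(paste0("ratings file not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       na = character(), progress = FALSE)
  validate_ratings(x)
}

#' @rdname read_ratings
#' @param ratings A ratings tibble.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings)
  readr::write_csv(ratings, path, na = "")
  invisible(path)
}

validate_ratings <- function(x) {
  need <- c("round", "panellist", "item", "dimension", "response")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("ratings: missing column(s) ", paste(miss, collapse = ", ")))
  }
  if (!"study" %in% names(x)) x$study <- NA_character_
  x <- as_tibble(x)
  x$round <- as.integer(x$round)
  x$response <- as.character(x$response)
  ok <- x$response %in% c(as.character(1:7), "OE", "", NA_character_)
  if (!all(ok)) {
    abort(paste0("ratings: invalid response value(s) at row(s) ",
                 paste(head(which(!ok), 5), collapse = ", "),
                 " (expected 1-7, \"OE\" or blank)"))
  }
  dup <- duplicated(x[c("round", "panellist", "item", "dimension")])
  if (any(dup)) {
    abort(paste0("ratings: duplicate (panellist, item, dimension) cell at row(s) ",
                 paste(head(which(dup), 5), collapse = ", ")))
  }
  x[c("study", "round", "panellist", "item", "dimension", "response")]
}

response_score <- function(response) {
  suppressWarnings(as.integer(ifelse(response %in% as.character(1:7),
                                     response, NA)))
}

#' Likert band summaries of a rating matrix
#'
#' Computes, for every `item x dimension x round` cell of a long-format
#' ratings table, the number of valid 1-7 responses, their median, per-score
#' counts `n1`..`n7` and the band percentages `pct_1_2`, `pct_3_5`, `pct_5_7`
#' and `pct_6_7`. "Outside my expertise" and missing responses are excluded
#' from the denominator, so each cell's implied n can differ. The median for
#' an even number of responses is the mean of the two central values, which is
#' why half-integer medians (e.g. 6.5) can occur.
#'
#' @param ratings A ratings tibble (see [read_ratings()]).
#' @param item,dimension Optional filters restricting the summary.
#' @return A tibble with one row per summarised cell.
#' @examples
#' r <- tibble::tibble(round = 1L, panellist = c("a", "b", "c"),
#'                     item = "x", dimension = "importance",
#'                     response = c("6", "7", "OE"))
#' summarize_ratings(r)
#' @export
summarize_ratings <- function(ratings, item = NULL, dimension = NULL) {
  x <- validate_ratings(ratings)
  if (!is.null(item)) {
    if (!all(item %in% x$item)) {
      abort(paste0("item not present in ratings: ",
                   paste(setdiff(item, x$item), collapse = ", ")))
    }
    x <- x[x$item %in% item, ]
  }
  if (!is.null(dimension)) x <- x[x$dimension %in% dimension, ]
  if (nrow(x) == 0) abort("summarize_ratings: no ratings after filtering")
  x$score <- response_score(x$response)
  out <- x |>
    group_by(.data$item, .data$dimension, .data$round) |>
    summarise(n_valid = sum(!is.na(.data$score)),
              median = if (sum(!is.na(.data$score)) > 0)
                stats::median(.data$score, na.rm = TRUE) else NA_real_,
              !!!score_count_exprs(),
              .groups = "drop")
  if (any(out$n_valid == 0)) {
    bad <- out[out$n_valid == 0, ]
    abort(paste0("undefined summary: no valid 1-7 responses for item(s) ",
                 paste(unique(bad$item), collapse = ", ")),
          class = "delphitriage_undefined_summary")
  }
  out |>
    mutate(pct_1_2 = 100 * (.data$n1 + .data$n2) / .data$n_valid,
           pct_3_5 = 100 * (.data$n3 + .data$n4 + .data$n5) / .data$n_valid,
           pct_5_7 = 100 * (.data$n5 + .data$n6 + .data$n7) / .data$n_valid,
           pct_6_7 = 100 * (.data$n6 + .data$n7) / .data$n_valid)
}

score_count_exprs <- function() {
  exprs <- lapply(1:7, function(k) {
    rlang::expr(sum(.data$score == !!k, na.rm = TRUE))
  })
  rlang::set_names(exprs, paste0("n", 1:7))
}

#' Consensus decisions on band summaries
#'
#' `include_indicator()` applies the inclusion rule to importance-band
#' summaries: included when `pct_6_7 >= include_t67` or
#' `pct_5_7 >= include_t57`. `statement_agreed()` applies the analogous
#' agreement rule with the `agree_*` thresholds. `assign_tier()` applies the
#' risk-tier rule: `"red"` when `pct_6_7` reaches the band threshold, else
#' `"amber"` on `pct_3_5`, else `"green"` on `pct_1_2`, else the medium-risk
#' majority fallback (combined 3-5 and 6-7 mass > 50%), else `"unassigned"`.
#' All comparisons are inclusive. The red and amber conditions are mutually
#' exclusive whenever the threshold exceeds 50, since two bands cannot both
#' hold 75% of the mass.
#'
#' Each function accepts a band-summary data frame (from
#' [summarize_ratings()] or the packaged published aggregates) and returns a
#' vector aligned with its rows; rows whose percentages are missing (items not
#' rated in a round) return `NA`.
#'
#' @param bands A data frame with the relevant `pct_*` columns. `assign_tier()`
#'   derives `pct_1_2` as `100 - pct_3_5 - pct_6_7` when absent (the published
#'   aggregates print only the 3-5 and 6-7 risk bands).
#' @param rule A [consensus_rule()].
#' @return `include_indicator()`/`statement_agreed()`: logical vector;
#'   `assign_tier()`: character vector of tiers.
#' @examples
#' include_indicator(data.frame(pct_5_7 = 100, pct_6_7 = 100))
#' assign_tier(data.frame(pct_3_5 = 89.3, pct_6_7 = 3.6))
#' @export
include_indicator <- function(bands, rule = consensus_rule()) {
  need_cols(bands, c("pct_5_7", "pct_6_7"), "include_indicator")
  bands$pct_6_7 >= rule$include_t67 | bands$pct_5_7 >= rule$include_t57
}

#' @rdname include_indicator
#' @export
statement_agreed <- function(bands, rule = consensus_rule()) {
  need_cols(bands, c("pct_5_7", "pct_6_7"), "statement_agreed")
  bands$pct_6_7 >= rule$agree_t67 | bands$pct_5_7 >= rule$agree_t57
}

#' @rdname include_indicator
#' @export
assign_tier <- function(bands, rule = consensus_rule()) {
  need_cols(bands, c("pct_3_5", "pct_6_7"), "assign_tier")
  p12 <- if ("pct_1_2" %in% names(bands)) bands$pct_1_2 else
    100 - bands$pct_3_5 - bands$pct_6_7
  t <- rule$tier_band_t
  tier <- rep(NA_character_, nrow(bands))
  known <- !is.na(bands$pct_6_7) & !is.na(bands$pct_3_5)
  tier[known] <- "unassigned"
  fallback <- rule$majority_fallback &
    (bands$pct_3_5 + bands$pct_6_7) > 50
  tier[known & fallback] <- "amber"
  tier[known & p12 >= t] <- "green"
  tier[known & bands$pct_3_5 >= t] <- "amber"
  tier[known & bands$pct_6_7 >= t] <- "red"
  tier
}

need_cols <- function(x, cols, fn) {
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    abort(paste0(fn, ": band summary lacks column(s) ",
                 paste(miss, collapse = ", ")))
  }
  invisible(x)
}

#' Run one Delphi round decision over a set of items
#'
#' Applies the inclusion or agreement rule to every item of a band-summary
#' table and reports the counts. Items with missing percentages for the round
#' (e.g. indicators only introduced in the second round, when summarising
#' round 1) are excluded from the denominator.
#'
#' @param bands A band-summary data frame with an `item` (or `id`) column and
#'   `pct_5_7`/`pct_6_7` columns; typically one round and one dimension of
#'   [published_indicator_bands()] or [published_statement_bands()], or output
#'   of [summarize_ratings()].
#' @param rule A [consensus_rule()].
#' @param decision `"inclusion"` (importance dimension) or `"agreement"`.
#' @return A `consensus_report`: access per-item decisions with [tidy()] and
#'   the counts with [glance()].
#' @examples
#' b <- published_indicator_bands(round = 1, dimension = "importance")
#' run_round(b, decision = "inclusion")
#' @export
run_round <- function(bands, rule = consensus_rule(),
                      decision = c("inclusion", "agreement")) {
  decision <- match.arg(decision)
  bands <- as_tibble(bands)
  if (!"item" %in% names(bands) && "id" %in% names(bands)) {
    bands$item <- bands$id
  }
  need_cols(bands, c("item", "pct_5_7", "pct_6_7"), "run_round")
  if ("dimension" %in% names(bands)) {
    dims <- unique(bands$dimension)
    if (length(dims) > 1) {
      abort(paste0("run_round: mixed dimensions in input (",
                   paste(dims, collapse = ", "), ")"))
    }
    expected <- if (decision == "inclusion") "importance" else "agreement"
    if (!identical(dims, expected)) {
      abort(paste0("run_round: decision '", decision, "' requires the ",
                   expected, " dimension, got '", dims, "'"))
    }
  }
  rated <- !is.na(bands$pct_5_7) & !is.na(bands$pct_6_7)
  rated_bands <- bands[rated, ]
  dec <- if (decision == "inclusion") {
    include_indicator(rated_bands, rule)
  } else {
    statement_agreed(rated_bands, rule)
  }
  decisions <- tibble(item = rated_bands$item,
                      pct_5_7 = rated_bands$pct_5_7,
                      pct_6_7 = rated_bands$pct_6_7,
                      included = dec)
  # flag decisions within half a printed decimal of a threshold: printed
  # rounding could flip these, so they deserve explicit attention
  t67 <- if (decision == "inclusion") rule$include_t67 else rule$agree_t67
  t57 <- if (decision == "inclusion") rule$include_t57 else rule$agree_t57
  decisions$near_threshold <- abs(decisions$pct_6_7 - t67) < 0.05 |
    abs(decisions$pct_5_7 - t57) < 0.05
  structure(list(decisions = decisions,
                 decision = decision,
                 round = if ("round" %in% names(bands))
                   unique(bands$round) else NA_integer_,
                 n_items = nrow(decisions),
                 n_excluded_unrated = sum(!rated),
                 n_included = sum(decisions$included),
                 proportion_included = sum(decisions$included) /
                   nrow(decisions),
                 rule = rule),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report: %s>\n", x$decision))
  cat(sprintf("  %d/%d items %s (%.1f%%)%s\n",
              x$n_included, x$n_items,
              if (x$decision == "inclusion") "included" else "agreed",
              100 * x$proportion_included,
              if (x$n_excluded_unrated > 0)
                sprintf("; %d unrated items excluded", x$n_excluded_unrated)
              else ""))
  near <- sum(x$decisions$near_threshold)
  if (near > 0) {
    cat(sprintf("  note: %d decision(s) within 0.05%% of a threshold\n", near))
  }
  invisible(x)
}

#' @export
tidy.consensus_report <- function(x, ...) x$decisions

#' @export
glance.consensus_report <- function(x, ...) {
  tibble(decision = x$decision,
         n_items = x$n_items,
         n_included = x$n_included,
         proportion_included = x$proportion_included,
         n_excluded_unrated = x$n_excluded_unrated,
         n_near_threshold = sum(x$decisions$near_threshold))
}

#' Ranking tallies and the first-choice winner
#'
#' `ranking_tally()` validates a table of options by rank-position counts
#' (columns `option, rank1, rank2, ...`). `winner_by_first_choice()` returns
#' the option with the plurality of first-preference votes; ties cascade to
#' second-preference counts, then third, and finally alphabetical option order,
#' so the result is deterministic.
#'
#' @param counts A data frame with an `option` column and numeric `rank<k>`
#'   columns.
#' @return `ranking_tally()`: a validated `ranking_tally` tibble;
#'   `winner_by_first_choice()`: a one-row tibble with `option` and
#'   `first_choices`.
#' @examples
#' t <- ranking_tally(published_classification_ranking())
#' winner_by_first_choice(t)
#' @export
ranking_tally <- function(counts) {
  counts <- as_tibble(counts)
  if (!"option" %in% names(counts)) abort("ranking_tally: need `option` column")
  rank_cols <- grep("^rank[0-9]+$", names(counts), value = TRUE)
  if (length(rank_cols) == 0) abort("ranking_tally: need rank1, rank2, ... columns")
  if (nrow(counts) == 0) abort("ranking_tally: empty tally")
  if (anyDuplicated(counts$option)) abort("ranking_tally: duplicate option")
  for (rc in rank_cols) {
    v <- suppressWarnings(as.numeric(counts[[rc]]))
    if (any(!is.na(v) & v < 0)) abort("ranking_tally: negative count")
    counts[[rc]] <- v
  }
  structure(counts[c("option", rank_cols)],
            class = c("ranking_tally", class(counts)),
            n_rankers = max(colSums(counts[rank_cols], na.rm = TRUE)))
}

#' @rdname ranking_tally
#' @param tally A `ranking_tally` (or coercible data frame).
#' @export
winner_by_first_choice <- function(tally) {
  tally <- ranking_tally(tally)
  rank_cols <- grep("^rank[0-9]+$", names(tally), value = TRUE)
  keys <- lapply(rank_cols, function(rc) -replace_na0(tally[[rc]]))
  ord <- do.call(order, c(keys, list(tally$option)))
  winner <- tally[ord[1], ]
  tibble(option = winner$option, first_choices = winner$rank1)
}

replace_na0 <- function(x) ifelse(is.na(x), 0, x)
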