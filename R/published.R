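#' Published Delphi aggregates packaged with delphitriage
#'
#' The development study published its complete round-by-round aggregate
#' results: per-indicator medians and Likert band percentages for both rounds
#' of the indicator Delphi (123 indicators, 109 of them rated in round 1),
#' per-statement aggregates for both rounds of the tool-use Delphi (29
#' statements in round 1, 30 in round 2), and the two ranking exercises.
#' These tables ship as plain-text fixtures, transcribed verbatim at the
#' printed one-decimal precision, so every headline consensus count can be
#' recomputed exactly.
#'
#' `published_indicator_bands()` returns the indicator aggregates, one row per
#' `indicator x round x dimension`. The `risk` dimension carries `pct_3_5` and
#' `pct_6_7` (the published risk bands); the `importance` dimension carries
#' `pct_5_7` and `pct_6_7`. Cells blank in print (the 14 indicators added for
#' round 2 have no round-1 data) are `NA`. `published_indicator_texts()` maps
#' each indicator id to its wording, printed row number, and collation group.
#'
#' `published_statement_bands()` and `published_statement_texts()` are the
#' analogous tables for the tool-use statements (dimension `agreement`, with
#' `pct_1_4`, `pct_5_7`, `pct_6_7`, the panel n, median and mean).
#'
#' `published_classification_ranking()` is the classification-system ranking
#' (3 options, 29 rankers); `published_review_frequency_ranking()` the
#' per-tier review-frequency ranking (30 rankers).
#'
#' @param round Optional filter: 1 or 2.
#' @param dimension Optional filter: `"risk"` or `"importance"`.
#' @return A tibble (rankings: a [ranking_tally()]).
#' @examples
#' published_indicator_bands(round = 2, dimension = "importance")
#' winner_by_first_choice(published_review_frequency_ranking("high"))
#' @export
published_indicator_bands <- function(round = NULL, dimension = NULL) {
  x <- read_extdata_csv("indicator_bands.csv",
                        readr::cols(.default = "c")) |>
    mutate(row = as.integer(.data$row),
           round = as.integer(.data$round),
           across(all_of(c("median", "pct_3_5", "pct_6_7", "pct_5_7")),
                  parse_printed))
  if (!is.null(round)) x <- x[x$round %in% round, ]
  if (!is.null(dimension)) {
    dimension <- match.arg(dimension, c("risk", "importance"))
    x <- x[x$dimension == dimension, ]
  }
  x
}

parse_printed <- function(x) suppressWarnings(as.numeric(x))

#' @rdname published_indicator_bands
#' @export
published_indicator_texts <- function() {
  read_extdata_csv("indicator_texts.csv",
                   readr::cols(row = "i", .default = "c"))
}

#' @rdname published_indicator_bands
#' @export
published_statement_bands <- function(round = NULL) {
  x <- read_extdata_csv("statement_bands.csv",
                        readr::cols(.default = "c")) |>
    mutate(row = as.integer(.data$row),
           round = as.integer(.data$round),
           n = suppressWarnings(as.integer(.data$n)),
           across(all_of(c("median", "mean", "pct_1_4", "pct_5_7", "pct_6_7")),
                  parse_printed),
           item = paste0("s", .data$row),
           dimension = "agreement")
  if (!is.null(round)) x <- x[x$round %in% round, ]
  x
}

#' @rdname published_indicator_bands
#' @export
published_statement_texts <- function() {
  read_extdata_csv("statement_texts.csv",
                   readr::cols(row = "i", statement = "c"))
}

#' @rdname published_indicator_bands
#' @export
published_classification_ranking <- function() {
  ranking_tally(read_extdata_csv("classification_ranking.csv",
                                 readr::cols(option = "c", .default = "d")))
}

#' @rdname published_indicator_bands
#' @param category `"high"`, `"medium"` or `"low"` risk tier block.
#' @export
published_review_frequency_ranking <- function(category = c("high", "medium",
                                                            "low")) {
  category <- match.arg(category)
  x <- read_extdata_csv("frequency_ranking.csv",
                        readr::cols(category = "c", option = "c",
                                    .default = "c"))
  x <- x[x$category == category, setdiff(names(x), "category")]
  for (rc in grep("^rank", names(x), value = TRUE)) {
    x[[rc]] <- suppressWarnings(as.numeric(x[[rc]]))
  }
  # drop all-blank rank columns (the high/low blocks have only three ranks)
  keep <- vapply(x, function(col) !all(is.na(col)), logical(1))
  ranking_tally(x[keep])
}

#' @rdname published_indicator_bands
#' @export
published_merge_plan <- function() {
  read_extdata_csv("merge_plan.csv", readr::cols(.default = "c"))
}
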