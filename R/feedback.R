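new_item_annotation <- "*Newly added indicator"

#' Build a controlled-feedback document for one panellist
#'
#' Between Delphi rounds each panellist receives controlled feedback: for
#' every item, their own previous rating, the group median, and the breakdown
#' of how many panel members selected each score, plus authored narrative
#' summaries of free-text comments. Items added for the new round are
#' annotated `*Newly added indicator` and carry "not rated"; modified items
#' are annotated `Modified from: <original text>`. Items the panellist
#' skipped (or rated outside their expertise) still show the group statistics
#' with their own cell marked accordingly, and no other panellist is
#' identifiable from the document.
#'
#' Narrative summaries are authored text supplied by the analyst (the
#' thematic analysis of comments is a human step, never auto-generated).
#'
#' @param ratings Round ratings (see [read_ratings()]) to summarise.
#' @param panellist Recipient panellist id; must appear in `ratings`.
#' @param new_items Character vector of item ids introduced for the next
#'   round (not present in `ratings`).
#' @param modified Named character vector: item id -> original wording, for
#'   modified items.
#' @param narratives Named character vector: item id -> narrative summary.
#' @param item_texts Named character vector: item id -> display wording.
#' @param item_order Character vector fixing block order (catalog order);
#'   defaults to rated items in first-appearance order, then `new_items`.
#' @param dimension Optional dimension filter when `ratings` spans several.
#' @return A `feedback_document`.
#' @examples
#' r <- tibble::tibble(round = 1L, panellist = rep(c("a", "b"), 2),
#'                     item = rep(c("x", "y"), each = 2),
#'                     dimension = "importance",
#'                     response = c("6", "7", "5", "OE"))
#' build_feedback(r, "a")
#' @export
build_feedback <- function(ratings, panellist, new_items = character(),
                           modified = character(), narratives = character(),
                           item_texts = character(), item_order = NULL,
                           dimension = NULL) {
  ratings <- validate_ratings(ratings)
  if (!is.null(dimension)) ratings <- ratings[ratings$dimension %in% dimension, ]
  if (!panellist %in% ratings$panellist) {
    abort(paste0("panellist '", panellist, "' is absent from the ratings"))
  }
  summaries <- summarize_ratings(ratings)
  rated_items <- unique(ratings$item)
  order_default <- c(rated_items, setdiff(new_items, rated_items))
  item_order <- item_order %||% order_default
  items <- intersect(item_order, order_default)
  own <- ratings[ratings$panellist == panellist, ]
  own_of <- rlang::set_names(own$response, own$item)
  lookup <- function(map, key, default) {
    if (key %in% names(map)) unname(map[[key]]) else default
  }
  blocks <- purrr::map(items, function(it) {
    is_new <- it %in% new_items && !it %in% rated_items
    s <- summaries[summaries$item == it, ]
    resp <- lookup(own_of, it, "")
    your <- if (is_new || resp == "") "not rated" else
      if (resp == "OE") "outside my expertise" else resp
    annotation <- if (is_new) new_item_annotation else
      if (it %in% names(modified)) paste0("Modified from: ", modified[[it]])
      else ""
    counts <- if (is_new) rep(0L, 7) else unlist(s[paste0("n", 1:7)])
    tibble(item = it,
           text = lookup(item_texts, it, it),
           your_rating = your,
           median = if (is_new) NA_real_ else s$median,
           !!!rlang::set_names(as.list(as.integer(counts)), paste0("n", 1:7)),
           narrative = lookup(narratives, it, ""),
           annotation = annotation)
  })
  structure(list(panellist = panellist,
                 round = max(ratings$round) + 1L,
                 blocks = bind_rows(blocks),
                 preamble = paste0(
                   "Controlled feedback for panellist ", panellist,
                   ". For each item you will find your previous rating, the ",
                   "group median, and how many panel members selected each ",
                   "score.")),
            class = "feedback_document")
}

#' @export
print.feedback_document <- function(x, ...) {
  cat(sprintf("<feedback_document for %s, round %d: %d block(s), %d new>\n",
              x$panellist, x$round, nrow(x$blocks),
              sum(x$blocks$annotation == new_item_annotation)))
  invisible(x)
}

#' Render a controlled-feedback document
#'
#' Deterministic, diffable text output. Markdown shows each item with its
#' annotation, the recipient's previous rating, the group median and a 1-7
#' count table; CSV emits columns
#' `item,your_rating,median,n1..n7,annotation`. Rendering the same document
#' twice is byte-identical.
#'
#' @param doc A `feedback_document`.
#' @param format `"markdown"` or `"csv"`.
#' @return A single string.
#' @export
render_feedback <- function(doc, format = c("markdown", "csv")) {
  if (!inherits(doc, "feedback_document")) abort("expected a feedback_document")
  format <- match.arg(format)
  b <- doc$blocks
  if (format == "csv") {
    cols <- c("item", "your_rating", "median", paste0("n", 1:7), "annotation")
    return(readr::format_csv(b[cols], na = ""))
  }
  lines <- c(paste0("# Round ", doc$round, " feedback - panellist ",
                    doc$panellist), "", doc$preamble, "")
  for (i in seq_len(nrow(b))) {
    r <- b[i, ]
    lines <- c(lines, paste0("## ", r$text))
    if (r$annotation != "") lines <- c(lines, paste0("_", r$annotation, "_"))
    lines <- c(lines,
               paste0("Your previous rating: ", r$your_rating),
               if (!is.na(r$median))
                 c(paste0("Group median: ", r$median),
                   "| score | 1 | 2 | 3 | 4 | 5 | 6 | 7 |",
                   "|-------|---|---|---|---|---|---|---|",
                   paste0("| n     | ",
                          paste(unlist(r[paste0("n", 1:7)]), collapse = " | "),
                          " |")),
               if (r$narrative != "")
                 paste0("Panel comments (summary): ", r$narrative),
               "")
  }
  paste(lines, collapse = "\n")
}

#' @rdname render_feedback
#' @param dir Output directory.
#' @return `write_feedback()`: the path written, invisibly
#'   (`feedback_<panellist>_<round>.md` or `.csv`).
#' @export
write_feedback <- function(doc, dir = ".", format = c("markdown", "csv")) {
  format <- match.arg(format)
  ext <- if (format == "markdown") "md" else "csv"
  path <- file.path(dir, paste0("feedback_", doc$panellist, "_", doc$round,
                                ".", ext))
  writeLines(render_feedback(doc, format), path, sep = "")
  invisible(path)
}
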