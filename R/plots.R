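#' Plot a consensus round
#'
#' Items ordered by their top-two-band percentage, with the rule's two
#' thresholds drawn as reference lines; included items are filled. Useful for
#' seeing how far non-consensus items sat from the rule.
#'
#' @param object A `consensus_report` from [run_round()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_report <- function(object, ...) {
  d <- object$decisions |>
    mutate(item = factor(.data$item,
                         levels = .data$item[order(.data$pct_6_7,
                                                   .data$pct_5_7)]))
  t67 <- if (object$decision == "inclusion") object$rule$include_t67 else
    object$rule$agree_t67
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct_6_7, y = .data$item,
                                  fill = .data$included)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_vline(xintercept = t67, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey70"),
                               name = if (object$decision == "inclusion")
                                 "included" else "agreed") +
    ggplot2::labs(x = "% of panel rating 6-7", y = NULL,
                  title = sprintf("%s decisions: %d/%d met the rule",
                                  object$decision, object$n_included,
                                  object$n_items)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Plot cohort triage results
#'
#' Bar chart of patients per traffic-light tier, escalated patients shown
#' separately within red.
#'
#' @param results A triage tibble from [triage_cohort()].
#' @return A ggplot object.
#' @export
plot_tier_distribution <- function(results) {
  d <- results |>
    mutate(category = if_else(.data$escalated, "red (escalated)", .data$tier),
           category = factor(.data$category,
                             levels = c("red", "red (escalated)", "amber",
                                        "green"))) |>
    count(.data$category)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n,
                                  fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("red" = "#d7301f",
                                          "red (escalated)" = "#fc8d59",
                                          "amber" = "#fdbb84",
                                          "green" = "#31a354"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "patients",
                  title = "Traffic-light triage of the cohort") +
    ggplot2::theme_minimal()
}

#' Plot a ranking tally
#'
#' Stacked first/second/third-choice counts per option.
#'
#' @param tally A [ranking_tally()].
#' @return A ggplot object.
#' @export
plot_ranking <- function(tally) {
  tally <- ranking_tally(tally)
  d <- as_tibble(tally) |>
    tidyr::pivot_longer(dplyr::starts_with("rank"), names_to = "rank",
                        names_prefix = "rank", values_to = "votes") |>
    filter(!is.na(.data$votes))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$votes, y = .data$option,
                                  fill = .data$rank)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1,
                               name = "preference") +
    ggplot2::labs(x = "votes", y = NULL) +
    ggplot2::theme_minimal()
}
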