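is_working_day <- function(date, policy) {
  wd <- as.integer(format(date, "%u"))
  wd %in% policy$working_days & !(date %in% policy$holidays)
}

add_working_days <- function(date, n, policy) {
  vapply(seq_along(date), function(i) {
    d <- date[i]; left <- n
    while (left > 0) {
      d <- d + 1
      if (is_working_day(d, policy)) left <- left - 1
    }
    as.numeric(d)
  }, numeric(1)) |> as.Date(origin = "1970-01-01")
}

#' Review due-window for a triage tier
#'
#' Red patients are due every 1-2 days and amber patients every 2-4 days
#' after their last review (calendar days, as the winning frequency options
#' are phrased); green patients are due once every working week, i.e. by the
#' 5th working day after the last review (Monday-Friday by default, minus
#' holidays), with the earliest green review the next calendar day.
#'
#' @param last_review Date (vector) of the last pharmacy review.
#' @param tier Tier (vector): `"red"`, `"amber"` or `"green"`.
#' @param policy A [review_policy()].
#' @return A tibble with `earliest` and `latest` Date columns.
#' @examples
#' due_window(as.Date("2026-01-05"), "red")   # Monday -> Tue..Wed
#' due_window(as.Date("2026-01-05"), "green") # Monday -> due by next Monday
#' @export
due_window <- function(last_review, tier, policy = review_policy()) {
  last_review <- as.Date(last_review)
  if (any(is.na(last_review))) abort("due_window: invalid last_review date")
  if (any(!tier %in% c("red", "amber", "green"))) {
    abort(paste0("due_window: unassigned or unknown tier: ",
                 paste(setdiff(tier, c("red", "amber", "green")),
                       collapse = ", ")))
  }
  n <- max(length(last_review), length(tier))
  last_review <- rep_len(last_review, n); tier <- rep_len(tier, n)
  earliest <- latest <- last_review
  for (tr in c("red", "amber")) {
    i <- tier == tr
    earliest[i] <- last_review[i] + policy[[tr]][1]
    latest[i] <- last_review[i] + policy[[tr]][2]
  }
  g <- tier == "green"
  if (any(g)) {
    earliest[g] <- last_review[g] + 1
    latest[g] <- add_working_days(last_review[g], policy$green_working_days,
                                  policy)
  }
  tibble(earliest = earliest, latest = latest)
}

#' Review schedules
#'
#' `review_schedule()` attaches a due-window to each patient/tier/last-review
#' triple; `mark_referral()` pulls a schedule's latest due date forward to a
#' referral date (a referral can only make a review earlier, never later) and
#' sets the referral flag; `is_overdue()` compares a schedule with an
#' evaluation date.
#'
#' @param patient_id,tier,last_review Vectors describing the patients.
#' @param policy A [review_policy()].
#' @return A schedule tibble with columns `patient_id, tier, last_review,
#'   earliest, latest, referral`.
#' @examples
#' s <- review_schedule("p1", "green", as.Date("2026-01-05"))
#' mark_referral(s, as.Date("2026-01-06"))
#' @export
review_schedule <- function(patient_id, tier, last_review,
                            policy = review_policy()) {
  w <- due_window(last_review, tier, policy)
  tibble(patient_id = as.character(patient_id), tier = tier,
         last_review = as.Date(last_review),
         earliest = w$earliest, latest = w$latest, referral = FALSE)
}

#' @rdname review_schedule
#' @param schedule A schedule tibble.
#' @param date Referral date.
#' @export
mark_referral <- function(schedule, date) {
  date <- as.Date(date)
  if (any(date < schedule$last_review)) {
    abort("mark_referral: referral date precedes the last review")
  }
  schedule |>
    mutate(latest = pmin(.data$latest, date),
           earliest = pmin(.data$earliest, .data$latest),
           referral = TRUE)
}

#' @rdname review_schedule
#' @param evaluation_date Date the schedule is checked against.
#' @export
is_overdue <- function(schedule, evaluation_date) {
  as.Date(evaluation_date) > schedule$latest
}

#' Ordered review worklist
#'
#' Joins triage results with review schedules and orders patients for the
#' day: overdue patients first, then patients whose window is open, then
#' future reviews; within each stratum red before amber before green; ties
#' broken by days overdue (descending) and then patient id. The ordering is
#' total and deterministic, and the output is a permutation of the input
#' patients. The overdue-first policy is a scheduling choice of this package
#' (the consensus statements order nothing); the sort key is exposed in the
#' output so alternative orderings can be derived.
#'
#' @param results Triage results (tibble with `patient_id` and `tier`, e.g.
#'   from [triage_cohort()]).
#' @param schedules A schedule tibble from [review_schedule()]; exactly one
#'   row per patient in `results`.
#' @param today Evaluation date.
#' @return A tibble ordered for review with columns `rank, patient_id, tier,
#'   due_earliest, due_latest, overdue, referral`.
#' @export
worklist <- function(results, schedules, today) {
  today <- as.Date(today)
  results <- as_tibble(results); schedules <- as_tibble(schedules)
  missing <- setdiff(results$patient_id, schedules$patient_id)
  if (length(missing)) {
    abort(paste0("worklist: no schedule for patient(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(schedules$patient_id) || anyDuplicated(results$patient_id)) {
    abort("worklist: patient ids must be unique")
  }
  x <- left_join(results[c("patient_id", "tier")],
                 schedules[c("patient_id", "earliest", "latest", "referral")],
                 by = "patient_id") |>
    mutate(overdue = today > .data$latest,
           stratum = if_else(.data$overdue, 0L,
                             if_else(today >= .data$earliest, 1L, 2L)),
           days_overdue = as.numeric(today - .data$latest))
  ord <- order(x$stratum, -as.integer(tier_severity(x$tier)),
               -x$days_overdue, x$patient_id)
  x[ord, ] |>
    mutate(rank = row_number()) |>
    select(all_of(c("rank", "patient_id", "tier")),
           due_earliest = "earliest", due_latest = "latest",
           all_of(c("overdue", "referral")))
}
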