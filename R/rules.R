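#' Consensus rule thresholds
#'
#' The percent-agreement rule used by the Delphi engine. An item is *included*
#' (or a statement *agreed*) when at least `t67` percent of valid ratings fall
#' in the top two Likert bands (6-7), or at least `t57` percent fall in the top
#' three bands (5-7). Risk tiers use a single `tier_t` threshold on the band
#' masses: high risk (red) when at least `tier_t`% rated 6-7, medium (amber)
#' when at least `tier_t`% rated 3-5, low (green) when at least `tier_t`%
#' rated 1-2. When no
#' band reaches the threshold and `majority_fallback` is `TRUE`, an item whose
#' combined 3-5 and 6-7 mass exceeds 50% is treated as medium risk, mirroring
#' the stakeholder fallback that a majority medium-or-high rating counts as
#' medium risk.
#'
#' All comparisons are inclusive (`>=`), matching the wording of the
#' consensus definitions; when decisions are computed from published
#' one-decimal percentages they are compared exactly as printed, with no
#' re-rounding.
#'
#' @param include_t67,include_t57 Inclusion thresholds (percent) for the 6-7
#'   and 5-7 bands. Defaults 75 and 85.
#' @param tier_band_t Tier threshold (percent) applied to each risk band.
#'   Default 75.
#' @param majority_fallback Apply the medium-risk majority fallback when no
#'   band reaches `tier_band_t`. Default `TRUE`.
#' @param agree_t67,agree_t57 Agreement thresholds (percent) for statements.
#'   Defaults 75 and 85.
#' @return A `consensus_rule` list.
#' @examples
#' consensus_rule()
#' consensus_rule(include_t67 = 80)
#' @export
consensus_rule <- function(include_t67 = 75, include_t57 = 85,
                           tier_band_t = 75, majority_fallback = TRUE,
                           agree_t67 = 75, agree_t57 = 85) {
  rule <- list(include_t67 = include_t67, include_t57 = include_t57,
               tier_band_t = tier_band_t,
               majority_fallback = isTRUE(majority_fallback),
               agree_t67 = agree_t67, agree_t57 = agree_t57)
  for (nm in setdiff(names(rule), "majority_fallback")) {
    v <- rule[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 100) {
      abort(paste0("consensus_rule: `", nm, "` must be a percent in (0, 100]"))
    }
  }
  structure(rule, class = "consensus_rule")
}

#' @export
print.consensus_rule <- function(x, ...) {
  cat("<consensus_rule>\n")
  cat(sprintf("  inclusion: >=%g%% rating 6-7 OR >=%g%% rating 5-7\n",
              x$include_t67, x$include_t57))
  cat(sprintf("  tiers:     red/amber/green band >=%g%%; majority fallback %s\n",
              x$tier_band_t, if (x$majority_fallback) "on" else "off"))
  cat(sprintf("  agreement: >=%g%% rating 6-7 OR >=%g%% rating 5-7\n",
              x$agree_t67, x$agree_t57))
  invisible(x)
}

#' Triage policy
#'
#' Controls classification and overrides. The default escalation threshold
#' moves a patient with more than 4 amber criteria into the red category; the
#' panel also endorsed the less sensitive >5 rule, so the threshold is
#' configurable. Overrides model the compulsory-comment clinical-judgement
#' rule.
#'
#' @param amber_escalation_threshold Integer; a patient with *more than* this
#'   many amber matches (and no red match) is escalated to red. Default 4.
#' @param allow_override Whether clinical-judgement overrides are permitted.
#' @param require_override_comment Whether an override must carry a non-empty
#'   comment. Default `TRUE`.
#' @return A `triage_policy` list.
#' @examples
#' triage_policy()
#' triage_policy(amber_escalation_threshold = 5)
#' @export
triage_policy <- function(amber_escalation_threshold = 4,
                          allow_override = TRUE,
                          require_override_comment = TRUE) {
  t <- amber_escalation_threshold
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 1 || t != floor(t)) {
    abort("triage_policy: `amber_escalation_threshold` must be an integer >= 1")
  }
  structure(list(amber_escalation_threshold = as.integer(t),
                 allow_override = isTRUE(allow_override),
                 require_override_comment = isTRUE(require_override_comment)),
            class = "triage_policy")
}

#' @export
print.triage_policy <- function(x, ...) {
  cat("<triage_policy>\n")
  cat(sprintf("  escalate to red when amber matches > %d\n",
              x$amber_escalation_threshold))
  cat(sprintf("  overrides %s%s\n",
              if (x$allow_override) "allowed" else "disabled",
              if (x$allow_override && x$require_override_comment)
                " (comment compulsory)" else ""))
  invisible(x)
}

#' Review-frequency policy
#'
#' Encodes the consensus review frequencies: every 1-2 days for red, every 2-4
#' days for amber (both calendar days, as phrased by the winning ranking
#' options), and once every working week for green -- due by the 5th working
#' day after the last review, or earlier on referral. The working week
#' defaults to Monday-Friday and accepts a holiday list.
#'
#' @param red,amber Length-2 numeric `c(min, max)` calendar-day intervals.
#' @param green_working_days Number of working days defining the green
#'   interval. Default 5.
#' @param working_days Integer weekdays counted as working days (1 = Monday
#'   ... 7 = Sunday). Default `1:5`.
#' @param holidays A `Date` vector of non-working holidays.
#' @return A `review_policy` list.
#' @examples
#' review_policy()
#' @export
review_policy <- function(red = c(1, 2), amber = c(2, 4),
                          green_working_days = 5,
                          working_days = 1:5, holidays = as.Date(character())) {
  for (nm in c("red", "amber")) {
    v <- get(nm)
    if (length(v) != 2 || any(v <= 0) || v[1] > v[2]) {
      abort(paste0("review_policy: `", nm, "` must be c(min, max) with 0 < min <= max"))
    }
  }
  if (green_working_days < 1) abort("review_policy: `green_working_days` must be >= 1")
  working_days <- sort(unique(as.integer(working_days)))
  if (length(working_days) == 0 || any(working_days < 1 | working_days > 7)) {
    abort("review_policy: `working_days` must be weekdays in 1..7")
  }
  structure(list(red = as.numeric(red), amber = as.numeric(amber),
                 green_working_days = as.integer(green_working_days),
                 working_days = working_days, holidays = as.Date(holidays)),
            class = "review_policy")
}

#' @export
print.review_policy <- function(x, ...) {
  cat("<review_policy>\n")
  cat(sprintf("  red:   every %g-%g calendar days\n", x$red[1], x$red[2]))
  cat(sprintf("  amber: every %g-%g calendar days\n", x$amber[1], x$amber[2]))
  cat(sprintf("  green: within %d working days (weekdays %s; %d holidays)\n",
              x$green_working_days, paste(x$working_days, collapse = ","),
              length(x$holidays)))
  invisible(x)
}

#' Read a review or triage policy from a YAML or JSON config file
#'
#' Config keys mirror the constructor arguments of [review_policy()] and
#' [triage_policy()]; unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param type `"review"` or `"triage"`.
#' @return A policy object.
#' @export
read_policy <- function(path, type = c("review", "triage")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("policy file not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ctor <- if (type == "review") review_policy else triage_policy
  allowed <- names(formals(ctor))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) abort(paste0("unknown policy keys: ", paste(bad, collapse = ", ")))
  if (!is.null(cfg$holidays)) cfg$holidays <- as.Date(unlist(cfg$holidays))
  do.call(ctor, cfg)
}
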