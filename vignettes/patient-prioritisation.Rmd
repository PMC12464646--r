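---
title: "Consensus rules and traffic-light triage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus rules and traffic-light triage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delphitriage)
```

`delphitriage` implements the computational core of a consensus-developed
patient prioritisation tool for mental-health inpatient pharmacy: the
modified-Delphi engine that decided which risk indicators enter the tool, and
the resulting red/amber/green triage engine. This vignette is the package's
own account of the methods: the decision rules and their assumptions, the
parameters that matter, the numerical conventions, and the places where the
design was genuinely open.

## The modified-Delphi model

A modified Delphi study runs an expert panel through successive anonymous
rating rounds with *controlled feedback* in between: each panellist sees the
group's medians and score breakdowns (plus narrative summaries of free-text
comments) before re-rating. The package models one round as a long-format
rating matrix -- one row per `(panellist, item, dimension)` with a response
that is a Likert score 1--7, an explicit *outside my expertise* (`"OE"`)
marker, or missing. Two assumptions follow from that design and are baked
into `summarize_ratings()`:

* **Denominators are per cell.** `OE` and missing responses are excluded
  from `n_valid` and from every percentage, so the implied `n` differs from
  item to item. This is the only reading consistent with the published
  aggregates, where adjacent items imply different denominators.
* **Rounds are independent inputs.** The package does not model opinion
  change between rounds; round 2 is simply a second matrix (usually with
  some dropout and some added items).

Band percentages are linear tallies: `pct_6_7` is the percentage of valid
responses scoring 6 or 7, `pct_5_7` of 5--7, `pct_3_5` of 3--5, `pct_1_2` of
1--2. The median of an even number of responses is the mean of the two
central values; half-integer medians (6.5) in the published tables confirm
that convention. A cell with *no* valid responses has no defined summary and
raises a classed error -- it is never reported as zero percentages, which
would silently satisfy "0% rated 6--7".

## Consensus decision rules

`consensus_rule()` holds the thresholds; all defaults are the study's own
values and all comparisons are inclusive (`>=`), matching the rule's
published wording:

| parameter | default | meaning |
|---|---|---|
| `include_t67` | 75 | inclusion: % rating 6--7 (important / very important) |
| `include_t57` | 85 | inclusion: % rating 5--7 |
| `tier_band_t` | 75 | tier: % mass required in one risk band |
| `majority_fallback` | `TRUE` | medium-risk fallback when no band reaches the threshold |
| `agree_t67` / `agree_t57` | 75 / 85 | agreement rule for tool-use statements |

The tier rule checks red (`pct_6_7`), then amber (`pct_3_5`), then green
(`pct_1_2`). Because 75 + 75 > 100, the red and amber conditions are
mutually exclusive by construction on any valid summary -- a property the
test suite asserts on random matrices rather than trusting the arithmetic.
The fallback ("a majority rated it medium or high") mirrors the stakeholder
decision for indicators that met inclusion but no tier band; with the
packaged aggregates it only ever yields amber, never green, and every
included indicator ends red or amber.

Two numerical choices deserve emphasis:

* **Printed percentages are authoritative when running from the packaged
  aggregates.** The fixtures store the published one-decimal percentages
  verbatim and decisions compare those exact values -- no re-rounding, no
  reconstruction of raw counts. Whether the original analysis thresholded
  raw counts or rounded percentages is unknowable from the publication, so
  `run_round()` flags any decision within 0.05 of a threshold
  (`near_threshold` in `tidy()`, counted in `glance()`) instead of silently
  absorbing the ambiguity.
* **Round denominators use only the items rated in that round.** Items
  introduced for round 2 have blank round-1 cells and are excluded from the
  round-1 denominator (109 of 123 indicators; 29 of 30 statements). The
  report exposes `n_excluded_unrated` so both denominators are always
  visible.

The ranking aggregator `winner_by_first_choice()` takes the option with the
plurality of first preferences and breaks ties by cascading to second, then
third preferences, then alphabetical option order. The cascade is needed in
practice: the medium-risk review-frequency block ends 11--11 on first
choices and is decided 8--7 on second choices. The alphabetical final step
merely guarantees determinism.

### Controlled feedback

`build_feedback()` assembles one document per panellist: per item, their own
previous rating ("not rated" / "outside my expertise" where applicable), the
group median, the full 1--7 count breakdown, an optional narrative summary,
and the literal annotations `*Newly added indicator` and
`Modified from: <original text>`. Narratives are always supplied text --
thematic analysis of comments is a human step and is deliberately not
automated. Both the counts and the median are shown because the published
description of the feedback links to a full breakdown without reproducing
it; showing both is the conservative superset. Rendering is deterministic
and the only panellist identifiable from a document is its recipient.

## The indicator catalog

A catalog is a tibble of indicators with a stable slug id, wording, one of
four collation groups (high-risk medicine, patient-, drug-,
hospital-related), provenance, a status (`active`, `modified`,
`merged_into:<id>`, `excluded`), a tier, and a matching predicate.
Editorial refinement is *absorption*: each merged indicator points at its
representative and leaves the active count, and each exclusion removes one
more -- the only reading under which the published arithmetic (82 agreed,
10 merged, 1 excluded, 71 in the tool) is consistent. `union_sources()`
implements the initial collation (48 + 415 sources with 3 shared giving
460), keeping both provenance annotations on shared entries.

The packaged merge plan deserves a caveat: the published main text names
only the CKD consolidation ("combined into 2 groups") and the counts. The
remaining eight merges and the single stakeholder exclusion are *inferred*
pairings of closely similar indicators, marked `inferred` in the plan's
note column. The resulting 71-indicator tool catalog is therefore faithful
in count, tiers and the stated CKD structure, but individual merge
memberships beyond CKD are editorial reconstructions.

## The triage engine

### Predicate grammar

Indicators match patient records through a deliberately small grammar:
medication name / class membership (lower-cased exact matching -- no
terminology service is assumed), a regular-medication count threshold
(inclusive, per the polypharmacy wording "`>= 10`"), missed-dose conditions,
lab comparisons, age bounds, keyed clinical flags, days-since-event
thresholds, and `manual`. Points where the grammar is strict:

* **Lab units are declared and must match the record exactly.** A mismatch
  (e.g. eGFR in mL/min vs mL/min/1.73m2) is an error, never a silent
  conversion. The most recent result for the named lab is the one compared.
* **Age bounds follow the printed wording exactly**: `>70`, `>80`, `<12`,
  `<18` are strict; the polypharmacy counts are inclusive.
* **`manual` indicators never match automatically.** Criteria that require
  clinical judgement or an external knowledge base -- significant drug
  interactions, significant adverse drug reactions, nonadherence, compound
  conditions like low sodium *plus* an antidepressant -- are asserted per
  patient through an explicit flag channel, and the match is audited as
  `mode = "manual"`. No interaction database is bundled, by design.
* **A missing event date does not match a days-since threshold**: the
  elapsed time is unknown, and an entirely empty record matches nothing.

The grammar has no conjunction or negation. That keeps predicates auditable
one datum at a time; the cost is that compound indicators become `manual`.

### Classification and overrides

`classify()` applies: red if any red match; else red with
`escalated = TRUE` if amber matches exceed `amber_escalation_threshold`;
else amber if any amber match; else green. The default threshold is 4
("more than 4 amber criteria"), the more sensitive of the two escalation
rules that both reached panel agreement (`>4` and `>5`); it is configurable
precisely because both passed. Classification is order-invariant and
monotone -- adding a match can never lower severity -- and active indicators
whose tier is unassigned are treated as amber with a warning, extending the
stakeholder fallback to run time. Overrides (`apply_override()`) model the
agreed clinical-judgement statement: any tier may be replaced, but the
original tier, author, timestamp and a compulsory non-empty comment are
retained; whitespace does not satisfy the comment requirement.

### Review scheduling

The winning review frequencies are phrased in days for red ("every 1--2
days") and amber ("every 2--4 days") but in working weeks for green ("once
every working week"). `review_policy()` therefore uses calendar-day
arithmetic for red/amber and working-day arithmetic for green (due by the
5th working day after the last review). The working week defaults to
Monday--Friday with a configurable holiday list, since no definition was
published. Referrals can only pull a due date earlier. The worklist order
-- overdue first, then open windows, then future; red before amber before
green within each stratum; ties by days overdue then patient id -- is this
package's own scheduling policy (nothing in the consensus statements orders
patients); the key columns are exposed so sites can re-sort.

## Synthetic data

The generators exist so that every engine is testable without clinical
data, and their defaults are the study's own conditions.

`generate_panel()` emulates the panel: 36 round-1 panellists with 7 lost
before round 2 (the published completion pattern), an outside-my-expertise
probability of 0.05 in distribution mode, and per-item score targets either
as exact counts (reproduced verbatim; uncounted panellists answer `OE`) or
as sampling distributions. In exact-count mode `summarize_ratings()`
recovers the specified counts exactly -- this is how published table rows
can be reproduced as live rating matrices.

`generate_cohort()` plants indicator matches: each planted predicate is
satisfied by construction (the medication added, the lab placed mid-band,
the flag set, the age moved past the bound), while background data is drawn
from ranges chosen not to trip the catalog (ages 25--65, at most 3 neutral
formulary medications, no flags, a review 2 days ago). Accidental matches
are handled in two layers: rejection sampling (default 25 retries per
patient) removes coincidental ones, and *logically implied* matches --
planting ten regular medications necessarily satisfies the five-medication
polypharmacy indicator, an age above 80 necessarily exceeds 70 -- are added
to the returned ground truth with `planted = FALSE` rather than silently
dropped. The generator's contract is therefore exact:
`match_indicators()` equals the ground truth row-for-row.

A single integer seed drives everything through a fixed splitting scheme
(dropout, round noise and cohort construction use distinct derived
streams), so same seed plus same spec is bit-identical down to the
serialised files, and the global RNG state is left untouched.

What the generators do **not** emulate: correlation structure between
indicators (real clozapine patients cluster with monitoring flags),
panellist-level rating styles or between-round opinion shift, missing-data
mechanisms other than uniform `OE`, and realistic medication lists beyond a
neutral formulary. Passing tests on synthetic cohorts therefore demonstrate
the engine's bookkeeping -- matching, tiering, escalation, scheduling -- not
clinical validity of the indicators themselves.

## Problem sizes and determinism in the test suite

The suite checks band summaries against an independent brute-force tally on
random matrices up to 50 x 50, triage recovery on 500-patient synthetic
cohorts, the amber-escalation boundary for every threshold 1--6, and the
full published-aggregate reproductions (109/123 indicators, 29/30
statements, both ranking exercises). Those sizes keep the whole suite under
a minute on one core while exercising every denominator edge case (blank
round-1 cells, `OE`-only panellists, even-`n` medians). All stochastic
tests fix their seeds; the published-aggregate checks are exact equalities
on counts, not tolerances.

## Known limitations

* The merge plan beyond the CKD consolidation is inferred (above); swap in
  a corrected `merge_plan.csv` if the authoritative plan becomes available.
* Predicates cover the mechanically checkable indicators; roughly half the
  tool's criteria are judgement calls and remain `manual` by design.
* Green-band risk percentages are derived (`100 - pct_3_5 - pct_6_7`) when
  only the published two risk bands are available, so they inherit printed
  rounding (within 0.15 of a percentage point).
* The scheduling worklist ordering and the green "earliest next day"
  convention are package policy, stated here rather than sourced from the
  consensus statements.
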