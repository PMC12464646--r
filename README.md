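# delphitriage

Modified-Delphi consensus analysis and traffic-light patient prioritisation
for mental-health inpatient pharmacy teams.

Mental-health wards carry a high burden of drug-related problems (clozapine
and lithium monitoring, covert administration, rapid tranquillisation,
polypharmacy), while pharmacy teams rarely have capacity to review every
inpatient every day. A pragmatic answer is a prioritisation tool: a catalog
of risk indicators agreed by expert consensus, a red/amber/green (RAG)
classification of each patient from those indicators, and review frequencies
per tier. `delphitriage` implements both halves of that workflow as an R
package:

* **the consensus engine** used to *build* such a tool -- Likert band
  summaries from long-format panel ratings, percent-agreement decision
  rules, risk-tier assignment, controlled-feedback documents for second-round
  panellists, and first-choice rank aggregation; and
* **the triage engine** that *is* the tool -- a machine-readable indicator
  catalog with a small predicate grammar, RAG classification with an
  amber-escalation rule and audited clinical-judgement overrides, and review
  scheduling on a working-day calendar.

The complete published aggregate data of the development study (both Delphi
rounds for 123 risk indicators and 30 tool-use statements, plus the two
ranking exercises) ships as plain-text fixtures, so every headline consensus
result can be recomputed from scratch.

## The decision rules

For each item, panellists rate on a fully labelled 7-point Likert scale (with
an *outside my expertise* option excluded from all denominators). Writing
`p(a-b)` for the percentage of valid ratings in bands `a..b`:

* **Inclusion / agreement:** an item reaches consensus iff
  `p(6-7) >= 75` **or** `p(5-7) >= 85` (both comparisons inclusive).
* **Risk tier:** red iff `p(6-7) >= 75`; else amber iff `p(3-5) >= 75`; else
  green iff `p(1-2) >= 75`; else amber if a majority (`p(3-5) + p(6-7) > 50`)
  rated medium-or-high (the stakeholder fallback); else unassigned.
* **Classification:** a patient is red if any red indicator matches, or --
  escalation -- if more than 4 amber indicators match; amber if any amber
  indicator matches; green otherwise. Overrides require a compulsory comment.
* **Review windows:** red every 1-2 days, amber every 2-4 days (calendar
  days), green once every working week (due by the 5th working day), or
  earlier on referral.

## Worked example

Re-run the consensus analysis on the packaged published aggregates:

```r
library(delphitriage)

bands <- published_indicator_bands(round = 2, dimension = "importance")
run_round(bands, decision = "inclusion")
#> <consensus_report: inclusion>
#>   82/123 items included (66.7%)
#>   note: 2 decision(s) within 0.05% of a threshold
```

82 of the 123 round-2 indicators met the rule (round 1: 47 of 109). The
`note` line flags decisions sitting exactly on a printed one-decimal
threshold, where published rounding could matter. Building the final tool
applies the packaged editorial plan (10 merges, 1 stakeholder exclusion) and
attaches matching predicates:

```r
tc <- tool_catalog()
catalog_counts(tc)
#> # A tibble: 1 x 4
#>   active merged excluded total
#>    <int>  <int>    <int> <int>
#> 1     71     10        1    82
```

Triage a patient against the 71-indicator tool:

```r
p <- patient_record("MH-0042", age = 83,
  medications = data.frame(name = c("clozapine", "atorvastatin"),
                           class = c("antipsychotic", "other")),
  labs = data.frame(name = "eGFR", value = 38, units = "mL/min",
                    date = "2026-01-10"),
  flags = "seclusion", last_review = "2026-01-12")

match_indicators(p, tc, today = as.Date("2026-01-14"))
#> # A tibble: 6 x 4
#>   indicator_id   tier  evidence                                  mode
#>   <chr>          <chr> <chr>                                     <chr>
#> 1 antipsychotics amber medication class antipsychotic: clozapine auto
#> 2 clozapine      red   medication: clozapine                     auto
#> 3 ckd-stage-3b   red   eGFR 38 mL/min                            auto
#> 4 age-over-80    amber age 83 years                              auto
#> 5 age-over-70    amber age 83 years                              auto
#> 6 seclusion      amber flag: seclusion                           auto

classify(match_indicators(p, tc, today = as.Date("2026-01-14")),
         patient_id = "MH-0042")
#> <triage_result MH-0042: RED; 2 red + 4 amber match(es)>

due_window(as.Date("2026-01-12"), "red")
#> # A tibble: 1 x 2
#>   earliest   latest
#>   <date>     <date>
#> 1 2026-01-13 2026-01-14
```

The patient is red (clozapine and an eGFR in the 30-44 mL/min band both
match red indicators), so the next review is due within 1-2 days of the last
one. `triage_cohort()` does this for a whole cohort, `review_schedule()` +
`worklist()` turn results into an ordered review list, and
`generate_panel()` / `generate_cohort()` produce seeded synthetic data with
known ground truth for testing. A shell dispatcher for batch runs is
installed at `inst/cli/delphitriage` (subcommands `consensus`, `triage`,
`synth`, `catalog-validate`).

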