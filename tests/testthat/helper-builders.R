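# shared builders for small in-code fixtures

ratings_from_scores <- function(scores, item = "x", dimension = "importance",
                                round = 1L) {
  tibble::tibble(round = round,
                 panellist = sprintf("P%03d", seq_along(scores)),
                 item = item, dimension = dimension,
                 response = as.character(scores))
}

# independent brute-force band tally: plain loops, no package internals
oracle_bands <- function(responses) {
  valid <- responses[responses %in% as.character(1:7)]
  v <- as.integer(valid)
  counts <- vapply(1:7, function(k) sum(v == k), integer(1))
  n <- length(v)
  list(n_valid = n,
       counts = counts,
       median = stats::median(v),
       pct_1_2 = 100 * sum(counts[1:2]) / n,
       pct_3_5 = 100 * sum(counts[3:5]) / n,
       pct_5_7 = 100 * sum(counts[5:7]) / n,
       pct_6_7 = 100 * sum(counts[6:7]) / n)
}

mini_catalog <- function() {
  preds <- c(
    clozapine = '{"type":"medication_name_in","names":["clozapine"]}',
    lithium = '{"type":"medication_name_in","names":["lithium"]}',
    `toxic-lithium-levels` = '{"type":"flag_present","flag":"toxic_lithium_level"}',
    `polypharmacy-10` = '{"type":"regular_med_count_ge","count":10}',
    `ckd-3b` = '{"type":"lab_compare","lab":"eGFR","op":"between","lo":30,"hi":44,"units":"mL/min"}',
    `age-over-80` = '{"type":"age_compare","op":"gt","value":80}',
    seclusion = '{"type":"flag_present","flag":"seclusion"}',
    `missed-any` = '{"type":"missed_dose_of","any":true}',
    `sig-interaction` = "manual")
  tiers <- c("red", "red", "red", "red", "red",
             "amber", "amber", "amber", "red")
  indicator_catalog(tibble::tibble(id = names(preds),
                                   text = names(preds),
                                   group = "patient_related",
                                   predicate = unname(preds),
                                   tier = tiers))
}

amber_only_matches <- function(n) {
  tibble::tibble(indicator_id = sprintf("a%02d", seq_len(n)),
                 tier = rep("amber", n),
                 evidence = "x", mode = "auto")
}
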