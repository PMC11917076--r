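# Compact builders for schema-valid records used across tests.

make_group <- function(n = 50L, age = 8, len = 4, waves = 3L,
                       category = "no_id", iq = NA_real_,
                       wave_ages = NULL, diagnosis = "ASD") {
  study_group(diagnosis, n, first_wave_mean_age = age,
              followup_length = len, n_waves = waves,
              wave_mean_ages = wave_ages,
              functioning = intellectual_functioning(category, iq))
}

make_record <- function(id = "test0001",
                        groups = list(make_group()),
                        informants = "parent",
                        score_level = "total",
                        designed = "no", adapted = "no",
                        overlaps = list(),
                        items_available = TRUE,
                        criteria_available = TRUE,
                        n_outcomes = 1L) {
  outcomes <- lapply(seq_len(n_outcomes), function(i) {
    outcome_measure("Test Scale", sprintf("Score %d", i), score_level,
                    construct = "behaviour problems",
                    informants = informants)
  })
  study_record(
    study_id = id, citation = paste("Study", id),
    groups = groups, outcomes = outcomes,
    instruments = list(instrument(
      "Test Scale", designed_for_ndd = designed, adapted_for_ndd = adapted,
      adaptation_note = if (adapted == "yes") "visual support" else NULL)),
    overlaps = overlaps,
    items_available = items_available,
    criteria_available = criteria_available)
}

make_overlap <- function(ref = "Score 1", addressed = "no") {
  overlap_finding(ref, "item wording", "criterion wording",
                  criterion_code = "X A1", match_code = "synonym",
                  addressed = addressed)
}

# an independent restatement of the three overall-aggregation principles,
# written against counts rather than the plurality shortcut the package
# uses; stops if a rating vector escapes all three principles
oracle_overall <- function(v) {
  nh <- sum(v == "high"); nl <- sum(v == "low"); nu <- sum(v == "unclear")
  if (nh == 2 && nl == 2) return("unclear")              # principle 2
  if ((nh + nl) == 2 && nu == 2) return("unclear")       # principle 3
  if (nh > nl && nh > nu) return("high")                 # principle 1
  if (nl > nh && nl > nu) return("low")
  if (nu > nh && nu > nl) return("unclear")
  stop("rating vector escapes all three aggregation principles: ",
       paste(v, collapse = ","))
}
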