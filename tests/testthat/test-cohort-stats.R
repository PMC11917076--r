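make_outcome <- function(instr, label, level) {
  outcome_measure(instr, label, level, informants = "parent")
}

with_outcomes <- function(...) {
  outs <- list(...)
  instr <- unique(vapply(outs, `[[`, character(1), "instrument_name"))
  study_record("s1", groups = list(make_group()), outcomes = outs,
               instruments = lapply(instr, function(nm)
                 instrument(nm, designed_for_ndd = "no",
                            adapted_for_ndd = "no")))
}

test_that("scale scores count at the most general reported level per instrument", {
  # a total beats a subscale of the same instrument
  r1 <- with_outcomes(make_outcome("CBCL", "Total", "total"),
                      make_outcome("CBCL", "Attention problems", "subscale"))
  expect_equal(count_scale_scores(r1), 1L)
  # subscales only: each counts
  r2 <- with_outcomes(make_outcome("ABC", "Irritability", "subscale"),
                      make_outcome("ABC", "Hyperactivity", "subscale"),
                      make_outcome("ABC", "Lethargy", "subscale"))
  expect_equal(count_scale_scores(r2), 3L)
  # total + two broadbands + four subscales of one instrument: the total wins
  r3 <- with_outcomes(make_outcome("SDQ", "Total difficulties", "total"),
                      make_outcome("SDQ", "Internalising", "broadband"),
                      make_outcome("SDQ", "Externalising", "broadband"),
                      make_outcome("SDQ", "Emotional", "subscale"),
                      make_outcome("SDQ", "Conduct", "subscale"),
                      make_outcome("SDQ", "Hyperactivity", "subscale"),
                      make_outcome("SDQ", "Peer problems", "subscale"))
  expect_equal(count_scale_scores(r3), 1L)
  # broadbands win over subscales in the absence of a total
  r4 <- with_outcomes(make_outcome("SDQ", "Internalising", "broadband"),
                      make_outcome("SDQ", "Externalising", "broadband"),
                      make_outcome("SDQ", "Emotional", "subscale"))
  expect_equal(count_scale_scores(r4), 2L)
  # independent instruments count independently
  r5 <- with_outcomes(make_outcome("SDQ", "Total difficulties", "total"),
                      make_outcome("CBCL", "Anxiety", "subscale"))
  expect_equal(count_scale_scores(r5), 2L)
})

test_that("a constructed three-study cohort summarises with exact percentages", {
  recs <- list(
    make_record(id = "a", designed = "no"),   # d4 high
    make_record(id = "b", designed = "no"),
    make_record(id = "c", designed = "yes"))  # d4 low
  ass <- assess_cohort(recs)
  s <- summarize_cohort(recs, ass)
  expect_equal(s$n_studies, 3L)
  # overall ratings: defaults give d1 low, d2 high, d3 high, d4 high/low
  overall <- vapply(ass, `[[`, character(1), "overall")
  expect_equal(unname(overall), c("high", "high", "unclear"))
  expect_equal(unname(s$overall_distribution[c("high", "unclear", "low")]),
               c(66.7, 33.3, 0.0))
  expect_equal(unname(s$domain_distribution["d4", c("high", "low")]),
               c(66.7, 33.3))
  # distribution percentages sum to 100 within rounding per row
  for (d in 1:4) {
    expect_lt(abs(sum(s$domain_distribution[paste0("d", d), ]) - 100), 0.3)
  }
  expect_lt(abs(sum(s$overall_distribution) - 100), 0.3)
  # count conservation
  expect_true(all(rowSums(s$domain_counts) == s$n_studies))
})

test_that("overlap, informant and instrument percentages use the stated denominators", {
  recs <- list(
    make_record(id = "a",
                overlaps = list(make_overlap(addressed = "no"))),
    make_record(id = "b",
                overlaps = list(make_overlap(addressed = "cant_tell"))),
    make_record(id = "c", informants = c("parent", "teacher")),
    make_record(id = "d", informants = character(0)))
  ass <- assess_cohort(recs)
  s <- summarize_cohort(recs, ass)
  expect_equal(s$pct_studies_with_overlap, 50.0)          # 2 of 4
  expect_equal(s$pct_overlap_studies_unaddressed, 50.0)   # 1 of the 2
  expect_equal(s$pct_multi_informant, 25.0)               # 1 of 4
  expect_equal(s$pct_outcomes_with_overlap, 50.0)         # 2 of 4 counted scores
  # same instrument name across studies counts once, case-insensitively
  expect_equal(s$n_distinct_instruments, 1L)
  expect_equal(s$pct_instruments_designed_for_ndd, 0.0)
})

test_that("child-perspective percentages condition on the missing subset", {
  recs <- list(
    make_record(id = "a", informants = c("parent", "child"),
                groups = list(make_group(age = 11, category = "no_id",
                                         iq = 100))),   # child rated
    make_record(id = "b", informants = "parent",
                groups = list(make_group(age = 11, category = "no_id",
                                         iq = 100))),   # missing, feasible
    make_record(id = "c", informants = "parent",
                groups = list(make_group(age = 2.5, len = 2,
                                         category = "unknown"))))
  ass <- assess_cohort(recs)
  s <- summarize_cohort(recs, ass)
  expect_equal(s$pct_child_missing, 66.7)          # b and c
  expect_equal(s$pct_feasible_among_missing, 50.0) # b of {b, c}
})

test_that("summaries are invariant to study order and reject misaligned inputs", {
  recs <- list(make_record(id = "a"), make_record(id = "b",
                                                  designed = "yes"),
               make_record(id = "c", informants = c("parent", "teacher")))
  ass <- assess_cohort(recs)
  s1 <- summarize_cohort(recs, ass)
  s2 <- summarize_cohort(recs[c(3, 1, 2)], ass)
  expect_equal(s1, s2)
  expect_error(summarize_cohort(recs[1:2], ass), "same unique study_ids")
  expect_error(summarize_cohort(list(), list()), "no studies")
})

test_that("descriptives report per-study ranges and cohort totals", {
  fixture <- load_fixture("worked_examples")
  df <- descriptives(fixture)
  expect_equal(nrow(df), 4L)
  alsem <- df[df$study_id == "alsem2013", ]
  expect_equal(alsem$last_wave_age_max, 4.50)
  expect_equal(alsem$n_children, 92L)
  co <- attr(df, "cohort")
  expect_equal(co$total_children, 92L + 65L + 58L + 421L)
  # single-study cohort: ranges collapse
  one <- descriptives(fixture$studies[1])
  co1 <- attr(one, "cohort")
  expect_equal(co1$first_wave_age_range[1], co1$first_wave_age_range[2])
})
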