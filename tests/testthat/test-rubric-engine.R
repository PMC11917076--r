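ans <- answer_levels()

test_that("domain 1 decision table matches the hand-coded rubric over all answer pairs", {
  # Low = no overlaps (1a yes) or all addressed (1b yes);
  # High = overlap identified and unaddressed; Unclear otherwise
  table1 <- c(
    "yes.yes" = "low", "yes.no" = "low", "yes.cant_tell" = "low",
    "no.yes" = "low", "no.no" = "high", "no.cant_tell" = "unclear",
    "cant_tell.yes" = "low", "cant_tell.no" = "unclear",
    "cant_tell.cant_tell" = "unclear")
  for (a in ans) for (b in ans) {
    expect_identical(rate_domain1(a, b), unname(table1[paste(a, b, sep = ".")]),
                     label = sprintf("rate_domain1(%s, %s)", a, b))
  }
})

test_that("domain 3 decision table matches the hand-coded rubric over all answer pairs", {
  # Low = infeasible (3a no) or child-rated (3b yes);
  # High = feasible yet not child-rated; Unclear otherwise
  table3 <- c(
    "yes.yes" = "low", "yes.no" = "high", "yes.cant_tell" = "unclear",
    "no.yes" = "low", "no.no" = "low", "no.cant_tell" = "low",
    "cant_tell.yes" = "low", "cant_tell.no" = "unclear",
    "cant_tell.cant_tell" = "unclear")
  for (a in ans) for (b in ans) {
    expect_identical(rate_domain3(a, b), unname(table3[paste(a, b, sep = ".")]),
                     label = sprintf("rate_domain3(%s, %s)", a, b))
  }
})

test_that("domain 2 rating matches the hand-coded table over informant count x age answer", {
  # rows: distinct informant types on the best outcome (0 = unknown);
  # cols: were all waves under six?
  cases <- list(
    list(inf = c("parent", "teacher"), age = 8, expect = "low"),
    list(inf = c("parent", "teacher"), age = 3, expect = "low"),
    list(inf = "parent", age = 3, expect = "low"),     # all waves under 6
    list(inf = "parent", age = 8, expect = "high"),
    list(inf = "parent", age = NA, expect = "unclear"),
    list(inf = character(0), age = 3, expect = "low"), # young age suffices
    list(inf = character(0), age = 8, expect = "unclear"),
    list(inf = character(0), age = NA, expect = "unclear"))
  for (cs in cases) {
    g <- if (is.na(cs$age)) {
      study_group("ASD", 50L, n_waves = 3L)  # no age information at all
    } else {
      make_group(age = cs$age, len = 1, waves = 3L)  # ages stay on one side of 6
    }
    r <- make_record(groups = list(g), informants = cs$inf)
    expect_identical(rate_domain2(r), cs$expect,
                     label = sprintf("informants=%s age=%s",
                                     paste(cs$inf, collapse = "+"), cs$age))
  }
})

test_that("domain 4 rating matches the hand-coded table over instrument answer pairs", {
  single <- function(d, a) {
    list(instrument("X", designed_for_ndd = d, adapted_for_ndd = a,
                    adaptation_note = if (a == "yes") "note" else NULL))
  }
  table4 <- c(
    "yes.yes" = "low", "yes.no" = "low", "yes.cant_tell" = "low",
    "no.yes" = "low", "no.no" = "high", "no.cant_tell" = "high",
    "cant_tell.yes" = "low", "cant_tell.no" = "high",
    "cant_tell.cant_tell" = "unclear")
  for (d in ans) for (a in ans) {
    expect_identical(rate_domain4(single(d, a)),
                     unname(table4[paste(d, a, sep = ".")]),
                     label = sprintf("rate_domain4(%s, %s)", d, a))
  }
  # mixed sets
  pass <- instrument("A", designed_for_ndd = "yes")
  fail <- instrument("B", designed_for_ndd = "no", adapted_for_ndd = "no")
  dark <- instrument("C")  # cant_tell on both
  expect_identical(rate_domain4(list(pass, fail)), "unclear")
  expect_identical(rate_domain4(list(fail, dark)), "unclear")
  expect_identical(rate_domain4(list(pass, pass)), "low")
  expect_identical(rate_domain4(list(fail, fail)), "high")
  expect_error(rate_domain4(list()), "no rateable")
})

test_that("overall aggregation is total, permutation-invariant and matches the principle oracle", {
  levels3 <- c("low", "unclear", "high")
  grid <- expand.grid(a = levels3, b = levels3, c = levels3, d = levels3,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 81L)
  for (i in seq_len(nrow(grid))) {
    v <- unlist(grid[i, ], use.names = FALSE)
    got <- aggregate_overall(v)
    expect_identical(got, oracle_overall(v),
                     label = paste(v, collapse = ","))
    # permutation invariance on a fixed non-trivial permutation and a sort
    expect_identical(aggregate_overall(v[c(3, 1, 4, 2)]), got)
    expect_identical(aggregate_overall(sort(v)), got)
  }
  # unanimity maps to itself
  for (lv in levels3) expect_identical(aggregate_overall(rep(lv, 4)), lv)
  # the documented non-monotonicity witness pair
  expect_identical(aggregate_overall(c("high", "high", "low", "unclear")),
                   "high")
  expect_identical(aggregate_overall(c("high", "high", "unclear", "unclear")),
                   "unclear")
  # display-only level and wrong arity are rejected
  expect_error(aggregate_overall(c("high", "low", "no_information", "low")))
  expect_error(aggregate_overall(c("high", "low", "low")), "four")
})

test_that("sub-question 1a/1b answers follow the overlap evidence", {
  expect_identical(answer_q1a(make_record()), "yes")
  expect_identical(answer_q1a(make_record(items_available = FALSE)),
                   "cant_tell")
  with_ov <- make_record(overlaps = list(make_overlap(addressed = "no")))
  expect_identical(answer_q1a(with_ov), "no")

  expect_identical(answer_q1b(make_record()), "yes")  # vacuous: comparison done
  expect_identical(answer_q1b(make_record(criteria_available = FALSE)),
                   "cant_tell")                       # nothing to compare
  mixed <- make_record(overlaps = list(make_overlap(addressed = "cant_tell"),
                                       make_overlap(addressed = "no")))
  expect_identical(answer_q1b(mixed), "no")
  all_yes <- make_record(overlaps = list(make_overlap(addressed = "yes"),
                                         make_overlap(addressed = "yes")))
  expect_identical(answer_q1b(all_yes), "yes")
  only_ct <- make_record(overlaps = list(make_overlap(addressed = "cant_tell")))
  expect_identical(answer_q1b(only_ct), "cant_tell")
  # and the finding-level risk map
  expect_identical(overlap_finding_risk(c("yes", "no", "cant_tell")),
                   c("low", "high", "unclear"))
})

test_that("wave ages are returned verbatim or interpolated over the follow-up", {
  g <- make_group(age = 10, len = 6, waves = 4L)
  expect_equal(wave_mean_ages(g), c(10, 12, 14, 16))
  g2 <- make_group(wave_ages = c(5, 6.5, 9), waves = 3L)
  expect_equal(wave_mean_ages(g2), c(5, 6.5, 9))
  g3 <- study_group("ASD", 20L, n_waves = 3L)      # no ages derivable
  expect_null(wave_mean_ages(g3))
  g4 <- study_group("ASD", 20L, first_wave_mean_age = 4, n_waves = 1L)
  expect_equal(wave_mean_ages(g4), 4)
})

test_that("under-six answer reacts to any school-age wave and to unknown ages", {
  expect_identical(answer_q2c(make_record(groups = list(
    make_group(age = 2.5, len = 2, waves = 3L)))), "yes")
  expect_identical(answer_q2c(make_record(groups = list(
    make_group(age = 4, len = 4, waves = 3L)))), "no")  # last waves reach 6+
  # one group with a known school-age wave decides even if another is unknown
  r <- make_record(groups = list(make_group(age = 9),
                                 study_group("CP", 10L, n_waves = 3L)))
  expect_identical(answer_q2c(r), "no")
  r2 <- make_record(groups = list(study_group("CP", 10L, n_waves = 3L)))
  expect_identical(answer_q2c(r2), "cant_tell")
})

test_that("self-report feasibility combines functioning bands, ages and wave fractions", {
  # no ID, 9+ at all waves
  expect_identical(answer_q3a(make_record(groups = list(
    make_group(age = 11, len = 6, waves = 3L, category = "no_id", iq = 99)))),
    "yes")
  # moderate/severe ID: never feasible, whatever the age
  expect_identical(answer_q3a(make_record(groups = list(
    make_group(age = 12, len = 5, waves = 3L,
               category = "moderate_severe_id", iq = 53)))), "no")
  # unknown functioning but all waves under the lowest threshold: forced no
  expect_identical(answer_q3a(make_record(groups = list(
    make_group(age = 2.5, len = 2, waves = 3L, category = "unknown")))), "no")
  # unknown functioning, school-age waves: cannot decide
  expect_identical(answer_q3a(make_record(groups = list(
    make_group(age = 10, len = 4, waves = 3L, category = "unknown")))),
    "cant_tell")
  # mild ID applies the 11-year threshold: 9-year-olds are not enough
  expect_identical(answer_q3a(make_record(groups = list(
    make_group(age = 9, len = 1, waves = 3L, category = "mild_id", iq = 60)))),
    "no")
  # exactly half of the waves at the threshold counts as feasible
  expect_identical(answer_q3a(make_record(groups = list(
    make_group(wave_ages = c(7, 8, 9, 10), waves = 4L,
               category = "no_id", iq = 100)))), "yes")
  # just under half is not
  expect_identical(answer_q3a(make_record(groups = list(
    make_group(wave_ages = c(7, 8, 8.5, 9), waves = 4L,
               category = "no_id", iq = 100)))), "no")
  # functioning majority is n-weighted across groups
  r <- make_record(groups = list(
    make_group(n = 10L, age = 12, len = 2, waves = 3L, category = "no_id",
               iq = 100),
    make_group(n = 90L, age = 12, len = 2, waves = 3L,
               category = "moderate_severe_id", iq = 50)))
  expect_identical(answer_q3a(r), "no")
})

test_that("child-rating answer distinguishes no, yes and unknown informants", {
  expect_identical(answer_q3b(make_record(informants = "parent")), "no")
  expect_identical(answer_q3b(make_record(informants = c("parent", "child"))),
                   "yes")
  expect_identical(answer_q3b(make_record(informants = character(0))),
                   "cant_tell")
})

test_that("assess_study is a pure function and wires ratings into the overall", {
  r <- make_record(informants = "parent",
                   groups = list(make_group(age = 10, len = 4, waves = 3L,
                                            category = "no_id", iq = 100)))
  a1 <- assess_study(r)
  a2 <- assess_study(r)
  expect_identical(a1, a2)
  expect_identical(a1$overall,
                   aggregate_overall(vapply(a1$domains, `[[`, character(1),
                                            "rating")))
  expect_length(a1$domains, 4L)
  expect_identical(vapply(a1$domains, `[[`, integer(1), "domain_id"), 1:4)
  # every rationale is non-empty text
  expect_true(all(nzchar(vapply(a1$domains, `[[`, character(1),
                                "rationale"))))
  # invalid records are rejected with study context
  bad <- make_record(id = "broken01", groups = list(make_group(n = -1L)))
  expect_error(assess_study(bad), "broken01")
})
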