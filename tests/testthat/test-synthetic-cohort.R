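test_that("identical seed and config give byte-identical cohorts; seeds differ", {
  cfg <- synth_config(n_studies = 12L, seed = 11L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_cohort(c1, p1); write_cohort(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  c3 <- generate_cohort(synth_config(n_studies = 12L, seed = 12L))
  expect_false(identical(c1, c3))
})

test_that("per-study substreams are counter-derived: extending the cohort does not shift earlier studies", {
  small <- generate_cohort(synth_config(n_studies = 5L, seed = 3L))
  large <- generate_cohort(synth_config(n_studies = 9L, seed = 3L))
  expect_identical(large$studies[1:5], small$studies)
})

test_that("generated records are schema-valid and sized as configured", {
  cohort <- generate_cohort(synth_config(n_studies = 49L, seed = 2L))
  expect_length(cohort$studies, 49L)
  for (s in cohort$studies) {
    rep <- validate_study(s)
    expect_equal(nrow(rep), 0L, label = s$study_id)  # no errors, no warnings
  }
})

test_that("the generator leaves the global RNG stream untouched", {
  set.seed(99); before <- .Random.seed
  invisible(generate_cohort(synth_config(n_studies = 3L, seed = 5L)))
  expect_identical(.Random.seed, before)
})

test_that("degenerate configurations force the corresponding domain ratings", {
  # every instrument designed for the population: domain 4 always low
  all_designed <- generate_cohort(synth_config(
    n_studies = 30L, seed = 4L, p_designed_for_ndd = 1, p_adapted = 0))
  d4 <- vapply(assess_cohort(all_designed),
               function(a) a$domains[[4]]$rating, character(1))
  expect_true(all(d4 == "low"))

  # single informant and school-aged children throughout: domain 2 always high
  single_old <- generate_cohort(synth_config(
    n_studies = 30L, seed = 5L, p_multi_informant = 0, p_child_rated = 0,
    first_wave_age_range = c(6.5, 12)))
  d2 <- vapply(assess_cohort(single_old),
               function(a) a$domains[[2]]$rating, character(1))
  expect_true(all(d2 == "high"))

  # no overlaps anywhere: domain 1 always low
  no_ov <- generate_cohort(synth_config(n_studies = 20L, seed = 6L,
                                        p_overlap_present = 0))
  d1 <- vapply(assess_cohort(no_ov),
               function(a) a$domains[[1]]$rating, character(1))
  expect_true(all(d1 == "low"))
})

test_that("empirical sub-question marginals recover the configured probabilities", {
  # moderate n here keeps the default suite fast; the acceptance suite
  # re-runs this check at n = 2000
  cfg <- synth_config(n_studies = 500L, seed = 8L)
  cohort <- generate_cohort(cfg)
  ass <- assess_cohort(cohort)
  df <- as.data.frame(ass)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  n <- cfg$n_studies

  p_ov <- mean(df$q1a == "no")
  expect_lt(abs(p_ov - cfg$p_overlap_present),
            3 * se(cfg$p_overlap_present, n))
  p_multi <- mean(as.integer(df$q2a) >= 2)
  expect_lt(abs(p_multi - cfg$p_multi_informant),
            3 * se(cfg$p_multi_informant, n))
  p_child <- mean(df$q3b == "yes")
  expect_lt(abs(p_child - cfg$p_child_rated),
            3 * se(cfg$p_child_rated, n))
})

test_that("invalid configurations are rejected before any generation", {
  expect_error(synth_config(p_overlap_present = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(iq_mixture = c(no_id = 0.5, mild_id = 0.5,
                                           moderate_severe_id = 0.5,
                                           unknown = 0.5)), "sum to 1")
  expect_error(synth_config(n_studies = 0), "positive")
  expect_error(synth_config(waves_range = c(5L, 3L)), "waves_range")
})
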