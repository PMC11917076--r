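# Domain 1: conceptual overlap ----------------------------------------------

#' Sub-question 1a: are the outcomes separated from the disability's core
#' characteristics?
#'
#' `"no"` when curated overlap findings exist; `"cant_tell"` when no
#' findings exist but the instrument items and/or the diagnostic criteria
#' needed for the comparison were unavailable; `"yes"` otherwise.
#'
#' @param record a validated [study_record()].
#' @return `"yes"`, `"no"` or `"cant_tell"`.
#' @export
answer_q1a <- function(record) {
  if (length(record$overlaps) > 0L) return("no")
  if (!record$items_available || !record$criteria_available) return("cant_tell")
  "yes"
}

#' Sub-question 1b: were the conceptual overlaps addressed?
#'
#' Per-finding addressed statuses roll up worst-case: any `"no"` gives
#' `"no"`; all `"yes"` gives `"yes"`; otherwise `"cant_tell"` (overlaps
#' mentioned but not fully addressed). With no findings the question is not
#' applicable: it returns a vacuous `"yes"` when the comparison was actually
#' possible (so domain 1 rates low via 1a) and `"cant_tell"` when it was
#' not, so that an unassessable overlap can never rate low.
#'
#' @inheritParams answer_q1a
#' @return `"yes"`, `"no"` or `"cant_tell"`.
#' @export
answer_q1b <- function(record) {
  if (length(record$overlaps) == 0L) {
    return(if (answer_q1a(record) == "yes") "yes" else "cant_tell")
  }
  addressed <- vapply(record$overlaps, `[[`, character(1), "addressed")
  if (any(addressed == "no")) return("no")
  if (all(addressed == "yes")) return("yes")
  "cant_tell"
}

#' Rate domain 1 (conceptual overlap)
#'
#' Low when no overlaps were identified (1a yes) or all overlaps were
#' addressed (1b yes); high when at least one overlap was identified and
#' not addressed (1a no and 1b no); unclear otherwise.
#'
#' @param q1a,q1b answers (`"yes"`/`"no"`/`"cant_tell"`).
#' @return `"low"`, `"unclear"` or `"high"`.
#' @export
rate_domain1 <- function(q1a, q1b) {
  check_enum(q1a, answer_levels(), "q1a")
  check_enum(q1b, answer_levels(), "q1b")
  if (q1a == "yes" || q1b == "yes") return("low")
  if (q1a == "no" && q1b == "no") return("high")
  "unclear"
}

#' Risk attached to a single overlap finding
#'
#' The per-finding risk column of the overlap table: an addressed overlap is
#' low risk, an unaddressed one high, and one merely mentioned but not fully
#' addressed unclear.
#'
#' @param addressed `"yes"`, `"no"` or `"cant_tell"` (vectorised).
#' @return `"low"`, `"high"` or `"unclear"`.
#' @export
#' @examples
#' overlap_finding_risk(c("yes", "no", "cant_tell"))
overlap_finding_risk <- function(addressed) {
  vapply(addressed, function(a) {
    check_enum(a, answer_levels(), "addressed")
    switch(a, yes = "low", no = "high", cant_tell = "unclear")
  }, character(1), USE.NAMES = FALSE)
}

# Wave ages -------------------------------------------------------------------

#' Mean age of a group at each data-collection wave
#'
#' Returns the explicitly extracted per-wave mean ages when present;
#' otherwise estimates them as equally spaced points from the first-wave
#' mean age across the follow-up interval (the estimation used when
#' articles report only the first-wave age and the spacing of waves).
#' Returns `NULL` when the ages cannot be established, which drives
#' "can't tell" answers downstream.
#'
#' @param group a [study_group()].
#' @return Numeric vector of mean ages (years), or `NULL` if unknown.
#' @export
#' @examples
#' g <- study_group("CP", 92, first_wave_mean_age = 2.5,
#'                  followup_length = 2, n_waves = 3)
#' wave_mean_ages(g)  # 2.5 3.5 4.5
wave_mean_ages <- function(group) {
  if (!is.null(group$wave_mean_ages) && length(group$wave_mean_ages) > 0L &&
      !anyNA(group$wave_mean_ages)) {
    return(as.numeric(group$wave_mean_ages))
  }
  a0 <- group$first_wave_mean_age
  if (is.na(a0)) return(NULL)
  k <- group$n_waves
  if (is.na(k)) return(NULL)
  if (k == 1L) return(a0)
  len <- group$followup_length
  if (is.na(len)) return(NULL)
  seq(a0, a0 + len, length.out = k)
}

#' Sub-question 2c: were participants under six at all data points?
#'
#' `"no"` as soon as any known wave mean age reaches school age (even if
#' other waves cannot be established); `"cant_tell"` when no wave reaches
#' school age but ages are unknown for one or more waves; `"yes"` when all
#' waves are known and below school age.
#'
#' @param record a validated [study_record()].
#' @param thresholds a [rubric_thresholds()].
#' @return `"yes"`, `"no"` or `"cant_tell"`.
#' @export
answer_q2c <- function(record, thresholds = rubric_thresholds()) {
  ages <- lapply(record$groups, wave_mean_ages)
  known <- unlist(ages[!vapply(ages, is.null, logical(1))])
  any_unknown <- any(vapply(ages, is.null, logical(1)))
  if (length(known) > 0L && any(known >= thresholds$school_age)) return("no")
  if (any_unknown || length(known) == 0L) return("cant_tell")
  "yes"
}

# Domain 2: informants --------------------------------------------------------

# internal: largest number of distinct informant types on any one outcome;
# 0 means informant information is missing throughout
max_informant_types <- function(record) {
  counts <- vapply(record$outcomes,
                   function(o) length(unique(o$informants)), integer(1))
  if (length(counts) == 0L) 0L else max(counts)
}

#' Rate domain 2 (over-reliance on a single informant)
#'
#' Low when at least one outcome was rated by two or more different
#' informant types, or when the children were below school age at all waves
#' (any number of informants suffices then); unclear when informant or age
#' information is lacking; high when a single informant type was used with
#' children at school age on one or more waves.
#'
#' @param record a validated [study_record()].
#' @param thresholds a [rubric_thresholds()].
#' @return `"low"`, `"unclear"` or `"high"`.
#' @export
rate_domain2 <- function(record, thresholds = rubric_thresholds()) {
  n_inf <- max_informant_types(record)
  if (n_inf >= thresholds$min_informants_school_age) return("low")
  q2c <- answer_q2c(record, thresholds)
  if (q2c == "yes") return("low")
  if (n_inf == 0L || q2c == "cant_tell") return("unclear")
  "high"
}

# Domain 3: the child's perspective -------------------------------------------

# internal: n-weighted majority functioning category across groups.
# Ties break toward the more impaired category (the cautious side for
# presumed self-report feasibility). "unknown" wins only if it alone holds
# the plurality.
majority_functioning <- function(record) {
  cats <- vapply(record$groups, function(g) g$functioning$category,
                 character(1))
  n <- vapply(record$groups, `[[`, integer(1), "n")
  w <- tapply(n, factor(cats, levels = functioning_categories()), sum,
              default = 0L)
  severity <- c(unknown = 0L, no_id = 1L, mild_id = 2L, moderate_severe_id = 3L)
  best <- names(w)[w == max(w)]
  best[which.max(severity[best])]
}

# internal: n-weighted fraction of (group, wave) observations with mean age
# at or above `age`, over groups with derivable ages. NULL if no group has
# derivable ages; attr "complete" is FALSE when some group lacks ages.
wave_age_fraction <- function(record, age) {
  num <- 0; den <- 0; complete <- TRUE
  for (g in record$groups) {
    a <- wave_mean_ages(g)
    if (is.null(a)) { complete <- FALSE; next }
    num <- num + g$n * sum(a >= age)
    den <- den + g$n * length(a)
  }
  if (den == 0) return(NULL)
  structure(num / den, complete = complete)
}

#' Sub-question 3a: was self-report theoretically plausible?
#'
#' Feasibility is judged from the n-weighted majority functioning category
#' across groups and the per-wave mean ages: with no intellectual
#' disability, self-report is plausible when at least half of the waves
#' (fraction >= `wave_fraction_for_feasible`, n-weighted over groups) are at
#' or above the no-ID age threshold (default 9 years); with mild ID the
#' mild-ID threshold applies (default 11); with moderate/severe ID
#' self-report is not considered plausible at any age. When the functioning
#' level is unknown, the answer is forced to `"no"` if most waves fall below
#' the lowest threshold (below it no category would be feasible), and is
#' `"cant_tell"` otherwise; missing age data likewise gives `"cant_tell"`
#' unless the moderate/severe rule already decides.
#'
#' @param record a validated [study_record()].
#' @param thresholds a [rubric_thresholds()].
#' @return `"yes"`, `"no"` or `"cant_tell"`.
#' @export
answer_q3a <- function(record, thresholds = rubric_thresholds()) {
  cat_ <- majority_functioning(record)
  if (cat_ == "moderate_severe_id") return("no")
  frac9 <- wave_age_fraction(record, thresholds$self_report_age_no_id)
  if (cat_ == "unknown") {
    if (!is.null(frac9) && isTRUE(attr(frac9, "complete")) &&
        frac9 < thresholds$wave_fraction_for_feasible) {
      return("no")  # below the lowest threshold at most waves: infeasible
    }                # for every functioning level, known IQ or not
    return("cant_tell")
  }
  age_lim <- if (cat_ == "no_id") thresholds$self_report_age_no_id else
    thresholds$self_report_age_mild_id
  frac <- wave_age_fraction(record, age_lim)
  if (is.null(frac) || !isTRUE(attr(frac, "complete"))) return("cant_tell")
  if (frac >= thresholds$wave_fraction_for_feasible) "yes" else "no"
}

#' Sub-question 3b: did the children rate their own mental health?
#'
#' `"yes"` when at least one outcome was self-rated; `"cant_tell"` when no
#' outcome is known to be self-rated but informant information is missing
#' for some outcome; `"no"` when all outcomes have known informants and
#' none is self-rated.
#'
#' @param record a validated [study_record()].
#' @return `"yes"`, `"no"` or `"cant_tell"`.
#' @export
answer_q3b <- function(record) {
  cr <- vapply(record$outcomes, `[[`, logical(1), "child_rated")
  if (any(cr %in% TRUE)) return("yes")
  if (anyNA(cr)) return("cant_tell")
  "no"
}

#' Rate domain 3 (omission of the child's perspective)
#'
#' Low when self-report was not deemed plausible (3a no) or the children
#' did rate at least one outcome (3b yes); high when no child-reported data
#' exist (3b no) even though child report was deemed feasible (3a yes);
#' unclear when either answer is "can't tell" and no low condition holds.
#'
#' @param q3a,q3b answers (`"yes"`/`"no"`/`"cant_tell"`).
#' @return `"low"`, `"unclear"` or `"high"`.
#' @export
rate_domain3 <- function(q3a, q3b) {
  check_enum(q3a, answer_levels(), "q3a")
  check_enum(q3b, answer_levels(), "q3b")
  if (q3a == "no" || q3b == "yes") return("low")
  if (q3a == "yes" && q3b == "no") return("high")
  "unclear"
}

# Domain 4: instrument suitability --------------------------------------------

#' Rate domain 4 (instruments not designed for or adapted to NDD)
#'
#' An instrument passes when it was designed for the population or
#' explicitly adapted to it. Low when every instrument passes; high when
#' none passes and every instrument has at least one definite negative
#' answer; unclear when some but not all pass, or when for some instrument
#' neither question could be answered.
#'
#' @param instruments list of [instrument()] objects actually used for
#'   mental-health outcomes (non-empty).
#' @return `"low"`, `"unclear"` or `"high"`.
#' @export
rate_domain4 <- function(instruments) {
  if (length(instruments) == 0L) {
    stop("no rateable outcome instruments", call. = FALSE)
  }
  designed <- vapply(instruments, `[[`, character(1), "designed_for_ndd")
  adapted <- vapply(instruments, `[[`, character(1), "adapted_for_ndd")
  passes <- designed == "yes" | adapted == "yes"
  both_unknown <- designed == "cant_tell" & adapted == "cant_tell"
  if (all(passes)) return("low")
  if (!any(passes) && !any(both_unknown)) return("high")
  "unclear"
}

# Overall aggregation ----------------------------------------------------------

#' Aggregate the four domain ratings into an overall rating
#'
#' Three principles: (1) a level assigned strictly more frequently than any
#' other wins; (2) two highs and two lows give `"unclear"`; (3) two
#' definite ratings (high or low) plus two unclears give `"unclear"`. The
#' function is total over all 81 rating vectors, permutation-invariant and
#' unanimity-preserving. `"no_information"` is display-only and rejected.
#'
#' @param ratings character vector of exactly four domain ratings, each
#'   `"low"`, `"unclear"` or `"high"`.
#' @return `"low"`, `"unclear"` or `"high"`.
#' @export
#' @examples
#' aggregate_overall(c("high", "high", "low", "low"))     # "unclear"
#' aggregate_overall(c("high", "high", "low", "unclear")) # "high"
aggregate_overall <- function(ratings) {
  if (length(ratings) != 4L) {
    stop("exactly four domain ratings required", call. = FALSE)
  }
  for (r in ratings) check_enum(r, c("low", "unclear", "high"), "rating")
  counts <- table(factor(ratings, levels = c("low", "unclear", "high")))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)  # principle 1: strict plurality
  "unclear"                           # principles 2 and 3: every tie at the
}                                     # top is a 2-2 split over four ratings

# Study assessment -------------------------------------------------------------

# internal: instruments actually used by the study's outcomes
outcome_instruments <- function(record) {
  used <- unique(tolower(vapply(record$outcomes, `[[`, character(1),
                                "instrument_name")))
  keep <- vapply(record$instruments,
                 function(i) tolower(i$name) %in% used, logical(1))
  record$instruments[keep]
}

# internal: aggregated 4a/4b answers across the instruments in use
answer_q4 <- function(instruments, which = c("designed_for_ndd",
                                             "adapted_for_ndd")) {
  which <- match.arg(which)
  a <- vapply(instruments, `[[`, character(1), which)
  if (any(a == "yes")) return("yes")       # at least one instrument
  if (all(a == "no")) return("no")
  "cant_tell"
}

#' Assess one study against the four-domain rubric
#'
#' Runs every sub-question, rates the four domains, aggregates the overall
#' rating and records a rationale string naming the triggering rule for
#' each rating. A pure function of the record and the thresholds.
#'
#' @param record a [study_record()]; validated first, with errors reported
#'   in the study's context.
#' @param thresholds a [rubric_thresholds()].
#' @return An object of class `ndd_assessment`: a list with `study_id`,
#'   `domains` (four per-domain lists with `domain_id`, `rating`, `answers`
#'   and `rationale`), `overall`, and `finding_risks` (per-overlap risk
#'   levels).
#' @export
#' @seealso [assess_cohort()], [aggregate_overall()]
assess_study <- function(record, thresholds = rubric_thresholds()) {
  stop_if_invalid(record, thresholds)

  q1a <- answer_q1a(record)
  q1b <- answer_q1b(record)
  d1 <- rate_domain1(q1a, q1b)
  r1 <- switch(d1,
    low = if (q1a == "yes") "no item-criterion overlaps identified" else
      "all identified overlaps addressed through design or statistical elements",
    high = "at least one overlap identified and not addressed",
    unclear = if (q1a == "cant_tell")
      "overlap could not be assessed (items and/or criteria unavailable)" else
      "overlaps mentioned but not fully addressed")

  n_inf <- max_informant_types(record)
  informants_used <- sort(unique(unlist(lapply(record$outcomes,
                                               `[[`, "informants"))))
  q2c <- answer_q2c(record, thresholds)
  d2 <- rate_domain2(record, thresholds)
  r2 <- switch(d2,
    low = if (n_inf >= thresholds$min_informants_school_age)
      sprintf("%d informant types rated the same outcome", n_inf) else
      sprintf("single informant acceptable: mean age below %g y at all waves",
              thresholds$school_age),
    high = sprintf(
      "single informant type (%s) with mean age %g y or above at one or more waves",
      paste(informants_used, collapse = "/"), thresholds$school_age),
    unclear = "informant or participant-age information lacking")

  q3a <- answer_q3a(record, thresholds)
  q3b <- answer_q3b(record)
  d3 <- rate_domain3(q3a, q3b)
  r3 <- switch(d3,
    low = if (q3b == "yes") "children rated at least one outcome" else
      "self-report not deemed plausible for this group",
    high = "no child-reported data although self-report was deemed feasible",
    unclear = "feasibility of or presence of child rating could not be established")

  used_instruments <- outcome_instruments(record)
  d4 <- rate_domain4(used_instruments)
  q4a <- answer_q4(used_instruments, "designed_for_ndd")
  q4b <- answer_q4(used_instruments, "adapted_for_ndd")
  r4 <- switch(d4,
    low = "all instruments designed for or adapted to the population",
    high = "no instrument designed for or adapted to the population",
    unclear = "instrument suitability mixed or not extractable")

  domains <- list(
    list(domain_id = 1L, rating = d1,
         answers = list(`1a` = q1a, `1b` = q1b), rationale = r1),
    list(domain_id = 2L, rating = d2,
         answers = list(`2a` = n_inf,
                        `2b` = paste(informants_used, collapse = ";"),
                        `2c` = q2c),
         rationale = r2),
    list(domain_id = 3L, rating = d3,
         answers = list(`3a` = q3a, `3b` = q3b), rationale = r3),
    list(domain_id = 4L, rating = d4,
         answers = list(`4a` = q4a, `4b` = q4b), rationale = r4)
  )

  structure(list(
    study_id = record$study_id,
    domains = domains,
    overall = aggregate_overall(c(d1, d2, d3, d4)),
    finding_risks = overlap_finding_risk(
      vapply(record$overlaps, `[[`, character(1), "addressed"))
  ), class = "ndd_assessment")
}

#' @export
print.ndd_assessment <- function(x, ...) {
  cat(sprintf("<ndd_assessment> %s\n", x$study_id))
  for (d in x$domains) {
    cat(sprintf("  D%d: %-7s (%s)\n", d$domain_id, d$rating, d$rationale))
  }
  cat(sprintf("  Overall: %s\n", x$overall))
  invisible(x)
}

#' Domain and overall ratings of an assessment as a named vector
#' @param x an `ndd_assessment`.
#' @return Named character vector `d1`..`d4`, `overall`.
#' @export
ratings <- function(x) {
  stopifnot(inherits(x, "ndd_assessment"))
  c(stats::setNames(vapply(x$domains, `[[`, character(1), "rating"),
                    paste0("d", 1:4)),
    overall = x$overall)
}

# Cohort assessment -------------------------------------------------------------

#' Assess every study in a cohort
#'
#' @param cohort a cohort file as returned by [read_cohort()] /
#'   [load_fixture()], or a plain list of [study_record()] objects.
#' @param thresholds a [rubric_thresholds()].
#' @return An object of class `ndd_assessment_set`: a list of
#'   `ndd_assessment` objects, with the thresholds attached as an
#'   attribute. Has `print()`, `summary()` (a cohort summary, see
#'   [summarize_cohort()]) and `as.data.frame()` methods.
#' @export
assess_cohort <- function(cohort, thresholds = rubric_thresholds()) {
  records <- cohort_studies(cohort)
  out <- lapply(records, assess_study, thresholds = thresholds)
  structure(out, class = "ndd_assessment_set", thresholds = thresholds,
            records = records)
}

# internal: accept a cohort file or a bare list of records
cohort_studies <- function(cohort) {
  if (inherits(cohort, "ndd_cohort")) return(cohort$studies)
  if (inherits(cohort, "ndd_study")) return(list(cohort))
  if (is.list(cohort) && all(vapply(cohort, inherits, logical(1), "ndd_study"))) {
    return(cohort)
  }
  stop("expected an ndd_cohort or a list of ndd_study records", call. = FALSE)
}

#' @export
print.ndd_assessment_set <- function(x, ...) {
  cat(sprintf("<ndd_assessment_set> %d studies\n", length(x)))
  df <- as.data.frame(x)
  print(df[, c("study_id", "d1", "d2", "d3", "d4", "overall")],
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ndd_assessment_set <- function(x, ...) {
  rows <- lapply(x, function(a) {
    ans <- do.call(c, lapply(a$domains, function(d) {
      stats::setNames(lapply(d$answers, function(v) as.character(v)),
                      paste0("q", names(d$answers)))
    }))
    cbind(data.frame(study_id = a$study_id, stringsAsFactors = FALSE),
          as.data.frame(t(ratings(a)), stringsAsFactors = FALSE),
          as.data.frame(ans, stringsAsFactors = FALSE, check.names = FALSE))
  })
  do.call(rbind, rows)
}
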