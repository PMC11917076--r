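# Cohort-level descriptive and distributional summaries.

# presentation rounding: half-up to one decimal, matching the printed style
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct <- function(num, den) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den, 1L)
}

#' Count a study's scale scores at the most general reported level
#'
#' Within each instrument of a study, total scale scores are counted first;
#' in their absence broad-band scores are counted; specific subscales are
#' counted only when the instrument reports neither a total nor a
#' broad-band score.
#'
#' @param record a [study_record()].
#' @return Integer count of scale scores.
#' @export
#' @examples
#' # a total plus a subscale of the same instrument counts once
count_scale_scores <- function(record) {
  sum(vapply(split_outcomes_by_instrument(record), function(out) {
    lv <- vapply(out, `[[`, character(1), "score_level")
    if (any(lv == "total")) sum(lv == "total")
    else if (any(lv == "broadband")) sum(lv == "broadband")
    else sum(lv == "subscale")
  }, integer(1)))
}

# internal: outcomes grouped by (case-normalized) instrument name
split_outcomes_by_instrument <- function(record) {
  nm <- tolower(vapply(record$outcomes, `[[`, character(1),
                       "instrument_name"))
  split(record$outcomes, nm)
}

# internal: logical flag per outcome: does it survive the counting rule?
counted_outcomes <- function(record) {
  nm <- tolower(vapply(record$outcomes, `[[`, character(1),
                       "instrument_name"))
  lv <- vapply(record$outcomes, `[[`, character(1), "score_level")
  out <- logical(length(nm))
  for (instr in unique(nm)) {
    idx <- nm == instr
    keep_level <- if (any(lv[idx] == "total")) "total"
      else if (any(lv[idx] == "broadband")) "broadband" else "subscale"
    out[idx] <- lv[idx] == keep_level
  }
  out
}

# internal: per-study helper flags used by several percentages
study_flags <- function(record, assessment) {
  ans <- list()
  for (d in assessment$domains) ans <- c(ans, d$answers)
  has_overlap <- length(record$overlaps) > 0L
  list(
    has_overlap = has_overlap,
    unaddressed = has_overlap && any(vapply(record$overlaps, `[[`,
                                            character(1), "addressed") == "no"),
    multi_informant = as.integer(ans$`2a`) >= 2L,
    single_informant_justified =
      as.integer(ans$`2a`) == 1L && identical(ans$`2c`, "yes"),
    child_missing = identical(ans$`3b`, "no"),
    feasible = identical(ans$`3a`, "yes")
  )
}

#' Summarize a cohort of assessed studies
#'
#' Computes the cohort-level descriptive counts and the distributional
#' percentages of the four domain ratings and the overall rating, together
#' with the per-domain prevalence figures (overlap, informants, child
#' perspective, instrument suitability). Percentages are rounded half-up to
#' one decimal; the underlying counts are carried alongside so nothing is
#' lost to rounding.
#'
#' Denominators: studies for study-level percentages; counted scale scores
#' (see [count_scale_scores()]) for `pct_outcomes_with_overlap`; studies
#' with at least one overlap for `pct_overlap_studies_unaddressed`; studies
#' without child rating for `pct_feasible_among_missing`; distinct
#' instrument names (case-insensitive, across the cohort) for
#' `pct_instruments_designed_for_ndd`.
#'
#' @param records list of [study_record()] objects (or an `ndd_cohort`).
#' @param assessments matching `ndd_assessment_set` (aligned by
#'   `study_id`; order may differ).
#' @return An object of class `ndd_summary` (a list; see fields in
#'   Details).
#' @export
summarize_cohort <- function(records, assessments) {
  records <- cohort_studies(records)
  if (length(records) == 0L) stop("no studies", call. = FALSE)
  rec_ids <- vapply(records, `[[`, character(1), "study_id")
  ass_ids <- vapply(assessments, `[[`, character(1), "study_id")
  if (!setequal(rec_ids, ass_ids) || anyDuplicated(rec_ids)) {
    stop("records and assessments must carry the same unique study_ids",
         call. = FALSE)
  }
  assessments <- assessments[match(rec_ids, ass_ids)]

  n_studies <- length(records)
  rl <- c("low", "unclear", "high")

  rating_mat <- t(vapply(assessments,
                         function(a) ratings(a)[1:4], character(4)))
  overall <- vapply(assessments, `[[`, character(1), "overall")

  domain_counts <- t(apply(rating_mat, 2L, function(col)
    table(factor(col, levels = rl))))
  rownames(domain_counts) <- paste0("d", 1:4)
  overall_counts <- table(factor(overall, levels = rl))

  domain_distribution <- round_half_up(100 * domain_counts / n_studies, 1L)
  overall_distribution <- round_half_up(100 * as.vector(overall_counts) /
                                          n_studies, 1L)
  names(overall_distribution) <- rl

  flags <- Map(study_flags, records, assessments)
  get_flag <- function(name) vapply(flags, `[[`, logical(1), name)

  n_with_overlap <- sum(get_flag("has_overlap"))
  n_child_missing <- sum(get_flag("child_missing"))

  # counted scale scores and overlap at the score level: a counted score
  # carries overlap when any curated finding points at an outcome of the
  # same instrument in the same study
  scores_per_study <- vapply(records, count_scale_scores, integer(1))
  overlap_scores <- vapply(records, function(r) {
    keep <- counted_outcomes(r)
    if (!any(keep) || length(r$overlaps) == 0L) return(0L)
    labels <- vapply(r$outcomes, `[[`, character(1), "score_label")
    instr <- tolower(vapply(r$outcomes, `[[`, character(1),
                            "instrument_name"))
    ref_instr <- instr[match(vapply(r$overlaps, `[[`, character(1),
                                    "outcome_ref"), labels)]
    sum(keep & instr %in% ref_instr)
  }, integer(1))

  # distinct instruments in use across the cohort (case-insensitive)
  inst_seen <- new.env(parent = emptyenv())
  for (r in records) {
    for (ins in outcome_instruments(r)) {
      key <- tolower(ins$name)
      prev <- if (is.null(inst_seen[[key]])) "no" else inst_seen[[key]]
      inst_seen[[key]] <- if (prev == "yes" ||
                              ins$designed_for_ndd == "yes") "yes" else
        ins$designed_for_ndd
    }
  }
  inst_names <- ls(inst_seen)
  n_instruments <- length(inst_names)
  n_designed <- sum(vapply(inst_names, function(k)
    identical(inst_seen[[k]], "yes"), logical(1)))

  structure(list(
    n_studies = n_studies,
    total_children = sum(vapply(records, function(r)
      sum(vapply(r$groups, `[[`, integer(1), "n")), integer(1))),
    n_scale_scores = sum(scores_per_study),
    n_distinct_instruments = n_instruments,
    domain_counts = domain_counts,
    domain_distribution = domain_distribution,
    overall_counts = as.vector(overall_counts),
    overall_distribution = overall_distribution,
    pct_outcomes_with_overlap = pct(sum(overlap_scores),
                                    sum(scores_per_study)),
    pct_studies_with_overlap = pct(n_with_overlap, n_studies),
    pct_overlap_studies_unaddressed = pct(sum(get_flag("unaddressed")),
                                          n_with_overlap),
    pct_multi_informant = pct(sum(get_flag("multi_informant")), n_studies),
    pct_single_informant_justified =
      pct(sum(get_flag("single_informant_justified")), n_studies),
    pct_child_missing = pct(n_child_missing, n_studies),
    pct_feasible_among_missing = pct(sum(get_flag("child_missing") &
                                           get_flag("feasible")),
                                     n_child_missing),
    pct_instruments_designed_for_ndd = pct(n_designed, n_instruments)
  ), class = "ndd_summary")
}

#' @export
summary.ndd_assessment_set <- function(object, ...) {
  records <- attr(object, "records")
  if (is.null(records)) {
    stop("assessment set carries no records; call summarize_cohort() directly",
         call. = FALSE)
  }
  summarize_cohort(records, object)
}

#' @export
print.ndd_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d studies, %d participating children\n",
              x$n_studies, x$total_children))
  cat(sprintf("%d scale scores from %d distinct instruments\n",
              x$n_scale_scores, x$n_distinct_instruments))
  cat("\nRisk-of-bias distribution (% of studies):\n")
  m <- rbind(x$domain_distribution,
             overall = x$overall_distribution)
  print(m)
  cat(sprintf("\nStudies with >= 1 item-criterion overlap:  %.1f%%\n",
              x$pct_studies_with_overlap))
  cat(sprintf("  ... of these, with unaddressed overlap:  %.1f%%\n",
              x$pct_overlap_studies_unaddressed))
  cat(sprintf("Counted scores carrying overlap:           %.1f%%\n",
              x$pct_outcomes_with_overlap))
  cat(sprintf("Multi-informant studies:                   %.1f%%\n",
              x$pct_multi_informant))
  cat(sprintf("Single informant justified by young age:   %.1f%%\n",
              x$pct_single_informant_justified))
  cat(sprintf("Child perspective missing:                 %.1f%%\n",
              x$pct_child_missing))
  cat(sprintf("  ... of these, self-report feasible:      %.1f%%\n",
              x$pct_feasible_among_missing))
  cat(sprintf("Instruments designed for NDD:              %.1f%%\n",
              x$pct_instruments_designed_for_ndd))
  invisible(x)
}

#' Study-characteristics descriptives
#'
#' Per-study first- and last-wave mean-age ranges, wave counts, follow-up
#' lengths and group sizes, plus cohort-level totals, ranges and means.
#' Because some published tables report one row per diagnosis group, the
#' cohort means of wave counts and follow-up length are reported both over
#' group rows and over studies (attribute `cohort`).
#'
#' @param records list of [study_record()] objects (or an `ndd_cohort`).
#' @return A data.frame (one row per study) with attribute `cohort`: a list
#'   of cohort-level descriptives.
#' @export
descriptives <- function(records) {
  records <- cohort_studies(records)
  if (length(records) == 0L) stop("no studies", call. = FALSE)
  per_group <- function(r, f) unlist(lapply(r$groups, f))
  rows <- lapply(records, function(r) {
    first <- per_group(r, function(g) g$first_wave_mean_age)
    last <- per_group(r, function(g) {
      a <- wave_mean_ages(g)
      if (is.null(a)) NA_real_ else a[length(a)]
    })
    waves <- per_group(r, function(g) g$n_waves)
    len <- per_group(r, function(g) g$followup_length)
    data.frame(
      study_id = r$study_id,
      n_groups = length(r$groups),
      n_children = sum(per_group(r, function(g) g$n)),
      first_wave_age_min = suppressWarnings(min(first, na.rm = TRUE)),
      first_wave_age_max = suppressWarnings(max(first, na.rm = TRUE)),
      last_wave_age_min = suppressWarnings(min(last, na.rm = TRUE)),
      last_wave_age_max = suppressWarnings(max(last, na.rm = TRUE)),
      followup_min = suppressWarnings(min(len, na.rm = TRUE)),
      followup_max = suppressWarnings(max(len, na.rm = TRUE)),
      waves_min = suppressWarnings(min(waves, na.rm = TRUE)),
      waves_max = suppressWarnings(max(waves, na.rm = TRUE)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  num <- as.matrix(df[, -(1:3)])
  num[!is.finite(num)] <- NA  # empty na.rm ranges become NA
  df[, -(1:3)] <- num

  all_groups <- unlist(lapply(records, `[[`, "groups"), recursive = FALSE)
  g_first <- vapply(all_groups, function(g) g$first_wave_mean_age, numeric(1))
  g_last <- vapply(all_groups, function(g) {
    a <- wave_mean_ages(g)
    if (is.null(a)) NA_real_ else a[length(a)]
  }, numeric(1))
  g_waves <- vapply(all_groups, function(g) as.numeric(g$n_waves), numeric(1))
  g_len <- vapply(all_groups, function(g) g$followup_length, numeric(1))
  attr(df, "cohort") <- list(
    n_studies = length(records),
    total_children = sum(df$n_children),
    first_wave_age_range = range(g_first, na.rm = TRUE),
    last_wave_age_range = range(g_last, na.rm = TRUE),
    followup_range = range(g_len, na.rm = TRUE),
    waves_range = range(g_waves, na.rm = TRUE),
    mean_waves_by_group = mean(g_waves, na.rm = TRUE),
    mean_waves_by_study = mean(rowMeans(df[, c("waves_min", "waves_max")]),
                               na.rm = TRUE),
    mean_followup_by_group = mean(g_len, na.rm = TRUE),
    mean_followup_by_study = mean(rowMeans(df[, c("followup_min",
                                                  "followup_max")]),
                                  na.rm = TRUE)
  )
  df
}
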