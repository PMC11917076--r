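# Cohort file io. JSON is the canonical format (UTF-8, "\n" newlines);
# a CSV export of assessments is provided for spreadsheet work.

SCHEMA_VERSIONS <- "1.0"

#' Construct a cohort container
#'
#' @param studies list of [study_record()] objects with unique ids.
#' @param schema_version schema version string.
#' @return An object of class `ndd_cohort` with fields `schema_version`
#'   and `studies`.
#' @export
new_cohort <- function(studies, schema_version = "1.0") {
  if (!schema_version %in% SCHEMA_VERSIONS) {
    stop(sprintf("unknown schema_version '%s' (supported: %s)",
                 schema_version, paste(SCHEMA_VERSIONS, collapse = ", ")),
         call. = FALSE)
  }
  ids <- vapply(studies, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate study_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(schema_version = schema_version, studies = studies),
            class = "ndd_cohort")
}

#' @export
print.ndd_cohort <- function(x, ...) {
  cat(sprintf("<ndd_cohort> schema %s, %d studies: %s\n", x$schema_version,
              length(x$studies),
              paste(vapply(x$studies, `[[`, character(1), "study_id"),
                    collapse = ", ")))
  invisible(x)
}

# serialization helpers --------------------------------------------------------

na_null <- function(x) if (length(x) == 0L || all(is.na(x))) NULL else x

group_to_list <- function(g) {
  list(diagnosis_label = g$diagnosis_label, n = g$n,
       percent_female = na_null(g$percent_female),
       first_wave_mean_age = na_null(g$first_wave_mean_age),
       followup_length = na_null(g$followup_length),
       n_waves = na_null(g$n_waves),
       wave_mean_ages = g$wave_mean_ages,
       functioning = list(category = g$functioning$category,
                          mean_iq = na_null(g$functioning$mean_iq)))
}

record_to_list <- function(r) {
  list(
    study_id = r$study_id, citation = r$citation,
    items_available = r$items_available,
    criteria_available = r$criteria_available,
    groups = lapply(r$groups, group_to_list),
    outcomes = lapply(r$outcomes, function(o) list(
      instrument_name = o$instrument_name, score_label = o$score_label,
      score_level = o$score_level, construct = o$construct,
      informants = as.list(o$informants),
      child_rated = na_null(o$child_rated))),
    instruments = lapply(r$instruments, function(ins) list(
      name = ins$name, designed_for_ndd = ins$designed_for_ndd,
      adapted_for_ndd = ins$adapted_for_ndd,
      adaptation_note = ins$adaptation_note)),
    overlaps = lapply(r$overlaps, function(ov) list(
      outcome_ref = ov$outcome_ref, item_text = ov$item_text,
      criterion_text = ov$criterion_text,
      criterion_code = ov$criterion_code, match_code = ov$match_code,
      addressed = ov$addressed))
  )
}

opt_num <- function(x, default = NA_real_) {
  if (is.null(x)) default else as.numeric(x)
}

list_to_record <- function(x, study_id = "?") {
  sid <- if (is.null(x$study_id)) study_id else x$study_id
  enum <- function(v, allowed, field) check_enum(v, allowed, field, sid)
  groups <- lapply(x$groups, function(g) {
    cat_ <- if (is.null(g$functioning$category)) "unknown" else
      g$functioning$category
    enum(cat_, functioning_categories(), "functioning$category")
    study_group(
      diagnosis_label = g$diagnosis_label, n = g$n,
      percent_female = opt_num(g$percent_female),
      first_wave_mean_age = opt_num(g$first_wave_mean_age),
      followup_length = opt_num(g$followup_length),
      n_waves = if (is.null(g$n_waves)) NA_integer_ else as.integer(g$n_waves),
      wave_mean_ages = if (is.null(g$wave_mean_ages)) NULL else
        as.numeric(unlist(g$wave_mean_ages)),
      functioning = list(category = cat_,
                         mean_iq = opt_num(g$functioning$mean_iq)))
  })
  outcomes <- lapply(x$outcomes, function(o) {
    enum(o$score_level, score_levels(), "score_level")
    outcome_measure(
      instrument_name = o$instrument_name, score_label = o$score_label,
      score_level = o$score_level,
      construct = if (is.null(o$construct)) "" else o$construct,
      informants = as.character(unlist(o$informants)),
      child_rated = if (is.null(o$child_rated)) NULL else o$child_rated)
  })
  instruments <- lapply(x$instruments, function(ins) {
    enum(ins$designed_for_ndd, answer_levels(), "designed_for_ndd")
    enum(ins$adapted_for_ndd, answer_levels(), "adapted_for_ndd")
    instrument(ins$name, ins$designed_for_ndd, ins$adapted_for_ndd,
               ins$adaptation_note)
  })
  overlaps <- lapply(x$overlaps, function(ov) {
    enum(ov$match_code, c("verbatim", "synonym", "concretisation"),
         "match_code")
    enum(ov$addressed, answer_levels(), "addressed")
    overlap_finding(ov$outcome_ref, ov$item_text, ov$criterion_text,
                    criterion_code = if (is.null(ov$criterion_code)) "" else
                      ov$criterion_code,
                    match_code = ov$match_code, addressed = ov$addressed)
  })
  study_record(
    study_id = x$study_id, citation = if (is.null(x$citation)) "" else
      x$citation,
    groups = groups, outcomes = outcomes, instruments = instruments,
    overlaps = overlaps,
    items_available = isTRUE(x$items_available),
    criteria_available = isTRUE(x$criteria_available))
}

#' Write a cohort to a JSON file
#'
#' The inverse of [read_cohort()]: writing then reading preserves every
#' field of every valid record. Output is UTF-8 with `"\n"` newlines.
#'
#' @param cohort an `ndd_cohort` (see [new_cohort()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ndd_cohort"))
  payload <- list(schema_version = cohort$schema_version,
                  studies = lapply(cohort$studies, record_to_list))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a cohort from a JSON file
#'
#' Parses and validates a cohort file: the schema version must be
#' supported, enumeration values must be legal (errors name the offending
#' field and study), and study ids must be unique.
#'
#' @param path path to a cohort JSON file.
#' @return An `ndd_cohort`.
#' @export
read_cohort <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$schema_version) || !x$schema_version %in% SCHEMA_VERSIONS) {
    stop(sprintf("unknown schema_version '%s' in %s (supported: %s)",
                 if (is.null(x$schema_version)) "<missing>" else
                   x$schema_version,
                 path, paste(SCHEMA_VERSIONS, collapse = ", ")),
         call. = FALSE)
  }
  studies <- lapply(x$studies, list_to_record)
  new_cohort(studies, x$schema_version)
}

#' Load a shipped fixture dataset
#'
#' Two fixtures ship with the package, transcribed from the published
#' review's printed tables:
#' \describe{
#'   \item{`worked_examples`}{an `ndd_cohort` of the four fully worked
#'     example studies (alsem2013, anderson2011, auerbach2008,
#'     baribeau2021) carrying every field needed to reproduce their
#'     printed domain ratings.}
#'   \item{`table3_characteristics`}{a data.frame of the full included-study
#'     characteristics table (one row per diagnosis group: study, diagnosis,
#'     first-wave mean age, n, percent female, follow-up length, wave
#'     count), descriptives only. Cells whose typeset layout was ambiguous
#'     are flagged via the `confidence` column (`"high"`/`"low"`) so
#'     descriptive checks can exclude them.}
#' }
#'
#' Fixtures ship read-only; copy before mutating.
#'
#' @param name `"worked_examples"` or `"table3_characteristics"`.
#' @return An `ndd_cohort` or a data.frame (see above).
#' @export
load_fixture <- function(name = c("worked_examples",
                                  "table3_characteristics")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".json"), package = "robndd")
  if (!nzchar(path)) stop(sprintf("fixture '%s' not installed", name),
                          call. = FALSE)
  if (name == "worked_examples") return(read_cohort(path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$rows
}

#' Export assessments as CSV
#'
#' One row per study: the four domain ratings, the overall rating and
#' every sub-question answer (columns `q1a`, `q1b`, `q2a`, `q2b`, `q2c`,
#' `q3a`, `q3b`, `q4a`, `q4b`).
#'
#' @param assessments an `ndd_assessment_set` (see [assess_cohort()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assessments_csv <- function(assessments, path) {
  df <- as.data.frame(assessments)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
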