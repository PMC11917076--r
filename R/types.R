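# Shared enumerations -------------------------------------------------------

#' Rubric enumerations
#'
#' Fixed vocabularies used throughout the package. `risk_levels()` returns
#' the four display levels; `"no_information"` is used only for display
#' (figure legends) and is never produced by the rubric itself.
#'
#' @return Character vector of allowed values.
#' @export
risk_levels <- function() c("low", "unclear", "high", "no_information")

#' @rdname risk_levels
#' @export
answer_levels <- function() c("yes", "no", "cant_tell")

#' @rdname risk_levels
#' @export
informant_types <- function() c("parent", "teacher", "child", "observation")

#' @rdname risk_levels
#' @export
functioning_categories <- function() {
  c("no_id", "mild_id", "moderate_severe_id", "unknown")
}

#' @rdname risk_levels
#' @export
score_levels <- function() c("total", "broadband", "subscale")

# internal: validate an enum value, with a path for error messages
check_enum <- function(x, allowed, field, study_id = NULL) {
  if (length(x) != 1L || is.na(x) || !x %in% allowed) {
    ctx <- if (is.null(study_id)) "" else sprintf(" in study '%s'", study_id)
    stop(sprintf("invalid value '%s' for %s%s; allowed: %s",
                 paste(x, collapse = ","), field, ctx,
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Normalize an informant label
#'
#' Maps common synonyms onto the four canonical informant types: "mother",
#' "father" and "primary caregiver" become `"parent"`; "self" becomes
#' `"child"`; school or preschool teachers become `"teacher"`.
#'
#' @param x character vector of informant labels.
#' @return character vector of canonical informant types.
#' @export
#' @examples
#' normalize_informant(c("Mother", "primary caregiver", "self"))
normalize_informant <- function(x) {
  if (length(x) == 0L) return(character(0))
  lx <- gsub("[^a-z ]", "", tolower(trimws(x)))
  map <- c(
    parent = "parent", mother = "parent", father = "parent",
    "primary caregiver" = "parent", caregiver = "parent",
    teacher = "teacher", "preschool teacher" = "teacher",
    "school teacher" = "teacher", "schoolteacher" = "teacher",
    child = "child", self = "child", "selfreport" = "child",
    "self report" = "child",
    observation = "observation", observer = "observation",
    "direct observation" = "observation"
  )
  out <- unname(map[lx])
  bad <- is.na(out)
  if (any(bad)) {
    stop(sprintf("unknown informant type(s): %s",
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

# Thresholds -----------------------------------------------------------------

#' Numeric cut-offs of the rubric
#'
#' All numeric thresholds used by the decision tables, with the rubric's
#' published values as defaults: school age starts at 6 years (domain 2);
#' self-report is presumed feasible from age 9 without intellectual
#' disability (ID) and from age 11 with mild ID (domain 3); mean IQ of 70 or
#' above maps to no ID, 55 to below 70 to mild ID, below 55 to
#' moderate/severe ID; two informant types suffice for school-aged samples;
#' and "half or more of the waves" is a fraction of 0.5.
#'
#' @param school_age years; waves at or above this age require multiple
#'   informants (domain 2).
#' @param self_report_age_no_id years; self-report feasibility age without
#'   ID (domain 3).
#' @param self_report_age_mild_id years; feasibility age with mild ID.
#' @param iq_no_id_min IQ points; minimum mean IQ classified as no ID.
#' @param iq_mild_id_min IQ points; minimum mean IQ classified as mild ID.
#' @param min_informants_school_age integer; informant types needed at
#'   school age.
#' @param wave_fraction_for_feasible fraction of waves (>= comparison) that
#'   must be at or above the applicable age for self-report to count as
#'   feasible.
#' @return An object of class `rubric_thresholds`.
#' @export
#' @examples
#' rubric_thresholds()
rubric_thresholds <- function(school_age = 6,
                              self_report_age_no_id = 9,
                              self_report_age_mild_id = 11,
                              iq_no_id_min = 70,
                              iq_mild_id_min = 55,
                              min_informants_school_age = 2L,
                              wave_fraction_for_feasible = 0.5) {
  t <- list(
    school_age = as.numeric(school_age),
    self_report_age_no_id = as.numeric(self_report_age_no_id),
    self_report_age_mild_id = as.numeric(self_report_age_mild_id),
    iq_no_id_min = as.numeric(iq_no_id_min),
    iq_mild_id_min = as.numeric(iq_mild_id_min),
    min_informants_school_age = as.integer(min_informants_school_age),
    wave_fraction_for_feasible = as.numeric(wave_fraction_for_feasible)
  )
  if (any(vapply(t, function(v) !is.finite(v) || v <= 0, logical(1)))) {
    stop("all rubric thresholds must be positive and finite", call. = FALSE)
  }
  if (t$iq_mild_id_min >= t$iq_no_id_min) {
    stop("iq_mild_id_min must be below iq_no_id_min", call. = FALSE)
  }
  structure(t, class = "rubric_thresholds")
}

#' @export
print.rubric_thresholds <- function(x, ...) {
  cat("Rubric thresholds:\n")
  cat(sprintf("  school age:                 %g y\n", x$school_age))
  cat(sprintf("  self-report age (no ID):    %g y\n", x$self_report_age_no_id))
  cat(sprintf("  self-report age (mild ID):  %g y\n", x$self_report_age_mild_id))
  cat(sprintf("  IQ bands: no ID >= %g, mild ID [%g, %g)\n",
              x$iq_no_id_min, x$iq_mild_id_min, x$iq_no_id_min))
  cat(sprintf("  informants at school age:   >= %d types\n",
              x$min_informants_school_age))
  cat(sprintf("  feasible wave fraction:     >= %g\n",
              x$wave_fraction_for_feasible))
  invisible(x)
}

#' Classify mean IQ into a functioning category
#'
#' Half-open bands: mean IQ at or above `iq_no_id_min` (default 70) is
#' `"no_id"`; from `iq_mild_id_min` (default 55) up to but excluding 70 is
#' `"mild_id"`; below 55 is `"moderate_severe_id"`. An IQ of exactly 70
#' therefore classifies as no ID, following the explicit "IQ < 70"
#' definition of intellectual disability.
#'
#' @param mean_iq numeric vector of group mean IQs (NA allowed).
#' @param thresholds a [rubric_thresholds()] object.
#' @return character vector of functioning categories (`"unknown"` for NA).
#' @export
#' @examples
#' iq_category(c(99.1, 70, 69.9, 58, 53, NA))
iq_category <- function(mean_iq, thresholds = rubric_thresholds()) {
  out <- rep("unknown", length(mean_iq))
  known <- !is.na(mean_iq)
  out[known & mean_iq >= thresholds$iq_no_id_min] <- "no_id"
  out[known & mean_iq < thresholds$iq_no_id_min &
        mean_iq >= thresholds$iq_mild_id_min] <- "mild_id"
  out[known & mean_iq < thresholds$iq_mild_id_min] <- "moderate_severe_id"
  out
}

# Record constructors --------------------------------------------------------

#' Intellectual functioning of a study group
#'
#' @param category one of `"no_id"`, `"mild_id"`, `"moderate_severe_id"`,
#'   `"unknown"`; if `NULL` it is derived from `mean_iq`.
#' @param mean_iq optional group mean IQ (points).
#' @param thresholds a [rubric_thresholds()] object used to derive or check
#'   the category.
#' @return A list with elements `category` and `mean_iq`.
#' @export
intellectual_functioning <- function(category = NULL, mean_iq = NA_real_,
                                     thresholds = rubric_thresholds()) {
  mean_iq <- as.numeric(mean_iq)
  if (is.null(category)) {
    category <- iq_category(mean_iq, thresholds)
  }
  check_enum(category, functioning_categories(), "functioning$category")
  list(category = category, mean_iq = mean_iq)
}

#' One diagnosis group within a study
#'
#' @param diagnosis_label label of the diagnosis (e.g. `"ASD"`).
#' @param n number of children (positive integer).
#' @param percent_female optional percentage in \[0, 100\].
#' @param first_wave_mean_age optional mean age (years) at the first wave.
#' @param followup_length optional years between first and last wave.
#' @param n_waves optional number of data-collection waves (>= 1).
#' @param wave_mean_ages optional explicit non-decreasing mean ages, one per
#'   wave; if absent, ages are estimated from the first-wave age and the
#'   follow-up interval (see [wave_mean_ages()]).
#' @param functioning an [intellectual_functioning()] list.
#' @return A list of class `ndd_group`.
#' @export
study_group <- function(diagnosis_label, n,
                        percent_female = NA_real_,
                        first_wave_mean_age = NA_real_,
                        followup_length = NA_real_,
                        n_waves = NA_integer_,
                        wave_mean_ages = NULL,
                        functioning = intellectual_functioning()) {
  structure(list(
    diagnosis_label = as.character(diagnosis_label),
    n = as.integer(n),
    percent_female = as.numeric(percent_female),
    first_wave_mean_age = as.numeric(first_wave_mean_age),
    followup_length = as.numeric(followup_length),
    n_waves = as.integer(n_waves),
    wave_mean_ages = if (is.null(wave_mean_ages)) NULL else
      as.numeric(wave_mean_ages),
    functioning = functioning
  ), class = "ndd_group")
}

#' A mental-health outcome score reported by a study
#'
#' `informants` may be empty only when the article does not report who
#' rated the outcome; empty informant sets propagate to "can't tell"
#' answers downstream. When informants are reported, `child_rated` must
#' equal `"child" %in% informants` (it defaults to exactly that).
#'
#' @param instrument_name name of the instrument the score comes from; must
#'   match an entry in the study's instrument list.
#' @param score_label label of the score (e.g. `"Total"`,
#'   `"Hyperactivity subscale"`); unique within the study.
#' @param score_level `"total"`, `"broadband"` or `"subscale"`.
#' @param construct free-text mental-health construct measured.
#' @param informants character vector of informant types (normalized via
#'   [normalize_informant()]).
#' @param child_rated logical; `NA` when informants are unknown.
#' @return A list of class `ndd_outcome`.
#' @export
outcome_measure <- function(instrument_name, score_label,
                            score_level = c("total", "broadband", "subscale"),
                            construct = "",
                            informants = character(0),
                            child_rated = NULL) {
  score_level <- match.arg(score_level)
  informants <- sort(unique(normalize_informant(informants)))
  if (is.null(child_rated)) {
    child_rated <- if (length(informants) == 0L) NA else
      "child" %in% informants
  }
  structure(list(
    instrument_name = as.character(instrument_name),
    score_label = as.character(score_label),
    score_level = score_level,
    construct = as.character(construct),
    informants = informants,
    child_rated = as.logical(child_rated)
  ), class = "ndd_outcome")
}

#' An instrument used to measure a mental-health outcome
#'
#' @param name instrument name (non-empty).
#' @param designed_for_ndd was the instrument explicitly developed for
#'   children with NDD? (`"yes"` / `"no"` / `"cant_tell"`).
#' @param adapted_for_ndd were adaptations for the study group explicitly
#'   mentioned? A `"yes"` requires `adaptation_note`.
#' @param adaptation_note free text describing the adaptation.
#' @return A list of class `ndd_instrument`.
#' @export
instrument <- function(name,
                       designed_for_ndd = c("cant_tell", "yes", "no"),
                       adapted_for_ndd = c("cant_tell", "yes", "no"),
                       adaptation_note = NULL) {
  designed_for_ndd <- match.arg(designed_for_ndd)
  adapted_for_ndd <- match.arg(adapted_for_ndd)
  structure(list(
    name = as.character(name),
    designed_for_ndd = designed_for_ndd,
    adapted_for_ndd = adapted_for_ndd,
    adaptation_note = if (is.null(adaptation_note)) NULL else
      as.character(adaptation_note)
  ), class = "ndd_instrument")
}

#' A curated item-criterion overlap finding
#'
#' One identified overlap between an instrument item and a diagnostic
#' criterion of the study population. `match_code` records how the overlap
#' manifests: verbatim similarity, a synonymic relationship, or one text
#' being a more concrete example of the other (concretisation).
#'
#' @param outcome_ref `score_label` of the outcome the item belongs to;
#'   must resolve within the study.
#' @param item_text the instrument item (non-empty).
#' @param criterion_text the diagnostic criterion (non-empty).
#' @param criterion_code locator in the diagnostic manual
#'   (e.g. `"ASD A3, DSM-5"`).
#' @param match_code `"verbatim"`, `"synonym"` or `"concretisation"`.
#' @param addressed was the overlap addressed through design or statistical
#'   elements? (`"yes"` / `"no"` / `"cant_tell"`).
#' @return A list of class `ndd_overlap`.
#' @export
overlap_finding <- function(outcome_ref, item_text, criterion_text,
                            criterion_code = "",
                            match_code = c("verbatim", "synonym",
                                           "concretisation"),
                            addressed = c("cant_tell", "yes", "no")) {
  match_code <- match.arg(match_code)
  addressed <- match.arg(addressed)
  structure(list(
    outcome_ref = as.character(outcome_ref),
    item_text = as.character(item_text),
    criterion_text = as.character(criterion_text),
    criterion_code = as.character(criterion_code),
    match_code = match_code,
    addressed = addressed
  ), class = "ndd_overlap")
}

#' One included study, as extracted for assessment
#'
#' @param study_id unique identifier within a cohort (e.g. `"alsem2013"`).
#' @param citation human-readable citation.
#' @param groups list of [study_group()] objects (>= 1).
#' @param outcomes list of [outcome_measure()] objects (>= 1).
#' @param instruments list of [instrument()] objects; every instrument name
#'   used by an outcome must appear here.
#' @param overlaps list of [overlap_finding()] objects (possibly empty).
#' @param items_available were the instrument items available for the
#'   overlap comparison?
#' @param criteria_available were the diagnostic criteria available?
#' @return A list of class `ndd_study`.
#' @export
#' @examples
#' s <- study_record(
#'   study_id = "demo2020",
#'   groups = list(study_group("ASD", n = 40, first_wave_mean_age = 7,
#'                             followup_length = 4, n_waves = 3)),
#'   outcomes = list(outcome_measure("SDQ", "Total difficulties", "total",
#'                                   informants = c("parent", "teacher"))),
#'   instruments = list(instrument("SDQ", designed_for_ndd = "no",
#'                                 adapted_for_ndd = "no"))
#' )
#' validate_study(s)
study_record <- function(study_id, citation = "", groups, outcomes,
                         instruments = list(), overlaps = list(),
                         items_available = TRUE, criteria_available = TRUE) {
  structure(list(
    study_id = as.character(study_id),
    citation = as.character(citation),
    groups = groups,
    outcomes = outcomes,
    instruments = instruments,
    overlaps = overlaps,
    items_available = isTRUE(items_available),
    criteria_available = isTRUE(criteria_available)
  ), class = "ndd_study")
}

#' @export
print.ndd_study <- function(x, ...) {
  cat(sprintf("<ndd_study> %s (%s)\n", x$study_id,
              if (nzchar(x$citation)) x$citation else "no citation"))
  cat(sprintf("  groups: %d (total n = %d); outcomes: %d; instruments: %d; overlaps: %d\n",
              length(x$groups),
              sum(vapply(x$groups, `[[`, integer(1), "n")),
              length(x$outcomes), length(x$instruments), length(x$overlaps)))
  invisible(x)
}

# Validation -----------------------------------------------------------------

report_row <- function(severity, field, message) {
  data.frame(severity = severity, field = field, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a study record
#'
#' Checks every structural invariant of the extraction schema and returns a
#' report of errors and warnings. Errors are invariant violations (the
#' record cannot be rated); warnings flag deviations from the review's
#' eligibility rules: fewer than three data-collection waves or less than
#' two years between the first and last wave.
#'
#' Validation is deterministic and idempotent.
#'
#' @param record an [study_record()] object.
#' @param thresholds a [rubric_thresholds()] object (for IQ-band
#'   consistency checks).
#' @return A data.frame of class `ndd_validation` with columns `severity`
#'   (`"error"`/`"warning"`), `field` and `message`.
#' @export
validate_study <- function(record, thresholds = rubric_thresholds()) {
  out <- report_row(character(0), character(0), character(0))
  err <- function(field, msg) out <<- rbind(out, report_row("error", field, msg))
  wrn <- function(field, msg) out <<- rbind(out, report_row("warning", field, msg))

  if (!is.character(record$study_id) || !nzchar(record$study_id)) {
    err("study_id", "study_id must be a non-empty string")
  }
  if (length(record$groups) < 1L) err("groups", "at least one group required")
  if (length(record$outcomes) < 1L) err("outcomes", "at least one outcome required")

  for (i in seq_along(record$groups)) {
    g <- record$groups[[i]]
    fld <- sprintf("groups[%d]", i)
    if (is.na(g$n) || g$n <= 0L) err(fld, "group size must be positive")
    if (!is.na(g$percent_female) &&
        (g$percent_female < 0 || g$percent_female > 100)) {
      err(fld, "percent_female must be in [0, 100]")
    }
    if (!is.na(g$first_wave_mean_age) && g$first_wave_mean_age < 0) {
      err(fld, "first_wave_mean_age must be non-negative")
    }
    if (!is.na(g$followup_length) && g$followup_length < 0) {
      err(fld, "followup_length must be non-negative")
    }
    if (!is.na(g$n_waves) && g$n_waves < 1L) {
      err(fld, "n_waves must be at least 1")
    }
    if (!is.null(g$wave_mean_ages)) {
      if (!is.na(g$n_waves) && length(g$wave_mean_ages) != g$n_waves) {
        err(fld, "wave_mean_ages length must equal n_waves")
      }
      if (is.unsorted(g$wave_mean_ages)) {
        err(fld, "wave_mean_ages must be non-decreasing")
      }
    }
    f <- g$functioning
    if (!f$category %in% functioning_categories()) {
      err(fld, sprintf("unknown functioning category '%s'", f$category))
    } else if (!is.na(f$mean_iq) &&
               f$category != iq_category(f$mean_iq, thresholds)) {
      err(fld, sprintf(
        "functioning category '%s' inconsistent with mean IQ %.1f (expected '%s')",
        f$category, f$mean_iq, iq_category(f$mean_iq, thresholds)))
    }
    # eligibility rule: >= 3 waves, >= 2 years between first and last wave
    if (!is.na(g$n_waves) && g$n_waves < 3L) {
      wrn(fld, sprintf(
        "n_waves = %d: eligibility required at least three waves of data collection",
        g$n_waves))
    }
    if (!is.na(g$followup_length) && g$followup_length < 2) {
      wrn(fld, sprintf(
        "followup_length = %.2f y: eligibility required two or more years between first and last wave",
        g$followup_length))
    }
  }

  inst_names <- vapply(record$instruments, `[[`, character(1), "name")
  if (any(!nzchar(inst_names))) {
    err("instruments", "instrument names must be non-empty")
  }
  if (anyDuplicated(tolower(inst_names))) {
    err("instruments", "duplicate instrument names")
  }
  for (i in seq_along(record$instruments)) {
    ins <- record$instruments[[i]]
    if (identical(ins$adapted_for_ndd, "yes") &&
        (is.null(ins$adaptation_note) || !nzchar(ins$adaptation_note))) {
      err(sprintf("instruments[%d]", i),
          "adaptation_note required when adapted_for_ndd = 'yes'")
    }
  }

  out_labels <- vapply(record$outcomes, `[[`, character(1), "score_label")
  if (anyDuplicated(out_labels)) {
    err("outcomes", "duplicate outcome score_label")
  }
  for (i in seq_along(record$outcomes)) {
    o <- record$outcomes[[i]]
    fld <- sprintf("outcomes[%d]", i)
    if (!tolower(o$instrument_name) %in% tolower(inst_names)) {
      err(fld, sprintf("instrument '%s' not listed in instruments",
                       o$instrument_name))
    }
    if (length(o$informants) > 0L &&
        !identical(o$child_rated, "child" %in% o$informants)) {
      err(fld, "child_rated must be true iff 'child' is an informant")
    }
    if (length(o$informants) == 0L && isTRUE(o$child_rated)) {
      err(fld, "child_rated = TRUE requires 'child' among informants")
    }
  }

  for (i in seq_along(record$overlaps)) {
    ov <- record$overlaps[[i]]
    fld <- sprintf("overlaps[%d]", i)
    if (!nzchar(ov$item_text)) err(fld, "item_text must be non-empty")
    if (!nzchar(ov$criterion_text)) err(fld, "criterion_text must be non-empty")
    if (!ov$outcome_ref %in% out_labels) {
      err(fld, sprintf("outcome_ref '%s' does not resolve to any outcome",
                       ov$outcome_ref))
    }
  }

  structure(out, class = c("ndd_validation", "data.frame"))
}

#' @export
print.ndd_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Study record valid: no errors, no warnings.\n")
    return(invisible(x))
  }
  for (sev in c("error", "warning")) {
    rows <- x[x$severity == sev, , drop = FALSE]
    if (nrow(rows) > 0L) {
      cat(sprintf("%ss:\n", sev))
      for (i in seq_len(nrow(rows))) {
        cat(sprintf("  [%s] %s\n", rows$field[i], rows$message[i]))
      }
    }
  }
  invisible(x)
}

# internal helper used across modules
validation_errors <- function(report) {
  report[report$severity == "error", , drop = FALSE]
}

stop_if_invalid <- function(record, thresholds = rubric_thresholds()) {
  rep <- validate_study(record, thresholds)
  errs <- validation_errors(rep)
  if (nrow(errs) > 0L) {
    stop(sprintf("study '%s' fails validation: %s", record$study_id,
                 paste(sprintf("[%s] %s", errs$field, errs$message),
                       collapse = "; ")), call. = FALSE)
  }
  invisible(record)
}
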