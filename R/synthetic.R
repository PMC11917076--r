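# Seeded synthetic cohorts with configurable categorical structure.
#
# The generator emulates the categorical skeleton the rubric consumes --
# sub-question marginals, group sizes, wave structure, functioning mix --
# not realistic item text (overlap findings carry placeholder wording).

#' Configuration for the synthetic-cohort generator
#'
#' Defaults reproduce the categorical structure reported for the reviewed
#' cohort of 49 longitudinal NDD studies: 44.9% of studies carry at least
#' one item-criterion overlap; identified overlaps are mostly unaddressed
#' (per-finding addressed distribution no/cant_tell/yes = .773/.127/.100);
#' 12.2% of studies take a multi-informant approach; 12.2% include child
#' self-report; 8.8% of instruments were designed for the population and
#' none were adapted; first-wave mean ages span 0.51-12.30 years, wave
#' counts 3-17 and follow-up lengths 2.00-16.74 years. The functioning
#' mixture is a package choice (see the methods vignette), since the
#' review reports no cohort-wide IQ distribution.
#'
#' @param n_studies number of studies to generate.
#' @param seed integer seed; the cohort is a pure function of
#'   (seed, config).
#' @param p_overlap_present probability a study carries >= 1 overlap
#'   finding.
#' @param p_overlap_addressed named probabilities (`yes`, `no`,
#'   `cant_tell`) for each finding's addressed status; must sum to 1.
#' @param p_multi_informant probability a study rates an outcome with two
#'   informant types.
#' @param p_child_rated probability a study includes child self-report.
#' @param p_designed_for_ndd probability an instrument was designed for
#'   children with NDD.
#' @param p_adapted probability an instrument was explicitly adapted.
#' @param first_wave_age_range range (years) of first-wave mean ages.
#' @param waves_range integer range of wave counts.
#' @param followup_range range (years) of follow-up lengths.
#' @param iq_mixture named probabilities over functioning categories
#'   (`no_id`, `mild_id`, `moderate_severe_id`, `unknown`); must sum to 1.
#' @param instruments_range integer range of instruments per study.
#' @param n_range integer range of children per group.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_studies = 49L,
                         seed = 1L,
                         p_overlap_present = 0.449,
                         p_overlap_addressed = c(yes = 0.100, no = 0.773,
                                                 cant_tell = 0.127),
                         p_multi_informant = 0.122,
                         p_child_rated = 0.122,
                         p_designed_for_ndd = 0.088,
                         p_adapted = 0,
                         first_wave_age_range = c(0.51, 12.30),
                         waves_range = c(3L, 17L),
                         followup_range = c(2.00, 16.74),
                         iq_mixture = c(no_id = 0.35, mild_id = 0.15,
                                        moderate_severe_id = 0.15,
                                        unknown = 0.35),
                         instruments_range = c(1L, 3L),
                         n_range = c(10L, 450L)) {
  cfg <- list(
    n_studies = as.integer(n_studies), seed = as.integer(seed),
    p_overlap_present = p_overlap_present,
    p_overlap_addressed = p_overlap_addressed[c("yes", "no", "cant_tell")],
    p_multi_informant = p_multi_informant,
    p_child_rated = p_child_rated,
    p_designed_for_ndd = p_designed_for_ndd,
    p_adapted = p_adapted,
    first_wave_age_range = as.numeric(first_wave_age_range),
    waves_range = as.integer(waves_range),
    followup_range = as.numeric(followup_range),
    iq_mixture = iq_mixture[functioning_categories()],
    instruments_range = as.integer(instruments_range),
    n_range = as.integer(n_range)
  )
  probs <- c(cfg$p_overlap_present, cfg$p_overlap_addressed,
             cfg$p_multi_informant, cfg$p_child_rated,
             cfg$p_designed_for_ndd, cfg$p_adapted, cfg$iq_mixture)
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$p_overlap_addressed) - 1) > 1e-8) {
    stop("p_overlap_addressed must sum to 1", call. = FALSE)
  }
  if (abs(sum(cfg$iq_mixture) - 1) > 1e-8) {
    stop("iq_mixture must sum to 1", call. = FALSE)
  }
  if (cfg$n_studies < 1L) stop("n_studies must be positive", call. = FALSE)
  if (cfg$waves_range[1] < 1L || diff(cfg$waves_range) < 0) {
    stop("invalid waves_range", call. = FALSE)
  }
  if (diff(cfg$first_wave_age_range) < 0 || diff(cfg$followup_range) < 0 ||
      diff(cfg$n_range) < 0 || diff(cfg$instruments_range) < 0) {
    stop("ranges must be non-decreasing", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# internal: derive a per-study substream seed from (cohort seed, counter),
# so that study i's draws do not depend on how many studies precede it.
# Knuth multiplicative hash folded into the 31-bit range R accepts.
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 2654435) %% 2147483647)
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate a schema-valid synthetic cohort
#'
#' Draws `n_studies` study records whose categorical structure follows the
#' configured marginals. Dependencies that the schema enforces are built
#' structurally, never probabilistically: a child-rated study always lists
#' the child among the informants, adapted instruments carry an adaptation
#' note, and every record passes [validate_study()] with zero errors.
#' Identical (seed, config) pairs give identical cohorts; the global RNG
#' state is restored on exit.
#'
#' @param config a [synth_config()].
#' @return An `ndd_cohort` (as from [read_cohort()]) with
#'   `config$n_studies` studies.
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_studies = 5, seed = 42))
#' length(cohort$studies)
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  studies <- lapply(seq_len(config$n_studies), function(i) {
    set.seed(substream_seed(config$seed, i))
    synth_study(config, i)
  })
  new_cohort(studies)
}

# internal: one synthetic study under the current RNG substream
synth_study <- function(cfg, i) {
  diagnosis <- sample(c("ASD", "ADHD", "CP", "ID", "Fragile X", "TBI",
                        "Hearing", "Spina bifida", "DD"), 1L)
  n <- sample(seq(cfg$n_range[1], cfg$n_range[2]), 1L)
  first_age <- runif1(cfg$first_wave_age_range)
  n_waves <- sample(seq(cfg$waves_range[1], cfg$waves_range[2]), 1L)
  followup <- runif1(cfg$followup_range)
  fcat <- sample(functioning_categories(), 1L, prob = cfg$iq_mixture)
  mean_iq <- switch(fcat,
    no_id = round(stats::runif(1, 85, 115), 1),
    mild_id = round(stats::runif(1, 55, 69.5), 1),
    moderate_severe_id = round(stats::runif(1, 30, 54.5), 1),
    unknown = NA_real_)
  group <- study_group(diagnosis, n,
                       percent_female = round(stats::runif(1, 0, 60), 1),
                       first_wave_mean_age = round(first_age, 2),
                       followup_length = round(followup, 2),
                       n_waves = n_waves,
                       functioning = intellectual_functioning(fcat, mean_iq))

  # informant structure drawn so the study-level marginals stay exact:
  # multi-informant and child-rated are independent coin flips; the
  # informant sets then realise both flags structurally
  multi <- stats::runif(1) < cfg$p_multi_informant
  child <- stats::runif(1) < cfg$p_child_rated
  informants <- if (multi && child) c("parent", "child")
    else if (multi) c("parent", "teacher")
    else if (child) "child" else "parent"

  n_inst <- sample(seq(cfg$instruments_range[1], cfg$instruments_range[2]), 1L)
  instruments <- lapply(seq_len(n_inst), function(j) {
    designed <- if (stats::runif(1) < cfg$p_designed_for_ndd) "yes" else "no"
    adapted <- if (stats::runif(1) < cfg$p_adapted) "yes" else "no"
    instrument(sprintf("Synthetic Scale %d-%d", i, j),
               designed_for_ndd = designed, adapted_for_ndd = adapted,
               adaptation_note = if (adapted == "yes")
                 "interview administration with explained items" else NULL)
  })
  outcomes <- lapply(seq_len(n_inst), function(j) {
    outcome_measure(sprintf("Synthetic Scale %d-%d", i, j),
                    score_label = sprintf("Scale %d total", j),
                    score_level = "total",
                    construct = "emotional and behavioural problems",
                    informants = informants)
  })

  overlaps <- list()
  if (stats::runif(1) < cfg$p_overlap_present) {
    n_ov <- sample(1:3, 1L)
    status <- sample(names(cfg$p_overlap_addressed), n_ov, replace = TRUE,
                     prob = cfg$p_overlap_addressed)
    overlaps <- lapply(seq_len(n_ov), function(k) {
      overlap_finding(outcome_ref = "Scale 1 total",
                      item_text = sprintf("placeholder item %d", k),
                      criterion_text = sprintf("placeholder criterion %d", k),
                      criterion_code = sprintf("%s A%d", diagnosis, k),
                      match_code = sample(c("verbatim", "synonym",
                                            "concretisation"), 1L),
                      addressed = status[k])
    })
  }

  study_record(
    study_id = sprintf("synth%04d", i),
    citation = sprintf("Synthetic study %d (%s)", i, diagnosis),
    groups = list(group), outcomes = outcomes,
    instruments = instruments, overlaps = overlaps,
    items_available = TRUE, criteria_available = TRUE)
}
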