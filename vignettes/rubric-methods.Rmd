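---
title: "The four-domain measurement rubric: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The four-domain measurement rubric: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robndd)
```

## What the engine models

`robndd` encodes a supplementary risk-of-bias rubric for longitudinal
studies of mental-health problems in children with neurodevelopmental
disorders (NDD). It is not a statistical model: it is a deterministic
classifier. Four measurement-related bias domains are each rated
`low` / `unclear` / `high` by a decision table over categorical
sub-question answers (`yes` / `no` / `cant_tell`), and the four ratings
aggregate into an overall judgement. The engine's unit of analysis is the
*study extraction*: group-level means (ages, IQ), the outcome scores
reported, their informants, the instruments used, and curated
item–criterion overlap findings. Individual participants are never
modelled.

Two assumptions run through everything:

* **Group means stand in for groups.** Ages and IQ are study-group means;
  "children aged 9 or older" means "group mean age ≥ 9". This mirrors how
  the evidence is reported and keeps the rubric computable from published
  tables.
* **Unknowns stay unknown.** Missing fields are represented explicitly and
  propagate to `cant_tell` answers and `unclear` ratings. Nothing is
  imputed.

## The decision tables

*Domain 1 (conceptual overlap).* `q1a` is `no` whenever curated overlap
findings exist, `cant_tell` when the items or criteria needed for the
comparison were unavailable, else `yes`. `q1b` rolls per-finding
`addressed` statuses up worst-case (any `no` → `no`; all `yes` → `yes`;
else `cant_tell`). Rating: low iff `q1a = yes` or `q1b = yes`; high iff
both are `no`; unclear otherwise. One subtlety: with zero findings `q1b`
is vacuously `yes` *only when the comparison was actually possible*
(`q1a = yes`). If items or criteria were unavailable, a literal vacuous
`yes` would rate the domain low even though the overlap could not be
assessed; the engine returns `cant_tell` instead so the rating stays
unclear, as the response options demand. Each finding also carries its own
risk level (`overlap_finding_risk()`: addressed → low, unaddressed → high,
merely mentioned → unclear), reproducing the finding-level column of the
published worked examples.

*Domain 2 (informants).* Low when any single outcome was rated by at least
`min_informants_school_age` (default 2) distinct informant types, or when
group mean age stayed below `school_age` (6 y) at every wave; high when a
single informant type met school-aged children at any wave; unclear when
informant identity or ages cannot be established. Establishing two
informant types short-circuits the age question: the rating is low even if
ages are unknown.

*Domain 3 (the child's perspective).* `q3a` (was self-report plausible?)
combines the functioning band with wave ages: no ID → feasible from
`self_report_age_no_id` (9 y); mild ID → from `self_report_age_mild_id`
(11 y, reflecting evidence that standard self-report instruments work from
that age in mild intellectual disability); moderate/severe ID → never.
"At half or more of the waves" is a `>=` comparison on the fraction of
waves meeting the age condition — exactly half counts as feasible. Rating:
low iff `q3a = no` or `q3b = yes` (children rated something); high iff
feasible yet nothing child-rated; unclear otherwise.

*Domain 4 (instrument suitability).* An instrument *passes* when it was
designed for the population or explicitly adapted to it. Low iff all
outcome instruments pass; high iff none passes and every instrument has at
least one definite negative; unclear for mixtures or when neither question
could be answered for some instrument. The sub-question wording speaks of
"at least one of the instruments" while the rating wording requires "all
instruments"; the engine resolves this per instrument (all / some / none
pass), which matches the rating-level response options exactly.

*Overall aggregation.* Strict plurality wins; two highs + two lows →
unclear; two definite + two unclear → unclear. Over four ratings these
three principles are exhaustive: any tie at the top of the count vector is
a 2–2 split, and every 2–2 split falls under principle 2 or 3. The rule is
permutation-invariant and unanimity-preserving but intentionally
non-monotone — (high, high, low, unclear) → high, yet
(high, high, unclear, unclear) → unclear — and the test suite pins this
witness pair so a "simplification" that changes the tie semantics fails.

## Thresholds

All cut-offs sit in one configurable object:

```{r}
rubric_thresholds()
```

Defaults are the rubric's published values and the acceptance tests pin
them. IQ bands are half-open: mean IQ exactly 70 classifies as no ID
(the intellectual-disability definition is explicitly "IQ < 70"), exactly
55 as mild ID.

## Derived quantities

*Wave ages.* When per-wave ages are not reported they are estimated as
equally spaced points from the first-wave mean age across the follow-up
interval — the same estimation the source review applied when articles
reported only intervals. A group with no derivable ages yields `NULL` and
drives `cant_tell` paths.

*Multi-group studies.* Published tables report one row per diagnosis
group. The engine combines groups by size: the functioning category is the
n-weighted majority (ties break toward the more impaired category — the
cautious side, since more impairment means self-report is *not* expected),
and wave-age fractions are n-weighted over (group, wave) pairs. The
combination is a package choice; the rubric's source is silent on it, and
weighting by group size is the least arbitrary option.

*Forced infeasibility.* When the functioning level is unknown but most
waves fall below the lowest age threshold (9 y), `q3a` is `no` regardless:
below that age no functioning band would be feasible. This rule is needed
to rate very young cohorts with no IQ data as "self-report not expected"
rather than "can't tell", matching the published worked example of a
preschool cerebral-palsy cohort.

## The overlap screen

The screen is an aid for humans, not a judge: it proposes `verbatim` and
`synonym` candidates and stays silent otherwise. The rubric consumes only
curated `overlap_finding()` records.

* **Normalization** is case-folding, punctuation stripping, a fixed
  stop-word list, and light suffix stemming (plural `s`/`es`; `ing`/`ed`
  only when a stem of four or more characters remains, so "fixed" survives
  while "learning" becomes "learn"). Deterministic and dependency-free by
  design; a full lemmatizer would add a dependency without changing what a
  recall-oriented screen needs.
* **Verbatim** fires at Jaccard similarity ≥ 0.5 on content tokens. The
  cut-off is an artifact choice — the original comparison was human and
  gives no numeric rule — and is surfaced as a parameter; 0.5 favours
  recall, which is the right error direction for a screen that humans
  confirm.
* **Synonym** fires when a lexicon pair bridges the texts. The lexicon is
  a plain editable text file seeded with the canonical
  hyperactive/overactive pair; transitive closure is deliberately not
  applied, so adding a pair never silently widens other pairs.
* **Concretisation** (one text a more concrete example of the other, e.g.
  poor school work vs. difficulties with academic skills) is a semantic
  judgement and is never emitted; such pairs surface as "no candidate —
  review manually".

Confidence is the Jaccard similarity after merging bridged pairs, hence
monotone in token overlap; identical non-empty texts always produce a
verbatim candidate at confidence 1, even when every token is a stop word.

## Cohort statistics

Scale scores are counted at the most general reported level per instrument
within a study: totals beat broad-band scores beat subscales. Percentages
use the denominators stated in their names: studies; counted scale scores
(for score-level overlap prevalence); studies with at least one overlap
(for the unaddressed share); studies without child rating (for the
feasible-among-missing share); distinct case-insensitive instrument names
(for instrument prevalences). A counted score is deemed to carry overlap
when any curated finding points at an outcome of the same instrument in
the same study — findings are often recorded against a subscale while the
counted score is the total of the same instrument. Rounding is half-up to
one decimal and applied only at presentation; raw counts are carried in
the summary object.

## The synthetic cohort generator

The generator exists so every pipeline stage is testable without any
download. It emulates the *categorical structure* the rubric consumes —
sub-question marginals, group sizes, wave counts, age and functioning
distributions — under the conditions of the reviewed cohort: 44.9% of
studies with at least one overlap; identified overlaps mostly unaddressed
(per-finding addressed distribution no/cant_tell/yes = .773/.127/.100);
12.2% multi-informant; 12.2% child-rated; 8.8% of instruments designed for
the population and none adapted; first-wave ages 0.51–12.30 y, wave counts
3–17, follow-up 2.00–16.74 y. The functioning mixture
(no ID .35 / mild .15 / moderate-severe .15 / unknown .35) is a package
choice — the review reports no cohort-wide IQ distribution — picked once
as a realistic mix for an NDD literature in which many studies do not
report IQ.

Design points:

* **Counter-derived substreams.** Each study's draws come from a seed
  derived from (cohort seed, study index), so generating a longer cohort
  extends a shorter one without shifting earlier studies; the global RNG
  state is saved and restored.
* **Structural dependencies.** Constraints the schema enforces are built
  in, never sampled: a child-rated study lists the child among its
  informants, adapted instruments carry a note, and informant sets realise
  the multi-informant and child-rated coin flips exactly, so both
  marginals stay independent and exact.
* **What it does not emulate.** Realistic item/criterion text (findings
  carry placeholder wording), multi-group studies, correlations between
  domains beyond those the rubric itself induces, and within-study
  instrument heterogeneity. Passing calibration tests therefore shows the
  engine is correct and the marginals recoverable — not that the generator
  reproduces real extraction data in any richer sense.

## Problem sizes and determinism

The default test suite checks marginal recovery at 500 synthetic studies
and the acceptance script at 2000, both within three standard errors of
the configured probabilities; the decision tables and the aggregation rule
are tested exhaustively (all 9-way and 81-way input crossings). All
figures render as hand-emitted SVG with fixed metrics, so identical inputs
give byte-identical files; PNG output goes through the standard graphics
device and carries no byte-determinism promise.

## Known limitations

* The shipped study-characteristics fixture transcribes a typeset table
  whose column layout is ambiguous in places; affected cells are flagged
  (`confidence = "low"`) rather than repaired, and one printed total
  (the participant sum) is not consistent with any defensible parse of its
  own table — the fixture keeps the faithful transcription.
* The full 49-study extraction lives in the source review's supplementary
  material and data deposit and is not redistributed here; the
  cohort-level reproduction checks that need it are present in the test
  suite but cannot pass from the printed worked examples alone.
* Inter-rater reliability of the rubric is out of scope (no second-rater
  data exists in the source), as is any psychometric evaluation of the
  named instruments.
* The boundary between an overlap "not fully addressed" (`cant_tell`) and
  "mention of some scores but not others" (`no`) is a curation judgement;
  the engine takes `addressed` statuses as input and never infers them
  from text.
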