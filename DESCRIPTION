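Package: robndd
Title: Measurement-Focused Risk of Bias Assessment for Longitudinal Studies
    of Mental Health in Children with Neurodevelopmental Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic rating engine for a four-domain,
    measurement-focused risk-of-bias rubric for longitudinal studies of
    mental health problems in children with neurodevelopmental disorders
    (NDD). The four domains cover conceptual overlap between outcome items
    and the diagnostic criteria defining the study group, over-reliance on a
    single informant, unwarranted omission of the child's own perspective,
    and the use of instruments neither designed for nor adapted to the
    population. The package provides a validated study-extraction schema
    (JSON and CSV), the domain decision tables and overall aggregation
    rules, a lexical screening aid proposing candidate item-criterion
    overlaps for human curation, cohort-level descriptive and distributional
    summaries, traffic-light and stacked-bar summary figures rendered as
    deterministic SVG, and a seeded synthetic-cohort generator for testing
    every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
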