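Package: dietrec
Title: Recurrent Food Consumption Measures from Longitudinal Food Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies habitual food consumption behavior from longitudinal
    food-diary logs. Identifies recurrent food-items and recurrent meals per
    individual and meal occasion from the relative frequency and span of their
    occurrences, summarizes habitual behavior with a three-level recurrence
    strength tuple (food-item, food-item-per-meal, and meal recurrence
    strength), assesses measurement reliability through a truncation-based
    estimation-error analysis with Kaplan-Meier summaries of sequence lengths,
    and provides contextual analyses across meal occasions and
    weekday/weekend splits. Includes diary preprocessing filters, a synthetic
    diary generator with controlled habitual structure for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
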