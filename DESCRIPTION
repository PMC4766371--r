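Package: aglsim
Title: Cross-Domain Artificial Grammar Learning: Stimuli, Simulated
    Learners, and Inferential Statistics
Version: 0.1.0
Authors@R:
    person("AGL", "Toolkit Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for statistical-sequential learning experiments with a
    cross-domain artificial grammar: six abstract elements split over two
    domains (e.g. auditory/visual modalities or perceptual categories),
    each followed by one same-domain and one cross-domain successor at
    equal probability. Generates learning streams and grammaticality test
    sets with within- or cross-domain violation injection, audits their
    statistical balance, binds elements to per-participant token mappings
    and millisecond trial schedules, simulates cohorts of
    transitional-probability learners with dissociable within- and
    cross-domain learning weights, and scores the resulting judgments with
    the standard behavioural battery: one-sample t tests against chance
    with Cohen's d, one-way repeated-measures ANOVA, mixed two-factor
    ANOVA with Mauchly's sphericity test and Greenhouse-Geisser
    correction, and Bonferroni-corrected pairwise comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
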