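Package: melagl
Title: Artificial Grammar Learning of Melody: Stimuli, Narmour Scoring, and
    Behavioral Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for artificial-grammar-learning (AGL) experiments on melody.
    Generates grammatical and five classes of ungrammatical melodic stimuli
    from a finite-state grammar over tone-pair terminals, quantifies melodies
    with a six-factor Narmour implication-realization scorer, searches
    one-to-one pitch mappings ranked by summed factor z-scores to construct
    maximally Narmour-inconsistent melody sets, renders stimuli to standard
    MIDI files, and implements the complete behavioral analysis pipeline
    (accuracy coding, planned one-sample t tests with sequential-Bonferroni
    correction, mixed-design ANOVA with within-subject contrasts, n-gram
    chunk-strength logistic regressions, and Type-2 d-prime), together with a
    synthetic-participant simulator so every analysis stage is testable
    without human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
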