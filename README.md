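# melagl

Tools for artificial-grammar-learning (AGL) experiments on melody.

In melodic AGL studies, participants incidentally learn melodies generated by
a finite-state grammar whose terminal symbols are *tone pairs* (each terminal
emits two pitches), and are then tested with forced-choice familiarity and
confidence judgments on old-grammatical, new-grammatical, and graded
ungrammatical stimuli. A central question is whether learning is constrained
by prior melodic expectancies, as formalized in Narmour's
implication–realization principles. `melagl` implements the full
computational apparatus of such a study:

- **Grammar core** — finite-state grammars over tone-pair alphabets:
  validation, bounded enumeration of grammatical sequences, a membership
  oracle, pitch realization, and seeded length-stratified selection of
  old/new grammatical stimulus sets. A documented fixture grammar (8
  terminals, two tagged pathways, 276 sequences of 8–30 tones) ships with
  the package.
- **Narmour scoring** — a six-factor quantification of the
  implication–realization principles. For each three-tone window with
  implicative interval *I* and realized interval *R*, predictability scores
  are assigned for registral direction (rd), registral return (rr),
  intervallic difference (id), proximity (pr = max(0, 6 − |R|)), closure
  (cl ∈ {0,1,2}) and consonance (co, a weight lookup on the octave-folded
  |R|); melody profiles are window means, set profiles are unweighted means
  over melodies.
- **Mapping optimizer** — searches one-to-one pitch mappings σ from the
  source pitch set into a bounded chromatic pool (image span ≤ 15
  semitones), scores each candidate by the summed z-scores of its six set-
  profile factors, z-scored across the candidate population
  (total(σ) = Σ_f z_f(σ)), and selects the extremal mapping. With
  `direction = "most_inconsistent"` this produces a maximally
  Narmour-inconsistent melody set whose abstract n-gram structure is
  identical to the source.
- **Stimulus factory** — five graded ungrammaticality constructions (fully
  random terminals; bigram-legal/trigram-illegal; legal anchors with random
  interior; cross-pathway hybrids; single swap/deletion), all certified
  against the membership oracle; length matching so the grammatical and
  ungrammatical length multisets are identical; assembly of the 66-item test
  set (17 + 16 + 6/6/7/7/7) and 51-presentation learning schedule; format-0
  MIDI rendering at a 330 ms inter-onset interval, velocity 100.
- **Response analysis** — accuracy coding (grammatical = correct iff
  familiar), 2 SD outlier screening, planned one-sample t tests against
  chance with Holm (sequential Bonferroni) correction, mixed-design Type III
  ANOVA (between: group, musicianship; within: grammaticality or error type)
  with partial η² and simple/repeated within-subject contrasts, n-gram
  average-chunk-strength predictors (sizes 1–8, pitch and interval views),
  per-participant ridge-stabilized logistic regressions with group-level
  coefficient t tests, Type-2 d′ for confidence, and exposure correlations.
- **Synthetic participants** — a generative cohort simulator (per-participant
  weights over intercept + chunk strengths + grammaticality; familiarity
  logistic in the evidence, confidence logistic in its magnitude) so every
  analysis stage is testable without human data.

## Worked example

```r
library(melagl)

g   <- fixture_grammar()
set <- assemble_test_set(g, seed = 1)
set
#> AGL stimulus set: 66 test stimuli ( 17 old-grammatical, 16 new-grammatical, 33 ungrammatical: 6/6/7/7/7 )
#> Learning schedule: 51 presentations in 3 blocks

resp <- simulate_cohort(cohort_config(seed = 7), set)
agl_analyze(resp, stimulus_manifest(set))
#> AGL behavioral analysis (focus group: experimental )
#>   participants kept: 31 (excluded: 0)
#>   overall accuracy: 0.644 (sd 0.068)
#>   planned t tests vs chance (Holm at alpha = 0.05 ):
#>  category  mean    sd  n     t df        p reject_holm
#>  old_gram 0.736 0.160 31  8.22 30 3.51e-09        TRUE
#>  new_gram 0.657 0.167 31  5.25 30 1.15e-05        TRUE
#>       et1 0.677 0.223 31  4.42 30 1.18e-04        TRUE
#>       et2 0.624 0.223 31  3.08 30 4.39e-03        TRUE
#>       et3 0.659 0.168 31  5.28 30 1.06e-05        TRUE
#>       et4 0.558 0.210 31  1.53 30 1.37e-01       FALSE
#>       et5 0.452 0.219 31 -1.23 30 2.27e-01       FALSE
#>   grammaticality ANOVA:
#>                   effect df_num df_den     ss ss_error    F       p    pes
#>                 musician      1     29 0.0285    0.554 1.49 0.23159 0.0490
#>           grammaticality      2     58 0.3384    1.434 6.84 0.00215 0.1909
#>  musician:grammaticality      2     58 0.0807    1.434 1.63 0.20450 0.0533
#>   Type-2 d': mean 0.0822 - t(30) = 1.366, p = 0.182 (mean 0.082, sd 0.335, n 31)
```

The planned-test table is read per row: mean accuracy for the category, its
SD over participants, and a one-sample t against the 0.5 chance level, with
the Holm decision at α = .05. Here the simulated cohort discriminates
grammatical structure and the easier error classes above chance, with
accuracy falling off across error types 1→5 (increasingly grammar-like
violations) — the graded-difficulty pattern the stimulus design is built to
produce. The ANOVA block reports the within-subject grammaticality effect
(old/new/ungrammatical) with partial η², and the d′ line summarizes
metacognitive sensitivity of the confidence judgments.

To build a Narmour-inconsistent version of the same materials:

```r
stim <- lapply(set$stimuli, `[[`, "pitches")
res  <- optimize_mapping(g$alphabet, stim, direction = "most_inconsistent",
                         seed = 1)
res$mapping
#> Pitch mapping: 60:70 62:73 64:65 65:60 67:71 69:72 71:66 72:61
inconsistent <- assemble_test_set(g, mapping = res$mapping, seed = 1)
render_stimulus_set(inconsistent, "midi_out")
```

A thin command-line front end over the same functions is installed at
`inst/scripts/melagl` (subcommands `generate`, `optimize`, `simulate`,
`analyze`).

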