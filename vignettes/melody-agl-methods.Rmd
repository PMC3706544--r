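---
title: "Methods: melodic artificial-grammar stimuli, Narmour scoring, and the analysis pipeline"
author: "melagl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: melodic artificial-grammar stimuli, Narmour scoring, and the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, codings and design choices behind
`melagl`: what each stage computes, which parameters matter and why their
defaults are what they are, what the synthetic-participant generator does and
does not emulate, and the package's known limitations.

## The stimulus system

### Grammar and terminals

Stimuli are generated by a finite-state grammar whose terminals are *tone
pairs*: each terminal emits two MIDI pitches, so a sequence of $k$ terminals
realizes a $2k$-tone melody. The grammar object carries states, a start
state, accepting states, labelled transitions, and optional *pathway* tags
that partition the non-shared states into two branches; the tags are what
makes the cross-pathway (error type 4) construction well defined.

The package ships a **fixture grammar** (`fixture_grammar()`,
`inst/extdata/grammar_fixture.yaml`). It is a documented substitute, not a
reconstruction of any published grammar: published grammar diagrams of this
kind are figures, not machine-readable data. The fixture is therefore built
to the structural properties the stimulus design needs, which the test suite
asserts directly:

- eight terminals (`a`–`h`) over eight pitches spanning one octave (60–72),
  mirroring the octave tessitura typical of such materials;
- an upper and a lower pathway leaving the shared start state and rejoining
  at the accept state, each contributing at least eight sequences;
- bounded loops, so enumeration to 15 terminal pairs is finite (276 distinct
  sequences, all 8–30 tones).

Grammaticality is decided by simulating the set of reachable states under
the label sequence (the grammar may be nondeterministic); enumeration is
depth-first with a lexicographic canonical order so results are
platform-independent.

### Selecting the 17 + 16 grammatical melodies

`build_grammatical_sets()` draws the old- and new-grammatical sets from the
enumerated sequences in the 8–30-tone window. The selection is a seeded
systematic sample along the length-sorted list (ties shuffled under the
seed), so the chosen 33 cover the length range rather than clustering at
short lengths; the old/new split then alternates along the length-sorted
order. Both choices serve the same design constraint as length matching:
neither melody length nor its distribution should cue old/new status.

### The five ungrammaticality classes

Each ungrammatical stimulus is generated to a *target length in pairs*
(assigned by `length_match()`, a seeded bijection from the grammatical
length multiset, so the grammatical and ungrammatical halves of the test set
have identical tone-length multisets) and is **certified** ungrammatical
against the membership oracle, with bounded rejection sampling (1,000 tries,
then an error — never silent acceptance):

1. uniform i.i.d. random terminals;
2. a random walk on the attested terminal-bigram graph, accepted only when
   at least one of its terminal trigrams is unattested in the grammatical
   set — locally legal transitions, globally illegal runs;
3. a grammatical beginning and ending (two terminals each by default,
   configurable) around a random interior;
4. the first ⌈L/2⌉ pairs of an upper-pathway donor joined to the tail of a
   lower-pathway donor (or vice versa, seeded coin);
5. one adjacent swap (of unequal neighbours) or one deletion applied to a
   grammatical donor; a deletion shortens by one pair, so its donor is
   chosen one pair longer than the target.

The numerical ordering 1→5 grades similarity to grammatical material, which
is what gives the error-type analysis its interpretation.

### Rendering

`render_midi()` writes format-0 single-track MIDI with 500 ticks per quarter
and a fixed tempo of 500,000 µs per quarter, so one tick equals one
millisecond exactly; note $k$ (0-based) starts at $k \times$ `ioi` ms.
Defaults: 330 ms inter-onset interval, velocity 100, piano program. The test
suite parses the written bytes back with an independent reader.

## Narmour scoring

Each three-tone window defines an implicative interval $I$ (tone 2 − tone 1)
and realized interval $R$ (tone 3 − tone 2). "Small" means $|I| \le 5$
semitones and "large" $|I| \ge 6$: the proximity threshold of five semitones
fixes the boundary, and the tritone is classed large. The six factors are
*predictability* codings — higher is more consistent with the principle:

- **rd** (registral direction, revised): 1 if a small interval continues in
  the same direction, or a large interval reverses; a lateral realization
  ($R = 0$) counts as "not the same direction", so it scores 1 after a large
  interval and 0 after a small one.
- **rr** (registral return): 1 iff the direction changes (non-lateral) and
  the third tone ends within ±2 semitones of the first ($|I + R| \le 2$).
- **id** (intervallic difference): small $I$ implies a similar-sized $R$
  ($\bigl||R|-|I|\bigr| \le 3$ with direction kept, $\le 2$ with direction
  changed); large $I$ implies a shrink of at least 3 semitones.
- **pr** (proximity, graded): $\max(0, 6 - |R|)$.
- **cl** (closure, additive 0–2): +1 for a direction change; +1 for a large
  interval followed by a sufficient shrink. The verbal rule "smaller than 3
  semitones for the identical registral direction" admits two readings
  (absolute size of $R$ vs. amount of shrink); the package codes the
  *shrink-amount* reading ($|R| \le |I| - 3$ same direction, $|R| \le |I|-2$
  changed direction), which keeps closure consistent with the id coding.
  The alternative reading is a configuration-level variant.
- **co** (consonance): a weight lookup on the octave-folded $|R|$. The
  13-element default vector follows classic consonance orderings
  (unison/octave and fifth high; semitone and tritone low). It is a
  configuration choice, not ground truth: downstream the factor is z-scored
  across candidate mappings, so only its relative ordering matters.

Melody profiles are arithmetic means over the $n_\text{tones} - 2$ windows
(defined only for ≥ 3 tones); set profiles are unweighted means over
melodies, so long melodies do not dominate. Invariances asserted by the
tests: transposition invariance, mirror (interval-negation) invariance, and
monotone non-increase of pr in $|R|$.

## The mapping optimizer

A candidate mapping is an injection from the 8 source pitches into a
chromatic pool; the default pool is a 15-semitone window centered on the
source tessitura (widening the octave to a tenth leaves room to break
registral return/direction without unbounded range), and every image must
span ≤ 15 semitones. When the number of span-feasible injections is at most
`limit` the population is enumerated exhaustively in lexicographic order;
otherwise a seeded uniform sample of `limit` distinct mappings is drawn. The
default limit is 200,000 scored mappings, which keeps the default search
under half a minute on one CPU while sampling the space densely enough for a
stable extreme.

Each candidate's raw score is the six-factor set profile of the *mapped*
full stimulus set. Scoring is vectorized by reducing the stimulus set to its
distinct tone triples with per-melody weights (the weighted sum over
distinct triples equals the per-melody-mean-then-mean-over-melodies
definition exactly; the tests verify equality against direct per-mapping
recomputation). Factors are z-scored across the candidate population using
the population SD; a zero-variance factor scores 0 for all candidates and is
flagged. The competitive total is the unweighted sum of the six z-scores.
Because all codings are predictability scores, *inconsistency* is the
minimal total; ties break by candidate order, and `mapping_report()` emits
the full ranking so a final solution can be re-selected by hand, mirroring
the manual final step of the original procedure.

## The behavioral analysis

Accuracy coding: grammatical stimuli are correct iff endorsed *familiar*,
ungrammatical iff rejected; with 33 grammatical and 33 ungrammatical items
chance is 0.5 by construction. Participants whose overall accuracy deviates
more than 2 SD from their group mean are excluded, with mean and SD computed
once (no iterative re-screening).

- Planned one-sample t tests (two-tailed, sample SD) compare each category's
  accuracy to chance; the family of seven (old, new, five error types) is
  Holm-corrected. `holm_adjust()` implements the step-down rule explicitly
  (the i-th smallest p compared with $\alpha/(m-i+1)$, stopping at the first
  failure); the tests cross-check it against `p.adjust`.
- The mixed ANOVA is the classical univariate split-plot decomposition,
  computed from a multivariate linear model with sum-to-zero contrasts and
  Type III sums of squares (via `car::Anova`), so unbalanced between groups
  (e.g. cohorts of 22 and 31) are handled; partial
  $\eta^2 = SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$. No
  sphericity correction is applied, matching the uncorrected contrasts it
  accompanies; degenerate inputs (zero effect and error SS) report F = 0
  rather than NaN. An independent brute-force sums-of-squares oracle checks
  the implementation on balanced toys.
- Within-subject contrasts (simple: each level vs. reference; repeated:
  adjacent levels) are one-sample t tests on participant-level difference
  scores, reported as $F = t^2$ on $(1, n-1)$ df.
- Average chunk strength (ACS) of a stimulus for size $n$ is the mean over
  the stimulus's overlapping $n$-grams of their occurrence counts across the
  training corpus — the 17 old-grammatical melodies, each counted once (the
  three learning blocks are repetition, not new material; a corpus
  multiplier would scale all counts equally). Views: pitch sequence, or the
  one-shorter interval sequence. In the regression feature matrix a stimulus
  too short to contain any $n$-gram of a given size contributes ACS 0 (it
  has no such chunks); `chunk_strength()` itself treats that as an error.
- Per-participant logistic regressions of the familiarity response on
  intercept + ACS(1–8) + grammaticality (coded 1/0) use unstandardized
  predictors and a tiny ridge penalty (1e−6) so complete separation — easy
  with 66 trials and 10 collinear predictors — yields finite coefficients
  while leaving well-conditioned fits numerically at the maximum-likelihood
  solution (verified against `glm`). Constant predictors are dropped and
  reported as missing. Group-level inference is a one-sample t of each
  coefficient against zero across participants.
- Type-2 d′ is $\Phi^{-1}(\text{hit}) - \Phi^{-1}(\text{fa})$ with hit =
  P(high confidence | correct) and fa = P(high confidence | incorrect);
  proportions of 0 or 1 are replaced by $1/(2N)$ and $1 - 1/(2N)$ with $N$
  the cell denominator. A participant with no correct or no incorrect trials
  has undefined d′ and is flagged.

## The synthetic-participant generator

The generator exists so that every analysis stage is exercised end to end
without human data. Participant $j$ draws a weight vector
$w_j \sim \mathcal N(\mu, \sigma^2)$ over the same predictors the analysis
fits (intercept, pitch-view ACS 1–8, grammaticality); familiarity is
Bernoulli$(\operatorname{logit}^{-1}(w_j \cdot x))$ and high confidence is
Bernoulli$(\operatorname{logit}^{-1}(\gamma \, |w_j \cdot x|))$. Generating
confidence from the *magnitude* of the response evidence (not from
accuracy) makes positive Type-2 d′ emerge mechanistically, the signature of
explicit judgment knowledge, while $\gamma = 0$ collapses confidence to a
fair coin.

Default calibration (a design choice, fixed before use and stated here
rather than tuned per run): the intercept (−1.9) offsets the mean bigram
chunk-strength contribution (0.05 per count on ACS2, which averages ≈ 26 for
ungrammatical and ≈ 38 for grammatical items on the fixture set), and the
grammaticality weight (0.6) places the expected evidence near +0.6 for
grammatical and −0.6 for ungrammatical stimuli, i.e. cohort mean accuracy in
the mid-.60s — the regime reported for Narmour-inconsistent materials, where
learning is present but impaired. Between-participant dispersion is scaled
per predictor (0.01 on raw-count ACS weights, 0.25–0.4 on the binary-scale
weights): a common scalar SD on raw chunk-strength predictors would swamp
the signal and produce all-or-none responders. $\gamma = 0.6$ puts mean d′
in (0, 1). Cohort defaults follow the study design: 31 participants, ~50%
musicians, exposure = 51 scheduled presentations plus a Poisson(15) number
of voluntary repeats, independent of ability (so exposure–performance
correlations are null by construction).

What the simulator deliberately does **not** emulate: serial-position and
learning-curve effects within the learning phase, response bias drift,
individual differences in the confidence criterion, or any dependence of
exposure on ability. Passing tests therefore demonstrate that the analysis
machinery is correct and well-calibrated under the assumed generative
model — not that the model captures human AGL behaviour.

## Problem sizes and tolerances in the test suite

The suite's simulation sizes are chosen to keep the full run around a
minute while leaving comfortable statistical margins: 400 replicate null
cohorts of 29 for the familywise type-I check (asserting the no-rejection
proportion above the lower Monte-Carlo envelope, ≥ 0.925, of a true-95%
process), 40 replicates of n = 400 for logistic parameter recovery within 2
standard errors (≥ 90%), and 2,000 synthetic participants for the
calibration check of the generative logistic (tolerance 0.04 on endorsement
probabilities). Exact structural assertions (set sizes, length multisets,
certification, MIDI timing) use no tolerance.

## Known limitations

- The fixture grammar and terminal pitches are configuration standing in
  for unpublished materials; any conclusions about a specific published
  grammar require loading that grammar's description.
- The consonance weight vector is a configured ordering, not an empirically
  estimated one; only its relative scale reaches the optimizer.
- Under the six predictability codings, the population optimum of the
  mapping search favours zigzag contours with mid-size consonant intervals:
  closure rewards direction changes and the consonance weights penalize
  seconds, so a smooth stepwise source set — including the identity mapping
  of the fixture materials — ranks in the upper half but not at the top of
  the consistency ranking. The anti-symmetry guarantees that do hold (and
  are tested) are: consistent selection > identity > inconsistent selection
  in total, and the inconsistent selection strictly flattens proximity and
  widens mean interval size relative to the identity.
- The per-participant regressions inherit the identifiability limits of 66
  trials with 10 collinear predictors; coefficients are interpretable at the
  group level (as in the published analysis style), not individually.
- `mixed_anova` covers up to two between-subject factors and one
  within-subject factor — the designs this paradigm uses — not general
  multi-way repeated measures.
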