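#' Narmour scoring configuration
#'
#' Holds the numeric coding thresholds for the six-factor quantification of
#' Narmour's implication-realization principles. An implicative interval is
#' "small" when its absolute size is at most `small_max` semitones and "large"
#' from `large_min` upward (the proximity threshold of 5 semitones fixes the
#' boundary; the tritone is classed large). `consonance_weights` is a
#' 13-element vector giving a consonance weight for each realized-interval
#' size 0..12; realized intervals beyond an octave are octave-folded. The
#' default weight vector is a configuration choice following classic
#' consonance orderings (unison/octave and perfect fifth high, semitone and
#' tritone low); only the relative scale matters downstream because mapping
#' scores are z-scored across candidates.
#'
#' @param small_max Largest "small" implicative interval, semitones.
#' @param large_min Smallest "large" implicative interval, semitones.
#' @param consonance_weights Numeric length-13 vector, intervals 0..12.
#' @return An object of class `narmour_config`.
#' @export
narmour_config <- function(small_max = 5L, large_min = 6L,
                           consonance_weights = c(
                             1.00, 0.10, 0.35, 0.60, 0.65, 0.75, 0.20,
                             0.90, 0.55, 0.60, 0.40, 0.15, 0.95)) {
  if (!(small_max < large_min)) stop("small_max must be below large_min")
  if (length(consonance_weights) != 13L)
    stop("consonance_weights must have 13 values (interval sizes 0..12)")
  structure(list(small_max = as.integer(small_max),
                 large_min = as.integer(large_min),
                 consonance_weights = as.numeric(consonance_weights)),
            class = "narmour_config")
}

# Vectorized six-factor scorer over triples of consecutive tones.
# p1, p2, p3: equal-length numeric vectors. Returns a matrix with columns
# rd, rr, id, pr, cl, co. Scores are "predictability" codings: higher =
# more consistent with the principles.
.narmour_factors <- function(p1, p2, p3, cfg) {
  I <- p2 - p1
  R <- p3 - p2
  aI <- abs(I); aR <- abs(R)
  sI <- sign(I); sR <- sign(R)
  small <- aI <= cfg$small_max
  large <- aI >= cfg$large_min
  same <- sR == sI & sR != 0

  # registral direction (revised): small continues, large reverses;
  # lateral realization counts as "not same direction"
  rd <- as.numeric((small & same) | (large & sR != sI))

  # registral return: direction change (non-lateral) ending within 2
  # semitones of the first tone of the triple
  rr <- as.numeric(sR != sI & R != 0 & abs(I + R) <= 2)

  # intervallic difference: small implies similar size (tolerance depends on
  # direction); large implies a shrink of at least 3 semitones
  diff_tol <- ifelse(same, 3, 2)
  id <- as.numeric((small & abs(aR - aI) <= diff_tol) | (large & aR <= aI - 3))

  # proximity, graded 0..6
  pr <- pmax(0, 6 - aR)

  # closure, additive 0..2: direction change; large interval followed by a
  # sufficient shrink (stricter when direction is kept)
  cl <- as.numeric(sR != sI) +
    as.numeric(large & ifelse(same, aR <= aI - 3, aR <= aI - 2))

  # consonance: weight lookup on the octave-folded realized interval
  fold <- aR
  while (any(fold > 12)) fold <- ifelse(fold > 12, fold - 12, fold)
  co <- cfg$consonance_weights[fold + 1L]

  cbind(rd = rd, rr = rr, id = id, pr = pr, cl = cl, co = co)
}

#' Six-factor Narmour scores for one interval pair
#'
#' Scores a single three-tone window: the implicative interval `I` (tone 2
#' minus tone 1) followed by the realized interval `R` (tone 3 minus tone 2).
#' All six components are "predictability" codings: higher values mean the
#' realization is more consistent with the principle.
#'
#' @param implicative Signed implicative interval, semitones.
#' @param realized Signed realized interval, semitones.
#' @param anchor Pitch of the first tone (needed for registral return).
#' @param cfg A [narmour_config].
#' @return Named numeric vector `rd`, `rr`, `id`, `pr`, `cl`, `co`.
#' @export
factor_scores <- function(implicative, realized, anchor = 60,
                          cfg = narmour_config()) {
  drop(.narmour_factors(anchor, anchor + implicative,
                        anchor + implicative + realized, cfg)[1, ])
}

#' Mean Narmour profile of a melody
#'
#' Averages the six factor scores over all `n_tones - 2` consecutive
#' three-tone windows of the melody.
#'
#' @param pitches Integer vector of MIDI note numbers, length >= 3.
#' @param cfg A [narmour_config].
#' @return Named numeric vector of the six factor means, with attribute
#'   `n_pairs` (number of windows averaged).
#' @export
melody_profile <- function(pitches, cfg = narmour_config()) {
  n <- length(pitches)
  if (n < 3L) stop("a Narmour profile needs at least 3 tones")
  f <- .narmour_factors(pitches[1:(n - 2)], pitches[2:(n - 1)], pitches[3:n], cfg)
  structure(colMeans(f), n_pairs = n - 2L)
}

#' Mean Narmour profile of a melody set
#'
#' Unweighted mean of [melody_profile] over the melodies: every melody
#' contributes equally regardless of its length.
#'
#' @param melodies List of pitch vectors (each >= 3 tones).
#' @param cfg A [narmour_config].
#' @return Named numeric vector of the six factor means.
#' @export
set_profile <- function(melodies, cfg = narmour_config()) {
  if (!length(melodies)) stop("empty melody set")
  colMeans(do.call(rbind, lapply(melodies, function(m)
    melody_profile(m, cfg)[1:6])))
}
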