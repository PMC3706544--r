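#' Default candidate pitch pool for mapping search
#'
#' Chromatic pitches in a window of the given span centered on the source
#' tessitura. The default span of 15 semitones widens the original octave
#' tessitura to a tenth, which leaves room for mappings that break registral
#' return / registral direction while keeping the overall range bounded.
#'
#' @param alphabet An [agl_alphabet] (the source pitches).
#' @param span Window span in semitones (max - min of the pool).
#' @return Integer vector of candidate MIDI pitches.
#' @export
default_target_pool <- function(alphabet, span = 15L) {
  mid <- (min(alphabet$pitch_set) + max(alphabet$pitch_set)) %/% 2L
  lo <- mid - span %/% 2L
  seq.int(max(0L, lo), min(127L, lo + span))
}

# TRUE iff some k-subset of pool fits in a window of the given span
.span_satisfiable <- function(pool, k, span) {
  pool <- sort(unique(pool))
  if (length(pool) < k) return(FALSE)
  any(vapply(seq_len(length(pool) - k + 1L), function(i)
    pool[i + k - 1L] - pool[i] <= span, logical(1)))
}

#' Candidate one-to-one pitch mappings
#'
#' Enumerates or samples injections from the source pitch set into the target
#' pool, subject to a span constraint on the image (max - min of the mapped
#' pitches). When the total number of span-feasible injections is at most
#' `limit` the enumeration is exhaustive and lexicographic; otherwise a
#' seeded uniform sample of `limit` distinct mappings is drawn.
#'
#' @param alphabet An [agl_alphabet]; its `pitch_set` is the mapping domain.
#' @param pool Candidate target pitches (default [default_target_pool]).
#' @param limit Maximum number of mappings to return (default 200000).
#' @param seed Integer seed for the sampling fallback.
#' @param span Maximum image span in semitones (default 15).
#' @return An object of class `agl_mappings`: integer matrix with one row per
#'   mapping and one column per source pitch (ascending source order);
#'   attributes `source` (the source pitches) and `exhaustive` (logical).
#' @export
candidate_mappings <- function(alphabet, pool = default_target_pool(alphabet),
                               limit = 200000L, seed = 1L, span = 15L) {
  source <- alphabet$pitch_set
  k <- length(source)
  pool <- sort(unique(as.integer(pool)))
  if (length(pool) < k)
    stop("target pool smaller than the source pitch set")
  if (!.span_satisfiable(pool, k, span))
    stop(sprintf("no %d-pitch image within a %d-semitone span exists in the pool",
                 k, span))
  n_inj <- prod(seq.int(length(pool), by = -1L, length.out = k))
  if (n_inj <= limit) {
    rows <- .enumerate_injections(pool, k, span)
  } else {
    set.seed(as.integer(seed))
    seen <- new.env(parent = emptyenv())
    rows <- matrix(0L, nrow = limit, ncol = k)
    got <- 0L
    tries <- 0L
    while (got < limit) {
      tries <- tries + 1L
      if (tries > 200L * limit)
        stop("could not draw the requested number of span-feasible mappings")
      cand <- pool[sample.int(length(pool), k)]
      if (max(cand) - min(cand) > span) next
      key <- paste(cand, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      got <- got + 1L
      rows[got, ] <- cand
    }
  }
  structure(rows, source = source, exhaustive = n_inj <= limit,
            class = c("agl_mappings", class(rows)))
}

# exhaustive lexicographic enumeration of span-feasible injections
# (breadth expansion over prefixes; pool is sorted, so prefix-major order is
# lexicographic)
.enumerate_injections <- function(pool, k, span) {
  P <- length(pool)
  rows <- matrix(pool, ncol = 1L)
  rmin <- pool; rmax <- pool
  for (d in seq_len(k - 1L)) {
    n <- nrow(rows)
    idx <- rep(seq_len(n), each = P)
    newcol <- rep(pool, times = n)
    M <- rows[idx, , drop = FALSE]
    dup <- rowSums(M == newcol) > 0L
    nmin <- pmin(rmin[idx], newcol)
    nmax <- pmax(rmax[idx], newcol)
    keep <- !dup & (nmax - nmin <= span)
    if (!any(keep)) stop("no span-feasible injection exists")
    rows <- cbind(M[keep, , drop = FALSE], newcol[keep])
    rmin <- nmin[keep]; rmax <- nmax[keep]
  }
  dimnames(rows) <- NULL
  rows
}

#' @export
print.agl_mappings <- function(x, ...) {
  cat(nrow(x), if (attr(x, "exhaustive")) "exhaustive" else "sampled",
      "one-to-one mappings of", ncol(x), "source pitches\n")
  invisible(x)
}

# i-th mapping of an agl_mappings matrix as a named source->target vector
mapping_at <- function(mappings, i) {
  m <- as.integer(mappings[i, ])
  names(m) <- as.character(attr(mappings, "source"))
  structure(m, class = "agl_mapping")
}

#' @export
print.agl_mapping <- function(x, ...) {
  cat("Pitch mapping:", paste(names(x), unclass(x), sep = ":", collapse = " "),
      "\n")
  invisible(x)
}

#' Apply a pitch mapping to melodies
#'
#' Pointwise substitution of every pitch through the one-to-one mapping.
#' Lengths and the terminal-level (label) structure are unchanged, so the
#' abstract n-gram structure of the melody set is preserved.
#'
#' @param mapping Named integer vector source pitch -> target pitch
#'   (as returned by [select_mapping]).
#' @param stimuli List of pitch vectors.
#' @return List of mapped pitch vectors.
#' @export
apply_mapping <- function(mapping, stimuli) {
  src <- as.integer(names(mapping))
  lapply(stimuli, function(p) {
    idx <- match(p, src)
    if (anyNA(idx))
      stop("pitch outside the mapping domain: ",
           paste(unique(p[is.na(idx)]), collapse = ", "))
    as.integer(unclass(mapping)[idx])
  })
}

# distinct tone triples of a stimulus set, as indices into `source`, with
# weights such that the weighted factor sum equals set_profile (per-melody
# mean of windows, then unweighted mean over melodies)
.triple_table <- function(stimuli, source) {
  M <- length(stimuli)
  keys <- character(0); w <- numeric(0)
  i1 <- i2 <- i3 <- integer(0)
  tab <- new.env(parent = emptyenv())
  for (p in stimuli) {
    n <- length(p)
    if (n < 3L) stop("all melodies must have at least 3 tones")
    idx <- match(p, source)
    if (anyNA(idx)) stop("stimulus pitch not in the source pitch set")
    Tm <- n - 2L
    wm <- 1 / (M * Tm)
    for (t in seq_len(Tm)) {
      key <- paste(idx[t], idx[t + 1L], idx[t + 2L])
      cur <- tab[[key]]
      if (is.null(cur)) tab[[key]] <- list(idx[t:(t + 2L)], wm)
      else tab[[key]][[2]] <- cur[[2]] + wm
    }
  }
  ks <- ls(tab)
  idx <- t(vapply(ks, function(k) tab[[k]][[1]], integer(3)))
  list(i1 = idx[, 1], i2 = idx[, 2], i3 = idx[, 3],
       w = vapply(ks, function(k) tab[[k]][[2]], numeric(1)))
}

#' Score candidate mappings by summed factor z-scores
#'
#' For each candidate mapping, computes the six-factor mean Narmour profile of
#' the mapped stimulus set (the raw score vector), z-scores each factor across
#' the candidate population (population SD; a zero-variance factor scores 0
#' for every candidate and is flagged), and sums the six z components into the
#' competitive total. Internally the stimulus set is reduced to its distinct
#' tone triples with per-melody weights, so scoring is vectorized across
#' candidates; tests verify equality with direct per-mapping recomputation.
#'
#' @param mappings An `agl_mappings` matrix from [candidate_mappings].
#' @param stimuli List of pitch vectors (the full grammatical + ungrammatical
#'   set, in source pitches).
#' @param cfg A [narmour_config].
#' @param chunk Number of mappings scored per vectorized block.
#' @return An object of class `agl_mapping_scores`: data.frame with columns
#'   `mapping` (row index), `raw_*` and `z_*` for the six factors, and
#'   `total`; attributes `mappings` and `constant_factors`.
#' @export
score_mappings <- function(mappings, stimuli, cfg = narmour_config(),
                           chunk = 4000L) {
  stopifnot(inherits(mappings, "agl_mappings"))
  n <- nrow(mappings)
  if (n < 2L) stop("z-scoring needs at least 2 candidate mappings")
  tt <- .triple_table(stimuli, attr(mappings, "source"))
  Tn <- length(tt$w)
  raw <- matrix(0, nrow = n, ncol = 6,
                dimnames = list(NULL, c("rd", "rr", "id", "pr", "cl", "co")))
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    C <- mappings[s:e, , drop = FALSE]
    nc <- nrow(C)
    f <- .narmour_factors(as.numeric(C[, tt$i1]), as.numeric(C[, tt$i2]),
                          as.numeric(C[, tt$i3]), cfg)
    for (j in 1:6)
      raw[s:e, j] <- matrix(f[, j], nrow = nc, ncol = Tn) %*% tt$w
  }
  mu <- colMeans(raw)
  sd_pop <- sqrt(colMeans(sweep(raw, 2, mu)^2))
  constant <- sd_pop == 0
  z <- sweep(raw, 2, mu)
  z[, !constant] <- sweep(z[, !constant, drop = FALSE], 2, sd_pop[!constant], "/")
  z[, constant] <- 0
  out <- data.frame(mapping = seq_len(n), raw, z = z, total = rowSums(z))
  names(out) <- c("mapping", paste0("raw_", colnames(raw)),
                  paste0("z_", colnames(raw)), "total")
  structure(out, mappings = mappings,
            constant_factors = colnames(raw)[constant],
            class = c("agl_mapping_scores", "data.frame"))
}

#' Select the extremal mapping from a scored population
#'
#' Picks the candidate with the maximal (`most_consistent`) or minimal
#' (`most_inconsistent`) summed z-score. All codings are predictability
#' scores, so Narmour-inconsistency corresponds to the minimal total. Ties
#' are broken by candidate order. The full ranking is available via
#' [mapping_report] so that a final solution can be re-selected by hand,
#' mirroring the manual final step of the original procedure.
#'
#' @param scores An `agl_mapping_scores` object.
#' @param direction `"most_inconsistent"` (default) or `"most_consistent"`.
#' @return The selected mapping as a named vector (class `agl_mapping`), with
#'   attributes `total` and `rank_index`.
#' @export
select_mapping <- function(scores,
                           direction = c("most_inconsistent", "most_consistent")) {
  direction <- match.arg(direction)
  stopifnot(inherits(scores, "agl_mapping_scores"), nrow(scores) >= 1L)
  i <- if (direction == "most_inconsistent") which.min(scores$total)
       else which.max(scores$total)
  m <- mapping_at(attr(scores, "mappings"), scores$mapping[i])
  attr(m, "total") <- scores$total[i]
  attr(m, "rank_index") <- i
  m
}

#' Ranked mapping report
#'
#' @param scores An `agl_mapping_scores` object.
#' @param direction Ranking direction as in [select_mapping].
#' @param path Optional path; when given, the table is written as TSV.
#' @param top Number of rows to keep (default all).
#' @return data.frame: rank, total, six raw means, six z-scores, and the
#'   assignment as `src:tgt` pairs.
#' @export
mapping_report <- function(scores, direction = "most_inconsistent",
                           path = NULL, top = nrow(scores)) {
  ord <- order(scores$total,
               decreasing = (direction == "most_consistent"))[seq_len(top)]
  mp <- attr(scores, "mappings")
  src <- attr(mp, "source")
  assign_str <- vapply(scores$mapping[ord], function(i)
    paste(src, mp[i, ], sep = ":", collapse = ","), character(1))
  rep <- data.frame(rank = seq_along(ord),
                    scores[ord, setdiff(names(scores), "mapping")],
                    assignment = assign_str, row.names = NULL)
  if (!is.null(path))
    utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rep
}

#' One-shot mapping optimization
#'
#' Convenience wrapper: builds the candidate population, scores it, and
#' selects the extremal mapping.
#'
#' @inheritParams candidate_mappings
#' @param stimuli List of pitch vectors in source pitches.
#' @param direction Passed to [select_mapping].
#' @param cfg A [narmour_config].
#' @return List with `mapping`, `scores`, and `direction`.
#' @export
optimize_mapping <- function(alphabet, stimuli,
                             direction = "most_inconsistent",
                             pool = default_target_pool(alphabet),
                             limit = 200000L, seed = 1L, span = 15L,
                             cfg = narmour_config()) {
  cands <- candidate_mappings(alphabet, pool = pool, limit = limit,
                              seed = seed, span = span)
  scores <- score_mappings(cands, stimuli, cfg)
  list(mapping = select_mapping(scores, direction), scores = scores,
       direction = direction)
}
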