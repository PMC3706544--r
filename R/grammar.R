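#' Tone-pair alphabet
#'
#' Construct the terminal alphabet of an AGL melody grammar. Each terminal
#' (a "tone pair") emits two pitches, so a sequence of k terminals realizes a
#' melody of 2k tones.
#'
#' @param pairs Named list; each element a length-2 integer vector of MIDI
#'   note numbers (0-127). Names are the terminal labels and must be unique.
#' @return An object of class `agl_alphabet` with elements `pairs`, `labels`,
#'   `pitch_set` (sorted distinct pitches) and `span` (max - min, semitones).
#' @export
agl_alphabet <- function(pairs) {
  if (is.null(names(pairs)) || anyDuplicated(names(pairs)) || any(names(pairs) == ""))
    stop("terminal labels must be unique and non-empty")
  pairs <- lapply(pairs, function(p) {
    p <- as.integer(p)
    if (length(p) != 2L || any(is.na(p)) || any(p < 0L) || any(p > 127L))
      stop("each terminal must be two MIDI note numbers in [0, 127]")
    p
  })
  pitch_set <- sort(unique(unlist(pairs, use.names = FALSE)))
  structure(
    list(pairs = pairs, labels = names(pairs), pitch_set = pitch_set,
         span = max(pitch_set) - min(pitch_set)),
    class = "agl_alphabet")
}

#' @export
print.agl_alphabet <- function(x, ...) {
  cat("Tone-pair alphabet:", length(x$labels), "terminals,",
      length(x$pitch_set), "pitches, span", x$span, "semitones\n")
  for (l in x$labels)
    cat(" ", l, ": (", x$pairs[[l]][1], ",", x$pairs[[l]][2], ")\n")
  invisible(x)
}

#' Load a finite-state melody grammar from a description
#'
#' Reads a structured grammar description (YAML file or an equivalent list)
#' with fields `states`, `start`, `accepts`, `transitions` (each a triple
#' `[from, label, to]`), optional `terminals` (label -> two MIDI pitches) and
#' optional `pathways` (tag -> states). The grammar is validated: transitions
#' may only reference declared states, and at least one accepting state must
#' be reachable from the start state.
#'
#' @param doc Path to a YAML file, or a list with the fields above.
#' @return An object of class `agl_grammar`: list with `states`, `start`,
#'   `accepts`, `transitions` (data.frame from/label/to), `labels`,
#'   `pathways` (named list of state vectors or NULL) and `alphabet`
#'   (an [agl_alphabet] or NULL when the document carries no terminals).
#' @export
load_grammar <- function(doc) {
  if (is.character(doc) && length(doc) == 1L) {
    if (!file.exists(doc)) stop("grammar file not found: ", doc)
    doc <- yaml::read_yaml(doc)
  }
  if (!is.list(doc)) stop("grammar description must be a file path or a list")
  need <- c("states", "start", "accepts", "transitions")
  miss <- setdiff(need, names(doc))
  if (length(miss)) stop("grammar description missing field(s): ",
                         paste(miss, collapse = ", "))
  states <- as.character(unlist(doc$states))
  start <- as.character(doc$start)
  accepts <- as.character(unlist(doc$accepts))
  tr <- doc$transitions
  if (!length(tr)) stop("grammar has no transitions")
  tr <- do.call(rbind, lapply(tr, function(t) {
    t <- as.character(unlist(t))
    if (length(t) != 3L) stop("each transition must be [from, label, to]")
    t
  }))
  transitions <- data.frame(from = tr[, 1], label = tr[, 2], to = tr[, 3],
                            stringsAsFactors = FALSE)
  if (length(start) != 1L || !(start %in% states))
    stop("start state must be one of the declared states")
  if (!all(accepts %in% states))
    stop("accepting state(s) not declared: ",
         paste(setdiff(accepts, states), collapse = ", "))
  bad <- setdiff(c(transitions$from, transitions$to), states)
  if (length(bad))
    stop("transition references unknown state(s): ", paste(bad, collapse = ", "))

  alphabet <- NULL
  if (!is.null(doc$terminals)) {
    alphabet <- agl_alphabet(doc$terminals)
    badl <- setdiff(transitions$label, alphabet$labels)
    if (length(badl))
      stop("transition uses label(s) not in the terminal alphabet: ",
           paste(badl, collapse = ", "))
  }
  pathways <- NULL
  if (!is.null(doc$pathways)) {
    pathways <- lapply(doc$pathways, function(s) as.character(unlist(s)))
    badp <- setdiff(unlist(pathways), states)
    if (length(badp))
      stop("pathway tag references unknown state(s): ", paste(badp, collapse = ", "))
  }
  g <- structure(
    list(states = states, start = start, accepts = accepts,
         transitions = transitions, labels = sort(unique(transitions$label)),
         pathways = pathways, alphabet = alphabet),
    class = "agl_grammar")
  # reachability of the accept set from start
  reach <- start
  repeat {
    nxt <- unique(c(reach, transitions$to[transitions$from %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (!any(accepts %in% reach))
    stop("no accepting state is reachable from the start state")
  g
}

#' @export
print.agl_grammar <- function(x, ...) {
  cat("Finite-state grammar:", length(x$states), "states,",
      nrow(x$transitions), "transitions, alphabet {",
      paste(x$labels, collapse = ","), "}\n")
  cat("  start:", x$start, " accepts:", paste(x$accepts, collapse = ","), "\n")
  if (!is.null(x$pathways))
    for (p in names(x$pathways))
      cat("  pathway", p, ":", paste(x$pathways[[p]], collapse = ","), "\n")
  invisible(x)
}

# successor map: list[state] -> data.frame(label, to)
.succ_map <- function(g) split(g$transitions[c("label", "to")], g$transitions$from)

#' Enumerate grammatical terminal sequences
#'
#' Depth-first enumeration of all accepting label paths of the grammar with at
#' most `max_pairs` terminals. Duplicate label strings (reached via different
#' state paths) are removed and the result is sorted lexicographically so the
#' enumeration order is platform-independent.
#'
#' @param g An [agl_grammar].
#' @param max_pairs Maximum sequence length in terminal pairs (>= 1).
#' @return A list of character vectors (terminal label sequences).
#' @export
enumerate_sequences <- function(g, max_pairs) {
  stopifnot(inherits(g, "agl_grammar"), max_pairs >= 1)
  succ <- .succ_map(g)
  out <- new.env(parent = emptyenv())
  walk <- function(state, path) {
    if (length(path) && state %in% g$accepts)
      assign(paste(path, collapse = "\x1f"), path, envir = out)
    if (length(path) >= max_pairs) return(invisible())
    s <- succ[[state]]
    if (is.null(s)) return(invisible())
    for (i in seq_len(nrow(s))) walk(s$to[i], c(path, s$label[i]))
    invisible()
  }
  walk(g$start, character(0))
  keys <- sort(ls(out))
  lapply(keys, function(k) get(k, envir = out))
}

#' Test grammaticality of a terminal sequence
#'
#' Nondeterministic membership test: simulates the set of reachable states
#' under the label sequence and accepts iff an accepting state is reached.
#'
#' @param g An [agl_grammar].
#' @param labels Character vector of terminal labels.
#' @return `TRUE` iff `labels` spells an accepting path of `g`.
#' @export
is_grammatical <- function(g, labels) {
  stopifnot(inherits(g, "agl_grammar"))
  labels <- as.character(labels)
  unknown <- setdiff(labels, g$labels)
  if (length(unknown))
    stop("unknown terminal label(s): ", paste(unknown, collapse = ", "))
  current <- g$start
  for (l in labels) {
    sel <- g$transitions$from %in% current & g$transitions$label == l
    current <- unique(g$transitions$to[sel])
    if (!length(current)) return(FALSE)
  }
  if (!length(labels)) return(g$start %in% g$accepts)
  any(current %in% g$accepts)
}

#' Realize a terminal sequence as a pitch sequence
#'
#' Concatenates each terminal's two pitches in order: a k-terminal sequence
#' becomes a 2k-tone melody.
#'
#' @param labels Character vector of terminal labels.
#' @param alphabet An [agl_alphabet].
#' @return Integer vector of MIDI note numbers, length `2 * length(labels)`.
#' @export
realize_pitches <- function(labels, alphabet) {
  stopifnot(inherits(alphabet, "agl_alphabet"))
  labels <- as.character(labels)
  unknown <- setdiff(labels, alphabet$labels)
  if (length(unknown))
    stop("unknown terminal label(s): ", paste(unknown, collapse = ", "))
  if (!length(labels)) return(integer(0))
  unlist(alphabet$pairs[labels], use.names = FALSE)
}

#' Classify the pathway of a grammatical sequence
#'
#' Finds an accepting state path for `labels` and reports which pathway tags
#' its non-shared states carry. Used to pick donor sequences for the
#' cross-pathway (error type 4) construction.
#'
#' @param g An [agl_grammar] with `pathways` tags.
#' @param labels Terminal label sequence (must be grammatical).
#' @return A pathway tag name, or `"mixed"` when states of several tags occur,
#'   or `"shared"` when no tagged state occurs on the path.
#' @export
sequence_pathway <- function(g, labels) {
  if (is.null(g$pathways)) stop("grammar has no pathway tags")
  path <- .accepting_state_path(g, labels)
  if (is.null(path)) stop("sequence is not grammatical; no pathway defined")
  tags <- unique(unlist(lapply(names(g$pathways), function(p)
    if (any(path %in% g$pathways[[p]])) p else NULL)))
  if (length(tags) == 0L) "shared" else if (length(tags) > 1L) "mixed" else tags
}

# first accepting state path (excluding start), or NULL
.accepting_state_path <- function(g, labels) {
  succ <- .succ_map(g)
  rec <- function(state, i, acc) {
    if (i > length(labels))
      return(if (state %in% g$accepts) acc else NULL)
    s <- succ[[state]]
    if (is.null(s)) return(NULL)
    s <- s[s$label == labels[i], , drop = FALSE]
    for (j in seq_len(nrow(s))) {
      r <- rec(s$to[j], i + 1L, c(acc, s$to[j]))
      if (!is.null(r)) return(r)
    }
    NULL
  }
  rec(g$start, 1L, character(0))
}

#' Select the old- and new-grammatical stimulus sets
#'
#' Enumerates the grammatical sequences whose realized tone length lies in
#' `tone_range`, draws `n_old + n_new` of them by a seeded length-stratified
#' systematic sample (so the selection covers the length range), and splits
#' them into disjoint old/new sets by alternating assignment along the
#' length-sorted order with ties broken by a seeded shuffle. Alternation keeps
#' the two length distributions comparable, so length is no cue to old/new
#' status.
#'
#' @param g An [agl_grammar].
#' @param n_old,n_new Set sizes (the study design uses 17 and 16).
#' @param seed Integer seed; the selection is reproducible.
#' @param tone_range Allowed melody length in tones (pairs are tones/2).
#' @param max_pairs Enumeration bound in terminal pairs.
#' @return List with elements `old` and `new`, each a list of label sequences.
#' @export
build_grammatical_sets <- function(g, n_old, n_new, seed = 1L,
                                   tone_range = c(8L, 30L),
                                   max_pairs = tone_range[2] %/% 2L) {
  stopifnot(n_old >= 0, n_new >= 0)
  seqs <- enumerate_sequences(g, max_pairs)
  len <- vapply(seqs, length, integer(1)) * 2L
  seqs <- seqs[len >= tone_range[1] & len <= tone_range[2]]
  n <- n_old + n_new
  if (length(seqs) < n)
    stop(sprintf("grammar yields %d sequences in the length window; %d required",
                 length(seqs), n))
  set.seed(as.integer(seed))
  # order by length, ties shuffled
  len <- vapply(seqs, length, integer(1))
  ord <- order(len, sample.int(length(seqs)))
  seqs <- seqs[ord]
  # systematic (evenly spaced) sample along the length-sorted list
  if (n > 0L) {
    idx <- unique(round(seq(1, length(seqs), length.out = n)))
    # rounding collisions: top up from unused indices
    if (length(idx) < n) {
      extra <- setdiff(seq_along(seqs), idx)
      idx <- sort(c(idx, sample(extra, n - length(idx))))
    }
    chosen <- seqs[idx]
  } else chosen <- list()
  take_old <- rep_len(c(TRUE, FALSE), n)
  if (sum(take_old) != n_old) {
    # alternation gives ceiling(n/2) to old; adjust tail assignments if needed
    need <- n_old - sum(take_old)
    flip <- if (need > 0) which(!take_old) else which(take_old)
    flip <- rev(flip)[seq_len(abs(need))]
    take_old[flip] <- !take_old[flip]
  }
  list(old = chosen[take_old], new = chosen[!take_old])
}

#' The fixture grammar shipped with the package
#'
#' A documented substitute grammar with eight tone-pair terminals (a-h),
#' eight states, and two tagged pathways (upper, lower) that rejoin at the
#' shared start and accept states. It is not a reconstruction of any published
#' grammar; it is built to satisfy the structural properties the stimulus
#' design needs: more than 33 distinct sequences of 8-30 tones, and at least
#' eight sequences per pathway. Terminals use eight pitches spanning one
#' octave.
#'
#' @return An [agl_grammar] with an embedded [agl_alphabet].
#' @export
fixture_grammar <- function() {
  load_grammar(system.file("extdata", "grammar_fixture.yaml",
                           package = "melagl", mustWork = TRUE))
}
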