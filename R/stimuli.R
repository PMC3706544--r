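# overlapping n-grams of a label vector, as collapsed strings
.ngrams <- function(labels, n) {
  L <- length(labels)
  if (L < n) return(character(0))
  vapply(seq_len(L - n + 1L), function(i)
    paste(labels[i:(i + n - 1L)], collapse = " "), character(1))
}

# attested n-gram set across a corpus of label sequences
.ngram_set <- function(seqs, n) unique(unlist(lapply(seqs, .ngrams, n = n)))

#' Generate one ungrammatical terminal sequence
#'
#' Builds a sequence of `target_len_pairs` terminals of the requested error
#' class and certifies it ungrammatical with [is_grammatical], rejection
#' sampling up to `max_tries` times. The five classes grade the similarity to
#' grammatical material:
#' \describe{
#'   \item{type 1}{entirely random terminal sequence (uniform i.i.d.).}
#'   \item{type 2}{every adjacent terminal bigram occurs in some grammatical
#'     sequence, but at least one terminal trigram occurs in none, i.e.
#'     transitions are locally legal while runs of three or more pairs are
#'     not.}
#'   \item{type 3}{a grammatical beginning and ending (anchor positions of
#'     `anchor_pairs` terminals each) around a type-1 random interior.}
#'   \item{type 4}{the first half of a sequence from one grammar pathway
#'     joined to the second half of a sequence from the other pathway.}
#'   \item{type 5}{a single adjacent swap or single deletion applied to a
#'     grammatical sequence (minimal perturbation).}
#' }
#'
#' @param type Integer 1-5.
#' @param g An [agl_grammar] (pathway tags required for type 4).
#' @param gram_seqs List of grammatical label sequences (the stimulus pool:
#'   bigram/trigram reference sets, anchors and donors are drawn from it).
#' @param target_len_pairs Desired length in terminal pairs.
#' @param seed Integer seed; generation is reproducible.
#' @param anchor_pairs Anchor length for type 3 (terminals at each end).
#' @param max_tries Rejection-sampling bound.
#' @return Character vector of terminal labels, certified ungrammatical, with
#'   attribute `error_type`.
#' @export
gen_ungrammatical <- function(type, g, gram_seqs, target_len_pairs, seed = 1L,
                              anchor_pairs = 2L, max_tries = 1000L) {
  stopifnot(type %in% 1:5, target_len_pairs >= 1L)
  set.seed(as.integer(seed))
  labels <- g$labels
  gen <- switch(type,
    `1` = function() sample(labels, target_len_pairs, replace = TRUE),
    `2` = local({
      bigrams <- .ngram_set(gram_seqs, 2L)
      parts <- strsplit(bigrams, " ", fixed = TRUE)
      succ <- split(vapply(parts, `[`, character(1), 2L),
                    vapply(parts, `[`, character(1), 1L))
      trigrams <- .ngram_set(gram_seqs, 3L)
      function() {
        s <- sample(names(succ), 1L)
        while (length(s) < target_len_pairs) {
          nxt <- succ[[s[length(s)]]]
          if (is.null(nxt)) return(NULL)   # walk stuck; retry
          s <- c(s, sample(nxt, 1L))
        }
        if (!any(!(.ngrams(s, 3L) %in% trigrams))) return(NULL)
        s
      }
    }),
    `3` = local({
      long_enough <- gram_seqs[vapply(gram_seqs, length, integer(1)) >= anchor_pairs]
      if (!length(long_enough)) stop("no grammatical sequence long enough for anchors")
      function() {
        if (target_len_pairs < 2L * anchor_pairs) return(NULL)
        pre <- long_enough[[sample.int(length(long_enough), 1L)]][seq_len(anchor_pairs)]
        sufseq <- long_enough[[sample.int(length(long_enough), 1L)]]
        suf <- sufseq[(length(sufseq) - anchor_pairs + 1L):length(sufseq)]
        mid <- sample(labels, target_len_pairs - 2L * anchor_pairs, replace = TRUE)
        c(pre, mid, suf)
      }
    }),
    `4` = local({
      if (is.null(g$pathways) || length(g$pathways) < 2L)
        stop("type-4 generation needs a grammar with two pathway tags")
      pw <- vapply(gram_seqs, function(s) sequence_pathway(g, s), character(1))
      tags <- names(g$pathways)[1:2]
      donors <- lapply(tags, function(t) gram_seqs[pw == t])
      if (any(!vapply(donors, length, integer(1))))
        stop("both pathways must contribute donor sequences for type 4")
      function() {
        flip <- sample(c(TRUE, FALSE), 1L)
        a <- donors[[if (flip) 1L else 2L]]
        b <- donors[[if (flip) 2L else 1L]]
        h <- ceiling(target_len_pairs / 2)
        a_ok <- a[vapply(a, length, integer(1)) >= h]
        b_ok <- b[vapply(b, length, integer(1)) >= target_len_pairs - h]
        if (!length(a_ok) || !length(b_ok)) return(NULL)
        da <- a_ok[[sample.int(length(a_ok), 1L)]]
        db <- b_ok[[sample.int(length(b_ok), 1L)]]
        c(da[seq_len(h)],
          db[(length(db) - (target_len_pairs - h) + 1L):length(db)])
      }
    }),
    `5` = local({
      lens <- vapply(gram_seqs, length, integer(1))
      function() {
        do_delete <- sample(c(TRUE, FALSE), 1L)
        if (do_delete && any(lens == target_len_pairs + 1L)) {
          cand <- gram_seqs[lens == target_len_pairs + 1L]
          s <- cand[[sample.int(length(cand), 1L)]]
          s[-sample.int(length(s), 1L)]
        } else if (any(lens == target_len_pairs)) {
          cand <- gram_seqs[lens == target_len_pairs]
          s <- cand[[sample.int(length(cand), 1L)]]
          pos <- which(s[-length(s)] != s[-1L])
          if (!length(pos)) return(NULL)
          i <- pos[sample.int(length(pos), 1L)]
          s[c(i, i + 1L)] <- s[c(i + 1L, i)]
          s
        } else NULL
      }
    }))
  for (i in seq_len(max_tries)) {
    s <- gen()
    if (!is.null(s) && length(s) == target_len_pairs && !is_grammatical(g, s))
      return(structure(s, error_type = type))
  }
  stop(sprintf("could not generate a certified type-%d sequence of %d pairs in %d tries",
               type, target_len_pairs, max_tries))
}

#' Length-match ungrammatical slots to grammatical lengths
#'
#' Assigns each ungrammatical slot a target length drawn bijectively from the
#' grammatical length list, so the two length multisets are identical and
#' stimulus length carries no grammaticality information.
#'
#' @param gram_lengths Integer vector of grammatical lengths.
#' @param n_slots Number of ungrammatical slots (must equal
#'   `length(gram_lengths)`).
#' @param seed Integer seed for the permutation.
#' @return Integer vector of length `n_slots`: target length per slot.
#' @export
length_match <- function(gram_lengths, n_slots, seed = 1L) {
  if (length(gram_lengths) != n_slots)
    stop(sprintf("count mismatch: %d grammatical lengths vs %d slots",
                 length(gram_lengths), n_slots))
  if (!n_slots) return(integer(0))
  set.seed(as.integer(seed))
  gram_lengths[sample.int(n_slots)]
}

#' Assemble the full AGL test set and learning schedule
#'
#' Builds the complete stimulus design: `n_old` old-grammatical and `n_new`
#' new-grammatical melodies from the grammar, ungrammatical stimuli of the
#' five error classes with counts `ungram_counts`, target lengths permutation-
#' matched to the grammatical lengths, and a learning schedule of
#' `learn_blocks` seeded random orderings of the old-grammatical items. An
#' optional pitch mapping is applied to every stimulus (labels and structure
#' unchanged). With the defaults this yields the 66-item test set
#' (17 + 16 + 6/6/7/7/7) and a 51-presentation learning schedule.
#'
#' @param g An [agl_grammar] with an embedded alphabet (or pass `alphabet`).
#' @param alphabet An [agl_alphabet]; defaults to `g$alphabet`.
#' @param mapping Optional named mapping vector from [select_mapping].
#' @param seed Integer master seed.
#' @param n_old,n_new Grammatical set sizes.
#' @param ungram_counts Integer vector of length 5: stimuli per error type.
#' @param learn_blocks Number of learning-phase blocks.
#' @return An object of class `agl_stimulus_set`: list with `stimuli` (list of
#'   stimulus records: id, category, error_type, labels, pitches, n_tones),
#'   `schedule` (data.frame block/position/id), `alphabet`, `mapping`.
#' @export
assemble_test_set <- function(g, alphabet = g$alphabet, mapping = NULL,
                              seed = 1L, n_old = 17L, n_new = 16L,
                              ungram_counts = c(6L, 6L, 7L, 7L, 7L),
                              learn_blocks = 3L) {
  if (is.null(alphabet)) stop("an alphabet is required")
  stopifnot(length(ungram_counts) == 5L)
  seed <- as.integer(seed)
  sets <- build_grammatical_sets(g, n_old, n_new, seed = seed)
  gram <- c(sets$old, sets$new)
  gram_pairs <- vapply(gram, length, integer(1))
  n_un <- sum(ungram_counts)
  targets <- length_match(gram_pairs, n_un, seed = seed + 1L)
  types <- rep.int(1:5, ungram_counts)

  stim <- list()
  add <- function(labels, category, error_type) {
    pitches <- realize_pitches(labels, alphabet)
    if (!is.null(mapping)) pitches <- apply_mapping(mapping, list(pitches))[[1]]
    stim[[length(stim) + 1L]] <<- list(
      id = sprintf("s%02d", length(stim) + 1L), category = category,
      error_type = error_type, labels = as.character(labels),
      pitches = pitches, n_tones = length(pitches))
  }
  for (s in sets$old) add(s, "old_gram", NA_integer_)
  for (s in sets$new) add(s, "new_gram", NA_integer_)
  for (i in seq_len(n_un))
    add(gen_ungrammatical(types[i], g, gram, targets[i],
                          seed = seed + 100L + i),
        "ungram", types[i])

  old_ids <- vapply(stim[seq_len(n_old)], `[[`, character(1), "id")
  set.seed(seed + 2L)
  schedule <- do.call(rbind, lapply(seq_len(learn_blocks), function(b)
    data.frame(block = b, position = seq_len(n_old),
               id = sample(old_ids), stringsAsFactors = FALSE)))
  structure(list(stimuli = stim, schedule = schedule, alphabet = alphabet,
                 mapping = mapping, seed = seed),
            class = "agl_stimulus_set")
}

#' @export
print.agl_stimulus_set <- function(x, ...) {
  cats <- vapply(x$stimuli, `[[`, character(1), "category")
  et <- vapply(x$stimuli, `[[`, integer(1), "error_type")
  cat("AGL stimulus set:", length(x$stimuli), "test stimuli (",
      sum(cats == "old_gram"), "old-grammatical,",
      sum(cats == "new_gram"), "new-grammatical,",
      sum(cats == "ungram"), "ungrammatical:",
      paste(tabulate(et[cats == "ungram"], 5), collapse = "/"), ")\n")
  cat("Learning schedule:", nrow(x$schedule), "presentations in",
      max(x$schedule$block), "blocks\n")
  if (!is.null(x$mapping)) cat("Pitch mapping applied\n")
  invisible(x)
}

#' Stimulus manifest as a data.frame
#'
#' @param set An `agl_stimulus_set`.
#' @return data.frame: id, category, error_type, label_sequence (dash-joined),
#'   pitch_csv (comma-joined MIDI numbers), n_tones.
#' @export
stimulus_manifest <- function(set) {
  data.frame(
    id = vapply(set$stimuli, `[[`, character(1), "id"),
    category = vapply(set$stimuli, `[[`, character(1), "category"),
    error_type = vapply(set$stimuli, `[[`, integer(1), "error_type"),
    label_sequence = vapply(set$stimuli, function(s)
      paste(s$labels, collapse = "-"), character(1)),
    pitch_csv = vapply(set$stimuli, function(s)
      paste(s$pitches, collapse = ","), character(1)),
    n_tones = vapply(set$stimuli, `[[`, integer(1), "n_tones"),
    stringsAsFactors = FALSE)
}

#' Write / read a stimulus manifest and learning schedule
#'
#' Plain TSV round-trip of an assembled stimulus set. `read_stimulus_set`
#' reconstructs an `agl_stimulus_set` (without alphabet/mapping provenance)
#' from the two files.
#'
#' @param set An `agl_stimulus_set`.
#' @param manifest_path,schedule_path Output TSV paths.
#' @return `write_stimulus_set` returns the paths invisibly;
#'   `read_stimulus_set` returns an `agl_stimulus_set`.
#' @export
write_stimulus_set <- function(set, manifest_path, schedule_path) {
  utils::write.table(stimulus_manifest(set), manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(set$schedule, schedule_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(manifest_path, schedule_path))
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(manifest_path, schedule_path) {
  man <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                           colClasses = c(id = "character",
                                          category = "character",
                                          error_type = "integer",
                                          label_sequence = "character",
                                          pitch_csv = "character",
                                          n_tones = "integer"))
  sched <- utils::read.table(schedule_path, sep = "\t", header = TRUE,
                             colClasses = c(block = "integer",
                                            position = "integer",
                                            id = "character"))
  stim <- lapply(seq_len(nrow(man)), function(i) list(
    id = man$id[i], category = man$category[i], error_type = man$error_type[i],
    labels = strsplit(man$label_sequence[i], "-", fixed = TRUE)[[1]],
    pitches = as.integer(strsplit(man$pitch_csv[i], ",", fixed = TRUE)[[1]]),
    n_tones = man$n_tones[i]))
  structure(list(stimuli = stim, schedule = sched, alphabet = NULL,
                 mapping = NULL, seed = NA_integer_),
            class = "agl_stimulus_set")
}
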