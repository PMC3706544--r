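#' Rendering specification for MIDI output
#'
#' @param ioi Inter-onset interval per note in milliseconds (default 330).
#' @param velocity MIDI note-on velocity, 1-127 (default 100).
#' @param program MIDI program number, 0-127 (default 0, acoustic piano).
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(ioi = 330, velocity = 100L, program = 0L) {
  if (ioi <= 0) stop("ioi must be positive")
  if (velocity < 1 || velocity > 127) stop("velocity must be in 1..127")
  if (program < 0 || program > 127) stop("program must be in 0..127")
  structure(list(ioi = ioi, velocity = as.integer(velocity),
                 program = as.integer(program)), class = "render_spec")
}

# MIDI variable-length quantity encoding
.vlq <- function(x) {
  x <- as.integer(x)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  # continuation bit on all but the last byte
  if (length(bytes) > 1L)
    bytes[-length(bytes)] <- bitwOr(bytes[-length(bytes)], 128L)
  as.raw(bytes)
}

.be <- function(x, n) as.raw(rev((x %/% 256L^(0:(n - 1L))) %% 256L))

#' Render a melody to a standard MIDI file
#'
#' Writes a format-0 single-track MIDI file in which note k (0-based) starts
#' at `k * ioi` milliseconds, lasts one inter-onset interval, and sounds at
#' the configured velocity. The file uses 500 ticks per quarter note with a
#' tempo of 500000 microseconds per quarter, so one tick equals one
#' millisecond exactly.
#'
#' @param pitches Integer vector of MIDI note numbers (non-empty).
#' @param path Output file path.
#' @param spec A [render_spec].
#' @return `path`, invisibly.
#' @export
render_midi <- function(pitches, path, spec = render_spec()) {
  pitches <- as.integer(pitches)
  if (!length(pitches)) stop("cannot render an empty melody")
  if (any(pitches < 0L | pitches > 127L)) stop("pitches must be in 0..127")
  ioi <- as.integer(round(spec$ioi))
  ev <- list()
  push <- function(delta, ...) ev[[length(ev) + 1L]] <<- c(.vlq(delta), as.raw(c(...)))
  push(0L, 0xFF, 0x51, 0x03, 0x07, 0xA1, 0x20)        # tempo 500000 us/quarter
  push(0L, 0xC0, spec$program)                         # program change, ch 1
  for (i in seq_along(pitches)) {
    push(0L, 0x90, pitches[i], spec$velocity)          # note on at i-1 IOIs
    push(ioi, 0x80, pitches[i], 0L)                    # note off one IOI later
  }
  push(0L, 0xFF, 0x2F, 0x00)                           # end of track
  track <- do.call(c, ev)
  out <- c(charToRaw("MThd"), .be(6L, 4), .be(0L, 2), .be(1L, 2), .be(500L, 2),
           charToRaw("MTrk"), .be(length(track), 4), track)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

#' Render every stimulus of a set to MIDI files
#'
#' @param set An `agl_stimulus_set`.
#' @param dir Output directory (created if missing).
#' @param spec A [render_spec].
#' @return Character vector of written paths, invisibly.
#' @export
render_stimulus_set <- function(set, dir, spec = render_spec()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(set$stimuli, function(s) {
    p <- file.path(dir, paste0(s$id, ".mid"))
    render_midi(s$pitches, p, spec)
    p
  }, character(1))
  invisible(paths)
}
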