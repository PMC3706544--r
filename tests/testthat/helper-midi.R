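# Minimal standard-MIDI-file reader, independent of the package writer.
# Returns division, tempo (us per quarter) and a data.frame of channel events
# with absolute tick times.
parse_midi <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u <- as.integer(raw)
  be <- function(i, n) sum(u[i:(i + n - 1L)] * 256^((n - 1L):0))
  stopifnot(rawToChar(raw[1:4]) == "MThd", be(5, 4) == 6)
  format <- be(9, 2); ntrk <- be(11, 2); division <- be(13, 2)
  stopifnot(rawToChar(raw[15:18]) == "MTrk")
  tlen <- be(19, 4)
  i <- 23L; end <- 22L + tlen
  time <- 0L; tempo <- NA_integer_
  ev <- list(); status <- NULL
  read_vlq <- function() {
    v <- 0L
    repeat {
      b <- u[i]; i <<- i + 1L
      v <- v * 128L + b %% 128L
      if (b < 128L) break
    }
    v
  }
  while (i <= end) {
    time <- time + read_vlq()
    b <- u[i]
    if (b == 0xFF) {
      type <- u[i + 1L]; len <- u[i + 2L]
      if (type == 0x51)
        tempo <- be(i + 3L, 3)
      i <- i + 3L + len
      if (type == 0x2F) break
    } else {
      if (b >= 128L) { status <- b; i <- i + 1L } # else running status
      hi <- status %/% 16L
      nbytes <- if (hi %in% c(12L, 13L)) 1L else 2L
      d <- u[i:(i + nbytes - 1L)]
      i <- i + nbytes
      ev[[length(ev) + 1L]] <- data.frame(
        tick = time,
        type = c(`8` = "note_off", `9` = "note_on", `12` = "program")[
          as.character(hi)],
        d1 = d[1], d2 = if (nbytes == 2L) d[2] else NA_integer_)
    }
  }
  list(format = format, n_tracks = ntrk, division = division, tempo = tempo,
       events = do.call(rbind, ev))
}

# note-on onsets in milliseconds
midi_onsets_ms <- function(parsed) {
  on <- parsed$events[parsed$events$type == "note_on" & parsed$events$d2 > 0, ]
  on$tick * (parsed$tempo / 1000) / parsed$division
}
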