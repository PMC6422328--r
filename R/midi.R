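# Standard MIDI File (format 1) writer / reader.
#
# Only the subset of SMF needed for the engine's three-voice texture is
# implemented: one tempo track carrying set-tempo meta events plus one named
# track per voice with program-change and note-on/note-off events. Written
# and parsed byte-by-byte; PPQ is ticks per quarter note, and one quarter
# note spans two eighth-note slots, so the set-tempo value (microseconds per
# quarter) is 2e6 * note_dur.

MIDI_VOICES <- c("piano", "cello", "bass")
MIDI_PROGRAMS <- c(piano = 0L, cello = 42L, bass = 32L)

uint_be <- function(x, nbytes) {
  as.raw((x %/% 256^((nbytes - 1):0)) %% 256)
}

# variable-length quantity: 7 bits per byte, high bit set on all but the last
vlq_encode <- function(x) {
  stopifnot(x >= 0)
  out <- as.raw(x %% 128)
  x <- x %/% 128
  while (x > 0) {
    out <- c(as.raw(128 + x %% 128), out)
    x <- x %/% 128
  }
  out
}

# build one MTrk chunk from a list of (tick, raw payload) message records
midi_track_chunk <- function(msgs) {
  ticks <- vapply(msgs, `[[`, numeric(1), "tick")
  ord <- order(ticks, vapply(msgs, `[[`, numeric(1), "rank"))
  body <- raw(0)
  prev <- 0
  for (i in ord) {
    body <- c(body, vlq_encode(round(msgs[[i]]$tick - prev)), msgs[[i]]$bytes)
    prev <- msgs[[i]]$tick
  }
  body <- c(body, vlq_encode(0), as.raw(c(0xFF, 0x2F, 0x00)))  # end of track
  c(charToRaw("MTrk"), uint_be(length(body), 4), body)
}

meta_msg <- function(tick, type, payload, rank = 0) {
  list(tick = tick, rank = rank,
       bytes = c(as.raw(c(0xFF, type)), vlq_encode(length(payload)), payload))
}

default_tempo_map <- function(events) {
  tm <- attr(events, "tempo_map")
  if (is.null(tm)) tm <- data.frame(time = 0, note_dur = 0.25)
  if (tm$time[1L] > 0) tm <- rbind(data.frame(time = 0, note_dur = tm$note_dur[1L]), tm)
  tm$us_per_qn <- round(2e6 * tm$note_dur)
  tm
}

# piecewise-linear second -> tick conversion under a tempo map
sec_to_tick <- function(t, tm, ppq) {
  bounds <- tm$time
  tick0 <- cumsum(c(0, diff(bounds) * 1e6 / (tm$us_per_qn[-nrow(tm)] / ppq)))
  i <- findInterval(t, bounds)
  i[i < 1L] <- 1L
  tick0[i] + (t - bounds[i]) * 1e6 / (tm$us_per_qn[i] / ppq)
}

#' Write note events to a Standard MIDI File (format 1)
#'
#' One tempo track plus one track per voice (piano, cello, bass; a voice with
#' no events still gets an empty named track). Tempo meta events are derived
#' from the eighth-note duration map attached by [generate_sequence()] (one
#' quarter note = two eighth notes), so the rendered timing reproduces the
#' engine's `note_dur` trajectory.
#'
#' @param events Non-empty event data frame (`onset`, `duration`, `pitch`,
#'   `velocity`, `voice`).
#' @param path Output file path.
#' @param tempo_map Optional data frame (`time`, `note_dur`) overriding the
#'   `tempo_map` attribute of `events`; defaults to a constant 0.25 s eighth
#'   note (120 BPM) when neither is present.
#' @param ppq Ticks per quarter note.
#' @return `path`, invisibly.
#' @seealso [read_midi()]
#' @export
write_midi <- function(events, path, tempo_map = NULL, ppq = 480L) {
  if (is.null(events) || nrow(events) == 0L) stopf("events must be non-empty")
  stopifnot(all(c("onset", "duration", "pitch", "velocity", "voice") %in%
                  names(events)))
  if (any(events$duration <= 0)) stopf("all durations must be positive")
  tm <- if (is.null(tempo_map)) default_tempo_map(events)
        else default_tempo_map(structure(events, tempo_map = tempo_map))

  tempo_msgs <- lapply(seq_len(nrow(tm)), function(i) {
    meta_msg(round(sec_to_tick(tm$time[i], tm, ppq)), 0x51,
             uint_be(tm$us_per_qn[i], 3))
  })
  tempo_track <- midi_track_chunk(
    c(list(meta_msg(0, 0x03, charToRaw("tempo"), rank = -2)), tempo_msgs))

  voice_tracks <- lapply(seq_along(MIDI_VOICES), function(vi) {
    voice <- MIDI_VOICES[vi]
    ch <- vi - 1L
    ev <- events[events$voice == voice, , drop = FALSE]
    msgs <- list(
      meta_msg(0, 0x03, charToRaw(voice), rank = -2),
      list(tick = 0, rank = -1,
           bytes = as.raw(c(0xC0 + ch, MIDI_PROGRAMS[[voice]]))))
    for (i in seq_len(nrow(ev))) {
      on_tick <- round(sec_to_tick(ev$onset[i], tm, ppq))
      off_tick <- round(sec_to_tick(ev$onset[i] + ev$duration[i], tm, ppq))
      msgs[[length(msgs) + 1L]] <- list(
        tick = on_tick, rank = 1,
        bytes = as.raw(c(0x90 + ch, ev$pitch[i], ev$velocity[i])))
      msgs[[length(msgs) + 1L]] <- list(
        tick = off_tick, rank = 0,  # offs sort before ons at equal ticks
        bytes = as.raw(c(0x80 + ch, ev$pitch[i], 0x40)))
    }
    midi_track_chunk(msgs)
  })

  header <- c(charToRaw("MThd"), uint_be(6, 4), uint_be(1, 2),
              uint_be(1L + length(MIDI_VOICES), 2), uint_be(ppq, 2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, tempo_track, do.call(c, voice_tracks)), con)
  invisible(path)
}

vlq_decode <- function(bytes, pos) {
  val <- 0
  repeat {
    b <- as.integer(bytes[pos])
    pos <- pos + 1L
    val <- val * 128 + (b %% 128)
    if (b < 128) break
  }
  list(value = val, pos = pos)
}

be_int <- function(bytes) sum(as.integer(bytes) * 256^((length(bytes) - 1):0))

# parse one MTrk body into a data frame of (tick, status, d1, d2) plus metas
parse_track <- function(body) {
  pos <- 1L
  tick <- 0
  running <- NA_integer_
  notes <- list()
  name <- NA_character_
  tempos <- list()
  while (pos <= length(body)) {
    d <- vlq_decode(body, pos)
    tick <- tick + d$value
    pos <- d$pos
    b <- as.integer(body[pos])
    if (b == 0xFF) {
      type <- as.integer(body[pos + 1L])
      ln <- vlq_decode(body, pos + 2L)
      payload <- body[seq.int(ln$pos, length.out = ln$value)]
      pos <- ln$pos + ln$value
      if (type == 0x2F) break
      if (type == 0x03) name <- rawToChar(payload)
      if (type == 0x51) tempos[[length(tempos) + 1L]] <-
          data.frame(tick = tick, us_per_qn = be_int(payload))
    } else if (b %in% c(0xF0, 0xF7)) {  # sysex: skip
      ln <- vlq_decode(body, pos + 1L)
      pos <- ln$pos + ln$value
    } else {
      if (b >= 0x80) { running <- b; pos <- pos + 1L } else b <- running
      hi <- b %/% 16
      ndata <- if (hi %in% c(12L, 13L)) 1L else 2L
      d1 <- as.integer(body[pos])
      d2 <- if (ndata == 2L) as.integer(body[pos + 1L]) else NA_integer_
      pos <- pos + ndata
      if (hi == 9L || hi == 8L)
        notes[[length(notes) + 1L]] <- data.frame(
          tick = tick, on = (hi == 9L && d2 > 0L), pitch = d1, velocity = d2)
    }
  }
  list(name = name,
       notes = if (length(notes)) do.call(rbind, notes) else NULL,
       tempos = if (length(tempos)) do.call(rbind, tempos) else NULL)
}

#' Read a Standard MIDI File written by [write_midi()]
#'
#' Parses the byte stream, reconstructs the tempo map from set-tempo meta
#' events, pairs note-on/note-off messages per track, and converts ticks back
#' to seconds. Voice labels are taken from the track-name meta events.
#'
#' @param path Path to a `.mid` file.
#' @return Event data frame (`onset`, `duration`, `pitch`, `velocity`,
#'   `voice`) ordered by onset, with the parsed `tempo_map` (tick,
#'   microseconds per quarter) as an attribute.
#' @export
read_midi <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (!identical(rawToChar(bytes[1:4]), "MThd")) stopf("not a MIDI file: %s", path)
  ppq <- be_int(bytes[13:14])
  ntrk <- be_int(bytes[11:12])
  pos <- 15L
  tracks <- vector("list", ntrk)
  for (k in seq_len(ntrk)) {
    stopifnot(identical(rawToChar(bytes[pos + 0:3]), "MTrk"))
    ln <- be_int(bytes[pos + 4:7])
    tracks[[k]] <- parse_track(bytes[seq.int(pos + 8L, length.out = ln)])
    pos <- pos + 8L + ln
  }
  tempos <- do.call(rbind, lapply(tracks, `[[`, "tempos"))
  if (is.null(tempos)) tempos <- data.frame(tick = 0, us_per_qn = 500000)
  tempos <- tempos[order(tempos$tick), , drop = FALSE]
  if (tempos$tick[1L] > 0)
    tempos <- rbind(data.frame(tick = 0, us_per_qn = tempos$us_per_qn[1L]), tempos)
  sec0 <- cumsum(c(0, diff(tempos$tick) * tempos$us_per_qn[-nrow(tempos)] / (ppq * 1e6)))
  tick_to_sec <- function(tk) {
    i <- pmax(findInterval(tk, tempos$tick), 1L)
    sec0[i] + (tk - tempos$tick[i]) * tempos$us_per_qn[i] / (ppq * 1e6)
  }

  out <- list()
  for (tr in tracks) {
    if (is.null(tr$notes)) next
    voice <- if (!is.na(tr$name)) tr$name else "unknown"
    nt <- tr$notes
    open <- list()  # FIFO of open note-ons per pitch
    for (i in seq_len(nrow(nt))) {
      key <- as.character(nt$pitch[i])
      if (nt$on[i]) {
        open[[key]] <- c(open[[key]], i)
      } else if (length(open[[key]])) {
        j <- open[[key]][1L]
        open[[key]] <- open[[key]][-1L]
        out[[length(out) + 1L]] <- data.frame(
          onset = tick_to_sec(nt$tick[j]),
          duration = tick_to_sec(nt$tick[i]) - tick_to_sec(nt$tick[j]),
          pitch = nt$pitch[j], velocity = nt$velocity[j], voice = voice,
          stringsAsFactors = FALSE)
      }
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else empty_events()
  ev <- ev[order(ev$onset, ev$pitch), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "tempo_map") <- tempos
  ev
}
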