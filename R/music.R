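#' Map an affect point onto the five music-structural parameters
#'
#' The rule base of the music engine: valence and arousal are translated into
#' tempo (eighth-note duration), rhythmic density (probability that an
#' eighth-note grid slot sounds), a MIDI-velocity range, a probability
#' distribution over three pitch registers, and a harmonic mode index on the
#' 7-step valence-ordered scale of church modes.
#'
#' * `note_dur = 0.3 - 0.15 * arousal` seconds (0.3 s at rest, 0.15 s fully
#'   aroused).
#' * `p_note = arousal`.
#' * velocities are drawn discrete-uniform in `{50, ..., round(40*arousal + 60)}`.
#' * register probabilities over (C3, C4, C5) follow the monotone pitch rule by
#'   default: all mass on C3 at valence 0, all on C5 at valence 1
#'   (`pitch_rule = "as-printed"` selects the non-monotone textbook piecewise
#'   form instead, see Details).
#' * `mode_index = round(7 - 6*valence)` clamped to 1..7 (1 = Lydian,
#'   7 = Locrian), halves rounded up.
#'
#' @details The as-printed register rule is `p(C3) = 2*val` for `val < 0.5`,
#'   `p(C5) = 2*(val - 0.5)` for `val >= 0.5`, remaining mass on C4. It is not
#'   monotone in valence (register drops back to C4 at both extremes of each
#'   branch); the monotone default replaces `p(C3) = 2*val` with
#'   `p(C3) = 1 - 2*val` so that low valence actually selects low registers.
#'
#' @param p An [affect_point()].
#' @param pitch_rule `"monotone"` (default) or `"as-printed"`.
#' @return An object of class `music_params`: list with `note_dur`, `p_note`,
#'   `vel_lo`, `vel_hi`, `register_probs` (named probability triple over
#'   C3/C4/C5), `mode_index`.
#' @examples
#' affect_to_params(affect_point(0, 0))$note_dur    # 0.3
#' affect_to_params(affect_point(0.5, 0.5))$mode_index  # 4 (Dorian)
#' @export
affect_to_params <- function(p, pitch_rule = c("monotone", "as-printed")) {
  stopifnot(inherits(p, "affect_point"))
  pitch_rule <- match.arg(pitch_rule)
  val <- p$valence
  aro <- p$arousal

  if (pitch_rule == "monotone") {
    if (val < 0.5) probs <- c(C3 = 1 - 2 * val, C4 = 2 * val, C5 = 0)
    else           probs <- c(C3 = 0, C4 = 1 - 2 * (val - 0.5), C5 = 2 * (val - 0.5))
  } else {
    if (val < 0.5) probs <- c(C3 = 2 * val, C4 = 1 - 2 * val, C5 = 0)
    else           probs <- c(C3 = 0, C4 = 1 - 2 * (val - 0.5), C5 = 2 * (val - 0.5))
  }

  out <- list(
    note_dur = 0.3 - 0.15 * aro,
    p_note = aro,
    vel_lo = 50L,
    vel_hi = as.integer(round_half_up(40 * aro + 60)),
    register_probs = probs,
    mode_index = as.integer(clamp(round_half_up(7 - 6 * val), 1, 7))
  )
  class(out) <- "music_params"
  out
}

# valence-ordered church modes (most positive first) with their tonic as a
# degree of the C-major scale
MODE_TABLE <- data.frame(
  mode_name = c("Lydian", "Ionian", "Mixolydian", "Dorian",
                "Aeolian", "Phrygian", "Locrian"),
  tonic_degree = c(4L, 1L, 5L, 2L, 6L, 3L, 7L),  # F C G D A E B
  stringsAsFactors = FALSE
)

C_MAJOR_PCS <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)  # C D E F G A B
PC_NAMES <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")

# triad on a degree of the C-major scale: root + two stacked diatonic thirds
diatonic_triad <- function(degree) {
  idx <- ((degree - 1L + c(0L, 2L, 4L)) %% 7L) + 1L
  pcs <- C_MAJOR_PCS[idx]
  third <- (pcs[2L] - pcs[1L]) %% 12L
  fifth <- (pcs[3L] - pcs[1L]) %% 12L
  quality <- if (third == 4L && fifth == 7L) "maj"
             else if (third == 3L && fifth == 7L) "min"
             else if (third == 3L && fifth == 6L) "dim"
             else "other"
  list(root_pc = pcs[1L], quality = quality, pcs = pcs,
       name = paste0(PC_NAMES[pcs[1L] + 1L], "_", quality))
}

#' Chord progression of a church mode
#'
#' Builds the four-bar tonic / subdominant-function / dominant-function / tonic
#' progression of the selected mode over the pitch-class material of C major
#' (every mode is a rotation of the white-key scale; the mode's tonic is the
#' corresponding degree of C major). The middle chords are the triads on the
#' mode-scale degrees 5 and 4, played dominant-first, which reproduces the
#' canonical Lydian realization F_maj | C_maj | B_dim | F_maj. The first and
#' fourth chords are always identical.
#'
#' @param mode_index Integer 1..7 on the valence-ordered scale
#'   (1 Lydian, 2 Ionian, 3 Mixolydian, 4 Dorian, 5 Aeolian, 6 Phrygian,
#'   7 Locrian).
#' @return An object of class `chord_progression`: list with `mode_name`,
#'   `mode_index`, `scale_pcs` (the mode's seven pitch classes) and `chords`,
#'   a list of 4 chords each holding `root_pc`, `quality`, `pcs`, `name`.
#' @examples
#' sapply(mode_to_progression(1)$chords, `[[`, "name")
#' @export
mode_to_progression <- function(mode_index) {
  if (!is.numeric(mode_index) || length(mode_index) != 1L ||
      mode_index != as.integer(mode_index) || mode_index < 1 || mode_index > 7)
    stopf("mode_index must be an integer in 1..7 (got %s)", format(mode_index))
  mode_index <- as.integer(mode_index)
  tonic <- MODE_TABLE$tonic_degree[mode_index]
  # degrees of the C-major scale counted from the mode tonic
  degree <- function(k) ((tonic - 1L + k - 1L) %% 7L) + 1L
  chords <- lapply(c(1L, 5L, 4L, 1L), function(k) diatonic_triad(degree(k)))
  scale_pcs <- C_MAJOR_PCS[((tonic - 1L + 0:6) %% 7L) + 1L]
  structure(list(mode_name = MODE_TABLE$mode_name[mode_index],
                 mode_index = mode_index,
                 scale_pcs = scale_pcs,
                 chords = chords),
            class = "chord_progression")
}

REGISTER_BASE <- c(C3 = 48L, C4 = 60L, C5 = 72L)

empty_events <- function() {
  data.frame(onset = numeric(0), duration = numeric(0), pitch = integer(0),
             velocity = integer(0), voice = character(0),
             stringsAsFactors = FALSE)
}

#' Sample one bar of note events
#'
#' A bar is 8 eighth-note slots of length `params$note_dur`. Each slot sounds
#' independently with probability `params$p_note`; a sounded slot draws a piano
#' note whose pitch class is uniform over the chord tones, placed in the octave
#' starting at a register (C3/C4/C5) sampled from `params$register_probs`, with
#' velocity uniform-integer in `[vel_lo, vel_hi]`. The cello sustains the chord
#' root (octave C3) for the whole bar and the bass doubles it an octave lower.
#' Randomness is taken from the current RNG state; seed with [set.seed()] or
#' use [generate_sequence()] for a fully seeded stream.
#'
#' @param params A `music_params` object from [affect_to_params()].
#' @param chord One chord from [mode_to_progression()] (`$chords[[i]]`).
#' @param bar_start Bar onset in seconds.
#' @return Data frame of note events: `onset`, `duration` (seconds), `pitch`
#'   (MIDI number), `velocity`, `voice` (piano/cello/bass).
#' @export
sample_bar <- function(params, chord, bar_start = 0) {
  stopifnot(inherits(params, "music_params"))
  slots <- bar_start + params$note_dur * (0:7)
  sounded <- stats::runif(8) < params$p_note
  n <- sum(sounded)
  piano <- if (n > 0) {
    regs <- sample(names(REGISTER_BASE), n, replace = TRUE,
                   prob = params$register_probs)
    tones <- chord$pcs[sample.int(length(chord$pcs), n, replace = TRUE)]
    data.frame(
      onset = slots[sounded],
      duration = rep(params$note_dur, n),
      pitch = REGISTER_BASE[regs] + tones,
      velocity = as.integer(sample(seq.int(params$vel_lo, params$vel_hi), n,
                                   replace = TRUE)),
      voice = rep("piano", n),
      stringsAsFactors = FALSE
    )
  } else empty_events()
  bar_len <- 8 * params$note_dur
  held_vel <- as.integer(round_half_up((params$vel_lo + params$vel_hi) / 2))
  held <- data.frame(
    onset = rep(bar_start, 2),
    duration = rep(bar_len, 2),
    pitch = c(REGISTER_BASE[["C3"]] + chord$root_pc,
              REGISTER_BASE[["C3"]] - 12L + chord$root_pc),
    velocity = rep(held_vel, 2),
    voice = c("cello", "bass"),
    stringsAsFactors = FALSE
  )
  out <- rbind(piano, held)
  rownames(out) <- NULL
  out
}

#' Generate a seeded stream of note events along an affect trajectory
#'
#' Bars are generated back-to-back; the four-chord progression advances one
#' chord per bar and cycles every 4 bars. The harmonic mode (hence the
#' progression) is re-read from the trajectory at each bar boundary; all other
#' parameters are re-read at every eighth-note slot boundary, so parameter
#' updates take effect at the next slot without mid-note discontinuities.
#' Identical `(trajectory, seed)` pairs produce identical event streams.
#'
#' @param traj An [affect_trajectory()] (or an [affect_point()], treated as a
#'   constant trajectory).
#' @param total_dur Total duration in seconds; the last bar may extend past it.
#' @param seed Integer RNG seed.
#' @param pitch_rule Passed to [affect_to_params()].
#' @return Event data frame as in [sample_bar()], ordered by onset, with
#'   attributes `bars` (per-bar table of `bar_start`, `mode_index`,
#'   `mode_name`, `chord`) and `tempo_map` (data frame `time`, `note_dur` of
#'   eighth-note duration changes, used by [write_midi()]).
#' @examples
#' ev <- generate_sequence(affect_point(1, 1), total_dur = 10, seed = 1)
#' head(ev)
#' @export
generate_sequence <- function(traj, total_dur, seed = 1L,
                              pitch_rule = c("monotone", "as-printed")) {
  if (inherits(traj, "affect_point")) traj <- constant_trajectory(traj)
  if (!inherits(traj, "affect_trajectory") || nrow(traj) == 0L)
    stopf("traj must be a non-empty affect_trajectory")
  stopifnot(is.numeric(total_dur), total_dur > 0)
  pitch_rule <- match.arg(pitch_rule)

  with_seed(seed, {
    t <- 0
    bar <- 0L
    pieces <- list()
    bars <- list()
    tempo <- list()
    last_dur <- NA_real_
    while (t < total_dur - 1e-9) {
      pb <- affect_to_params(trajectory_at(traj, t), pitch_rule)
      prog <- mode_to_progression(pb$mode_index)
      chord <- prog$chords[[(bar %% 4L) + 1L]]
      # per-slot parameter refresh: slot durations can change within a bar
      slot_events <- list()
      st <- t
      for (slot in 1:8) {
        ps <- affect_to_params(trajectory_at(traj, st), pitch_rule)
        if (is.na(last_dur) || ps$note_dur != last_dur) {
          tempo[[length(tempo) + 1L]] <- data.frame(time = st,
                                                    note_dur = ps$note_dur)
          last_dur <- ps$note_dur
        }
        if (stats::runif(1) < ps$p_note) {
          reg <- sample(names(REGISTER_BASE), 1L, prob = ps$register_probs)
          tone <- chord$pcs[sample.int(length(chord$pcs), 1L)]
          slot_events[[length(slot_events) + 1L]] <- data.frame(
            onset = st, duration = ps$note_dur,
            pitch = REGISTER_BASE[[reg]] + tone,
            velocity = as.integer(sample(seq.int(ps$vel_lo, ps$vel_hi), 1L)),
            voice = "piano", stringsAsFactors = FALSE)
        }
        st <- st + ps$note_dur
      }
      bar_len <- st - t
      held_vel <- as.integer(round_half_up((pb$vel_lo + pb$vel_hi) / 2))
      slot_events[[length(slot_events) + 1L]] <- data.frame(
        onset = rep(t, 2), duration = rep(bar_len, 2),
        pitch = c(REGISTER_BASE[["C3"]] + chord$root_pc,
                  REGISTER_BASE[["C3"]] - 12L + chord$root_pc),
        velocity = rep(held_vel, 2),
        voice = c("cello", "bass"), stringsAsFactors = FALSE)
      pieces[[bar + 1L]] <- do.call(rbind, slot_events)
      bars[[bar + 1L]] <- data.frame(bar_start = t, mode_index = pb$mode_index,
                                     mode_name = prog$mode_name,
                                     chord = chord$name,
                                     stringsAsFactors = FALSE)
      t <- st
      bar <- bar + 1L
    }
    ev <- do.call(rbind, pieces)
    ev <- ev[order(ev$onset, ev$pitch), , drop = FALSE]
    rownames(ev) <- NULL
    attr(ev, "bars") <- do.call(rbind, bars)
    attr(ev, "tempo_map") <- do.call(rbind, tempo)
    attr(ev, "seed") <- seed
    ev
  })
}
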