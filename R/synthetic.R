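# Synthetic EEG: 1/f background, class-dependent narrow-band oscillations,
# and a simulated responder, so decoder, protocol and evaluation code are
# exercisable end-to-end without hardware.

# n samples of 1/f^exponent Gaussian noise via spectral shaping of white
# noise; uses the current RNG state. Normalized by the analytic constant
# (sqrt of the mean squared spectral weight) so E[var] = 1 regardless of the
# realization or the chunk length - normalizing by the sample SD would tie
# relative band power to the chunk length and bias stitched-together streams.
pink_noise <- function(n, fs, exponent = 1) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n        # two-sided frequency axis
  scale <- c(0, f[-1L]^(-exponent / 2))  # kill DC
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x / sqrt(mean(scale^2))
}

# band-limited unit-variance noise (amplitude-modulated carriers for the
# planted oscillatory effects); uses the current RNG state
band_noise <- function(n, fs, band, order = 2L, ripple = 0.5) {
  flt <- design_bandpass(band[1L], band[2L], fs, order, ripple)
  x <- zerophase_filter(flt$b, flt$a, stats::rnorm(n))
  x / stats::sd(x)
}

#' Generate a multichannel 1/f background EEG recording
#'
#' Independent `1/f^exponent` Gaussian noise per channel (exponent 0 gives
#' white noise), scaled to a common standard deviation, labeled with the
#' standard 14-channel montage. Fully deterministic under `seed`.
#'
#' @param duration Length in seconds.
#' @param n_channels Number of channels.
#' @param fs Sampling rate in Hz.
#' @param exponent Spectral slope of the background.
#' @param seed Integer RNG seed.
#' @param sd Per-channel standard deviation in microvolts.
#' @param channel_names Channel labels.
#' @return An [eeg_recording()] with an empty event table.
#' @export
gen_background <- function(duration, n_channels = 14L, fs = 128, exponent = 1,
                           seed = 1L, sd = 10,
                           channel_names = emotiv_montage()[seq_len(n_channels)]) {
  stopifnot(duration > 0)
  with_seed(seed, gen_background_impl(duration, n_channels, fs, exponent, sd,
                                      channel_names))
}

gen_background_impl <- function(duration, n_channels = 14L, fs = 128,
                                exponent = 1, sd = 10,
                                channel_names = emotiv_montage()[seq_len(n_channels)]) {
  n <- round(duration * fs)
  samples <- t(vapply(seq_len(n_channels),
                      function(ch) sd * pink_noise(n, fs, exponent),
                      numeric(n)))
  eeg_recording(samples, fs, channel_names)
}

#' Planted class effect for synthetic calibration recordings
#'
#' Describes the oscillatory band-power difference between the happy and sad
#' listening conditions: a band-limited noise component added to a subset of
#' channels with class-specific amplitude. Neutral periods receive the mean of
#' the two class amplitudes.
#'
#' @param channels Channels carrying the effect.
#' @param band Frequency band (lo, hi) in Hz of the added oscillation.
#' @param amp Named amplitudes (standard deviation in microvolts) of the
#'   oscillation per class, `c(sad = ..., happy = ...)`.
#' @param background_sd Background standard deviation in microvolts.
#' @param effect_size Scalar multiplying both class amplitudes; 0 removes the
#'   planted effect entirely (null data).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(channels = c("P7", "P8", "O1", "O2"),
                        band = c(8, 13),
                        amp = c(sad = 30, happy = 10),
                        background_sd = 10,
                        effect_size = 1) {
  stopifnot(all(c("sad", "happy") %in% names(amp)), all(amp >= 0),
            effect_size >= 0, background_sd > 0, length(band) == 2L)
  structure(list(channels = channels, band = band, amp = amp,
                 background_sd = background_sd, effect_size = effect_size),
            class = "effect_spec")
}

#' Generate a synthetic calibration recording
#'
#' Lays out a full calibration session (six 20-s excerpts interleaved with six
#' 10-s idle periods, 180 s total, plus a short background tail so every
#' analysis window that starts inside a period is full length). During happy /
#' sad / neutral periods a band-limited oscillation is added to the effect's
#' channels with the class-specific amplitude; idle periods are background
#' only. The event table is embedded in the returned recording.
#'
#' @param effect An [effect_spec()].
#' @param seed Integer RNG seed (drives both the schedule order and the
#'   noise).
#' @param exponent Background spectral slope.
#' @param tail_s Background tail after the last idle period, seconds.
#' @return An [eeg_recording()] with the schedule's events.
#' @export
gen_calibration_recording <- function(effect = effect_spec(), seed = 1L,
                                      exponent = 1, tail_s = 4) {
  stopifnot(inherits(effect, "effect_spec"))
  with_seed(seed, {
    sched <- build_calibration_schedule_impl()
    total <- sum(sched$duration) + tail_s
    rec <- gen_background_impl(total, exponent = exponent,
                               sd = effect$background_sd)
    fs <- rec$fs
    ch_idx <- match(effect$channels, rec$channel_names)
    if (anyNA(ch_idx)) stopf("effect channels not in montage")
    class_amp <- c(effect$amp["sad"] , effect$amp["happy"],
                   mean(effect$amp[c("sad", "happy")]))
    names(class_amp) <- c("sad", "happy", "neutral")
    for (i in seq_len(nrow(sched))) {
      lab <- sched$label[i]
      if (lab == "idle") next
      amp <- effect$effect_size * class_amp[[lab]]
      if (amp <= 0) next
      idx <- (round(sched$onset[i] * fs) + 1L):round((sched$onset[i] + sched$duration[i]) * fs)
      for (ci in ch_idx) {
        rec$samples[ci, idx] <- rec$samples[ci, idx] +
          amp * band_noise(length(idx), fs, effect$band)
      }
    }
    rec$events <- sched[, c("onset", "duration", "label")]
    rec
  })
}

#' Configuration of the simulated closed-loop responder
#'
#' The responder emulates a participant who self-induces emotions: an internal
#' affect state in \[0, 1\] follows first-order dynamics towards the active
#' task target (1 for `to_happy`, 0 for `to_sad`) during action periods and
#' relaxes towards a personal bias during rest; emitted EEG is 1/f background
#' plus a band-limited oscillation on the coupled channels whose amplitude is
#' a monotone function of the state. Calibrating the decoder on a recording
#' generated with [responder_effect()] aligns its discriminant with the
#' coupled features, closing the loop.
#'
#' @param channels Coupled channels.
#' @param band Coupled band (lo, hi) in Hz; gamma by default, echoing the
#'   emotion-related gamma modulations the coupling emulates.
#' @param amp_lo,amp_hi Oscillation amplitude (microvolt SD) at state 0 / 1;
#'   the default gain map interpolates linearly (monotone).
#' @param gain Optional custom monotone gain function `state -> amplitude`.
#' @param tau_action,tau_rest First-order time constants (seconds) of the
#'   state dynamics during action and rest; `Inf` freezes the state
#'   (decoupled null responder).
#' @param bias Personal resting-state bias in \[0, 1\].
#' @param exponent Background spectral slope.
#' @param background_sd Background SD in microvolts.
#' @return Object of class `responder_config`.
#' @export
responder_config <- function(channels = c("FC6", "F4", "F8", "AF4"),
                             band = c(30, 47),
                             amp_lo = 5, amp_hi = 30, gain = NULL,
                             tau_action = 5, tau_rest = 10, bias = 0.5,
                             exponent = 1, background_sd = 10) {
  stopifnot(amp_lo >= 0, amp_hi >= amp_lo, tau_action > 0, tau_rest > 0,
            bias >= 0, bias <= 1)
  if (is.null(gain)) gain <- function(s) amp_lo + (amp_hi - amp_lo) * clamp01(s)
  structure(list(channels = channels, band = band, amp_lo = amp_lo,
                 amp_hi = amp_hi, gain = gain, tau_action = tau_action,
                 tau_rest = tau_rest, bias = bias, exponent = exponent,
                 background_sd = background_sd),
            class = "responder_config")
}

#' Calibration effect matched to a responder
#'
#' Returns the [effect_spec()] whose class amplitudes equal the responder's
#' gain at state 0 (sad) and 1 (happy) on the coupled channels/band, so that a
#' model calibrated on [gen_calibration_recording()] discriminates along the
#' responder's coupled features.
#'
#' @param cfg A [responder_config()].
#' @return An [effect_spec()].
#' @export
responder_effect <- function(cfg) {
  stopifnot(inherits(cfg, "responder_config"))
  effect_spec(channels = cfg$channels, band = cfg$band,
              amp = c(sad = cfg$gain(0), happy = cfg$gain(1)),
              background_sd = cfg$background_sd)
}

# advance the first-order responder state by dt towards target with time
# constant tau (tau = Inf freezes the state)
responder_step_state <- function(state, target, tau, dt) {
  if (!is.finite(tau)) return(state)
  state + (target - state) * (1 - exp(-dt / tau))
}

#' Generate a pair of series with a planted unidirectional lagged dependence
#'
#' `x` is white noise and `y(t) = coef * x(t - lag) + noise`: `x`
#' Granger-causes `y`, never the reverse. Fixture for causality tests.
#'
#' @param coef Coupling coefficient, `|coef| < 1`.
#' @param lag Lag in samples (>= 1).
#' @param n Series length.
#' @param seed Integer RNG seed.
#' @return List with numeric vectors `x` and `y` of length `n`.
#' @export
gen_var_pair <- function(coef = 0.8, lag = 1L, n = 600L, seed = 1L) {
  stopifnot(abs(coef) < 1, lag >= 1L, n > lag + 1L)
  with_seed(seed, {
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    y[(lag + 1L):n] <- y[(lag + 1L):n] + coef * x[1L:(n - lag)]
    list(x = x, y = y)
  })
}

#' Random mood self-assessment ratings
#'
#' Fourteen bipolar 7-point items emulating the pre-session mood
#' questionnaire; used when simulating participant sessions.
#'
#' @param seed Integer RNG seed.
#' @return Named integer vector of 14 ratings in 1..7.
#' @export
gen_mood_ratings <- function(seed = 1L) {
  items <- c("exhausted_refreshed", "calmed_excited", "distracted_concentrated",
             "scattered_focused", "angry_contented", "tired_awake",
             "sad_happy", "tense_relaxed", "bored_interested",
             "insecure_confident", "passive_active", "gloomy_cheerful",
             "restless_serene", "weary_alert")
  with_seed(seed, stats::setNames(sample.int(7L, length(items), replace = TRUE),
                                  items))
}
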