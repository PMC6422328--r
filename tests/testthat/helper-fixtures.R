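# Shared fixtures, built once per test run and memoised (several suites need
# the same calibrated model / session and they are the expensive objects).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# responder biased slightly sad so to_happy trials dominate, gamma-coupled
fx_cfg <- function() fixture("cfg", responder_config(bias = 0.35))

# strong-effect calibration recording matched to the responder coupling
fx_cal_rec <- function() fixture("cal_rec",
  gen_calibration_recording(responder_effect(fx_cfg()), seed = 101))

fx_model <- function() fixture("model", calibrate(fx_cal_rec()))

# 20-trial closed-loop session (the paper's familiarization-session size)
fx_session <- function() fixture("session",
  run_session(fx_model(), fx_cfg(), n_trials = 20L, seed = 7))

# null-effect calibration recording (no class difference at all)
fx_null_rec <- function() fixture("null_rec",
  gen_calibration_recording(effect_spec(effect_size = 0), seed = 202))

# magnitude response of the package's band-pass at frequency f (Hz); analytic
# oracle independent of the time-domain filtering path
filter_gain <- function(lo, hi, fs, f, order = 2L, ripple = 0.5) {
  flt <- design_bandpass(lo, hi, fs, order, ripple)
  z <- exp(-2i * pi * f / fs)
  vapply(z, function(zz) {
    k <- 0:(length(flt$b) - 1L)
    Mod(sum(flt$b * zz^k) / sum(flt$a * zz^k))
  }, numeric(1))
}

# lightweight stand-in session for statistics that only need trial means and
# mood ratings (synthetic by construction)
fake_session <- function(tasks, rest_means, action_means, mood = NULL,
                         participant = "fake") {
  trials <- Map(function(i, tk, r, a)
    list(trial = i, task = tk, rest_mean = r, action_mean = a),
    seq_along(tasks), tasks, rest_means, action_means)
  structure(list(participant = participant, trials = trials,
                 mood_ratings = mood),
            class = "bci_session")
}
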