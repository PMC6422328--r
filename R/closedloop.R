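# Closed-loop rest/action protocol: wires decoder scores into music-engine
# parameters against a simulated responder. Time is simulated; samples are
# generated responder-side, scored with the calibrated model every 0.5 s, and
# every action-period score update sets the engine input to val = aro = s.

#' Run a closed-loop interaction session
#'
#' Each trial is a 15-s resting period with no music (scores logged in the
#' background), task assignment from the mean resting score ([assign_task()]),
#' a 2-s cue gap, and a 30-s action period in which every 0.5-s score update
#' drives the music engine with `val = aro = s` while the responder's internal
#' state tracks the task target. Scores are computed with the online machinery
#' (latest 4-s window per 0.5-s step); a score belongs to the period it is
#' emitted in, so the first resting scores use data reaching back into the
#' previous action period, matching the streaming convention. A 4-s lead-in
#' precedes the first trial and a 4-s tail follows the last one so every
#' analysis window is full length.
#'
#' @param model A calibrated `affect_model` (see [calibrate()]); its
#'   discriminant should align with the responder's coupled features (see
#'   [responder_effect()]).
#' @param cfg A [responder_config()].
#' @param n_trials Number of trials (the reference protocols use 20 or 50).
#' @param seed Integer seed; fixed seed + config give identical score traces.
#' @param rest_s,cue_s,action_s Period durations in seconds.
#' @param participant Participant identifier stored in the session.
#' @param mood_ratings Optional named vector of 14 bipolar 7-point mood items
#'   (see [gen_mood_ratings()]).
#' @param render_music If `TRUE`, the action-period score trajectory is
#'   rendered to note events per trial (stored as `trials[[i]]$music`); no
#'   music events ever occur during rest.
#' @return Object of class `bci_session`: `participant`, `trials` (each with
#'   `task`, `rest_scores`, `action_scores`, `rest_mean`, `action_mean`,
#'   `states`, optional `music`), `model`, `recording`, raw feature matrix
#'   `features` with `feature_index` (window start, trial, period),
#'   `score_log`, `mood_ratings`, `config`, `seed`.
#' @export
run_session <- function(model, cfg, n_trials = 20L, seed = 1L,
                        rest_s = 15, cue_s = 2, action_s = 30,
                        participant = "sim", mood_ratings = NULL,
                        render_music = FALSE) {
  stopifnot(inherits(model, "affect_model"), inherits(cfg, "responder_config"),
            n_trials >= 0L)
  fs <- model$fs
  step <- model$step_s
  win <- model$window_s
  montage <- model$channels
  eps <- 1e-9

  with_seed(seed, {
    # the whole session's background and coupled-band carrier are generated
    # continuously up front (no chunk seams that could bias rest-vs-action
    # spectra); the responder then only modulates the carrier's amplitude in
    # 0.5-s steps as its internal state evolves
    total <- win + n_trials * (rest_s + cue_s + action_s) + win
    nsamp <- round(total * fs)
    spp <- round(step * fs)
    bg <- gen_background_impl(total, n_channels = length(montage), fs = fs,
                              exponent = cfg$exponent, sd = cfg$background_sd,
                              channel_names = montage)$samples
    ch_idx <- match(cfg$channels, montage)
    if (anyNA(ch_idx)) stopf("responder channels not in the model montage")
    carrier <- t(vapply(ch_idx, function(i) band_noise(nsamp, fs, cfg$band),
                        numeric(nsamp)))
    state <- cfg$bias
    amps <- rep(NA_real_, round(total / step))  # carrier amplitude per step

    # advance the responder over [t0, t0 + duration) towards `target`
    advance <- function(t0, duration, target, tau) {
      ks <- round(t0 / step) + seq_len(round(duration / step))
      states <- numeric(length(ks))
      for (j in seq_along(ks)) {
        state <<- responder_step_state(state, target, tau, step)
        states[j] <- state
        amps[ks[j]] <<- cfg$gain(state)
      }
      states
    }
    # modulated samples for the window [t - win, t]
    window_at <- function(t) {
      i1 <- round(t * fs)
      idx <- (i1 - round(win * fs) + 1L):i1
      data <- bg[, idx, drop = FALSE]
      ks <- (idx[1L] - 1L) %/% spp + 1L  # first step covering the window
      amp <- rep(amps[ks:(ks + round(win / step) - 1L)], each = spp)
      data[ch_idx, ] <- data[ch_idx, ] + carrier[, idx, drop = FALSE] *
        rep(amp, each = length(ch_idx))
      data
    }

    Tend <- win
    tick_times <- numeric(0)
    tick_scores <- numeric(0)
    feat_chunks <- list()
    next_tick <- win

    score_upto <- function(t_max) {
      if (next_tick > t_max + eps) return(invisible())
      ends <- seq(next_tick, t_max + eps, by = step)
      if (!length(ends)) return(invisible())
      segs <- lapply(ends, function(t)
        list(data = window_at(t), start = t - win, label = "stream", fs = fs))
      F <- features_matrix(segs, model$band_defs,
                           order = model$filter$order,
                           ripple = model$filter$ripple)
      Fp <- prepare_features(model, F)
      s <- score_sigmoid(model$alpha, as.numeric(Fp %*% model$w) + model$b)
      tick_times <<- c(tick_times, ends)
      tick_scores <<- c(tick_scores, s)
      feat_chunks[[length(feat_chunks) + 1L]] <<- F
      next_tick <<- ends[length(ends)] + step
      invisible()
    }

    advance(0, win, cfg$bias, cfg$tau_rest)   # lead-in

    trials <- vector("list", n_trials)
    ev_rows <- list()
    for (i in seq_len(n_trials)) {
      rest_onset <- Tend
      states_rc <- advance(rest_onset, rest_s + cue_s, cfg$bias, cfg$tau_rest)
      Tend <- Tend + rest_s + cue_s
      score_upto(rest_onset + rest_s)
      ri <- which(tick_times > rest_onset + eps &
                    tick_times <= rest_onset + rest_s + eps)
      rest_scores <- data.frame(time = tick_times[ri], score = tick_scores[ri])
      task <- assign_task(rest_scores$score)
      target <- if (task == "to_happy") 1 else 0

      action_onset <- rest_onset + rest_s + cue_s
      states_a <- advance(action_onset, action_s, target, cfg$tau_action)
      Tend <- Tend + action_s
      score_upto(action_onset + action_s)
      ai <- which(tick_times > action_onset + eps &
                    tick_times <= action_onset + action_s + eps)
      action_scores <- data.frame(time = tick_times[ai], score = tick_scores[ai])

      trial <- list(trial = i, task = task,
                    rest_onset = rest_onset, action_onset = action_onset,
                    rest_scores = rest_scores, action_scores = action_scores,
                    rest_mean = mean(rest_scores$score),
                    action_mean = mean(action_scores$score),
                    states = c(states_rc, states_a), valid = TRUE)
      if (render_music) {
        traj <- affect_trajectory(action_scores$time - action_onset - step,
                                  valence = action_scores$score,
                                  arousal = action_scores$score)
        trial$music <- generate_sequence(traj, action_s,
                                         seed = derive_seed(seed, i))
      }
      trials[[i]] <- trial
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        onset = c(rest_onset, rest_onset + rest_s, action_onset),
        duration = c(rest_s, cue_s, action_s),
        label = c("rest", "cue", paste0("action_", sub("to_", "", task))))
    }
    advance(Tend, win, cfg$bias, cfg$tau_rest)  # tail
    Tend <- Tend + win
    score_upto(Tend)

    # assemble the full modulated recording
    M <- bg
    amp_per_sample <- rep(amps, each = spp)
    M[ch_idx, ] <- M[ch_idx, ] + carrier *
      rep(amp_per_sample, each = length(ch_idx))

    events <- if (length(ev_rows)) do.call(rbind, ev_rows)
              else data.frame(onset = numeric(0), duration = numeric(0),
                              label = character(0))
    recording <- eeg_recording(M, fs, montage, events)
    features <- do.call(rbind, feat_chunks)
    starts <- tick_times - win
    fidx <- data.frame(start = starts, trial = NA_integer_,
                       period = NA_character_, stringsAsFactors = FALSE)
    for (i in seq_len(n_trials)) {
      tr <- trials[[i]]
      fidx$trial[starts >= tr$rest_onset - eps &
                   starts < tr$rest_onset + rest_s - eps] <- i
      fidx$period[starts >= tr$rest_onset - eps &
                    starts < tr$rest_onset + rest_s - eps] <- "rest"
      fidx$trial[starts >= tr$action_onset - eps &
                   starts < tr$action_onset + action_s - eps] <- i
      fidx$period[starts >= tr$action_onset - eps &
                    starts < tr$action_onset + action_s - eps] <- "action"
    }
    score_log <- do.call(rbind, lapply(trials, function(tr) rbind(
      data.frame(trial = tr$trial, task = tr$task, period = "rest",
                 time_s = tr$rest_scores$time, score = tr$rest_scores$score),
      data.frame(trial = tr$trial, task = tr$task, period = "action",
                 time_s = tr$action_scores$time, score = tr$action_scores$score))))

    structure(list(participant = participant, trials = trials, model = model,
                   recording = recording, features = features,
                   feature_index = fidx, score_log = score_log,
                   mood_ratings = mood_ratings,
                   config = list(responder = cfg, rest_s = rest_s,
                                 cue_s = cue_s, action_s = action_s,
                                 n_trials = n_trials),
                   seed = seed),
              class = "bci_session")
  })
}

#' @export
print.bci_session <- function(x, ...) {
  tasks <- vapply(x$trials, `[[`, character(1), "task")
  cat(sprintf("<bci_session '%s': %d trials (%d to_happy / %d to_sad), %.1f min simulated>\n",
              x$participant, length(x$trials),
              sum(tasks == "to_happy"), sum(tasks == "to_sad"),
              recording_duration(x$recording) / 60))
  invisible(x)
}

#' Run a single closed-loop trial
#'
#' Convenience wrapper running a one-trial session; see [run_session()] for
#' the trial timeline.
#'
#' @inheritParams run_session
#' @return A single trial record (see [run_session()]).
#' @export
run_trial <- function(model, cfg, seed = 1L, render_music = FALSE, ...) {
  run_session(model, cfg, n_trials = 1L, seed = seed,
              render_music = render_music, ...)$trials[[1L]]
}

#' Write a session's score log and manifest
#'
#' Writes `scores.csv` (trial, task, period, time_s, score), `mood.csv` if
#' ratings are present, and `manifest.json` (configuration, seed, montage) to
#' a directory.
#'
#' @param session A `bci_session`.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_session_log <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$score_log, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  if (!is.null(session$mood_ratings))
    utils::write.csv(data.frame(item = names(session$mood_ratings),
                                rating = as.integer(session$mood_ratings)),
                     file.path(dir, "mood.csv"), row.names = FALSE)
  cfg <- session$config
  manifest <- list(
    participant = session$participant, seed = session$seed,
    n_trials = cfg$n_trials, rest_s = cfg$rest_s, cue_s = cfg$cue_s,
    action_s = cfg$action_s,
    responder = cfg$responder[setdiff(names(cfg$responder), "gain")],
    montage = session$model$channels)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
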