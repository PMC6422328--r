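CLASS_AFFECT <- list(
  sad = c(valence = 0, arousal = 0),
  neutral = c(valence = 0.5, arousal = 0.5),
  happy = c(valence = 1, arousal = 1)
)

#' Build the pseudo-randomized calibration stimulus schedule
#'
#' Six 20-s musical excerpts (each of sad, neutral, happy presented twice) in
#' a pseudo-random order with no two consecutive excerpts of the same class,
#' each followed by a 10-s idle period with no music: 180 s (three minutes) in
#' total. Sad plays at valence/arousal (0, 0), neutral at (0.5, 0.5), happy at
#' (1, 1).
#'
#' @param seed Integer RNG seed.
#' @param excerpt_s,idle_s Durations of excerpts and idle periods in seconds.
#' @return Data frame of class `stimulus_schedule`: `onset`, `duration`,
#'   `label`, `valence`, `arousal` (affect columns are `NA` for idle rows).
#' @examples
#' sched <- build_calibration_schedule(seed = 1)
#' sum(sched$duration)  # 180
#' @export
build_calibration_schedule <- function(seed = 1L, excerpt_s = 20, idle_s = 10) {
  with_seed(seed, build_calibration_schedule_impl(excerpt_s, idle_s))
}

# uses the current RNG state (callers that manage their own seed)
build_calibration_schedule_impl <- function(excerpt_s = 20, idle_s = 10) {
  classes <- rep(names(CLASS_AFFECT), each = 2L)
  repeat {
    ord <- sample(classes)
    if (all(ord[-1L] != ord[-length(ord)])) break
  }
  rows <- list()
  t <- 0
  for (cl in ord) {
    aff <- CLASS_AFFECT[[cl]]
    rows[[length(rows) + 1L]] <- data.frame(
      onset = t, duration = excerpt_s, label = cl,
      valence = aff[["valence"]], arousal = aff[["arousal"]])
    t <- t + excerpt_s
    rows[[length(rows) + 1L]] <- data.frame(
      onset = t, duration = idle_s, label = "idle",
      valence = NA_real_, arousal = NA_real_)
    t <- t + idle_s
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stimulus_schedule", "data.frame")
  out
}

#' Assign the trial task from resting-period scores
#'
#' When the average resting score tends towards the sad state (mean < 0.5) the
#' task is to modulate towards happy; otherwise (mean >= 0.5) towards sad.
#'
#' @param rest_scores Non-empty numeric vector of scores in (0, 1).
#' @return `"to_happy"` or `"to_sad"`.
#' @examples
#' assign_task(c(0.2, 0.3))  # "to_happy"
#' @export
assign_task <- function(rest_scores) {
  if (length(rest_scores) == 0L) stopf("rest_scores must be non-empty")
  if (mean(rest_scores) < 0.5) "to_happy" else "to_sad"
}
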