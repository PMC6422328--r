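#' Affect point in the valence-arousal plane
#'
#' The two-dimensional circumplex coordinates that drive the music engine and
#' that the EEG decoder estimates. Valence encodes pleasantness (0 = negative,
#' 1 = positive), arousal encodes activation (0 = calm, 1 = excited). Both
#' coordinates are clamped into \[0, 1\] on construction.
#'
#' @param valence Numeric scalar, clamped to \[0, 1\].
#' @param arousal Numeric scalar, clamped to \[0, 1\].
#' @return An object of class `affect_point` with fields `valence`, `arousal`.
#' @examples
#' affect_point(1, 1)     # "happy" corner
#' affect_point(-2, 0.3)  # valence clamped to 0
#' @export
affect_point <- function(valence, arousal) {
  stopifnot(is.numeric(valence), length(valence) == 1L, is.finite(valence),
            is.numeric(arousal), length(arousal) == 1L, is.finite(arousal))
  structure(list(valence = clamp01(valence), arousal = clamp01(arousal)),
            class = "affect_point")
}

#' @export
print.affect_point <- function(x, ...) {
  cat(sprintf("<affect_point valence=%.3f arousal=%.3f>\n", x$valence, x$arousal))
  invisible(x)
}

#' Valence/arousal trajectory through affective space
#'
#' A piecewise-constant (zero-order-hold) path of affect breakpoints: the
#' affect active at time `t` is the last breakpoint at or before `t`.
#' Continuous ramps are represented by dense breakpoints.
#'
#' @param time Numeric vector of breakpoint times in seconds; strictly
#'   increasing and starting at 0.
#' @param valence,arousal Numeric vectors of the same length as `time`;
#'   clamped to \[0, 1\].
#' @return An object of class `affect_trajectory`: a data frame with columns
#'   `time`, `valence`, `arousal`.
#' @examples
#' affect_trajectory(c(0, 10), valence = c(0, 1), arousal = c(0.5, 0.5))
#' @export
affect_trajectory <- function(time, valence, arousal) {
  stopifnot(is.numeric(time), length(time) >= 1L,
            length(valence) == length(time), length(arousal) == length(time))
  if (time[1L] != 0) stopf("trajectory must start at time 0 (got %g)", time[1L])
  if (any(diff(time) <= 0)) stopf("trajectory times must be strictly increasing")
  structure(data.frame(time = time, valence = clamp01(valence),
                       arousal = clamp01(arousal)),
            class = c("affect_trajectory", "data.frame"))
}

#' Constant trajectory at a single affect point
#' @param point An [affect_point()] (or anything coercible via its two fields).
#' @return An [affect_trajectory()] with one breakpoint at t = 0.
#' @export
constant_trajectory <- function(point) {
  affect_trajectory(0, point$valence, point$arousal)
}

# affect active at time t (zero-order hold)
trajectory_at <- function(traj, t) {
  i <- findInterval(t, traj$time)
  i <- max(i, 1L)
  affect_point(traj$valence[i], traj$arousal[i])
}

#' Read / write a trajectory as CSV
#'
#' CSV layout: header `time_s,valence,arousal`, one breakpoint per row.
#'
#' @param path File path.
#' @return `read_trajectory_csv` returns an [affect_trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "valence", "arousal")
  if (!all(need %in% names(d)))
    stopf("trajectory CSV must have columns %s", paste(need, collapse = ","))
  affect_trajectory(d$time_s, d$valence, d$arousal)
}

#' @rdname read_trajectory_csv
#' @param traj An [affect_trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(data.frame(time_s = traj$time, valence = traj$valence,
                              arousal = traj$arousal),
                   path, row.names = FALSE)
  invisible(path)
}
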