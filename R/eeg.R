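#' Standard 14-channel consumer EEG montage (10-20 positions)
#'
#' Channel order used throughout the package for recordings, feature vectors
#' and models.
#'
#' @return Character vector of 14 channel labels.
#' @export
emotiv_montage <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}

#' Annotated multichannel EEG recording
#'
#' Container for a channels-by-time sample matrix (microvolts), its sampling
#' rate, channel labels and an event table of labeled periods.
#'
#' @param samples Numeric matrix, channels x time samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one label per row of `samples`.
#' @param events Data frame with columns `onset`, `duration` (seconds) and
#'   `label`; every event interval must lie within the recording.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_names = emotiv_montage(),
                          events = NULL) {
  stopifnot(is.matrix(samples), is.numeric(samples), fs > 0)
  if (nrow(samples) != length(channel_names))
    stopf("channel count (%d) != number of channel names (%d)",
          nrow(samples), length(channel_names))
  dur <- ncol(samples) / fs
  if (is.null(events))
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         label = character(0), stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "label") %in% names(events)))
  if (nrow(events) && any(events$onset < 0 | events$onset + events$duration > dur + 1e-9))
    stopf("event intervals must lie within the %0.1f s recording", dur)
  rownames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %d ch x %.1f s @ %g Hz, %d events>\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs, nrow(x$events)))
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Read / write EEG recordings and event tables as CSV
#'
#' Sample CSV layout: first column `time_s`, remaining columns named after the
#' channels, values in microvolts. Event CSV layout: `onset_s`, `duration_s`,
#' `label`.
#'
#' @param path,events_path File paths. `events_path` may be `NULL` when the
#'   recording carries no annotations.
#' @return `read_eeg_csv` returns an [eeg_recording()].
#' @export
read_eeg_csv <- function(path, events_path = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (names(d)[1L] != "time_s") stopf("first column must be time_s")
  fs <- 1 / stats::median(diff(d$time_s))
  samples <- t(as.matrix(d[, -1L, drop = FALSE]))
  events <- if (!is.null(events_path)) read_events_csv(events_path)
  eeg_recording(samples, fs = round(fs, 6), channel_names = names(d)[-1L],
                events = events)
}

#' @rdname read_eeg_csv
#' @param rec An [eeg_recording()].
#' @export
write_eeg_csv <- function(rec, path, events_path = NULL) {
  d <- data.frame(time_s = (seq_len(ncol(rec$samples)) - 1L) / rec$fs)
  d[rec$channel_names] <- t(rec$samples)
  utils::write.csv(d, path, row.names = FALSE)
  if (!is.null(events_path)) write_events_csv(rec$events, events_path)
  invisible(path)
}

#' @rdname read_eeg_csv
#' @export
read_events_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(d)))
    stopf("events CSV must have columns %s", paste(need, collapse = ","))
  data.frame(onset = d$onset_s, duration = d$duration_s,
             label = as.character(d$label), stringsAsFactors = FALSE)
}

#' @rdname read_eeg_csv
#' @param events Event data frame (`onset`, `duration`, `label`).
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(data.frame(onset_s = events$onset,
                              duration_s = events$duration,
                              label = events$label),
                   path, row.names = FALSE)
  invisible(path)
}

#' Resample a recording to a target rate
#'
#' Fourier-domain resampling per channel (band-limited, zero delay): the
#' spectrum is truncated or zero-padded to the new length. Used to bring
#' non-128 Hz inputs onto the decoder's native rate before processing. Events
#' (in seconds) are unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param fs_target Target sampling rate in Hz.
#' @return An [eeg_recording()] at `fs_target`.
#' @export
resample_recording <- function(rec, fs_target = 128) {
  if (abs(rec$fs - fs_target) < 1e-9) return(rec)
  n_in <- ncol(rec$samples)
  n_out <- round(n_in * fs_target / rec$fs)
  out <- t(apply(rec$samples, 1L, fft_resample, n_out = n_out))
  eeg_recording(out, fs_target, rec$channel_names, rec$events)
}

# band-limited resampling of one series to n_out samples via FFT
fft_resample <- function(x, n_out) {
  n <- length(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  keep <- min(n, n_out) %/% 2L
  Y[1L] <- X[1L]                                   # DC
  Y[2L:(keep + 1L)] <- X[2L:(keep + 1L)]           # positive frequencies
  Y[(n_out - keep + 1L):n_out] <- X[(n - keep + 1L):n]  # negative frequencies
  if (n_out %% 2L == 0L && keep == n_out %/% 2L)   # split shared Nyquist bin
    Y[keep + 1L] <- Re(Y[keep + 1L])
  # amplitude-preserving normalization (ifft carries 1/n_out, spectrum 1/n_in)
  Re(stats::fft(Y, inverse = TRUE)) / n
}
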