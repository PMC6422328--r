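# Zero-phase Chebyshev band-pass filtering.
#
# The decoder filters every 4-s segment independently (no continuous
# filtering), forward and backward so the net phase shift is zero. The filter
# is a 2nd-order Chebyshev Type-I IIR band-pass (0.5 dB passband ripple by
# default). The forward-backward pass is implemented on stats::filter (whose
# convolution/recursion loops run in C and accept matrix input, letting many
# channels/segments be filtered in one call) with the same zero-padding
# convention as signal::filtfilt, to which it is numerically identical.

#' Design the decoder's band-pass filter
#'
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Chebyshev prototype order (the default 2 gives a 4th-degree
#'   band-pass polynomial).
#' @param ripple Passband ripple in dB.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
design_bandpass <- function(lo, hi, fs, order = 2L, ripple = 0.5) {
  if (!(lo > 0 && hi > lo && hi < fs / 2))
    stopf("band edges must satisfy 0 < lo < hi < fs/2 (got %g-%g Hz at fs=%g)",
          lo, hi, fs)
  flt <- signal::cheby1(order, ripple, c(lo, hi) / (fs / 2), type = "pass")
  list(b = flt$b, a = flt$a)
}

# forward-backward IIR filtering of the columns of X (time down the rows);
# numerically identical to signal::filtfilt applied per column
zerophase_filter <- function(b, a, X) {
  x_was_vec <- is.null(dim(X))
  if (x_was_vec) X <- matrix(X, ncol = 1L)
  n <- nrow(X)
  npad <- 2L * max(length(a), length(b))
  one_pass <- function(M) iir_filter_mat(b, a, M)
  Y <- one_pass(rbind(X, matrix(0, npad, ncol(X))))
  Y <- one_pass(Y[nrow(Y):1L, , drop = FALSE])
  Y <- Y[nrow(Y):1L, , drop = FALSE][seq_len(n), , drop = FALSE]
  if (x_was_vec) Y[, 1L] else Y
}

#' Zero-phase band-pass filter one EEG segment
#'
#' Applies the 2nd-order zero-phase Chebyshev band-pass to each channel of a
#' segment in isolation (forward-backward, zero net phase shift).
#'
#' @param seg A segment from [segment_stream()] (list with `data` channels x
#'   samples, `start`, `label`, `fs`), or a bare channels x samples matrix if
#'   `fs` is given.
#' @param lo,hi Band edges in Hz.
#' @param fs Sampling rate; taken from `seg$fs` when missing.
#' @param order,ripple Filter design parameters, see [design_bandpass()].
#' @return The segment (or matrix) with filtered `data`.
#' @export
bandpass <- function(seg, lo, hi, fs = NULL, order = 2L, ripple = 0.5) {
  bare <- is.matrix(seg)
  data <- if (bare) seg else seg$data
  fs <- fs %||% seg$fs
  if (is.null(fs)) stopf("fs must be supplied for a bare matrix")
  flt <- design_bandpass(lo, hi, fs, order, ripple)
  filtered <- t(zerophase_filter(flt$b, flt$a, t(data)))
  dimnames(filtered) <- dimnames(data)
  if (bare) return(filtered)
  seg$data <- filtered
  seg
}
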