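#' Default EEG frequency bands
#'
#' Theta (4-7 Hz), alpha (8-13 Hz), low beta (14-21 Hz), high beta (22-29 Hz)
#' and gamma (30-47 Hz). Delta is excluded because low frequencies are prone
#' to ocular artifacts and drift.
#'
#' @return Data frame with columns `band`, `lo`, `hi`.
#' @export
default_bands <- function() {
  data.frame(band = c("theta", "alpha", "beta_lo", "beta_hi", "gamma"),
             lo = c(4, 8, 14, 22, 30),
             hi = c(7, 13, 21, 29, 47),
             stringsAsFactors = FALSE)
}

feature_names <- function(channels, bands) {
  as.vector(t(outer(channels, bands$band, paste, sep = ".")))
}

# sigmoid score clamped into the open interval: the true sigmoid never
# reaches 0 or 1, only floating point rounds it there for |d| beyond ~355
score_sigmoid <- function(alpha, d) {
  s <- stats::plogis(alpha * d)
  pmin(pmax(s, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Cut labeled periods of a recording into overlapping analysis segments
#'
#' Window start times are placed at every `step_s` inside each labeled period
#' (`floor(duration / step)` windows per period); a window belongs to the
#' period containing its start sample and may extend beyond the period
#' boundary into the following data, mirroring the online convention of
#' labeling a window by when it begins. Windows that would run past the end of
#' the recording are dropped with a warning, as is a period shorter than one
#' step.
#'
#' @param rec An [eeg_recording()] with an event table.
#' @param window_s Window length in seconds (default 4, the decoder's native
#'   segment length).
#' @param step_s Hop between window starts (default 0.5, i.e. 87.5% overlap).
#' @param labels Optional character vector restricting which event labels are
#'   segmented.
#' @return List of segments; each is a list with `data` (channels x samples),
#'   `start` (seconds), `label`, `fs`.
#' @export
segment_stream <- function(rec, window_s = 4, step_s = 0.5, labels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- recording_duration(rec)
  if (dur < window_s) stopf("recording (%.1f s) shorter than one window", dur)
  ev <- rec$events
  if (!is.null(labels)) ev <- ev[ev$label %in% labels, , drop = FALSE]
  nw <- round(window_s * rec$fs)
  out <- list()
  dropped <- 0L
  for (i in seq_len(nrow(ev))) {
    nstarts <- floor(ev$duration[i] / step_s + 1e-9)
    if (nstarts < 1L) {
      warnf("period '%s' at %.1f s is shorter than one step; no segments",
            ev$label[i], ev$onset[i])
      next
    }
    starts <- ev$onset[i] + step_s * (seq_len(nstarts) - 1L)
    for (s in starts) {
      i0 <- round(s * rec$fs) + 1L
      if (i0 + nw - 1L > ncol(rec$samples)) { dropped <- dropped + 1L; next }
      out[[length(out) + 1L]] <- list(
        data = rec$samples[, i0:(i0 + nw - 1L), drop = FALSE],
        start = s, label = ev$label[i], fs = rec$fs)
    }
  }
  if (dropped > 0L)
    warnf("%d window(s) extended past the end of the recording and were dropped",
          dropped)
  out
}

#' Log band-power feature vector of one segment
#'
#' One feature per (channel, band): the natural log of the variance of the
#' zero-phase band-filtered channel. Features are ordered channel-major
#' (all bands of channel 1, then channel 2, ...), giving 14 x 5 = 70 features
#' under the default montage and bands.
#'
#' @param seg A segment from [segment_stream()].
#' @param band_defs Band table as from [default_bands()].
#' @param order,ripple Filter design parameters.
#' @return Named numeric vector of length `channels * bands`.
#' @export
extract_features <- function(seg, band_defs = default_bands(),
                             order = 2L, ripple = 0.5) {
  features_matrix(list(seg), band_defs, order = order, ripple = ripple)[1L, ]
}

#' Feature matrix of many segments (batched)
#'
#' Same computation as [extract_features()], applied to a list of equal-length
#' segments in one pass per band.
#'
#' @inheritParams extract_features
#' @param segments List of segments from [segment_stream()].
#' @return Numeric matrix, one row per segment, columns named
#'   `channel.band` in channel-major order.
#' @export
features_matrix <- function(segments, band_defs = default_bands(),
                            order = 2L, ripple = 0.5) {
  stopifnot(length(segments) >= 1L)
  fs <- segments[[1L]]$fs
  channels <- rownames(segments[[1L]]$data)
  nC <- nrow(segments[[1L]]$data)
  nT <- ncol(segments[[1L]]$data)
  nS <- length(segments)
  nB <- nrow(band_defs)
  # stack all segments' channels as columns: time x (channel within segment)
  big <- matrix(0, nT, nC * nS)
  for (i in seq_len(nS)) {
    if (!identical(dim(segments[[i]]$data), c(nC, nT)))
      stopf("all segments must have identical dimensions")
    big[, ((i - 1L) * nC + 1L):(i * nC)] <- t(segments[[i]]$data)
  }
  out <- matrix(NA_real_, nS, nC * nB)
  for (bi in seq_len(nB)) {
    flt <- design_bandpass(band_defs$lo[bi], band_defs$hi[bi], fs, order, ripple)
    filt <- zerophase_filter(flt$b, flt$a, big)
    v <- (colSums(filt^2) - colSums(filt)^2 / nT) / (nT - 1)
    if (any(v <= 0 | !is.finite(v))) {
      bad <- which(v <= 0 | !is.finite(v))[1L]
      stopf("zero-variance (flat/dead) channel '%s' in segment %d: log band power undefined",
            channels[(bad - 1L) %% nC + 1L], (bad - 1L) %/% nC + 1L)
    }
    # column (i-1)*nC + c holds segment i, channel c -> feature col (c-1)*nB + bi
    out[, (seq_len(nC) - 1L) * nB + bi] <- matrix(log(v), nS, nC, byrow = TRUE)
  }
  colnames(out) <- feature_names(channels, band_defs)
  out
}

#' Baseline vector from idle observations
#'
#' Element-wise mean of the feature vectors observed during idle (no-music)
#' periods; subtracted from every observation to remove per-session offsets.
#'
#' @param idle_features Matrix (rows = observations) or single vector.
#' @return Numeric vector, one mean per feature.
#' @export
compute_baseline <- function(idle_features) {
  if (is.null(dim(idle_features))) idle_features <- rbind(idle_features)
  if (nrow(idle_features) < 1L) stopf("at least one idle observation required")
  colMeans(idle_features)
}

#' Closed-form two-class linear discriminant
#'
#' Weight vector `w = (S1 + S2 + lambda I)^-1 (mu2 - mu1)` from the class-wise
#' sample means and covariances, with a ridge term `lambda` stabilizing the
#' ill-conditioned pooled covariance (70 features from ~80 observations). The
#' bias places the decision hyperplane at the class-mean midpoint by default
#' (`b = -w' (mu1 + mu2) / 2`), so the discriminant is zero - and the sigmoid
#' score 0.5 - exactly between the classes; `bias = "as-printed"` instead uses
#' the unhalved form `b = -w'(mu1 + mu2)` some formulations print.
#'
#' @param X_sad Observations of the class mapped to score 0 (rows).
#' @param X_happy Observations of the class mapped to score 1 (rows).
#' @param ridge Ridge weight `lambda`; default `1e-3 * trace(S1+S2) / d`.
#' @param bias `"midpoint"` (default) or `"as-printed"`.
#' @return List with `w`, `b`, `mu1`, `mu2`, `ridge`.
#' @export
fit_lda <- function(X_sad, X_happy, ridge = NULL,
                    bias = c("midpoint", "as-printed")) {
  bias <- match.arg(bias)
  stopifnot(is.matrix(X_sad), is.matrix(X_happy),
            ncol(X_sad) == ncol(X_happy))
  if (nrow(X_sad) < 2L || nrow(X_happy) < 2L)
    stopf("need at least 2 observations per class")
  mu1 <- colMeans(X_sad)
  mu2 <- colMeans(X_happy)
  S <- stats::cov(X_sad) + stats::cov(X_happy)
  d <- ncol(X_sad)
  if (is.null(ridge)) ridge <- 1e-3 * sum(diag(S)) / d
  w <- tryCatch(
    solve(S + diag(ridge, d), mu2 - mu1),
    error = function(e)
      stopf("regularized covariance is singular (%s); increase `ridge`",
            conditionMessage(e)))
  b <- if (bias == "midpoint") -sum(w * (mu1 + mu2)) / 2 else -sum(w * (mu1 + mu2))
  list(w = as.numeric(w), b = b, mu1 = mu1, mu2 = mu2, ridge = ridge)
}

#' Sigmoid affect score of a prepared feature vector
#'
#' `s = 1 / (1 + exp(-alpha * (w' f + b)))`, strictly increasing in the
#' discriminant; a feature vector at the class-mean midpoint scores exactly
#' 0.5 for any steepness `alpha`. The input must already be baseline-subtracted
#' and standardized with the model's stored parameters (see
#' [prepare_features()]).
#'
#' @param model An `affect_model` from [calibrate()] (or any list carrying
#'   `w`, `b`, `alpha`).
#' @param f Prepared feature vector, `length(w)` entries.
#' @return Score in the open interval (0, 1).
#' @export
affect_score <- function(model, f) {
  if (length(f) != length(model$w))
    stopf("feature vector length %d does not match model dimension %d",
          length(f), length(model$w))
  d <- sum(model$w * f) + model$b
  score_sigmoid(model$alpha, d)
}

#' Baseline-subtract and standardize raw features with a model's parameters
#'
#' @param model An `affect_model`.
#' @param f Raw feature vector or matrix (rows = observations).
#' @return Prepared features, same shape as `f`.
#' @export
prepare_features <- function(model, f) {
  if (is.null(dim(f)))
    (f - model$baseline - model$feat_mean) / model$feat_sd
  else
    sweep(sweep(f, 2L, model$baseline + model$feat_mean), 2L, model$feat_sd, "/")
}

#' Calibrate an affect model from an annotated recording
#'
#' Runs the offline modeling pipeline on a calibration recording: extract the
#' happy/sad listening periods and idle periods, segment (4 s windows, 0.5 s
#' hop), zero-phase band-pass filter each segment, extract log band-power
#' features, average the idle observations into a baseline vector, subtract it
#' from the class observations, standardize them (per feature, over the two
#' fitted classes), and fit the regularized linear discriminant. Neutral
#' periods are never fitted. The returned model carries every parameter needed
#' online (baseline, standardization, weights, bias, sigmoid steepness, band
#' definitions, montage).
#'
#' @param rec An [eeg_recording()] whose events contain at least two `happy`,
#'   two `sad` and one `idle` period. Non-128 Hz recordings are resampled.
#' @param alpha Sigmoid steepness of the online score (default 2).
#' @param ridge Ridge weight for [fit_lda()]; `NULL` for the trace-scaled
#'   default.
#' @param band_defs Band table, see [default_bands()].
#' @param window_s,step_s Segmentation parameters.
#' @param order,ripple Filter design parameters.
#' @param lda_bias Passed to [fit_lda()].
#' @return Object of class `affect_model`.
#' @export
calibrate <- function(rec, alpha = 2, ridge = NULL, band_defs = default_bands(),
                      window_s = 4, step_s = 0.5, order = 2L, ripple = 0.5,
                      lda_bias = "midpoint") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (abs(rec$fs - 128) > 1e-9) rec <- resample_recording(rec, 128)
  counts <- table(rec$events$label)
  for (lab in c("happy", "sad")) {
    if (is.na(counts[lab]) || counts[lab] < 2L)
      stopf("calibration recording must contain >= 2 '%s' periods", lab)
  }
  if (is.na(counts["idle"]) || counts["idle"] < 1L)
    stopf("calibration recording must contain >= 1 'idle' period")

  segs <- segment_stream(rec, window_s, step_s,
                         labels = c("happy", "sad", "idle"))
  labs <- vapply(segs, `[[`, character(1), "label")
  F <- features_matrix(segs, band_defs, order = order, ripple = ripple)

  baseline <- compute_baseline(F[labs == "idle", , drop = FALSE])
  Xc <- sweep(F[labs != "idle", , drop = FALSE], 2L, baseline)
  cls <- labs[labs != "idle"]
  feat_mean <- colMeans(Xc)
  feat_sd <- apply(Xc, 2L, stats::sd)
  if (any(feat_sd <= 0)) stopf("zero-variance feature after baseline clearing")
  Xs <- sweep(sweep(Xc, 2L, feat_mean), 2L, feat_sd, "/")
  lda <- fit_lda(Xs[cls == "sad", , drop = FALSE],
                 Xs[cls == "happy", , drop = FALSE],
                 ridge = ridge, bias = lda_bias)

  structure(list(
    w = lda$w, b = lda$b, alpha = alpha, ridge = lda$ridge,
    baseline = baseline, feat_mean = feat_mean, feat_sd = feat_sd,
    band_defs = band_defs, channels = rec$channel_names, fs = 128,
    window_s = window_s, step_s = step_s,
    filter = list(order = order, ripple = ripple),
    class_orientation = c(low = "sad", high = "happy"),
    feature_names = colnames(F),
    n_obs = c(happy = sum(cls == "happy"), sad = sum(cls == "sad"),
              idle = sum(labs == "idle"))
  ), class = "affect_model")
}

#' @export
print.affect_model <- function(x, ...) {
  cat(sprintf(
    "<affect_model %d features (%d ch x %d bands), alpha=%g, ridge=%.3g>\n",
    length(x$w), length(x$channels), nrow(x$band_defs), x$alpha, x$ridge))
  cat(sprintf("  fitted on %d happy / %d sad obs, baseline from %d idle obs\n",
              x$n_obs[["happy"]], x$n_obs[["sad"]], x$n_obs[["idle"]]))
  invisible(x)
}

#' Score a recording as an online stream
#'
#' Emits one score per `step_s`, each computed from the latest `window_s` of
#' data (the first at `t = window_s`), applying the model's stored baseline
#' and standardization before the sigmoid discriminant.
#'
#' @param model An `affect_model`.
#' @param rec An [eeg_recording()] of at least one window length, with the
#'   model's montage.
#' @return Data frame with `time` (window end, seconds) and `score`.
#' @export
stream_scores <- function(model, rec) {
  stopifnot(inherits(model, "affect_model"), inherits(rec, "eeg_recording"))
  if (!identical(rec$channel_names, model$channels))
    stopf("recording montage does not match the model montage")
  if (abs(rec$fs - model$fs) > 1e-9) rec <- resample_recording(rec, model$fs)
  dur <- recording_duration(rec)
  if (dur < model$window_s) stopf("recording shorter than one window")
  ends <- seq(model$window_s, dur + 1e-9, by = model$step_s)
  nw <- round(model$window_s * rec$fs)
  segs <- lapply(ends, function(t) {
    i1 <- round(t * rec$fs)
    list(data = rec$samples[, (i1 - nw + 1L):i1, drop = FALSE],
         start = t - model$window_s, label = "stream", fs = rec$fs)
  })
  F <- features_matrix(segs, model$band_defs,
                       order = model$filter$order, ripple = model$filter$ripple)
  Fp <- prepare_features(model, F)
  data.frame(time = ends,
             score = score_sigmoid(model$alpha,
                                  as.numeric(Fp %*% model$w) + model$b))
}

#' Serialize / deserialize an affect model as JSON
#'
#' All vectors, band definitions, montage and configuration are written as a
#' single JSON document at full floating-point precision, so a round trip is
#' lossless to text precision.
#'
#' @param model An `affect_model`.
#' @param path File path.
#' @return `read_affect_model` returns the restored `affect_model`.
#' @export
write_affect_model <- function(model, path) {
  x <- unclass(model)
  x$band_defs <- as.list(x$band_defs)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_affect_model
#' @export
read_affect_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$band_defs <- as.data.frame(x$band_defs, stringsAsFactors = FALSE)
  x$n_obs <- unlist(x$n_obs)
  x$class_orientation <- unlist(x$class_orientation)
  x$baseline <- stats::setNames(as.numeric(x$baseline), x$feature_names)
  x$feat_mean <- stats::setNames(as.numeric(x$feat_mean), x$feature_names)
  x$feat_sd <- stats::setNames(as.numeric(x$feat_sd), x$feature_names)
  structure(x, class = "affect_model")
}
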