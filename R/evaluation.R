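# Offline and closed-loop evaluation statistics: repeated cross-validation
# with a binomial chance threshold, modulation statistics with one-tailed
# paired t-tests, per-feature band-power contrasts, mood correlations, and
# pairwise Granger causality.

#' Binomial chance-level threshold for a two-class classifier
#'
#' The smallest correct-classification count `k` whose exceedance probability
#' under Binomial(n, 1/2) is at most `p_sig` (i.e. `P(X > k) <= p_sig`),
#' expressed as a percentage `100 k / n`. An observed accuracy above this
#' threshold is unlikely under chance at level `p_sig`.
#'
#' @param n_obs Number of observations (>= 1).
#' @param p_sig Significance level.
#' @return Threshold accuracy in percent.
#' @examples
#' chance_threshold(80)  # 58.75
#' @export
chance_threshold <- function(n_obs, p_sig = 0.05) {
  stopifnot(n_obs >= 1)
  100 * stats::qbinom(1 - p_sig, n_obs, 0.5) / n_obs
}

# area under the ROC curve of continuous scores (rank / Mann-Whitney form,
# equivalent to the trapezoidal rule over all thresholds)
roc_auc <- function(scores, is_positive) {
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified cross-validation of the calibration model
#'
#' Estimates offline decoder performance the way the reference protocol does:
#' the two-class calibration data are partitioned into non-overlapping 1-s
#' windows (2 trials/class x 20 s -> 80 observations, 40 per class), and
#' k-fold cross-validation is repeated with reshuffled stratified folds. The
#' full pipeline runs per fold without leakage: the idle baseline is fixed
#' (idle data are never part of the folds), but standardization and the LDA
#' are re-estimated on the training folds only. Accuracy is the fraction of
#' test observations on the correct side of the score midpoint; AUC is
#' computed from the continuous discriminant.
#'
#' @param rec Calibration recording with happy/sad/idle events.
#' @param repeats Number of reshuffled repetitions.
#' @param folds Number of folds.
#' @param seed Integer RNG seed.
#' @param window_s CV window length in seconds (non-overlapping).
#' @param ridge,band_defs,order,ripple Pipeline parameters, see [calibrate()].
#' @return Object of class `cv_result`: list with `summary` (mean per-class
#'   accuracy, overall `acc`, `auc`, all accuracies in percent), `per_repeat`
#'   data frame, `fold_table` (repeats x folds accuracy matrix), `n_obs`.
#' @export
cross_validate <- function(rec, repeats = 100L, folds = 10L, seed = 1L,
                           window_s = 1, ridge = NULL,
                           band_defs = default_bands(),
                           order = 2L, ripple = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (abs(rec$fs - 128) > 1e-9) rec <- resample_recording(rec, 128)
  segs <- segment_stream(rec, window_s = window_s, step_s = window_s,
                         labels = c("happy", "sad", "idle"))
  labs <- vapply(segs, `[[`, character(1), "label")
  F <- features_matrix(segs, band_defs, order = order, ripple = ripple)
  baseline <- compute_baseline(F[labs == "idle", , drop = FALSE])
  X <- sweep(F[labs != "idle", , drop = FALSE], 2L, baseline)
  y <- labs[labs != "idle"]
  n <- nrow(X)
  if (min(table(y)) < folds)
    stopf("too few windows per class (%d) for %d folds", min(table(y)), folds)

  with_seed(seed, {
    per_repeat <- vector("list", repeats)
    fold_table <- matrix(NA_real_, repeats, folds)
    for (r in seq_len(repeats)) {
      fold <- integer(n)
      for (cl in unique(y)) {       # stratified reshuffle
        idx <- which(y == cl)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      d_all <- numeric(n)
      correct <- logical(n)
      for (k in seq_len(folds)) {
        tr <- fold != k
        mu <- colMeans(X[tr, , drop = FALSE])
        sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
        sdv[sdv <= 0] <- 1
        std <- function(M) sweep(sweep(M, 2L, mu), 2L, sdv, "/")
        lda <- fit_lda(std(X[tr & y == "sad", , drop = FALSE]),
                       std(X[tr & y == "happy", , drop = FALSE]),
                       ridge = ridge)
        d <- as.numeric(std(X[!tr, , drop = FALSE]) %*% lda$w) + lda$b
        d_all[!tr] <- d
        correct[!tr] <- (d > 0) == (y[!tr] == "happy")
        fold_table[r, k] <- 100 * mean(correct[!tr])
      }
      per_repeat[[r]] <- data.frame(
        repeat_id = r,
        acc_happy = 100 * mean(correct[y == "happy"]),
        acc_sad = 100 * mean(correct[y == "sad"]),
        acc = 100 * mean(correct),
        auc = roc_auc(d_all, y == "happy"))
    }
    per_repeat <- do.call(rbind, per_repeat)
    structure(list(
      summary = c(acc_happy = mean(per_repeat$acc_happy),
                  acc_sad = mean(per_repeat$acc_sad),
                  acc = mean(per_repeat$acc),
                  auc = mean(per_repeat$auc)),
      per_repeat = per_repeat,
      fold_table = fold_table,
      n_obs = n,
      chance = chance_threshold(n)),
      class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cv_result n=%d: happy %.1f%% / sad %.1f%% / ACC %.1f%% / AUC %.2f (chance %.2f%%)>\n",
    x$n_obs, s[["acc_happy"]], s[["acc_sad"]], s[["acc"]], s[["auc"]], x$chance))
  invisible(x)
}

# closed-form one-tailed paired t-test; returns p = 0.5 for the degenerate
# all-differences-zero case instead of erroring
paired_t_onetailed <- function(a, b, alternative) {
  d <- a - b
  m <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t <- mean(d) / (sd_d / sqrt(m))
  }
  p <- if (alternative == "greater") stats::pt(t, m - 1, lower.tail = FALSE)
       else stats::pt(t, m - 1)
  list(t = t, df = m - 1, p = p)
}

#' Modulation performance statistics of a session
#'
#' For each task, trial-wise resting and action mean scores are aggregated
#' into the resting mean (RM), action mean (AM), total deviation
#' (TD_happy = AM - RM, TD_sad = RM - AM) and mean score difference s_diff
#' (trial-averaged action minus rest mean), and the deviation between action
#' and rest is tested with a one-tailed paired t-test (right-tailed for
#' `to_happy`, left-tailed for `to_sad`) at the marginal significance
#' threshold p < 0.1. A task with fewer than 2 trials is marked unavailable
#' (mirroring imbalanced task distributions).
#'
#' @param session A `bci_session` from [run_session()], or a data frame with
#'   columns `task`, `rest_mean`, `action_mean`.
#' @param p_threshold Significance threshold for the reported flag.
#' @return Data frame of class `modulation_stats`, one row per task:
#'   `task`, `n_trials`, `RM`, `AM`, `TD`, `s_diff`, `t`, `df`, `p`,
#'   `significant`, `available`.
#' @export
modulation_stats <- function(session, p_threshold = 0.1) {
  tr <- if (inherits(session, "bci_session")) {
    data.frame(task = vapply(session$trials, `[[`, character(1), "task"),
               rest_mean = vapply(session$trials, `[[`, numeric(1), "rest_mean"),
               action_mean = vapply(session$trials, `[[`, numeric(1), "action_mean"))
  } else as.data.frame(session)
  stopifnot(all(c("task", "rest_mean", "action_mean") %in% names(tr)))
  out <- lapply(c("to_happy", "to_sad"), function(task) {
    d <- tr[tr$task == task, , drop = FALSE]
    m <- nrow(d)
    if (m < 2L)
      return(data.frame(task = task, n_trials = m, RM = NA_real_,
                        AM = NA_real_, TD = NA_real_, s_diff = NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        significant = NA, available = FALSE))
    RM <- mean(d$rest_mean)
    AM <- mean(d$action_mean)
    TD <- if (task == "to_happy") AM - RM else RM - AM
    tt <- paired_t_onetailed(d$action_mean, d$rest_mean,
                             if (task == "to_happy") "greater" else "less")
    data.frame(task = task, n_trials = m, RM = RM, AM = AM, TD = TD,
               s_diff = AM - RM, t = tt$t, df = tt$df, p = tt$p,
               significant = tt$p < p_threshold, available = TRUE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("modulation_stats", "data.frame")
  out
}

#' Per-feature band-power contrast between action and rest
#'
#' For every trial of the given task, the mean log band-power feature vector
#' over the resting-period segments is subtracted from the mean over the
#' action-period segments (one observation per trial, one value per of the 70
#' features). Observations are standardized within participant to minimize
#' inter-participant variation, pooled, and tested per feature against zero
#' with two-sided t-tests under a Bonferroni threshold of
#' `p_sig / n_features`. Features with zero pooled variance get an undefined
#' statistic and are never flagged.
#'
#' @param sessions A `bci_session` or list of them (one per participant).
#' @param task `"to_happy"` or `"to_sad"`.
#' @param p_sig Family-wise significance level before Bonferroni division.
#' @return Data frame with one row per feature: `feature`, `mean_diff`
#'   (standardized), `t`, `p`, `p_bonferroni_threshold`, `significant`.
#' @export
bandpower_contrast <- function(sessions, task = "to_happy", p_sig = 0.05) {
  if (inherits(sessions, "bci_session")) sessions <- list(sessions)
  obs <- list()
  for (s in sessions) {
    tasks <- vapply(s$trials, `[[`, character(1), "task")
    use <- which(tasks == task)
    if (length(use) < 2L) {
      warnf("session '%s' has %d '%s' trial(s) (need >= 2); skipped",
            s$participant, length(use), task)
      next
    }
    fi <- s$feature_index
    rows <- t(vapply(use, function(i) {
      act <- which(!is.na(fi$trial) & fi$trial == i & fi$period == "action")
      rst <- which(!is.na(fi$trial) & fi$trial == i & fi$period == "rest")
      colMeans(s$features[act, , drop = FALSE]) -
        colMeans(s$features[rst, , drop = FALSE])
    }, numeric(ncol(s$features))))
    # within-participant standardization: rescale by the participant's own
    # per-feature SD (the mean is kept - it carries the effect being tested)
    sdv <- apply(rows, 2L, stats::sd)
    ok <- sdv > 0
    rows[, ok] <- sweep(rows[, ok, drop = FALSE], 2L, sdv[ok], "/")
    obs[[length(obs) + 1L]] <- rows  # zero-SD columns stay unscaled
  }
  if (!length(obs))
    stopf("no session with >= 2 '%s' trials; cannot compute contrast", task)
  Xd <- do.call(rbind, obs)
  n <- nrow(Xd)
  mu <- colMeans(Xd)
  sdv <- apply(Xd, 2L, stats::sd)
  t_stat <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), NA_real_)
  p <- 2 * stats::pt(abs(t_stat), n - 1, lower.tail = FALSE)
  thr <- p_sig / ncol(Xd)
  data.frame(feature = colnames(Xd), mean_diff = mu, t = t_stat, p = p,
             p_bonferroni_threshold = thr,
             significant = !is.na(p) & p < thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlations between modulation performance and mood self-assessment
#'
#' Pearson correlations between the six performance measures (RM, AM, TD for
#' each task) and each mood questionnaire item across participant-sessions,
#' with two-sided p-values and marginal (p < 0.1) / significant (p < 0.05)
#' flags. Pairs involving a zero-variance column are flagged undefined.
#'
#' @param sessions List of >= 3 `bci_session` objects carrying
#'   `mood_ratings`.
#' @return Data frame with `measure`, `item`, `r`, `p`, `marginal`,
#'   `significant`, `defined`.
#' @export
mood_correlations <- function(sessions) {
  if (inherits(sessions, "bci_session")) sessions <- list(sessions)
  if (length(sessions) < 3L) stopf("need >= 3 participant-sessions")
  meas <- t(vapply(sessions, function(s) {
    ms <- modulation_stats(s)
    c(RM_happy = ms$RM[ms$task == "to_happy"],
      AM_happy = ms$AM[ms$task == "to_happy"],
      TD_happy = ms$TD[ms$task == "to_happy"],
      RM_sad = ms$RM[ms$task == "to_sad"],
      AM_sad = ms$AM[ms$task == "to_sad"],
      TD_sad = ms$TD[ms$task == "to_sad"])
  }, numeric(6)))
  moods <- t(vapply(sessions, function(s) {
    if (is.null(s$mood_ratings)) stopf("session '%s' has no mood ratings",
                                       s$participant)
    as.numeric(s$mood_ratings)
  }, numeric(length(sessions[[1L]]$mood_ratings))))
  colnames(moods) <- names(sessions[[1L]]$mood_ratings)
  out <- list()
  for (mcol in colnames(meas)) for (icol in colnames(moods)) {
    x <- meas[, mcol]
    y <- moods[, icol]
    ok <- stats::complete.cases(x, y)
    defined <- sum(ok) >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0
    if (defined) {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r <- unname(ct$estimate)
      p <- ct$p.value
    } else {
      r <- NA_real_
      p <- NA_real_
    }
    out[[length(out) + 1L]] <- data.frame(
      measure = mcol, item = icol, r = r, p = p,
      marginal = defined & !is.na(p) & p < 0.1,
      significant = defined & !is.na(p) & p < 0.05,
      defined = defined, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# OLS F-test of whether `lags of x` improve prediction of `y` beyond
# `lags of y` (bivariate Granger causality at fixed lag order)
granger_F <- function(y, x, nlags) {
  n <- length(y)
  if (n <= 3 * nlags + 1L) stopf("series too short for %d lags", nlags)
  idx <- (nlags + 1L):n
  Y <- y[idx]
  lagmat <- function(v) vapply(seq_len(nlags), function(l) v[idx - l],
                               numeric(length(idx)))
  Xr <- cbind(1, lagmat(y))
  Xf <- cbind(Xr, lagmat(x))
  rss <- function(Xm) {
    fit <- stats::lm.fit(Xm, Y)
    sum(fit$residuals^2)
  }
  rss_r <- rss(Xr)
  rss_f <- rss(Xf)
  df2 <- length(Y) - ncol(Xf)
  F <- ((rss_r - rss_f) / nlags) / (rss_f / df2)
  list(F = F, p = stats::pf(F, nlags, df2, lower.tail = FALSE), df2 = df2)
}

#' Pairwise Granger causality between a feedback score and feature series
#'
#' For every feature, both directions (score -> feature and feature -> score)
#' are tested with a bivariate vector-autoregression F-test at a fixed lag
#' order: does adding `nlags` lags of the predictor improve an OLS model of
#' the target beyond its own `nlags` lags? P-values are Bonferroni-corrected
#' over all tests actually performed (2 per feature; constant series are
#' flagged and skipped) before thresholding.
#'
#' @param score_series Numeric vector (e.g. concatenated action-period
#'   scores, one per 0.5-s observation; 10 lags then span 5 s).
#' @param feature_matrix Numeric matrix, one column per feature, rows aligned
#'   with `score_series`.
#' @param nlags Fixed lag order.
#' @param p_thresh Significance threshold applied to the corrected p-values.
#' @return Object of class `granger_result`: data frame `table` with
#'   `feature`, `direction` (`"s->f"` or `"f->s"`), `F`, `p`, `p_adj`,
#'   `significant`, `skipped`; plus `nlags` and `n_tests` metadata.
#' @export
granger_pairwise <- function(score_series, feature_matrix, nlags = 10L,
                             p_thresh = 0.01) {
  if (is.null(dim(feature_matrix)))
    feature_matrix <- matrix(feature_matrix, ncol = 1L)
  stopifnot(length(score_series) == nrow(feature_matrix))
  feats <- colnames(feature_matrix) %||% paste0("f", seq_len(ncol(feature_matrix)))
  rows <- list()
  s_const <- stats::sd(score_series) < 1e-12
  for (k in seq_len(ncol(feature_matrix))) {
    f <- feature_matrix[, k]
    skip <- s_const || stats::sd(f) < 1e-12
    for (dir in c("s->f", "f->s")) {
      if (skip) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = feats[k], direction = dir, F = NA_real_, p = NA_real_,
          skipped = TRUE, stringsAsFactors = FALSE)
      } else {
        g <- if (dir == "s->f") granger_F(f, score_series, nlags)
             else granger_F(score_series, f, nlags)
        rows[[length(rows) + 1L]] <- data.frame(
          feature = feats[k], direction = dir, F = g$F, p = g$p,
          skipped = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  n_tests <- sum(!tab$skipped)
  tab$p_adj <- pmin(1, tab$p * n_tests)
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < p_thresh
  structure(list(table = tab, nlags = nlags, n_tests = n_tests,
                 p_thresh = p_thresh),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("<granger_result %d tests at %d lags, %d significant at p<%g (Bonferroni)>\n",
              x$n_tests, x$nlags, sum(x$table$significant, na.rm = TRUE),
              x$p_thresh))
  invisible(x)
}
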