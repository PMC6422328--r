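make_labeled_rec <- function(events, duration, seed = 1) {
  rec <- gen_background(duration, seed = seed)
  rec$events <- events
  rec
}

test_that("segment counts follow the duration/step convention", {
  # one 20-s labeled period with a 4-s tail available: 40 windows
  rec <- make_labeled_rec(data.frame(onset = 0, duration = 20, label = "happy"),
                          duration = 24)
  expect_length(segment_stream(rec), 40L)
  # one 10-s idle period: 20 windows
  rec <- make_labeled_rec(data.frame(onset = 0, duration = 10, label = "idle"),
                          duration = 14)
  segs <- segment_stream(rec)
  expect_length(segs, 20L)
  expect_equal(vapply(segs, `[[`, numeric(1), "start"),
               seq(0, 9.5, by = 0.5))
  expect_true(all(vapply(segs, function(s) ncol(s$data) == 512L, logical(1))))
  # non-overlapping windows: window_s == step_s
  expect_length(segment_stream(rec, window_s = 1, step_s = 1), 10L)
  # windows running past the end of the recording are dropped with a warning
  rec <- make_labeled_rec(data.frame(onset = 0, duration = 20, label = "happy"),
                          duration = 20)
  expect_warning(segs <- segment_stream(rec), "dropped")
  expect_length(segs, 33L)   # starts 0 .. 16 only
  # a period shorter than one step yields nothing, with a warning
  rec <- make_labeled_rec(data.frame(onset = 0, duration = 0.2, label = "idle"),
                          duration = 10)
  expect_warning(segs <- segment_stream(rec), "shorter than one step")
  expect_length(segs, 0L)
})

test_that("zero-phase band-pass matches its design frequency response", {
  fs <- 128
  t <- (0:511) / fs
  seg <- list(data = rbind(A = sin(2 * pi * 10 * t)), start = 0,
              label = "x", fs = fs)
  out <- bandpass(seg, 8, 13)
  mid <- 150:350
  # in-band tone: amplitude within two passes of the 0.5 dB ripple of unity
  amp <- max(abs(out$data[1, mid]))
  expect_gt(amp, 10^(-0.5 * 2 / 20) - 0.01)
  expect_lt(amp, 1.01)
  # and equal to the analytic gain at 10 Hz
  expect_equal(amp, filter_gain(8, 13, fs, 10)^2, tolerance = 1e-2)
  # stop-band tone: variance crushed below 1%
  seg50 <- list(data = rbind(A = sin(2 * pi * 50 * t)), start = 0,
                label = "x", fs = fs)
  out50 <- bandpass(seg50, 8, 13)
  expect_lt(stats::var(out50$data[1, ]) / stats::var(seg50$data[1, ]), 0.01)
  # invalid edges rejected
  expect_error(bandpass(seg, 13, 8), "band edges")
  expect_error(bandpass(seg, 0, 13), "band edges")
  expect_error(bandpass(seg, 8, 70), "band edges")
})

test_that("filtering is zero-phase: time reversal commutes away from edges", {
  set.seed(2)
  x <- matrix(rnorm(512), 1)
  fwd <- bandpass(x, 8, 13, fs = 128)
  rev_ <- bandpass(x[, 512:1, drop = FALSE], 8, 13, fs = 128)
  expect_equal(fwd[1, 100:412], rev_[1, 413:101], tolerance = 1e-3)
})

test_that("the compiled zero-phase path agrees with signal::filtfilt", {
  set.seed(3)
  flt <- signal::cheby1(2, 0.5, c(8, 13) / 64, type = "pass")
  for (i in 1:5) {
    x <- rnorm(512)
    expect_equal(affectbci:::zerophase_filter(flt$b, flt$a, x),
                 signal::filtfilt(flt, x), tolerance = 1e-12)
  }
})

test_that("log band-power features have the right shape and scaling", {
  fs <- 128
  segs <- segment_stream(make_labeled_rec(
    data.frame(onset = 0, duration = 4, label = "idle"), 8, seed = 4),
    step_s = 4)
  f <- extract_features(segs[[1]])
  expect_length(f, 70L)
  expect_true(all(is.finite(f)))
  expect_equal(names(f)[1:5],
               paste("AF3", c("theta", "alpha", "beta_lo", "beta_hi", "gamma"),
                     sep = "."))
  expect_equal(names(f)[66:70],
               paste("AF4", c("theta", "alpha", "beta_lo", "beta_hi", "gamma"),
                     sep = "."))

  # an in-band sinusoid of amplitude A gives ~ log(A^2 / 2) on its (ch, band)
  A <- 2
  seg <- segs[[1]]
  seg$data[3, ] <- A * sin(2 * pi * 10 * (0:511) / fs)
  f2 <- extract_features(seg)
  gain <- filter_gain(8, 13, fs, 10)^2   # two-pass analytic gain at 10 Hz
  expect_equal(f2[["F3.alpha"]], log(gain^2 * A^2 / 2), tolerance = 0.05)

  # doubling a channel exactly quadruples every band variance
  seg2 <- segs[[1]]
  seg2$data[5, ] <- 2 * seg2$data[5, ]
  f3 <- extract_features(seg2)
  t7 <- grepl("^T7\\.", names(f3))
  expect_equal(f3[t7] - extract_features(segs[[1]])[t7],
               setNames(rep(log(4), 5), names(f3)[t7]), tolerance = 1e-10)
  expect_equal(f3[!t7], extract_features(segs[[1]])[!t7])

  # a dead channel is an error naming the culprit
  seg3 <- segs[[1]]
  seg3$data[2, ] <- 0
  expect_error(extract_features(seg3), "F7")
})

test_that("baseline is the element-wise idle mean", {
  v <- rnorm(70)
  expect_equal(compute_baseline(rbind(v)), v, ignore_attr = TRUE)
  expect_equal(unname(compute_baseline(rbind(v, -v))), rep(0, 70))
  set.seed(9)
  M <- matrix(rnorm(120 * 70), 120)
  expect_equal(compute_baseline(M), apply(M, 2, mean))
  expect_error(compute_baseline(M[0, , drop = FALSE]), "idle")
})

test_that("closed-form LDA matches hand linear algebra on a tiny worked set", {
  X1 <- rbind(c(0, 0), c(1, 1), c(2, 0))
  X2 <- rbind(c(4, 0), c(5, 1), c(6, 0))
  # hand-computed: mu1 = (1, 1/3), mu2 = (5, 1/3); S1 = S2 = [[1, 0], [0, 1/3]]
  # S = S1 + S2 = [[2, 0], [0, 2/3]]; w = S^-1 (mu2 - mu1) = (2, 0)
  fit <- fit_lda(X1, X2, ridge = 0)
  expect_equal(fit$w, c(2, 0))
  expect_equal(fit$b, -sum(c(2, 0) * (c(1, 1 / 3) + c(5, 1 / 3))) / 2)
  # midpoint scores exactly 0.5 at any steepness
  model <- list(w = fit$w, b = fit$b, alpha = 7)
  expect_equal(affect_score(model, c(3, 1 / 3)), 0.5)

  # isotropic well-separated classes: w parallel to the mean difference
  set.seed(11)
  A <- matrix(rnorm(400), ncol = 2)
  B <- sweep(matrix(rnorm(400), ncol = 2), 2, c(6, 6), "+")
  f2 <- fit_lda(A, B)
  cosine <- sum(f2$w * c(6, 6)) / sqrt(sum(f2$w^2) * 72)
  expect_gt(cosine, 0.99)

  # symmetric 1-D classes: discriminant zero at the origin
  a <- matrix(rnorm(2000, -1), ncol = 1)
  b <- matrix(rnorm(2000, +1), ncol = 1)
  f1 <- fit_lda(a, b)
  zero_at <- -f1$b / f1$w
  expect_lt(abs(zero_at), 0.1)

  expect_error(fit_lda(X1[1, , drop = FALSE], X2), "2 observations")
})

test_that("sigmoid scoring has the right limits and worked value", {
  model <- list(w = 1, b = 0, alpha = 2)
  expect_equal(affect_score(model, 1), 1 / (1 + exp(-2)))   # 0.8808
  expect_equal(affect_score(model, 1), 0.8807971, tolerance = 1e-6)
  expect_gt(affect_score(model, 50), 1 - 1e-10)
  expect_lt(affect_score(model, -50), 1e-10)
  s <- vapply(seq(-3, 3, by = 0.5),
              function(d) affect_score(model, d), numeric(1))
  expect_true(all(diff(s) > 0))   # strictly monotone in the discriminant
  expect_error(affect_score(list(w = c(1, 2), b = 0, alpha = 2), 1),
               "does not match")
})

test_that("calibration consumes the protocol's observation counts", {
  m <- fx_model()
  expect_length(m$w, 70L)
  expect_equal(unname(m$n_obs), c(80L, 80L, 120L), ignore_attr = TRUE)
  expect_true(all(m$feat_sd > 0))
  expect_equal(m$alpha, 2)
})

test_that("standardized calibration features are zero-mean unit-variance", {
  rec <- fx_cal_rec()
  segs <- segment_stream(rec, labels = c("happy", "sad", "idle"))
  labs <- vapply(segs, `[[`, character(1), "label")
  F <- features_matrix(segs)
  m <- fx_model()
  Xs <- prepare_features(m, F[labs != "idle", ])
  expect_equal(unname(colMeans(Xs)), rep(0, 70), tolerance = 1e-10)
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, 70), tolerance = 1e-10)
})

test_that("a planted class effect is recovered on held-out data", {
  m <- fx_model()
  held <- gen_calibration_recording(responder_effect(fx_cfg()), seed = 999)
  segs <- segment_stream(held, labels = c("happy", "sad"))
  labs <- vapply(segs, `[[`, character(1), "label")
  F <- prepare_features(m, features_matrix(segs))
  s <- stats::plogis(m$alpha * (as.numeric(F %*% m$w) + m$b))
  expect_gt(mean(s[labs == "happy"]), 0.5)
  expect_lt(mean(s[labs == "sad"]), 0.5)
})

test_that("swapping class labels negates the weight vector", {
  rec <- fx_cal_rec()
  swapped <- rec
  swapped$events$label <- c(happy = "sad", sad = "happy", neutral = "neutral",
                            idle = "idle")[rec$events$label]
  m2 <- calibrate(swapped)
  m1 <- fx_model()
  expect_equal(m2$w, -m1$w, tolerance = 1e-8)
  expect_equal(m2$b, -m1$b, tolerance = 1e-8)
})

test_that("calibration rejects recordings with missing class labels", {
  rec <- fx_cal_rec()
  rec$events <- rec$events[rec$events$label != "sad", ]
  expect_error(calibrate(rec), "'sad'")
  rec2 <- fx_cal_rec()
  rec2$events <- rec2$events[rec2$events$label != "idle", ]
  expect_error(calibrate(rec2), "'idle'")
})

test_that("online scoring emits one score per step from 4 s onward", {
  m <- fx_model()
  rec <- gen_background(34, seed = 6)
  sc <- stream_scores(m, rec)
  expect_equal(nrow(sc), 61L)
  expect_equal(sc$time, seq(4, 34, by = 0.5))
  expect_true(all(sc$score > 0 & sc$score < 1))

  bad <- gen_background(10, n_channels = 4, seed = 6)
  expect_error(stream_scores(m, bad), "montage")
})

test_that("stationary noise yields trendless scores; a planted ramp a rising one", {
  m <- fx_model()
  cfg <- fx_cfg()
  with_seed <- affectbci:::with_seed
  # null: stationary input (background + constant mid-gain coupled band),
  # 20 seeded runs, slope t-test at the 5% level
  pvals <- vapply(1:20, function(s) {
    rec <- gen_background(24, seed = 3000 + s)
    idx <- match(cfg$channels, rec$channel_names)
    with_seed(4000 + s, {
      for (ci in idx) {
        osc <- affectbci:::band_noise(ncol(rec$samples), rec$fs, cfg$band)
        rec$samples[ci, ] <- rec$samples[ci, ] + cfg$gain(0.5) * osc
      }
    })
    sc <- stream_scores(m, rec)
    sc <- sc[seq(1, nrow(sc), by = 8), ]   # disjoint windows: independent scores
    summary(stats::lm(score ~ time, sc))$coefficients["time", 4]
  }, numeric(1))
  expect_lte(sum(pvals < 0.05), 3L)   # ~1 expected under the null

  # coupled-band amplitude ramp along +w: smoothed score rises monotonically
  rec <- gen_background(40, seed = 77)
  ramp <- seq(cfg$gain(0), cfg$gain(1), length.out = ncol(rec$samples))
  idx <- match(cfg$channels, rec$channel_names)
  with_seed(78, {
    for (ci in idx) {
      osc <- affectbci:::band_noise(ncol(rec$samples), rec$fs, cfg$band)
      rec$samples[ci, ] <- rec$samples[ci, ] + ramp * osc
    }
  })
  sc <- stream_scores(m, rec)
  smooth <- stats::filter(sc$score, rep(1 / 9, 9))
  smooth <- smooth[!is.na(smooth)]
  expect_gt(cor(seq_along(smooth), smooth, method = "spearman"), 0.9)
})

test_that("affect models survive a JSON round trip losslessly", {
  m <- fx_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_affect_model(m, path)
  m2 <- read_affect_model(path)
  for (fld in c("w", "b", "alpha", "ridge", "baseline", "feat_mean", "feat_sd"))
    expect_equal(m2[[fld]], m[[fld]], tolerance = 1e-12, label = fld)
  expect_identical(m2$channels, m$channels)
  expect_identical(m2$band_defs$band, m$band_defs$band)
  f <- rnorm(70)
  expect_equal(affect_score(m2, f), affect_score(m, f), tolerance = 1e-12)
})

test_that("identical recording and configuration give identical models and scores", {
  rec <- fx_cal_rec()
  m1 <- calibrate(rec)
  m2 <- calibrate(rec)
  expect_identical(m1$w, m2$w)
  s1 <- stream_scores(m1, gen_background(10, seed = 12))
  s2 <- stream_scores(m2, gen_background(10, seed = 12))
  expect_identical(s1, s2)
})
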