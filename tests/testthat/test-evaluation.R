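test_that("the binomial chance threshold matches its anchors and trend", {
  expect_identical(chance_threshold(80, 0.05), 58.75)
  # n = 2, enumerated by brute force over the 4 coin-flip outcomes:
  # P(X > 1) = 0.25 > 0.05, P(X > 2) = 0 <= 0.05, so k = 2 -> 100%
  expect_identical(chance_threshold(2, 0.05), 100)
  th <- vapply(20:200, chance_threshold, numeric(1))
  expect_true(all(th >= 50 & th <= 100))
  # law-of-large-numbers trend (at spacing 20; adjacent n have parity wiggles)
  expect_true(all(th[21:181] < th[1:161]))
})

test_that("cross-validation windows the calibration data into 80 observations", {
  cv <- fixture("cv_strong", cross_validate(fx_cal_rec(), repeats = 20, seed = 1))
  expect_equal(cv$n_obs, 80L)
  expect_equal(cv$chance, 58.75)
  expect_equal(dim(cv$fold_table), c(20L, 10L))
  expect_equal(nrow(cv$per_repeat), 20L)
  expect_true(all(cv$per_repeat$acc >= 0 & cv$per_repeat$acc <= 100))
  expect_true(all(cv$per_repeat$auc >= 0 & cv$per_repeat$auc <= 1))
})

test_that("cross-validation recovers a strong planted effect and stays at chance under the null", {
  cv <- fixture("cv_strong", cross_validate(fx_cal_rec(), repeats = 20, seed = 1))
  expect_gte(cv$summary[["acc"]], 90)
  expect_gte(cv$summary[["auc"]], 0.95)
  cvn <- cross_validate(fx_null_rec(), repeats = 20, seed = 1)
  expect_gt(cvn$summary[["acc"]], 40)
  expect_lt(cvn$summary[["acc"]], 60)
})

test_that("cross-validation rejects data with too few windows for the folds", {
  rec <- gen_background(30, seed = 3)
  rec$events <- data.frame(onset = c(0, 6, 12), duration = c(5, 5, 5),
                           label = c("happy", "sad", "idle"))
  expect_error(cross_validate(rec, repeats = 2, folds = 10, seed = 1),
               "too few windows")
})

test_that("modulation statistics match hand arithmetic on a toy session", {
  s <- fake_session(tasks = rep("to_happy", 3),
                    rest_means = c(0.40, 0.50, 0.45),
                    action_means = c(0.60, 0.70, 0.50))
  ms <- modulation_stats(s)
  h <- ms[ms$task == "to_happy", ]
  # spreadsheet arithmetic: RM = 0.45, AM = 0.60, TD = s_diff = 0.15
  expect_equal(h$RM, 0.45)
  expect_equal(h$AM, 0.60)
  expect_equal(h$TD, 0.15)
  expect_equal(h$s_diff, 0.15)
  # independent oracle: stats::t.test paired right-tailed
  tt <- stats::t.test(c(0.60, 0.70, 0.50), c(0.40, 0.50, 0.45),
                      paired = TRUE, alternative = "greater")
  expect_equal(h$t, unname(tt$statistic))
  expect_equal(h$p, tt$p.value)
  # the task with no trials is marked unavailable
  expect_false(ms$available[ms$task == "to_sad"])

  # sad-task orientation: TD_sad = RM - AM, left-tailed test
  s2 <- fake_session(rep("to_sad", 3), c(0.8, 0.7, 0.75), c(0.5, 0.45, 0.6))
  sd_ <- modulation_stats(s2)[2, ]
  expect_equal(sd_$TD, mean(c(0.8, 0.7, 0.75)) - mean(c(0.5, 0.45, 0.6)))
  tt2 <- stats::t.test(c(0.5, 0.45, 0.6), c(0.8, 0.7, 0.75),
                       paired = TRUE, alternative = "less")
  expect_equal(sd_$p, tt2$p.value)
})

test_that("degenerate no-effect trials give s_diff 0 and p = 0.5", {
  s <- fake_session(rep("to_happy", 4), rep(0.5, 4), rep(0.5, 4))
  h <- modulation_stats(s)[1, ]
  expect_equal(h$s_diff, 0)
  expect_equal(h$p, 0.5)
  expect_false(h$significant)
})

test_that("TD identities hold exactly on a simulated session", {
  ms <- modulation_stats(fx_session())
  for (i in which(ms$available)) {
    expected <- if (ms$task[i] == "to_happy") ms$AM[i] - ms$RM[i]
                else ms$RM[i] - ms$AM[i]
    expect_identical(ms$TD[i], expected)
    expect_identical(ms$s_diff[i], ms$AM[i] - ms$RM[i])
  }
  # s_diff equals the mean of trial-wise differences to machine precision
  s <- fx_session()
  tasks <- vapply(s$trials, `[[`, character(1), "task")
  diffs <- vapply(s$trials, function(tr) tr$action_mean - tr$rest_mean,
                  numeric(1))
  for (task in unique(tasks)) {
    expect_equal(ms$s_diff[ms$task == task], mean(diffs[tasks == task]),
                 tolerance = 1e-14)
  }
})

test_that("band-power contrasts recover a planted coupled-band effect", {
  bc <- fixture("bc_happy", bandpower_contrast(fx_session(), "to_happy"))
  expect_equal(nrow(bc), 70L)
  expect_equal(unique(bc$p_bonferroni_threshold), 0.05 / 70)
  cfg <- fx_cfg()
  planted <- paste0(cfg$channels, ".gamma")
  expect_true(all(bc$significant[bc$feature %in% planted]))
  # nothing flagged on channels that carry no effect
  planted_ch <- sub("\\..*$", "", planted)
  off_target <- !sub("\\..*$", "", bc$feature) %in% planted_ch
  expect_false(any(bc$significant[off_target]))
})

test_that("band-power contrasts reject single-trial input and constant data", {
  s <- fake_session(c("to_happy", "to_sad", "to_sad"), rep(0.5, 3), rep(0.6, 3))
  s$features <- matrix(1, 3, 4)
  s$feature_index <- data.frame(start = 1:3, trial = 1:3, period = "action")
  expect_error(suppressWarnings(bandpower_contrast(s, "to_happy")),
               "cannot compute")

  # constant features: t undefined everywhere, nothing flagged
  s2 <- fx_session()
  s2$features <- matrix(2.5, nrow(s2$features), 4,
                        dimnames = list(NULL, paste0("f", 1:4)))
  bc <- bandpower_contrast(s2, "to_happy")
  expect_true(all(is.na(bc$t)))
  expect_false(any(bc$significant))
})

test_that("mood correlations detect self-correlation and match the textbook formula", {
  set.seed(71)
  sessions <- lapply(1:6, function(i) {
    s <- fake_session(rep(c("to_happy", "to_sad"), each = 3),
                      runif(6, 0.3, 0.5), runif(6, 0.5, 0.8),
                      mood = gen_mood_ratings(i), participant = paste0("P", i))
    s
  })
  # plant: first mood item equals TD_sad of the session
  for (i in seq_along(sessions)) {
    ms <- modulation_stats(sessions[[i]])
    sessions[[i]]$mood_ratings[1] <- ms$TD[ms$task == "to_sad"]
  }
  tab <- mood_correlations(sessions)
  planted <- tab[tab$measure == "TD_sad" &
                   tab$item == names(sessions[[1]]$mood_ratings)[1], ]
  expect_equal(planted$r, 1, tolerance = 1e-12)
  expect_true(planted$significant)

  # hand-computed Pearson r on one (measure, item) pair
  x <- vapply(sessions, function(s) {
    ms <- modulation_stats(s); ms$RM[ms$task == "to_happy"]
  }, numeric(1))
  y <- vapply(sessions, function(s) as.numeric(s$mood_ratings[2]), numeric(1))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- tab[tab$measure == "RM_happy" &
               tab$item == names(sessions[[1]]$mood_ratings)[2], ]
  expect_equal(got$r, r_hand, tolerance = 1e-12)

  # zero-variance mood item: undefined, flagged as such
  for (i in seq_along(sessions)) sessions[[i]]$mood_ratings[3] <- 4
  tab2 <- mood_correlations(sessions)
  flat <- tab2[tab2$item == names(sessions[[1]]$mood_ratings)[3], ]
  expect_true(all(!flat$defined))
  expect_true(all(is.na(flat$r)))

  expect_error(mood_correlations(sessions[1:2]), ">= 3")
})

test_that("independent columns produce ~5% nominally significant mood correlations", {
  set.seed(81)
  frac <- replicate(100, {
    sessions <- lapply(1:10, function(i)
      fake_session(rep(c("to_happy", "to_sad"), each = 2),
                   runif(4), runif(4),
                   mood = setNames(rnorm(14), paste0("item", 1:14))))
    tab <- mood_correlations(sessions)
    mean(tab$significant)
  })
  expect_gt(mean(frac), 0.030)
  expect_lt(mean(frac), 0.070)
})

test_that("Granger tests recover a planted unidirectional dependence", {
  vp <- gen_var_pair(coef = 0.8, lag = 1, n = 600, seed = 5)
  g <- granger_pairwise(vp$x, cbind(y = vp$y), nlags = 10)
  tab <- g$table
  expect_true(tab$significant[tab$direction == "s->f"])    # x drives y
  expect_false(tab$significant[tab$direction == "f->s"])
  expect_equal(g$n_tests, 2L)

  # a longer planted lag still inside the window is detected
  vp3 <- gen_var_pair(coef = 0.8, lag = 3, n = 600, seed = 6)
  g3 <- granger_pairwise(vp3$x, cbind(y = vp3$y), nlags = 10)
  expect_true(g3$table$significant[g3$table$direction == "s->f"])

  # a pure copy shifted by one lag: forward F dwarfs the reverse F
  x <- affectbci:::with_seed(9, rnorm(300))
  y <- c(0, x[-300])
  gc <- granger_pairwise(x, cbind(y = y), nlags = 10)
  expect_gt(gc$table$F[gc$table$direction == "s->f"],
            gc$table$F[gc$table$direction == "f->s"])
})

test_that("the Granger F-test agrees with lmtest::grangertest", {
  vp <- gen_var_pair(coef = 0.5, lag = 2, n = 400, seed = 8)
  g <- granger_pairwise(vp$x, cbind(y = vp$y), nlags = 10)
  ref <- lmtest::grangertest(vp$y ~ vp$x, order = 10)   # does x cause y?
  expect_equal(g$table$F[g$table$direction == "s->f"], ref$F[2],
               tolerance = 1e-8)
  expect_equal(g$table$p[g$table$direction == "s->f"],
               ref$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("independent white noise stays null after Bonferroni correction", {
  hits <- vapply(1:50, function(s) {
    vp <- gen_var_pair(coef = 0, lag = 1, n = 300, seed = 1000 + s)
    any(granger_pairwise(vp$x, cbind(y = vp$y), nlags = 10)$table$significant)
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("constant series are flagged and skipped, not tested", {
  x <- rnorm(200)
  g <- granger_pairwise(x, cbind(flat = rep(1, 200), ok = rnorm(200)),
                        nlags = 5)
  tab <- g$table
  expect_true(all(tab$skipped[tab$feature == "flat"]))
  expect_true(all(is.na(tab$F[tab$feature == "flat"])))
  expect_false(any(tab$skipped[tab$feature == "ok"]))
  expect_equal(g$n_tests, 2L)   # only the performed tests enter the family
})
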