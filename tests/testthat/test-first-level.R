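test_that("the white-matter drift regressor matches its definition", {
  g <- volume_grid(c(6, 6, 4), 3)
  wm <- brain_mask(g, array(TRUE, c(6, 6, 4)))
  n_vol <- 80
  ramp <- seq_len(n_vol)
  # every WM voxel an identical ramp -> output is the z-scored ramp
  series <- matrix(rep(ramp, prod(g$shape)), n_vol)
  expect_equal(wm_drift_regressor(series, wm), as.numeric(scale(ramp)),
               tolerance = 1e-12)
  # white noise over 1000 voxels -> SD approximately 1/sqrt(1000)
  g2 <- volume_grid(c(10, 10, 10), 3)
  wm2 <- brain_mask(g2, array(TRUE, c(10, 10, 10)))
  set.seed(5)
  noise <- matrix(rnorm(200 * 1000), 200)
  out <- wm_drift_regressor(noise, wm2)
  expect_lt(abs(mean(out)), 1e-10)
  expect_lt(abs(sd(out) - 1 / sqrt(1000)), 0.3 / sqrt(1000))
  # constant voxels are excluded; all-constant is an error
  series[, 1] <- 1
  expect_warning(wm_drift_regressor(series, wm), "zero-variance")
  expect_error(wm_drift_regressor(matrix(1, n_vol, prod(g$shape)), wm),
               "zero temporal variance")
})

test_that("design matrices carry the study's regressor counts", {
  # Day-1 run: 12 Enc + 12 ImRet + 12 cues = 36 regressors of interest
  enc <- toy_trials("Enc", 24); im <- toy_trials("ImRet", 24)
  run1 <- rbind(enc[enc$run == 1, ], im[im$run == 1, ])
  run1$onset <- 10 + (seq_len(nrow(run1)) - 1) * 60
  run1$cue_onset <- ifelse(is.na(run1$cue_onset), NA, run1$onset - 2)
  n_vol <- ceiling((max(run1$onset) + 60) / 2.62)
  d1 <- build_design_matrix(run1, n_vol, 2.62, motion = NULL,
                            wm_drift = NULL)
  expect_equal(sum(d1$interest), 36)
  # Day-8 run: 24 DelRet + 24 cues = 48 regressors of interest
  del <- toy_trials("DelRet", 24)
  del$onset <- 10 + (seq_len(24) - 1) * 60
  del$cue_onset <- del$onset - 2
  n_vol <- ceiling((max(del$onset) + 60) / 2.62)
  d8 <- build_design_matrix(del, n_vol, 2.62)
  expect_equal(sum(d8$interest), 48)
  # eight no-interest columns when motion and WM drift are supplied
  d8n <- build_design_matrix(del, n_vol, 2.62,
                             motion = matrix(rnorm(n_vol * 6), n_vol),
                             wm_drift = rnorm(n_vol))
  expect_equal(sum(!d8n$interest), 8 + 1)   # rating + 6 motion + WM + icpt
})

test_that("the 12 s exclusion variant re-times retrieval regressors", {
  tt <- toy_trials("DelRet", 2)
  tt$onset <- c(20, 100); tt$duration <- c(30, 40)
  tt$cue_onset <- tt$onset - 2
  n_vol <- 80
  d <- build_design_matrix(tt, n_vol, 2.62, variant = "exclude_first_12s",
                           drop_initial = 0)
  # interest boxcar of 18 s starting 12 s after onset
  ref <- hrf_regressor(32, 18, n_vol, 2.62)
  expect_equal(unname(d$X[, which(d$labels == "trial_DelRet_v01")]),
               ref, tolerance = 1e-12)
  # the excluded 12 s get their own no-interest column
  expect_true("excl12_DelRet_v01" %in% d$labels)
  expect_false(d$interest[d$labels == "excl12_DelRet_v01"])
  expect_error(build_design_matrix(transform(tt, duration = 10), n_vol,
                                   2.62, variant = "exclude_first_12s",
                                   drop_initial = 0), "12 s")
})

test_that("collinear designs are rejected with the offending columns named", {
  tt <- toy_trials("Enc", 2)
  tt$onset <- c(20, 20); tt$duration <- c(30, 30)   # identical regressors
  expect_error(build_design_matrix(tt, 60, 2.62, drop_initial = 0),
               "rank deficient|collinear")
})

test_that("GLM t-maps recover injected patterns and respect shifts", {
  cfg <- generator_config(n_subjects = 1, n_videos = 4, shape = c(10, 10, 8),
                          noise_sd = 0.2, seed = 13)
  ts <- generate_timeseries_study(cfg)
  r1 <- ts$subjects[[1]]$runs[["1"]]
  wm <- wm_drift_regressor(r1$data, ts$wm_mask)
  des <- build_design_matrix(r1$trials, r1$n_volumes, cfg$tr,
                             motion = r1$motion, wm_drift = wm,
                             drop_initial = r1$drop_initial)
  ps <- fit_trial_tmaps(r1$data, des, ts$gm_mask)
  truth <- ts$truth$runs[[1]][["1"]]$patterns
  rs <- sapply(seq_len(nrow(ps$values)), function(i)
    cor(ps$values[i, ], truth[[i]]))
  expect_gt(min(rs), 0.9)
  # adding a constant to the data leaves estimates unchanged (intercept)
  ps2 <- fit_trial_tmaps(r1$data + 100, des, ts$gm_mask)
  expect_equal(ps2$values, ps$values, tolerance = 1e-8)
})

test_that("null series yield Student-t distributed trial statistics", {
  set.seed(17)
  shape <- c(20, 25, 10)                     # 5000 voxels
  g <- volume_grid(shape, 3)
  m <- brain_mask(g, array(TRUE, shape))
  n_vol <- 120
  tt <- toy_trials("Enc", 2)
  tt$onset <- c(30, 160); tt$duration <- c(35, 40)
  des <- build_design_matrix(tt, n_vol, 2.62, drop_initial = 5)
  series <- matrix(rnorm(n_vol * prod(shape)), n_vol)
  ps <- fit_trial_tmaps(series, des, m)
  df <- (n_vol - 5) - ncol(des$X)
  ks <- ks.test(ps$values[1, ], function(q) pt(q, df))
  expect_gt(ks$p.value, 0.01)
})

test_that("pattern recovery improves monotonically with SNR", {
  rec <- sapply(c(2, 0.5, 0.1), function(nsd) {
    cfg <- generator_config(n_subjects = 1, n_videos = 4,
                            shape = c(10, 10, 8), noise_sd = nsd, seed = 31)
    ts <- generate_timeseries_study(cfg)
    r1 <- ts$subjects[[1]]$runs[["1"]]
    wm <- wm_drift_regressor(r1$data, ts$wm_mask)
    des <- build_design_matrix(r1$trials, r1$n_volumes, cfg$tr,
                               motion = r1$motion, wm_drift = wm,
                               drop_initial = r1$drop_initial)
    ps <- fit_trial_tmaps(r1$data, des, ts$gm_mask)
    truth <- ts$truth$runs[[1]][["1"]]$patterns
    mean(sapply(seq_len(nrow(ps$values)), function(i)
      cor(ps$values[i, ], truth[[i]])))
  })
  expect_true(all(diff(rec) > 0))
})
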