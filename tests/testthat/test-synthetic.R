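test_that("identical seeds give bit-identical studies", {
  a <- small_study(2, 8, c(8, 8, 6), delta = 0.3, region_size = 60,
                   seed = 42)
  b <- small_study(2, 8, c(8, 8, 6), delta = 0.3, region_size = 60,
                   seed = 42)
  expect_identical(a$subjects[[1]]$patterns$Enc$values,
                   b$subjects[[1]]$patterns$Enc$values)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$subjects[[2]]$trials, b$subjects[[2]]$trials)
  c <- small_study(2, 8, c(8, 8, 6), delta = 0.3, region_size = 60,
                   seed = 43)
  expect_false(identical(a$subjects[[1]]$patterns$Enc$values,
                         c$subjects[[1]]$patterns$Enc$values))
})

roi_gap <- function(study, region, phase_a = "Enc", phase_b = "DelRet") {
  mean(sapply(study$subjects, function(su) {
    pa <- su$patterns[[phase_a]]; pb <- su$patterns[[phase_b]]
    w <- build_same_vs_different(pa$trials, pb$trials)
    r <- roi_rsa(pa, pb, region, w)
    r$mean_same_z - r$mean_diff_z
  }))
}

test_that("null construction: zero delta gives a zero same-different gap", {
  st <- small_study(6, 24, c(10, 10, 8), delta = 0, region_size = 300,
                    seed = 7)
  gaps <- sapply(st$subjects, function(su) {
    w <- build_same_vs_different(su$patterns$Enc$trials,
                                 su$patterns$DelRet$trials)
    r <- roi_rsa(su$patterns$Enc, su$patterns$DelRet, st$region, w)
    r$mean_same_z - r$mean_diff_z
  })
  # |mean| within 3 SE of zero across the subject-level gaps
  expect_lt(abs(mean(gaps)), 3 * sd(gaps) / sqrt(length(gaps)) + 1e-12)
})

test_that("the generator is calibrated: empirical gap matches delta_z_same", {
  set.seed(301)
  gaps <- replicate(100, {
    st <- small_study(8, 24, c(14, 14, 10), delta = 0.3, region_size = 400,
                      seed = sample.int(2^30, 1))
    roi_gap(st, st$region)
  })
  expect_lt(abs(mean(gaps) - 0.3), 0.2 * 0.3)
  # and considerably tighter than the 20% bound in practice
  expect_lt(abs(mean(gaps) - 0.3), 4 * sd(gaps) / sqrt(length(gaps)) + 0.01)
})

test_that("impossible and incoherent similarity targets are rejected", {
  m <- full_mask(c(8, 8, 6))
  reg <- region_sphere(m, 50)
  cfg <- generator_config(n_subjects = 2, n_videos = 4, shape = c(8, 8, 6),
                          effects = list(effect_spec(
                            reg, c(enc_imret = 3, enc_delret = 3,
                                   imret_delret = 0.01))),
                          seed = 1)
  expect_error(generate_pattern_study(cfg, mask = m), "impossible")
  cfg2 <- generator_config(n_subjects = 2, n_videos = 4, shape = c(8, 8, 6),
                           effects = list(effect_spec(
                             reg, c(enc_imret = 0.3, enc_delret = 0.3,
                                    imret_delret = 0))),
                           seed = 1)
  expect_error(generate_pattern_study(cfg2, mask = m), "incoherent")
  # region outside the brain mask
  small <- ellipsoid_mask(volume_grid(c(8, 8, 6), 3), fraction = 0.6)
  cfg3 <- generator_config(n_subjects = 2, n_videos = 4, shape = c(8, 8, 6),
                           effects = list(effect_spec(region_sphere(m, 200))),
                           seed = 1)
  expect_error(generate_pattern_study(cfg3, mask = small), "outside")
})

test_that("behavior tables match the scoring model", {
  st <- small_study(21, 24, c(8, 8, 6), seed = 11)
  b <- st$behavior
  # half-point granularity, non-negative, no cap
  expect_true(all(b$detail_score >= 0))
  expect_true(all(abs(b$detail_score * 2 - round(b$detail_score * 2)) <
                    1e-9))
  # group mean within 2 SE of the configured 11.5
  se <- sd(b$detail_score) / sqrt(nrow(b))
  expect_lt(abs(mean(b$detail_score) - 11.5), 2 * se + 0.15)
  # relative scores: per-video across-subject means are zero
  relm <- tapply(b$relative_score, b$video_id, mean)
  expect_lt(max(abs(relm)), 1e-9)
  # vividness on scale, dropping by about the configured amount
  expect_true(all(b$vividness_imret >= 1 & b$vividness_imret <= 6))
  drop <- mean(b$vividness_imret - b$vividness_delret)
  expect_lt(abs(drop - 0.7), 0.35)
  # retrieval durations within the self-paced window
  expect_true(all(b$retrieval_duration_imret > 20 &
                    b$retrieval_duration_imret < 55))
})

test_that("with zero coupling, scores are unrelated to reinstatement", {
  st <- small_study(10, 24, c(10, 10, 8), delta = 0.25, region_size = 250,
                    coupling = 0, seed = 21)
  # per-video measured same-pair z versus score, pooled across subjects
  rs <- sapply(seq_along(st$subjects), function(s) {
    su <- st$subjects[[s]]
    pa <- su$patterns$ImRet; pb <- su$patterns$DelRet
    cols <- match(which(st$region$voxels), which(st$mask$voxels))
    z <- sapply(seq_len(24), function(v) {
      i <- which(pa$trials$video_id == v); j <- which(pb$trials$video_id == v)
      fisher_z(cor(pa$values[i, cols], pb$values[j, cols]))
    })
    sc <- st$behavior$detail_score[st$behavior$subject_id ==
                                     sprintf("sub-%02d", s)]
    cor(z, sc[order(st$behavior$video_id[st$behavior$subject_id ==
                                           sprintf("sub-%02d", s)])])
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.02)
})

test_that("time-series studies have consistent timing and recoverable structure", {
  cfg <- generator_config(n_subjects = 1, n_videos = 4, shape = c(10, 10, 8),
                          noise_sd = 0.1, seed = 5)
  ts <- generate_timeseries_study(cfg)
  tt <- ts$subjects[[1]]$trials
  validate_trial_table(tt, n_videos = 4)
  # onsets strictly increasing within run with at least the ISI gap
  for (run in unique(tt$run)) {
    rt <- tt[tt$run == run, ]
    rt <- rt[order(rt$onset), ]
    if (nrow(rt) > 1) {
      gaps <- rt$onset[-1] - (rt$onset[-nrow(rt)] + rt$duration[-nrow(rt)])
      expect_true(all(gaps >= cfg$isi - 1e-9))
    }
  }
  # data dimensions consistent with the trial table
  r1 <- ts$subjects[[1]]$runs[["1"]]
  expect_equal(nrow(r1$data), r1$n_volumes)
  expect_gte(r1$n_volumes * cfg$tr, max(r1$trials$onset + r1$trials$duration))
})

test_that("videos with identical latent patterns become most similar as noise vanishes", {
  # two videos share one latent: their estimated patterns must correlate
  # higher than any non-matching pair in the low-noise limit
  cfg0 <- generator_config(n_subjects = 1, n_videos = 4,
                           shape = c(10, 10, 8), noise_sd = 0.01, seed = 9)
  gm <- generate_timeseries_study(cfg0)$gm_mask   # analysis mask geometry
  reg <- region_sphere(gm, 150)
  cfg <- generator_config(n_subjects = 1, n_videos = 4, shape = c(10, 10, 8),
                          noise_sd = 0.01,
                          effects = list(effect_spec(reg, 1.2)), seed = 9)
  ts <- generate_timeseries_study(cfg)
  run <- ts$subjects[[1]]$runs[["3"]]
  wm <- wm_drift_regressor(run$data, ts$wm_mask)
  des <- build_design_matrix(run$trials, run$n_volumes, cfg$tr,
                             motion = run$motion, wm_drift = wm,
                             drop_initial = run$drop_initial)
  ps <- fit_trial_tmaps(run$data, des, ts$gm_mask)
  # same-video similarity against encoding patterns from the same latent
  cols <- match(which(reg$voxels), which(ts$gm_mask$voxels))
  truth <- generate_pattern_study(cfg, mask = ts$gm_mask)
  pe <- truth$subjects[[1]]$patterns$Enc
  r <- cor(t(ps$values[, cols]), t(pe$values[, cols]))
  same <- r[cbind(seq_len(4), match(ps$trials$video_id,
                                    pe$trials$video_id))]
  diff_max <- max(r[outer(ps$trials$video_id, pe$trials$video_id, "!=")])
  expect_gt(min(same), diff_max)
})
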