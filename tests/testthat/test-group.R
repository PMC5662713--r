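make_maps <- function(n, shape, f = function(i) rnorm(prod(shape))) {
  g <- volume_grid(shape, 3)
  lapply(seq_len(n), function(i) stat_map(g, array(f(i), shape), "z"))
}

test_that("one-sample and paired t maps follow their definitions", {
  set.seed(81)
  shape <- c(6, 6, 4)
  # degenerate: identical constant maps -> flagged infinity
  maps <- make_maps(5, shape, function(i) rep(2, prod(shape)))
  tm <- one_sample_t_map(maps)
  expect_true(all(tm$values == Inf))
  expect_gt(attr(tm, "flagged_infinite"), 0)
  # n = 2 with negated copy -> t identically 0
  g <- volume_grid(shape, 3)
  v <- array(rnorm(prod(shape)), shape)
  expect_error(one_sample_t_map(list(stat_map(g, v, "z"),
                                     stat_map(g, -v, "z"))), "3 subjects")
  # paired: identical conditions -> 0; adding a common map changes nothing
  a <- make_maps(6, shape)
  expect_true(all(paired_t_map(a, a)$values == 0 |
                    is.nan(paired_t_map(a, a)$values)))
  b <- make_maps(6, shape)
  common <- array(rnorm(prod(shape)), shape)
  ac <- lapply(a, function(m) stat_map(g, m$values + common, "z"))
  bc <- lapply(b, function(m) stat_map(g, m$values + common, "z"))
  expect_equal(paired_t_map(ac, bc)$values, paired_t_map(a, b)$values,
               tolerance = 1e-10)
  expect_error(paired_t_map(a, b[1:3]), "mismatch")
})

test_that("null subject maps give t(n-1)-distributed voxel statistics", {
  set.seed(83)
  maps <- make_maps(21, c(20, 25, 10))
  tm <- one_sample_t_map(maps)
  ks <- ks.test(as.numeric(tm$values), function(q) pt(q, 20))
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster FWE is deterministic, ROI-consistent and monotone", {
  set.seed(85)
  shape <- c(10, 10, 8)
  # plant a strong effect so clusters exist
  bump <- array(0, shape); bump[3:6, 3:6, 3:5] <- 1.2
  maps <- make_maps(12, shape, function(i)
    as.numeric(bump) + rnorm(prod(shape)))
  r1 <- cluster_fwe(maps, n_permutations = 500, seed = 9)
  r2 <- cluster_fwe(maps, n_permutations = 500, seed = 9)
  expect_identical(r1$clusters, r2$clusters)
  # whole-brain ROI is the same as no ROI
  whole <- full_mask(shape)
  r3 <- cluster_fwe(maps, n_permutations = 500, seed = 9, roi = whole)
  expect_identical(r1$clusters, r3$clusters)
  # corrected p non-increasing in observed cluster size
  if (nrow(r1$clusters) > 1) {
    o <- order(r1$clusters$size)
    expect_true(all(diff(r1$clusters$p_fwe[o]) <= 1e-12))
  }
  # significant cluster recovered inside the planted region
  expect_true(any(r1$clusters$significant))
  top <- which(r1$cluster_map == 1)
  expect_gt(mean(top %in% which(bump > 0)), 0.5)
  # no supra-threshold voxels -> empty result, not an error
  null_maps <- make_maps(8, c(6, 6, 4), function(i) rep(0, 144) +
                           rnorm(144, sd = 1e-3))
  r0 <- cluster_fwe(null_maps, cdt_p = 1e-6, n_permutations = 100, seed = 2)
  expect_equal(nrow(r0$clusters), 0)
})

test_that("small-volume correction restricts inference to the ROI", {
  set.seed(87)
  shape <- c(10, 10, 8)
  bump <- array(0, shape); bump[7:9, 7:9, 5:7] <- 1.5
  maps <- make_maps(12, shape, function(i)
    as.numeric(bump) + rnorm(prod(shape)))
  g <- volume_grid(shape, 3)
  roi_vox <- array(FALSE, shape); roi_vox[1:4, 1:4, 1:4] <- TRUE
  roi <- brain_mask(g, roi_vox)
  r <- cluster_fwe(maps, n_permutations = 500, seed = 4, roi = roi)
  # the strong effect lies outside the ROI and must not appear
  expect_true(nrow(r$clusters) == 0 ||
                all(which(r$cluster_map > 0) %in% which(roi_vox)))
})

test_that("the 2x3 repeated-measures interaction has the right shape", {
  # identical same-different gap in all phases -> interaction F exactly 0
  # (noise centred within each type-by-phase cell so the cell means carry
  # no interaction component while the residual stratum stays nonzero)
  d <- expand.grid(subject = 1:12, corr_type = c("same", "diff"),
                   phase_pair = c("EI", "ED", "ID"))
  subj_eff <- rnorm(12)[d$subject]
  eps <- rnorm(nrow(d), sd = 0.1)
  eps <- eps - ave(eps, d$corr_type, d$phase_pair)
  d$value <- subj_eff + ifelse(d$corr_type == "same", 0.3, 0) + eps
  a <- interaction_anova_2x3(d)
  expect_lt(a$F, 1e-10)
  expect_equal(a$df1, 2)
  expect_equal(a$df2, 22)             # (2-1)(3-1)(12-1)
  # n = 20 subjects -> df2 = 38
  d20 <- expand.grid(subject = 1:20, corr_type = c("same", "diff"),
                     phase_pair = c("EI", "ED", "ID"))
  d20$value <- rnorm(nrow(d20))
  expect_equal(interaction_anova_2x3(d20)$df2, 38)
  # a phase-specific doubling of the gap drives F up
  d2 <- d
  d2$value <- d2$value + ifelse(d2$corr_type == "same" &
                                  d2$phase_pair == "ID", 0.6, 0) +
    rnorm(nrow(d2), sd = 0.05)
  a2 <- interaction_anova_2x3(d2)
  expect_gt(a2$F, a$F)
  expect_lt(a2$p, 0.05)
  expect_error(interaction_anova_2x3(d[-1, ]), "missing")
})
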