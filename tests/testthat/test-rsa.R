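test_that("fisher_z is the clipped atanh", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_true(is.finite(fisher_z(-1)))
  expect_error(fisher_z(1.01), "outside")
})

test_that("same-vs-different weights implement the run-aware contrast", {
  enc <- toy_trials("Enc", 24); im <- toy_trials("ImRet", 24)
  w <- build_same_vs_different(enc, im)
  # 2 runs x 12 videos: 24 same and 12*11*2 = 264 different weighted pairs
  expect_equal(sum(w$weights > 0), 24)
  expect_equal(sum(w$weights < 0), 264)
  expect_lt(abs(sum(w$weights)), 1e-12)
  expect_true(all(w$weights[w$excluded] == 0))
  # between-run pairs are the excluded ones
  expect_equal(sum(w$excluded), 2 * 12 * 12)

  # phase pairs involving DelRet have no exclusions: 24 same, 552 different
  del <- toy_trials("DelRet", 24)
  w2 <- build_same_vs_different(im, del)
  expect_equal(sum(w2$weights > 0), 24)
  expect_equal(sum(w2$weights < 0), 24 * 23)
  expect_lt(abs(sum(w2$weights)), 1e-12)
  expect_false(any(w2$excluded))

  # the contrast equals mean(same) - mean(diff): positive weights 1/24
  expect_equal(unique(w2$weights[w2$weights > 0]), 1 / 24)
  expect_equal(unique(w2$weights[w2$weights < 0]), -1 / 552)
  # raw-sum mode scales by the number of same pairs
  w3 <- build_same_vs_different(im, del, normalize = "sum")
  expect_equal(w3$weights, w2$weights * 24)
})

test_that("weighted-diagonal weights are centred scores on same pairs", {
  im <- toy_trials("ImRet", 2); del <- toy_trials("DelRet", 2)
  w <- build_weighted_diagonal(im, del, c(10, 14))
  expect_equal(sort(w$weights[w$weights != 0]), c(-2, 2))
  expect_true(all(w$weights[outer(im$video_id, del$video_id, "!=")] == 0))
  expect_lt(abs(sum(w$weights)), 1e-12)
  expect_warning(build_weighted_diagonal(im, del, c(3, 3)), "constant")
})

test_that("sphere neighborhoods match lattice enumeration", {
  # independent enumeration of integer lattice points with |x|^2 <= r^2
  lattice_count <- sum(outer(outer((-3:3)^2, (-3:3)^2, "+"), (-3:3)^2,
                             "+") <= 9)
  expect_equal(lattice_count, 123)
  m <- full_mask(c(11, 11, 11))
  nb <- sphere_neighborhood(666, searchlight_spec(3), m)  # centre (6,6,6)
  expect_length(nb, 123)
  expect_true(666 %in% nb)
  # radius 0.5 -> just the centre
  expect_identical(sphere_neighborhood(666, searchlight_spec(0.5), m), 666L)
  # centre near the boundary -> strict subset
  edge <- sphere_neighborhood(1, searchlight_spec(3), m)
  expect_lt(length(edge), 123)
  expect_true(all(edge %in% which(m$voxels)))
})

test_that("searchlight equals the brute-force oracle on a toy study", {
  st <- small_study(1, 8, c(8, 8, 6), delta = 0.4, region_size = 60,
                    seed = 3)
  su <- st$subjects[[1]]
  spec <- searchlight_spec(2, 5)
  for (pp in list(c("Enc", "ImRet"), c("ImRet", "DelRet"))) {
    pa <- su$patterns[[pp[1]]]; pb <- su$patterns[[pp[2]]]
    w <- build_same_vs_different(pa$trials, pb$trials)
    engine <- searchlight_rsa(pa, pb, w, spec)
    oracle <- naive_searchlight(pa, pb, w, radius = 2, min_voxels = 5)
    expect_lt(max(abs(engine$values - oracle), na.rm = TRUE), 1e-10)
  }
})

test_that("constant pairwise correlations are annihilated by zero-sum weights", {
  m <- full_mask(c(8, 8, 6))
  base_a <- rnorm(sum(m$voxels)); base_b <- rnorm(sum(m$voxels))
  pa <- toy_pattern_set(m, "ImRet", 4,
                        matrix(base_a, 4, length(base_a), byrow = TRUE))
  pb <- toy_pattern_set(m, "DelRet", 4,
                        matrix(base_b, 4, length(base_b), byrow = TRUE))
  w <- build_same_vs_different(pa$trials, pb$trials)
  mp <- searchlight_rsa(pa, pb, w, searchlight_spec(2, 5))
  expect_lt(max(abs(mp$values), na.rm = TRUE), 1e-12)
})

test_that("the statistic is symmetric in the phases up to transposition", {
  st <- small_study(1, 6, c(8, 8, 6), delta = 0.3, region_size = 50,
                    seed = 8)
  pa <- st$subjects[[1]]$patterns$Enc
  pb <- st$subjects[[1]]$patterns$DelRet
  w <- build_same_vs_different(pa$trials, pb$trials)
  wt <- w
  wt$weights <- t(w$weights); wt$excluded <- t(w$excluded)
  wt$trials_a <- w$trials_b; wt$trials_b <- w$trials_a
  a <- searchlight_rsa(pa, pb, w, searchlight_spec(2, 5))
  b <- searchlight_rsa(pb, pa, wt, searchlight_spec(2, 5))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("permuting video labels nulls the expected contrast", {
  st <- small_study(1, 12, c(8, 8, 6), delta = 0.5, region_size = 80,
                    seed = 12)
  pa <- st$subjects[[1]]$patterns$ImRet
  pb <- st$subjects[[1]]$patterns$DelRet
  set.seed(99)
  gaps <- replicate(200, {
    perm <- pb
    perm$trials$video_id <- sample(perm$trials$video_id)
    w <- build_same_vs_different(pa$trials, perm$trials)
    r <- roi_rsa(pa, perm, st$region, w)
    r$mean_same_z - r$mean_diff_z
  })
  expect_lt(abs(mean(gaps)), 3 * sd(gaps) / sqrt(length(gaps)))
})

test_that("ROI statistics honour self-correlation and degenerate input", {
  m <- full_mask(c(6, 6, 4))
  pa <- toy_pattern_set(m, "ImRet", 4)
  w <- build_same_vs_different(pa$trials, toy_trials("DelRet", 4))
  pb <- pattern_set(m$grid, m, toy_trials("DelRet", 4), pa$values)
  roi <- region_sphere(m, 30)
  r <- roi_rsa(pa, pb, roi, w)
  expect_equal(r$mean_same_z, atanh(1 - 1e-7))
  expect_error(roi_rsa(pa, pb, region_sphere(m, 1), w), "at least 2")
})

test_that("zero-variance patterns contribute zero correlation, with a count", {
  m <- full_mask(c(6, 6, 4))
  vals <- matrix(rnorm(4 * sum(m$voxels)), 4)
  vals[1, ] <- 5                            # flat pattern
  pa <- toy_pattern_set(m, "ImRet", 4, vals)
  pb <- toy_pattern_set(m, "DelRet", 4)
  w <- build_same_vs_different(pa$trials, pb$trials)
  mp <- searchlight_rsa(pa, pb, w, searchlight_spec(2, 5))
  expect_gt(attr(mp, "zero_variance_pairs"), 0)
  expect_true(all(is.finite(mp$values[m$voxels])))
})
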