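#' Fisher z transform of a correlation
#'
#' `atanh` with clipping at `1 - 1e-7` so that perfect correlations map to a
#' large finite value; odd and strictly increasing.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @return Fisher-z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlation outside [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Searchlight specification
#'
#' @param radius_voxels sphere radius in voxel-index units (Euclidean,
#'   centre included, boundary distance equal to the radius included).
#' @param min_voxels minimum in-mask neighborhood size; smaller
#'   neighborhoods yield `NaN` at that centre.
#' @return An object of class `searchlight_spec`.
#' @export
searchlight_spec <- function(radius_voxels = 3, min_voxels = 10L) {
  stopifnot(radius_voxels > 0, min_voxels >= 1)
  structure(list(radius_voxels = radius_voxels,
                 min_voxels = as.integer(min_voxels)),
            class = "searchlight_spec")
}

# integer offsets of the sphere lattice
sphere_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

#' Spherical searchlight neighborhood of one voxel
#'
#' All in-mask voxels within `radius_voxels` (Euclidean distance in voxel
#' index units) of the centre, centre included.
#'
#' @param center 1-based linear voxel index of the centre (must be in-mask).
#' @param spec a [searchlight_spec()].
#' @param mask a [brain_mask()].
#' @return Sorted integer vector of 1-based linear voxel indices.
#' @export
sphere_neighborhood <- function(center, spec, mask) {
  shape <- mask$grid$shape
  if (!mask$voxels[center]) stop("centre voxel is outside the mask")
  co <- voxel_coords(center, shape)
  off <- sphere_offsets(spec$radius_voxels)
  pts <- sweep(off, 2, as.numeric(co), "+")
  ok <- pts[, 1] >= 0 & pts[, 1] < shape[1] &
    pts[, 2] >= 0 & pts[, 2] < shape[2] &
    pts[, 3] >= 0 & pts[, 3] < shape[3]
  pts <- pts[ok, , drop = FALSE]
  lin <- as.integer(1 + pts[, 1] + shape[1] * (pts[, 2] + shape[2] *
                                                 pts[, 3]))
  sort(lin[mask$voxels[lin]])
}

#' Same-versus-different RSA contrast matrix
#'
#' Zero-sum trial-pair weights: same-video pairs get `+1/N_same`,
#' different-video pairs `-1/N_diff`, so the contrast equals
#' mean(same-video Fisher z) minus mean(different-video Fisher z). For the
#' Enc/ImRet comparison (both phases on Day 1), between-run pairs are
#' excluded to account for run effects; phase pairs involving delayed
#' retrieval have no exclusions. With `normalize = "sum"` the weights are
#' scaled by `N_same`, giving the raw summed difference (a fixed positive
#' multiple of the mean form for a constant design).
#'
#' @param trials_a,trials_b trial tables of the two phases (one trial per
#'   video each).
#' @param exclude_between_run_day1 logical; default `NULL` auto-detects
#'   (exclusion applies when both phases are Day-1 phases).
#' @param normalize `"mean"` or `"sum"`.
#' @return An object of class `weight_matrix`.
#' @export
build_same_vs_different <- function(trials_a, trials_b,
                                    exclude_between_run_day1 = NULL,
                                    normalize = c("mean", "sum")) {
  normalize <- match.arg(normalize)
  if (!setequal(trials_a$video_id, trials_b$video_id))
    stop("the two trial sets must cover the same videos")
  if (is.null(exclude_between_run_day1)) {
    day1 <- c("Enc", "ImRet")
    exclude_between_run_day1 <-
      all(as.character(trials_a$phase) %in% day1) &&
      all(as.character(trials_b$phase) %in% day1)
  }
  same <- outer(trials_a$video_id, trials_b$video_id, "==")
  excluded <- matrix(FALSE, nrow(trials_a), nrow(trials_b))
  if (exclude_between_run_day1)
    excluded <- outer(trials_a$run, trials_b$run, "!=")
  n_same <- sum(same & !excluded)
  n_diff <- sum(!same & !excluded)
  if (n_same == 0L) stop("all same-video pairs are excluded")
  w <- matrix(0, nrow(trials_a), nrow(trials_b))
  w[same & !excluded] <- 1 / n_same
  w[!same & !excluded] <- -1 / n_diff
  if (normalize == "sum") w <- w * n_same
  structure(list(trials_a = trials_a, trials_b = trials_b, weights = w,
                 kind = "same_vs_different", excluded = excluded),
            class = "weight_matrix")
}

#' Behaviour-weighted diagonal RSA contrast matrix
#'
#' Nonzero weights only on same-video pairs; the weight for a video is its
#' score minus the mean score across the subject's videos, so the weights
#' sum to zero by construction and the contrast detects regions where
#' reinstatement is stronger for higher-scoring videos. When the supplied
#' scores are relative memory scores (per-video across-subject centred, see
#' [relative_performance()]) they are re-centred across videos here.
#'
#' @param trials_a,trials_b trial tables of the two phases.
#' @param scores_per_video numeric vector of one score per video, indexed by
#'   video id.
#' @return An object of class `weight_matrix`.
#' @export
build_weighted_diagonal <- function(trials_a, trials_b, scores_per_video) {
  if (!setequal(trials_a$video_id, trials_b$video_id))
    stop("the two trial sets must cover the same videos")
  vids <- sort(unique(trials_a$video_id))
  sc <- scores_per_video[vids]
  if (anyNA(sc)) stop("missing score for some video")
  centred <- sc - mean(sc)
  if (all(abs(centred) < 1e-12))
    warning("constant scores: all weights zero, statistic identically 0")
  same <- outer(trials_a$video_id, trials_b$video_id, "==")
  w <- matrix(0, nrow(trials_a), nrow(trials_b))
  # one same pair per video here; if a video had several, split its weight
  for (k in seq_along(vids)) {
    pairs <- which(same & outer(trials_a$video_id == vids[k],
                                trials_b$video_id == vids[k], "&"))
    w[pairs] <- centred[k] / length(pairs)
  }
  structure(list(trials_a = trials_a, trials_b = trials_b, weights = w,
                 kind = "weighted_diagonal",
                 excluded = matrix(FALSE, nrow(trials_a), nrow(trials_b))),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix %s, %dx%d, %d nonzero, sum=%.2e>\n",
              x$kind, nrow(x$weights), ncol(x$weights),
              sum(x$weights != 0), sum(x$weights)))
  invisible(x)
}

check_conformable <- function(patterns_a, patterns_b, w) {
  if (!grids_equal(patterns_a$grid, patterns_b$grid))
    stop("pattern sets are not on a common grid")
  if (!identical(patterns_a$mask$voxels, patterns_b$mask$voxels))
    stop("pattern sets have different masks")
  if (nrow(w$weights) != nrow(patterns_a$values) ||
      ncol(w$weights) != nrow(patterns_b$values))
    stop("weight matrix is not conformable with the pattern sets")
}

#' Searchlight RSA map
#'
#' For every in-mask centre voxel v, computes
#' `S(v) = sum_ij w_ij * atanh(corr(a_i[N(v)], b_j[N(v)]))`, the weighted
#' sum of Fisher-transformed Pearson correlations between phase-A and
#' phase-B trial patterns over the spherical in-mask neighborhood `N(v)`,
#' and assigns it to the centre voxel. Centres whose neighborhood is
#' smaller than `min_voxels` get `NaN`; a pattern with zero variance in a
#' neighborhood contributes z = 0 to its pairs and is counted in the
#' `zero_variance_pairs` attribute.
#'
#' @param patterns_a,patterns_b [pattern_set()] objects on one grid/mask.
#' @param w a [weight_matrix()] conformable with the two sets.
#' @param spec a [searchlight_spec()].
#' @return A [stat_map()] (`searchlight_sum`) with attributes `phase_pair`,
#'   `weight_kind` and `zero_variance_pairs`.
#' @export
searchlight_rsa <- function(patterns_a, patterns_b, w,
                            spec = searchlight_spec()) {
  check_conformable(patterns_a, patterns_b, w)
  mask <- patterns_a$mask
  shape <- mask$grid$shape
  idx <- mask_indices(mask)
  col_of_lin <- rep.int(-1L, prod(shape))
  col_of_lin[idx] <- seq_along(idx) - 1L
  nz <- which(w$weights != 0, arr.ind = TRUE)
  res <- cpp_searchlight(t(patterns_a$values), t(patterns_b$values),
                         shape, idx - 1L, col_of_lin,
                         sphere_offsets(spec$radius_voxels),
                         nz[, 1] - 1L, nz[, 2] - 1L,
                         w$weights[nz], spec$min_voxels)
  vol <- array(NaN, shape)
  vol[idx] <- res$values
  out <- stat_map(mask$grid, vol, "searchlight_sum")
  attr(out, "phase_pair") <- paste(as.character(w$trials_a$phase[1]),
                                   as.character(w$trials_b$phase[1]),
                                   sep = "/")
  attr(out, "weight_kind") <- w$kind
  attr(out, "zero_variance_pairs") <- res$zero_variance_pairs
  out
}

#' ROI RSA statistics
#'
#' Treats all ROI voxels as one pattern. For a same-versus-different
#' contrast, returns the average Fisher-transformed same-video and
#' different-video correlations separately (group tests are done
#' downstream), honouring the weight matrix's pair exclusions. For a
#' weighted-diagonal contrast, returns the weighted sum of Fisher-z values.
#'
#' @param patterns_a,patterns_b [pattern_set()] objects on one grid/mask.
#' @param roi a [brain_mask()] lying within the pattern mask, >= 2 voxels.
#' @param w a [weight_matrix()].
#' @return For `same_vs_different`, a list with `mean_same_z` and
#'   `mean_diff_z`; for `weighted_diagonal`, a list with `value`.
#' @export
roi_rsa <- function(patterns_a, patterns_b, roi, w) {
  check_conformable(patterns_a, patterns_b, w)
  mask <- patterns_a$mask
  roi_idx <- mask_indices(roi)
  if (length(roi_idx) < 2L) stop("ROI must contain at least 2 voxels")
  cols <- match(roi_idx, mask_indices(mask))
  if (anyNA(cols)) stop("ROI extends outside the pattern mask")
  A <- patterns_a$values[, cols, drop = FALSE]
  B <- patterns_b$values[, cols, drop = FALSE]
  sd_a <- apply(A, 1, stats::sd)
  sd_b <- apply(B, 1, stats::sd)
  r <- matrix(0, nrow(A), nrow(B))
  ok_a <- sd_a > 1e-12; ok_b <- sd_b > 1e-12
  zero_var <- sum(!ok_a) * nrow(B) + sum(ok_a) * sum(!ok_b)
  if (any(ok_a) && any(ok_b))
    r[ok_a, ok_b] <- stats::cor(t(A[ok_a, , drop = FALSE]),
                                t(B[ok_b, , drop = FALSE]))
  z <- fisher_z(r)
  if (w$kind == "same_vs_different") {
    same <- outer(w$trials_a$video_id, w$trials_b$video_id, "==")
    keep <- !w$excluded
    out <- list(mean_same_z = mean(z[same & keep]),
                mean_diff_z = mean(z[!same & keep]))
  } else {
    out <- list(value = sum(w$weights * z))
  }
  attr(out, "zero_variance_pairs") <- zero_var
  out
}
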