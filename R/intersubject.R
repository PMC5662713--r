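#' Smoothing specification
#' @param fwhm_mm Gaussian kernel full width at half maximum in mm (>= 0;
#'   0 means no smoothing).
#' @return An object of class `smoothing_spec`.
#' @export
smoothing_spec <- function(fwhm_mm = 6) {
  stopifnot(fwhm_mm >= 0)
  structure(list(fwhm_mm = fwhm_mm), class = "smoothing_spec")
}

#' Gaussian smoothing of a volume within a mask
#'
#' Separable Gaussian smoothing with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis, converted from mm to voxels by the voxel size. Values are
#' renormalized within the mask (ratio-of-smoothed-products) so masked-out
#' neighbours do not dilute edge voxels; voxels outside the mask are
#' returned unchanged as `NaN`/input.
#'
#' @param values 3D array on the grid.
#' @param grid a [volume_grid()].
#' @param spec a [smoothing_spec()].
#' @param mask optional [brain_mask()]; default smooths the full volume.
#' @return Smoothed 3D array.
#' @export
smooth_volume <- function(values, grid, spec = smoothing_spec(),
                          mask = NULL) {
  if (spec$fwhm_mm == 0) return(values)
  sigma_vox <- spec$fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size
  if (is.null(mask)) {
    sm <- cpp_gaussian_smooth(as.numeric(values), grid$shape, sigma_vox)
    return(array(sm, grid$shape))
  }
  m <- as.numeric(mask$voxels)
  v <- as.numeric(values)
  v[m == 0] <- 0
  num <- cpp_gaussian_smooth(v, grid$shape, sigma_vox)
  den <- cpp_gaussian_smooth(m, grid$shape, sigma_vox)
  out <- array(as.numeric(values), grid$shape)
  idx <- which(mask$voxels)
  out[idx] <- num[idx] / den[idx]
  out
}

#' Smooth every trial pattern of a pattern set
#'
#' Un-masks each trial row, smooths it (mask-renormalized), and re-masks.
#' @param patterns a [pattern_set()].
#' @param spec a [smoothing_spec()].
#' @return A [pattern_set()] of smoothed patterns.
#' @export
smooth_pattern_set <- function(patterns, spec = smoothing_spec()) {
  if (spec$fwhm_mm == 0) return(patterns)
  idx <- mask_indices(patterns$mask)
  vals <- patterns$values
  for (i in seq_len(nrow(vals))) {
    vol <- array(0, patterns$grid$shape)
    vol[idx] <- vals[i, ]
    sm <- smooth_volume(vol, patterns$grid, spec, patterns$mask)
    vals[i, ] <- sm[idx]
  }
  pattern_set(patterns$grid, patterns$mask, patterns$trials, vals)
}

#' Leave-one-out average pattern across subjects
#'
#' Voxelwise mean, over all subjects except `subject`, of each subject's
#' pattern for a given video and phase. Requires at least 3 subjects.
#'
#' @param pattern_sets list of per-subject [pattern_set()] objects for one
#'   phase, on a common grid/mask.
#' @param subject index of the held-out subject.
#' @param video_id video whose pattern to average.
#' @return Numeric vector over the mask voxels.
#' @export
leave_one_out_average <- function(pattern_sets, subject, video_id) {
  n <- length(pattern_sets)
  if (n < 3L) stop("leave-one-out averaging requires at least 3 subjects")
  others <- setdiff(seq_len(n), subject)
  rows <- vapply(others, function(s) {
    ps <- pattern_sets[[s]]
    r <- which(ps$trials$video_id == video_id)
    if (length(r) != 1L) stop("expected exactly one trial per video")
    ps$values[r, ]
  }, numeric(ncol(pattern_sets[[1]]$values)))
  rowMeans(rows)
}

#' Inter-subject searchlight RSA
#'
#' For each subject, correlates the subject's (smoothed) phase-A patterns
#' with the leave-one-out average of all other subjects' (smoothed) phase-B
#' patterns for each video, using the same searchlight and contrast-weight
#' machinery as the within-subject analysis.
#'
#' @param patterns_a,patterns_b lists of per-subject [pattern_set()] objects
#'   for the two phases (common grid/mask).
#' @param w a [weight_matrix()] built from one subject's trial tables (video
#'   sets are identical across subjects); the leave-one-out set is ordered
#'   by the phase-B trials of that table.
#' @param spec a [searchlight_spec()].
#' @param smoothing a [smoothing_spec()]; applied to both phases before
#'   correlating (pass `smoothing_spec(0)` if patterns are pre-smoothed).
#' @return List of per-subject [stat_map()] objects.
#' @export
intersubject_searchlight <- function(patterns_a, patterns_b, w,
                                     spec = searchlight_spec(),
                                     smoothing = smoothing_spec()) {
  n <- length(patterns_a)
  if (n < 3L || length(patterns_b) != n)
    stop("need >= 3 subjects with both phases")
  if (smoothing$fwhm_mm > 0) {
    patterns_a <- lapply(patterns_a, smooth_pattern_set, spec = smoothing)
    patterns_b <- lapply(patterns_b, smooth_pattern_set, spec = smoothing)
  }
  # grand sum over subjects per video (phase B), video order of subject 1
  ref_trials <- w$trials_b
  V <- ncol(patterns_b[[1]]$values)
  sums <- matrix(0, nrow(ref_trials), V)
  per_subj <- vector("list", n)
  for (s in seq_len(n)) {
    ps <- patterns_b[[s]]
    r <- match(ref_trials$video_id, ps$trials$video_id)
    per_subj[[s]] <- ps$values[r, , drop = FALSE]
    sums <- sums + per_subj[[s]]
  }
  out <- vector("list", n)
  for (s in seq_len(n)) {
    loo_vals <- (sums - per_subj[[s]]) / (n - 1)
    loo <- pattern_set(patterns_b[[s]]$grid, patterns_b[[s]]$mask,
                       ref_trials, loo_vals)
    # align the subject's phase-A rows with the weight matrix rows
    pa <- patterns_a[[s]]
    ra <- match(w$trials_a$video_id, pa$trials$video_id)
    pa_aligned <- pattern_set(pa$grid, pa$mask,
                              pa$trials[ra, , drop = FALSE],
                              pa$values[ra, , drop = FALSE])
    out[[s]] <- searchlight_rsa(pa_aligned, loo, w, spec)
  }
  out
}
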