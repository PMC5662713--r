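#' Voxel grid geometry
#'
#' A `volume_grid` records the shape of a 3D voxel array, the voxel size in
#' mm, and the 4x4 voxel-to-world affine. Voxel indices are 0-based when
#' mapped through the affine; all volumes in one analysis must share a grid.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param voxel_size numeric scalar or length-3 vector, mm per axis (> 0).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size` with the origin at the grid centre.
#' @param space free-text space label (e.g. `"common"`, `"native"`).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = 3, affine = NULL,
                        space = "common") {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  stopifnot(all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("grid affine must be invertible")
  structure(list(shape = shape, voxel_size = voxel_size,
                 affine = affine, space = space),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, %.3g x %.3g x %.3g mm, space '%s'>\n",
              paste(x$shape, collapse = "x"),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$space))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$affine - b$affine)) < tol
}

#' Binary mask on a voxel grid
#'
#' @param grid a [volume_grid()].
#' @param voxels logical (or coercible) array with the grid's shape; must
#'   select at least one voxel.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(grid, voxels) {
  stopifnot(inherits(grid, "volume_grid"))
  voxels <- array(as.logical(voxels), dim = grid$shape)
  if (anyNA(voxels)) stop("mask may not contain NA")
  if (!any(voxels)) stop("mask must select at least one voxel")
  structure(list(grid = grid, voxels = voxels), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask %d / %d voxels>\n", sum(x$voxels),
              prod(x$grid$shape)))
  invisible(x)
}

#' Linear (1-based) indices of the voxels selected by a mask
#' @param mask a [brain_mask()].
#' @return Integer vector of in-mask voxel indices, column-major order.
#' @export
mask_indices <- function(mask) which(mask$voxels)

#' Ellipsoidal brain mask filling a grid
#'
#' Convenience constructor used by the synthetic generator: an ellipsoid with
#' semi-axes just inside the grid, mimicking a brain-shaped analysis mask.
#' @param grid a [volume_grid()].
#' @param fraction semi-axis length as a fraction of the half-extent.
#' @return A [brain_mask()].
#' @export
ellipsoid_mask <- function(grid, fraction = 1) {
  s <- grid$shape
  ctr <- (s - 1) / 2
  semi <- pmax(fraction * (s - 1) / 2, 0.5)
  idx <- expand.grid(x = 0:(s[1] - 1), y = 0:(s[2] - 1), z = 0:(s[3] - 1))
  d <- ((idx$x - ctr[1]) / semi[1])^2 + ((idx$y - ctr[2]) / semi[2])^2 +
    ((idx$z - ctr[3]) / semi[3])^2
  brain_mask(grid, array(d <= 1, dim = s))
}

#' Spherical region of a given size inside a mask
#'
#' Takes the `n_voxels` in-mask voxels nearest (Euclidean, voxel units) to a
#' centre, producing a compact quasi-spherical ROI of exactly the requested
#' size. Used to place synthetic effect regions and ROIs.
#'
#' @param mask a [brain_mask()] delimiting candidate voxels.
#' @param n_voxels region size in voxels.
#' @param center 0-based voxel coordinates of the centre; defaults to the
#'   mask centroid.
#' @return A [brain_mask()] on the same grid.
#' @export
region_sphere <- function(mask, n_voxels, center = NULL) {
  stopifnot(inherits(mask, "brain_mask"), n_voxels >= 1)
  idx <- mask_indices(mask)
  if (n_voxels > length(idx))
    stop("requested region larger than the mask")
  co <- voxel_coords(idx, mask$grid$shape)
  if (is.null(center)) center <- colMeans(co)
  d <- sqrt(colSums((t(co) - center)^2))
  keep <- idx[order(d)[seq_len(n_voxels)]]
  vox <- array(FALSE, mask$grid$shape)
  vox[keep] <- TRUE
  brain_mask(mask$grid, vox)
}

# 0-based (x, y, z) coordinates for 1-based linear indices
voxel_coords <- function(lin, shape) {
  lin0 <- lin - 1L
  x <- lin0 %% shape[1]
  rem <- lin0 %/% shape[1]
  cbind(x = x, y = rem %% shape[2], z = rem %/% shape[2])
}

#' Per-trial pattern set
#'
#' The unit object of every RSA: a trial-by-voxel matrix of per-trial
#' statistic values restricted to an analysis mask, with its trial table.
#'
#' @param grid a [volume_grid()].
#' @param mask a [brain_mask()] on `grid`.
#' @param trials trial table (one row per pattern row, see
#'   [validate_trial_table()]).
#' @param values numeric matrix, trials x in-mask voxels, all finite.
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(grid, mask, trials, values) {
  stopifnot(inherits(grid, "volume_grid"), inherits(mask, "brain_mask"))
  if (!grids_equal(grid, mask$grid)) stop("mask grid differs from grid")
  values <- as.matrix(values)
  if (nrow(values) != nrow(trials))
    stop("pattern rows (", nrow(values), ") do not match trial rows (",
         nrow(trials), ")")
  if (ncol(values) != sum(mask$voxels))
    stop("pattern columns (", ncol(values), ") do not match mask voxels (",
         sum(mask$voxels), ")")
  if (!all(is.finite(values)))
    stop("pattern values must be finite within the mask")
  structure(list(grid = grid, mask = mask, trials = trials, values = values),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set %d trials x %d voxels (%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(unique(as.character(x$trials$phase)), collapse = "/")))
  invisible(x)
}

#' Voxelwise statistic volume
#'
#' @param grid a [volume_grid()].
#' @param values 3D numeric array on the grid; `NaN`/`NA` allowed outside the
#'   analysis mask.
#' @param stat_kind one of `"searchlight_sum"`, `"t"`, `"F"`, `"z"`.
#' @param df degrees of freedom (for `t`/`F` maps), else `NULL`.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(grid, values, stat_kind = c("searchlight_sum", "t",
                                                 "F", "z"), df = NULL) {
  stat_kind <- match.arg(stat_kind)
  stopifnot(inherits(grid, "volume_grid"))
  values <- array(as.numeric(values), dim = grid$shape)
  structure(list(grid = grid, values = values, stat_kind = stat_kind,
                 df = df), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map %s, %s%s>\n", paste(x$grid$shape, collapse = "x"),
              x$stat_kind,
              if (is.null(x$df)) "" else paste0(", df=",
                                                paste(x$df, collapse = ","))))
  invisible(x)
}

#' Validate a trial table
#'
#' Checks the invariants of the study design: phases `Enc`/`ImRet`/`DelRet`;
#' Day-1 phases in runs 1-2 and delayed retrieval in run 3; video ids in
#' 1..24 (or `n_videos`); unique (phase, video) per subject; vividness on the
#' 1-6 scale for retrieval trials.
#'
#' @param trials data frame of trials.
#' @param n_videos number of distinct videos in the design.
#' @return `trials`, invisibly, with `phase` as a factor.
#' @export
validate_trial_table <- function(trials, n_videos = 24) {
  req <- c("subject_id", "phase", "run", "video_id", "onset", "duration")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trial table missing columns: ",
                         paste(miss, collapse = ", "))
  trials$phase <- factor(as.character(trials$phase),
                         levels = c("Enc", "ImRet", "DelRet"))
  if (anyNA(trials$phase)) stop("phase must be Enc, ImRet or DelRet")
  if (!all(trials$video_id %in% seq_len(n_videos)))
    stop("video_id out of range 1..", n_videos)
  day1 <- trials$phase %in% c("Enc", "ImRet")
  if (!all(trials$run[day1] %in% 1:2))
    stop("Enc/ImRet trials must be in run 1 or 2")
  if (!all(trials$run[!day1] == 3L))
    stop("DelRet trials must be in run 3")
  key <- interaction(trials$subject_id, trials$phase, trials$video_id,
                     drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (subject, phase, video) trials")
  if ("vividness" %in% names(trials)) {
    v <- trials$vividness[trials$phase != "Enc"]
    v <- v[!is.na(v)]
    if (length(v) && (any(v < 1) || any(v > 6)))
      stop("vividness ratings must lie in [1, 6]")
  }
  invisible(trials)
}
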