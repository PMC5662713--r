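#' @useDynLib reinstatr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical trial-table column order (BIDS-like events dialect: onset and
# duration first)
TRIAL_COLUMNS <- c("onset", "duration", "subject_id", "phase", "run",
                   "video_id", "cue_onset", "vividness",
                   "retrieval_duration")

grid_from_nifti <- function(img, space = "common") {
  d <- dim(img)
  if (length(d) < 3L) stop("expected a 3D (or 4D) NIfTI volume")
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  pd <- attr(img, "pixdim")
  vs <- if (!is.null(pd) && length(pd) >= 3) abs(pd[1:3]) else
    sqrt(colSums(aff[1:3, 1:3]^2))
  volume_grid(d[1:3], voxel_size = vs, affine = aff, space = space)
}

nifti_with_grid <- function(values, grid) {
  img <- RNifti::asNifti(array(values, dim = grid$shape))
  RNifti::pixdim(img) <- grid$voxel_size
  aff <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  img
}

#' Read a binary mask from NIfTI
#'
#' Nonzero voxels are in-mask.
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return A [brain_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  brain_mask(grid, vals != 0)
}

#' Write a mask to NIfTI
#' @param mask a [brain_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- nifti_with_grid(as.numeric(mask$voxels), mask$grid)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a statistic map to NIfTI
#'
#' Values are stored at double precision so a write-read round trip is
#' bitwise exact; `NaN` outside the analysis mask is preserved.
#'
#' @param map a [stat_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  img <- nifti_with_grid(map$values, map$grid)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a statistic map from NIfTI
#' @param path input path.
#' @param stat_kind statistic kind to record on the result.
#' @param df optional degrees of freedom.
#' @return A [stat_map()].
#' @export
read_stat_map <- function(path, stat_kind = "searchlight_sum", df = NULL) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  stat_map(grid, vals, stat_kind = stat_kind, df = df)
}

#' Read a pattern set from per-trial volumes
#'
#' @param volume_paths character vector of per-trial NIfTI maps, one per
#'   trial-table row, in row order.
#' @param mask_path NIfTI mask delimiting the analysis voxels.
#' @param trial_table_path TSV trial table (see [read_trial_table()]).
#' @return A [pattern_set()].
#' @export
read_pattern_set <- function(volume_paths, mask_path, trial_table_path) {
  mask <- read_mask(mask_path)
  trials <- read_trial_table(trial_table_path)
  if (length(volume_paths) != nrow(trials))
    stop("alignment error: ", length(volume_paths), " volumes for ",
         nrow(trials), " trial rows")
  idx <- mask_indices(mask)
  values <- matrix(NA_real_, nrow(trials), length(idx))
  for (i in seq_along(volume_paths)) {
    img <- RNifti::readNifti(volume_paths[i])
    g <- grid_from_nifti(img)
    if (!grids_equal(g, mask$grid))
      stop("shape error: volume ", volume_paths[i],
           " is not on the mask grid")
    v <- as.array(img)
    values[i, ] <- v[idx]
  }
  pattern_set(mask$grid, mask, trials, values)
}

#' Write a pattern set as per-trial volumes plus an events table
#'
#' Un-masks each trial row into a full volume (NaN outside the mask) and
#' writes `trial_<i>.nii.gz` files alongside `events.tsv`.
#'
#' @param patterns a [pattern_set()].
#' @param dir output directory (created if needed).
#' @return Character vector of the volume paths, invisibly.
#' @export
write_pattern_set <- function(patterns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- mask_indices(patterns$mask)
  paths <- character(nrow(patterns$values))
  for (i in seq_len(nrow(patterns$values))) {
    vol <- array(NaN, patterns$grid$shape)
    vol[idx] <- patterns$values[i, ]
    paths[i] <- file.path(dir, sprintf("trial_%03d.nii.gz", i))
    write_stat_map(stat_map(patterns$grid, vol, "t"), paths[i])
  }
  write_trial_table(patterns$trials, file.path(dir, "events.tsv"))
  invisible(paths)
}

#' Read a trial table from TSV
#'
#' Expects a tab-separated file with a header row in the BIDS-like events
#' dialect (`onset` and `duration` first).
#' @param path input TSV.
#' @return A validated trial data frame.
#' @export
read_trial_table <- function(path) {
  tt <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_trial_table(tt)
  tt$phase <- factor(tt$phase, levels = c("Enc", "ImRet", "DelRet"))
  tt
}

#' Write a trial table to TSV in canonical column order
#' @param trials trial data frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  cols <- intersect(TRIAL_COLUMNS, names(trials))
  cols <- c(cols, setdiff(names(trials), cols))
  utils::write.table(trials[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
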