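# Small in-code fixtures shared across the suite.

full_mask <- function(shape, voxel_size = 3) {
  g <- volume_grid(shape, voxel_size)
  brain_mask(g, array(TRUE, shape))
}

# minimal valid trial table: one trial per video, Day-1 phases split over
# two runs (first half run 1), delayed retrieval in run 3
toy_trials <- function(phase, n_videos, subject = "sub-01") {
  run <- if (phase %in% c("Enc", "ImRet"))
    rep(1:2, each = n_videos / 2) else rep(3L, n_videos)
  onset <- 10 + (seq_len(n_videos) - 1) * 50
  tt <- data.frame(subject_id = subject, phase = phase, run = run,
                   video_id = seq_len(n_videos), onset = onset,
                   duration = 38,
                   cue_onset = if (phase == "Enc") NA_real_ else onset - 2,
                   vividness = if (phase == "Enc") NA_real_ else 4,
                   retrieval_duration = if (phase == "Enc") NA_real_ else 35)
  tt$phase <- factor(tt$phase, levels = c("Enc", "ImRet", "DelRet"))
  tt
}

toy_pattern_set <- function(mask, phase, n_videos, values = NULL) {
  tt <- toy_trials(phase, n_videos)
  if (is.null(values))
    values <- matrix(rnorm(n_videos * sum(mask$voxels)), n_videos)
  pattern_set(mask$grid, mask, tt, values)
}

# Independent brute-force searchlight oracle: direct lattice enumeration of
# the sphere and stats::cor per centre, no shared code with the engine.
naive_searchlight <- function(pa, pb, w, radius = 3, min_voxels = 10) {
  shape <- pa$grid$shape
  mask_idx <- which(pa$mask$voxels)
  out <- array(NaN, shape)
  off <- expand.grid(dx = -ceiling(radius):ceiling(radius),
                     dy = -ceiling(radius):ceiling(radius),
                     dz = -ceiling(radius):ceiling(radius))
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= radius^2, ]
  col_of <- rep(NA_integer_, prod(shape))
  col_of[mask_idx] <- seq_along(mask_idx)
  for (v in mask_idx) {
    lin0 <- v - 1
    x <- lin0 %% shape[1]
    y <- (lin0 %/% shape[1]) %% shape[2]
    z <- lin0 %/% (shape[1] * shape[2])
    px <- x + off$dx; py <- y + off$dy; pz <- z + off$dz
    ok <- px >= 0 & px < shape[1] & py >= 0 & py < shape[2] &
      pz >= 0 & pz < shape[3]
    lin <- 1 + px[ok] + shape[1] * (py[ok] + shape[2] * pz[ok])
    cols <- col_of[lin]
    cols <- cols[!is.na(cols)]
    if (length(cols) < min_voxels) next
    r <- cor(t(pa$values[, cols, drop = FALSE]),
             t(pb$values[, cols, drop = FALSE]))
    z_mat <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
    out[v] <- sum(w$weights * z_mat)
  }
  out
}

# study generation shortcut
small_study <- function(n_subjects, n_videos, shape, delta = 0,
                        region_size = 0, coupling = 0, shared = 0,
                        seed = 1, mask = NULL) {
  g <- volume_grid(shape, 3)
  if (is.null(mask)) mask <- brain_mask(g, array(TRUE, shape))
  effects <- list()
  region <- NULL
  if (region_size > 0) {
    region <- region_sphere(mask, region_size)
    effects <- list(effect_spec(region, delta_z_same = delta,
                                behavior_coupling = coupling,
                                shared_fraction = shared))
  }
  cfg <- generator_config(n_subjects = n_subjects, n_videos = n_videos,
                          shape = shape, effects = effects, seed = seed)
  st <- generate_pattern_study(cfg, mask = mask)
  st$region <- region
  st
}
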