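#' Effect specification for the synthetic generator
#'
#' Describes one region carrying ground-truth reinstatement structure: the
#' target mean excess Fisher-z similarity of same-video over different-video
#' pattern pairs per phase pair, an optional coupling of per-video
#' reinstatement strength to centred memory scores, and the fraction of each
#' video's latent pattern that is common across subjects.
#'
#' @param region a [brain_mask()] lying within the study brain mask.
#' @param delta_z_same target same-minus-different Fisher-z gap; scalar or
#'   named length-3 vector `c(enc_imret=, enc_delret=, imret_delret=)`.
#'   Must be non-negative.
#' @param behavior_coupling slope (>= 0) of the per-video same-pair Fisher-z
#'   target on the video's centred memory score.
#' @param shared_fraction fraction in `[0, 1]` of each video's latent
#'   pattern shared across subjects.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(region, delta_z_same = 0.25, behavior_coupling = 0,
                        shared_fraction = 0) {
  stopifnot(inherits(region, "brain_mask"), all(delta_z_same >= 0),
            behavior_coupling >= 0,
            shared_fraction >= 0, shared_fraction <= 1)
  if (length(delta_z_same) == 1L)
    delta_z_same <- rep(delta_z_same, 3L)
  if (length(delta_z_same) != 3L)
    stop("delta_z_same must be scalar or length 3")
  names(delta_z_same) <- c("enc_imret", "enc_delret", "imret_delret")
  structure(list(region = region, delta_z_same = delta_z_same,
                 behavior_coupling = behavior_coupling,
                 shared_fraction = shared_fraction),
            class = "effect_spec")
}

#' Synthetic study configuration
#'
#' Defaults emulate the study design: 21 subjects, 24 silent videos of
#' 29-48 s, encoding plus immediate retrieval split over two Day-1 runs of
#' 12 videos, delayed retrieval of all 24 videos in one Day-8 run, TR
#' 2.62 s, 12 s inter-stimulus fixation, 2 s retrieval cues, self-paced
#' retrieval in a 20-55 s window, free-recall detail scores with mean 11.5
#' (SD 2.7) and a 0.7-point vividness drop from immediate (mean 4.2) to
#' delayed retrieval on the 1-6 scale.
#'
#' @param n_subjects number of subjects.
#' @param n_videos number of videos; must be divisible by the Day-1 run
#'   count (2).
#' @param shape,voxel_size grid geometry (small by default so a full study
#'   simulates in seconds to minutes).
#' @param tr repetition time in s.
#' @param video_duration_range min/max video duration, s.
#' @param isi inter-stimulus fixation duration, s.
#' @param cue_duration retrieval cue duration, s.
#' @param rating_duration modelled duration of the vividness rating event, s.
#' @param retrieval_duration_mean,retrieval_duration_sd mean/SD of the
#'   self-paced retrieval durations for (ImRet, DelRet), truncated to the
#'   20-55 s window.
#' @param noise_sd SD of additive measurement noise in time-series mode.
#' @param effects list of [effect_spec()] regions (non-overlapping).
#' @param behavior_mean_details,behavior_sd mean/SD of per-video free-recall
#'   detail scores.
#' @param vividness_mean_imret mean immediate-retrieval vividness.
#' @param vividness_drop mean vividness decrease after one week.
#' @param seed integer seed making the study fully reproducible.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 21, n_videos = 24,
                             shape = c(24, 28, 24), voxel_size = 3,
                             tr = 2.62,
                             video_duration_range = c(29, 48),
                             isi = 12, cue_duration = 2,
                             rating_duration = 4,
                             retrieval_duration_mean = c(35.1, 33.6),
                             retrieval_duration_sd = c(8.0, 8.8),
                             noise_sd = 1,
                             effects = list(),
                             behavior_mean_details = 11.5,
                             behavior_sd = 2.7,
                             vividness_mean_imret = 4.2,
                             vividness_drop = 0.7,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_videos >= 2, n_videos %% 2 == 0,
            tr > 0, all(video_duration_range > 0), isi > 0,
            cue_duration > 0, noise_sd >= 0)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_videos = as.integer(n_videos),
                 shape = as.integer(shape), voxel_size = voxel_size,
                 tr = tr, video_duration_range = video_duration_range,
                 isi = isi, cue_duration = cue_duration,
                 rating_duration = rating_duration,
                 retrieval_duration_mean = retrieval_duration_mean,
                 retrieval_duration_sd = retrieval_duration_sd,
                 noise_sd = noise_sd, effects = effects,
                 behavior_mean_details = behavior_mean_details,
                 behavior_sd = behavior_sd,
                 vividness_mean_imret = vividness_mean_imret,
                 vividness_drop = vividness_drop,
                 seed = as.integer(seed)),
            class = "generator_config")
}

PHASES <- c("Enc", "ImRet", "DelRet")

# Solve per-phase latent loadings a = (a_Enc, a_ImRet, a_DelRet) such that
# atanh(a_p * a_q) equals the requested same-pair Fisher-z target for each
# phase pair (order: Enc/ImRet, Enc/DelRet, ImRet/DelRet).
solve_phase_loadings <- function(z_targets) {
  t3 <- tanh(pmax(z_targets, 0))
  eps <- 1e-10
  pos <- t3 > eps
  if (!any(pos)) return(c(0, 0, 0))
  if (all(pos)) {
    a <- sqrt(c(t3[1] * t3[2] / t3[3],
                t3[1] * t3[3] / t3[2],
                t3[2] * t3[3] / t3[1]))
    if (any(a >= 1))
      stop("impossible delta_z_same: implied pattern correlation >= 1")
    return(a)
  }
  if (sum(pos) == 1L) {
    a <- c(0, 0, 0)
    r <- sqrt(t3[which(pos)])
    if (r >= 1) stop("impossible delta_z_same: implied correlation >= 1")
    phases_of_pair <- list(c(1, 2), c(1, 3), c(2, 3))[[which(pos)]]
    a[phases_of_pair] <- r
    return(a)
  }
  stop("incoherent delta_z_same: two positive pair targets require the ",
       "third to be positive as well")
}

round_half <- function(x) round(x * 2) / 2

rtrunc_window <- function(n, mean, sd, lo = 20.5, hi = 54.5) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Per-subject trial table with full timing for the three runs.
build_subject_trials <- function(config, subject_id, video_durations,
                                 ret_dur_im, ret_dur_del, order_day1,
                                 order_day8) {
  nv <- config$n_videos
  half <- nv %/% 2L
  rows <- list()
  for (run in 1:2) {
    vids <- order_day1[seq((run - 1) * half + 1, run * half)]
    t <- 10
    for (v in vids) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id, phase = "Enc", run = run, video_id = v,
        onset = t, duration = video_durations[v], cue_onset = NA_real_,
        vividness = NA_real_, retrieval_duration = NA_real_)
      t <- t + video_durations[v] + config$isi
    }
    for (v in vids) {
      cue <- t
      onset <- cue + config$cue_duration
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id, phase = "ImRet", run = run, video_id = v,
        onset = onset, duration = ret_dur_im[v], cue_onset = cue,
        vividness = NA_real_, retrieval_duration = ret_dur_im[v])
      t <- onset + ret_dur_im[v] + config$rating_duration + config$isi
    }
  }
  t <- 10
  for (v in order_day8) {
    cue <- t
    onset <- cue + config$cue_duration
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subject_id, phase = "DelRet", run = 3L, video_id = v,
      onset = onset, duration = ret_dur_del[v], cue_onset = cue,
      vividness = NA_real_, retrieval_duration = ret_dur_del[v])
    t <- onset + ret_dur_del[v] + config$rating_duration + config$isi
  }
  tt <- do.call(rbind, rows)
  tt$phase <- factor(tt$phase, levels = PHASES)
  validate_trial_table(tt, n_videos = nv)
  tt
}

#' Generate a full multi-subject pattern study
#'
#' Draws per-trial pattern maps directly (bypassing BOLD simulation and the
#' GLM): within each effect region, the same-video pattern pairs across
#' phases share a latent component whose loading is solved from the
#' requested Fisher-z gap via `corr = tanh(z)`; outside effect regions
#' patterns are unit-variance Gaussian noise. Detail scores drive per-video
#' reinstatement strength when `behavior_coupling > 0`, and a
#' `shared_fraction` of each video's latent pattern is identical across
#' subjects. Fully reproducible from `config$seed`.
#'
#' @param config a [generator_config()].
#' @param mask optional analysis [brain_mask()]; default is an ellipsoid
#'   filling the grid.
#' @return A list with elements `config`, `grid`, `mask`, `subjects` (per
#'   subject: `trials` and `patterns`, a list of [pattern_set()] per phase),
#'   `behavior` (see [generate_behavior()]) and `truth` (ground-truth
#'   record: per-effect loadings, latents seeds, scores).
#' @export
generate_pattern_study <- function(config, mask = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  grid <- volume_grid(config$shape, config$voxel_size)
  if (is.null(mask)) mask <- ellipsoid_mask(grid)
  stopifnot(grids_equal(grid, mask$grid))
  vox_idx <- mask_indices(mask)
  V <- length(vox_idx)
  ns <- config$n_subjects
  nv <- config$n_videos

  # effect regions: membership columns within the mask
  eff_cols <- lapply(config$effects, function(e) {
    if (any(e$region$voxels & !mask$voxels))
      stop("effect region extends outside the brain mask")
    match(mask_indices(e$region), vox_idx)
  })
  if (length(eff_cols) > 1L) {
    all_cols <- unlist(eff_cols)
    if (anyDuplicated(all_cols)) stop("effect regions overlap")
  }

  # study-level stimulus properties
  video_durations <- stats::runif(nv, config$video_duration_range[1],
                                  config$video_duration_range[2])

  # detail scores come first: they drive reinstatement strength
  scores <- matrix(round_half(pmax(0, stats::rnorm(
    ns * nv, config$behavior_mean_details, config$behavior_sd))),
    ns, nv)
  rel_scores <- sweep(scores, 2, colMeans(scores))

  # per-effect latent loadings per subject x video x phase
  truth_effects <- vector("list", length(config$effects))
  latents <- vector("list", length(config$effects))
  for (ei in seq_along(config$effects)) {
    e <- config$effects[[ei]]
    m <- length(eff_cols[[ei]])
    loadings <- array(0, c(ns, nv, 3L),
                      dimnames = list(NULL, NULL, PHASES))
    a_base <- solve_phase_loadings(e$delta_z_same)
    zbar <- mean(e$delta_z_same)
    for (s in seq_len(ns)) for (v in seq_len(nv)) {
      if (e$behavior_coupling == 0) {
        loadings[s, v, ] <- a_base
      } else {
        # behaviour shifts the (mean) same-pair Fisher-z target; all phase
        # loadings are scaled jointly so the pair system stays coherent
        target <- max(zbar + e$behavior_coupling * rel_scores[s, v], 0)
        if (zbar > 0) {
          a <- a_base * sqrt(tanh(target) / tanh(zbar))
        } else {
          a <- rep(sqrt(tanh(target)), 3L)
        }
        if (any(a >= 1))
          stop("impossible delta_z_same/behavior_coupling: implied ",
               "correlation >= 1")
        loadings[s, v, ] <- a
      }
    }
    shared <- matrix(stats::rnorm(m * nv), m, nv)        # across-subject
    private <- array(stats::rnorm(m * nv * ns), c(m, nv, ns))
    f <- e$shared_fraction
    L <- array(0, c(m, nv, ns))
    for (s in seq_len(ns))
      L[, , s] <- sqrt(f) * shared + sqrt(1 - f) * private[, , s]
    latents[[ei]] <- L
    truth_effects[[ei]] <- list(region = e$region, cols = eff_cols[[ei]],
                                loadings = loadings,
                                shared_fraction = f,
                                behavior_coupling = e$behavior_coupling,
                                delta_z_same = e$delta_z_same,
                                shared_latent = shared)
  }

  # trial tables and patterns
  subjects <- vector("list", ns)
  for (s in seq_len(ns)) {
    ret_im <- rtrunc_window(nv, config$retrieval_duration_mean[1],
                            config$retrieval_duration_sd[1])
    ret_del <- rtrunc_window(nv, config$retrieval_duration_mean[2],
                             config$retrieval_duration_sd[2])
    trials <- build_subject_trials(config, sprintf("sub-%02d", s),
                                   video_durations, ret_im, ret_del,
                                   sample.int(nv), sample.int(nv))
    patterns <- list()
    for (pi in seq_along(PHASES)) {
      ph <- PHASES[pi]
      ph_trials <- trials[trials$phase == ph, , drop = FALSE]
      vals <- matrix(stats::rnorm(nrow(ph_trials) * V), nrow(ph_trials), V)
      for (ei in seq_along(config$effects)) {
        cols <- eff_cols[[ei]]
        for (r in seq_len(nrow(ph_trials))) {
          v <- ph_trials$video_id[r]
          a <- truth_effects[[ei]]$loadings[s, v, pi]
          if (a > 0)
            vals[r, cols] <- a * latents[[ei]][, v, s] +
              sqrt(1 - a^2) * vals[r, cols]
        }
      }
      patterns[[ph]] <- pattern_set(grid, mask, ph_trials, vals)
    }
    subjects[[s]] <- list(trials = trials, patterns = patterns)
  }

  behavior <- generate_behavior(config,
                                list(scores = scores,
                                     rel_scores = rel_scores),
                                subjects)
  # copy vividness into the trial tables (per subject x phase x video)
  for (s in seq_len(ns)) {
    bt <- behavior[behavior$subject_id == sprintf("sub-%02d", s), ]
    for (ph in c("ImRet", "DelRet")) {
      col <- if (ph == "ImRet") "vividness_imret" else "vividness_delret"
      tt <- subjects[[s]]$trials
      sel <- tt$phase == ph
      tt$vividness[sel] <- bt[[col]][match(tt$video_id[sel], bt$video_id)]
      subjects[[s]]$trials <- tt
      subjects[[s]]$patterns[[ph]]$trials$vividness <-
        bt[[col]][match(subjects[[s]]$patterns[[ph]]$trials$video_id,
                        bt$video_id)]
    }
  }

  list(config = config, grid = grid, mask = mask, subjects = subjects,
       behavior = behavior,
       truth = list(effects = truth_effects, scores = scores,
                    rel_scores = rel_scores,
                    video_durations = video_durations))
}

#' Generate the behavioral table for a study
#'
#' Produces per subject-by-video detail scores (non-negative, half-point
#' granularity), relative (per-video across-subject centred) scores, and
#' immediate/delayed vividness ratings on the 1-6 scale whose mean drops by
#' `vividness_drop` after a week and which correlate positively with the
#' detail scores.
#'
#' @param config a [generator_config()].
#' @param latent_strengths list carrying the `scores` matrix (and
#'   `rel_scores`) produced during pattern generation.
#' @param subjects optional per-subject records holding trial tables with
#'   retrieval durations to copy into the table.
#' @return A data frame with one row per subject x video.
#' @export
generate_behavior <- function(config, latent_strengths, subjects = NULL) {
  scores <- latent_strengths$scores
  ns <- nrow(scores); nv <- ncol(scores)
  rel <- sweep(scores, 2, colMeans(scores))
  std <- t(scale(t(scores)))
  std[is.na(std)] <- 0

  subj_offset <- stats::rnorm(ns, 0, 0.35)
  drop_s <- stats::rnorm(ns, config$vividness_drop, 0.40)
  viv_im <- config$vividness_mean_imret + subj_offset + 0.25 * std +
    matrix(stats::rnorm(ns * nv, 0, 0.5), ns, nv)
  viv_im <- pmin(pmax(viv_im, 1), 6)
  viv_del <- viv_im - drop_s + matrix(stats::rnorm(ns * nv, 0, 0.3), ns, nv)
  viv_del <- pmin(pmax(viv_del, 1), 6)

  out <- do.call(rbind, lapply(seq_len(ns), function(s) {
    rd_im <- rd_del <- rep(NA_real_, nv)
    if (!is.null(subjects)) {
      tt <- subjects[[s]]$trials
      im <- tt[tt$phase == "ImRet", ]
      del <- tt[tt$phase == "DelRet", ]
      rd_im[im$video_id] <- im$retrieval_duration
      rd_del[del$video_id] <- del$retrieval_duration
    }
    data.frame(subject_id = sprintf("sub-%02d", s), video_id = seq_len(nv),
               detail_score = scores[s, ], relative_score = rel[s, ],
               vividness_imret = viv_im[s, ], vividness_delret = viv_del[s, ],
               retrieval_duration_imret = rd_im,
               retrieval_duration_delret = rd_del)
  }))
  rownames(out) <- NULL
  out
}

#' Generate BOLD time series for a study
#'
#' Simulates run-wise 4D series as HRF-convolved boxcars carrying each
#' trial's spatial pattern, plus a global low-frequency drift expressed most
#' strongly in a designated white-matter compartment, motion-correlated
#' nuisance signal, and white Gaussian noise. The latent pattern structure
#' and trial timing are identical to [generate_pattern_study()]'s.
#'
#' @param config a [generator_config()] (typically with a small grid).
#' @param drift_amplitude SD of the global drift signal added to every voxel
#'   (unit gain on average).
#' @param motion_amplitude SD of the per-voxel motion-artifact couplings.
#' @param drop_initial number of initial dummy volumes included at the start
#'   of each run (discarded before model fitting).
#' @return A list with `grid`, `gm_mask` (analysis mask), `wm_mask`,
#'   `subjects` (per subject: `trials` and `runs`, each run a list with the
#'   volumes-by-voxel `data` matrix over the full grid, `n_volumes`,
#'   `motion` series and the run's trial rows), and `truth` (injected
#'   patterns per trial, drift series, loadings).
#' @export
generate_timeseries_study <- function(config, drift_amplitude = 1,
                                      motion_amplitude = 0.2,
                                      drop_initial = 5L) {
  stopifnot(inherits(config, "generator_config"))
  # pattern machinery first (uses config$seed)
  grid <- volume_grid(config$shape, config$voxel_size)
  brain <- ellipsoid_mask(grid)
  wm <- region_sphere(brain, max(8L, round(0.06 * sum(brain$voxels))))
  gm_vox <- brain$voxels & !wm$voxels
  gm <- brain_mask(grid, gm_vox)
  study <- generate_pattern_study(config, mask = gm)

  nvox <- prod(grid$shape)
  gm_idx <- mask_indices(gm)
  wm_idx <- mask_indices(wm)
  tr <- config$tr

  subjects <- vector("list", config$n_subjects)
  truth_runs <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    trials <- study$subjects[[s]]$trials
    runs <- list()
    truth_s <- list()
    for (run in sort(unique(trials$run))) {
      rt <- trials[trials$run == run, , drop = FALSE]
      run_end <- max(rt$onset + rt$duration) + 25
      n_after <- ceiling(run_end / tr)
      n_vols <- n_after + drop_initial
      times <- (seq_len(n_vols) - 1) * tr   # volume acquisition times
      # trials exceed scan duration guard
      if (max(rt$onset + rt$duration) > n_vols * tr)
        stop("timing error: trials exceed run duration")

      data <- matrix(0, n_vols, nvox)
      pat_truth <- vector("list", nrow(rt))
      for (i in seq_len(nrow(rt))) {
        ph <- as.character(rt$phase[i])
        ps <- study$subjects[[s]]$patterns[[ph]]
        row <- which(ps$trials$video_id == rt$video_id[i])
        pat <- numeric(nvox)
        pat[gm_idx] <- ps$values[row, ]
        reg <- hrf_regressor(rt$onset[i], rt$duration[i], n_vols, tr)
        data <- data + outer(reg, pat)
        pat_truth[[i]] <- ps$values[row, ]
      }
      # cue and rating responses share a fixed spatial pattern each
      if (any(!is.na(rt$cue_onset))) {
        cue_pat <- numeric(nvox)
        cue_pat[gm_idx] <- stats::rnorm(length(gm_idx))
        reg <- hrf_regressor(rt$cue_onset[!is.na(rt$cue_onset)],
                             rep(config$cue_duration,
                                 sum(!is.na(rt$cue_onset))), n_vols, tr)
        data <- data + outer(reg, cue_pat)
        rate_pat <- numeric(nvox)
        rate_pat[gm_idx] <- stats::rnorm(length(gm_idx))
        ro <- rt$onset[!is.na(rt$cue_onset)] +
          rt$duration[!is.na(rt$cue_onset)]
        reg <- hrf_regressor(ro, rep(config$rating_duration, length(ro)),
                             n_vols, tr)
        data <- data + outer(reg, rate_pat)
      }
      # global drift: smooth low-frequency signal, per-voxel gain near 1
      ph <- stats::runif(3, 0, 2 * pi)
      fr <- stats::runif(3, 0.002, 0.008)
      drift <- rowSums(sapply(1:3, function(k) sin(2 * pi * fr[k] * times +
                                                     ph[k])))
      drift <- as.numeric(scale(drift)) * drift_amplitude
      gain <- 1 + 0.1 * stats::rnorm(nvox)
      data <- data + outer(drift, gain)
      # motion series (random walks) with voxelwise artifact couplings
      motion <- apply(matrix(stats::rnorm(n_vols * 6, 0, 0.02), n_vols, 6),
                      2, cumsum)
      coup <- matrix(stats::rnorm(6 * nvox, 0, motion_amplitude), 6, nvox)
      data <- data + motion %*% coup
      if (config$noise_sd > 0)
        data <- data + matrix(stats::rnorm(n_vols * nvox, 0,
                                           config$noise_sd), n_vols, nvox)
      runs[[as.character(run)]] <- list(run = run, data = data,
                                        n_volumes = n_vols,
                                        drop_initial = drop_initial,
                                        motion = motion, trials = rt)
      truth_s[[as.character(run)]] <- list(drift = drift,
                                           patterns = pat_truth)
    }
    subjects[[s]] <- list(trials = trials, runs = runs)
    truth_runs[[s]] <- truth_s
  }

  list(grid = grid, gm_mask = gm, wm_mask = wm, subjects = subjects,
       behavior = study$behavior,
       truth = c(study$truth, list(runs = truth_runs)))
}
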