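#' Canonical double-gamma haemodynamic response function
#'
#' Standard two-gamma HRF (response peak 6 s, undershoot peak 16 s,
#' undershoot ratio 1/6), normalized to unit integral.
#'
#' @param t time in seconds (vector).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

#' HRF-convolved boxcar regressor
#'
#' Builds the convolution of one or more boxcars with the canonical HRF at a
#' microtime resolution of 16 bins per TR, then samples it at volume
#' acquisition times `(0, TR, 2 TR, ...)`.
#'
#' @param onsets event onsets, s.
#' @param durations event durations, s (recycled).
#' @param n_volumes number of volumes in the run.
#' @param tr repetition time, s.
#' @param oversample microtime bins per TR.
#' @return Numeric vector of length `n_volumes`.
#' @export
hrf_regressor <- function(onsets, durations, n_volumes, tr,
                          oversample = 16L) {
  durations <- rep_len(durations, length(onsets))
  dt <- tr / oversample
  n_fine <- n_volumes * oversample
  tf <- (seq_len(n_fine) - 1) * dt
  box <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    on <- onsets[i]; off <- onsets[i] + durations[i]
    box[tf >= on & tf < off] <- box[tf >= on & tf < off] + 1
  }
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_fine)] * dt
  conv[1L + (seq_len(n_volumes) - 1L) * oversample]
}

#' Global white-matter drift regressor
#'
#' Z-scores every white-matter voxel's time course (mean 0, SD 1 over time)
#' and returns the per-volume mean over those voxels. Voxels with zero
#' temporal variance are excluded with a warning.
#'
#' @param series volumes-by-voxels matrix over the full grid, or a 4D array.
#' @param wm_mask a [brain_mask()] selecting white-matter voxels.
#' @return Numeric vector, one value per volume, mean approximately 0.
#' @export
wm_drift_regressor <- function(series, wm_mask) {
  if (is.array(series) && length(dim(series)) == 4L) {
    d <- dim(series)
    series <- t(matrix(series, prod(d[1:3]), d[4]))
  }
  idx <- mask_indices(wm_mask)
  if (length(idx) == 0L) stop("empty white-matter mask")
  wm <- series[, idx, drop = FALSE]
  sds <- apply(wm, 2, stats::sd)
  bad <- sds < .Machine$double.eps^0.5
  if (all(bad)) stop("all white-matter voxels have zero temporal variance")
  if (any(bad))
    warning(sum(bad), " zero-variance white-matter voxel(s) excluded")
  wm <- wm[, !bad, drop = FALSE]
  z <- scale(wm)
  rowMeans(z)
}

#' Retrieval model variant
#'
#' `full_trial` models each retrieval trial over its whole duration;
#' `exclude_first_12s` moves the first 12 s of every retrieval trial into a
#' separate no-interest column, so the trial-of-interest regressor spans
#' `[onset + 12, offset]` — the cue-control analysis.
#' @param mode `"full_trial"` or `"exclude_first_12s"`.
#' @return The validated mode string.
#' @export
retrieval_variant <- function(mode = c("full_trial", "exclude_first_12s")) {
  match.arg(mode)
}

#' Build a first-level design matrix for one run
#'
#' One HRF-convolved column per trial of interest (encoding and retrieval
#' trials, durations as given), one 2 s cue column per retrieval trial,
#' no-interest columns for the vividness rating events, six motion series,
#' the global white-matter drift series, and an intercept. Rows correspond
#' to the volumes retained after discarding the initial ones.
#'
#' @param trials trial rows for the run.
#' @param n_volumes total volumes acquired in the run (before discarding).
#' @param tr repetition time, s.
#' @param motion volumes-by-6 motion parameter matrix (full run), or `NULL`.
#' @param wm_drift white-matter drift series (full run), or `NULL`.
#' @param variant see [retrieval_variant()].
#' @param drop_initial initial volumes discarded for T1 equilibrium.
#' @param rating_duration modelled duration of the rating event, s.
#' @return A list with the design matrix `X` (retained volumes x columns),
#'   `labels`, `interest` (logical: trial-of-interest columns), `trials`
#'   (rows matching the interest columns in order) and `drop_initial`.
#' @export
build_design_matrix <- function(trials, n_volumes, tr, motion = NULL,
                                wm_drift = NULL,
                                variant = "full_trial",
                                drop_initial = 5L, rating_duration = 4) {
  variant <- retrieval_variant(variant)
  run_dur <- n_volumes * tr
  if (any(trials$onset + trials$duration > run_dur))
    stop("timing error: trial extends past the end of the run")
  cols <- list(); labels <- character(); interest <- logical()
  is_ret <- trials$phase != "Enc"
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset[i]; du <- trials$duration[i]
    if (is_ret[i] && variant == "exclude_first_12s") {
      if (du <= 12)
        stop("retrieval trial shorter than the 12 s exclusion window")
      cols[[length(cols) + 1L]] <- hrf_regressor(on + 12, du - 12,
                                                 n_volumes, tr)
      labels <- c(labels, sprintf("trial_%s_v%02d",
                                  as.character(trials$phase[i]),
                                  trials$video_id[i]))
      interest <- c(interest, TRUE)
      cols[[length(cols) + 1L]] <- hrf_regressor(on, 12, n_volumes, tr)
      labels <- c(labels, sprintf("excl12_%s_v%02d",
                                  as.character(trials$phase[i]),
                                  trials$video_id[i]))
      interest <- c(interest, FALSE)
    } else {
      cols[[length(cols) + 1L]] <- hrf_regressor(on, du, n_volumes, tr)
      labels <- c(labels, sprintf("trial_%s_v%02d",
                                  as.character(trials$phase[i]),
                                  trials$video_id[i]))
      interest <- c(interest, TRUE)
    }
  }
  # cue columns (2 s events), regressors of interest in the run count but
  # never entered into RSAs
  cue_rows <- which(!is.na(trials$cue_onset))
  for (i in cue_rows) {
    cols[[length(cols) + 1L]] <- hrf_regressor(trials$cue_onset[i], 2,
                                               n_volumes, tr)
    labels <- c(labels, sprintf("cue_%s_v%02d",
                                as.character(trials$phase[i]),
                                trials$video_id[i]))
    interest <- c(interest, TRUE)
  }
  # vividness rating events, one no-interest column for all of them
  if (length(cue_rows)) {
    ro <- trials$onset[cue_rows] + trials$duration[cue_rows]
    cols[[length(cols) + 1L]] <- hrf_regressor(ro,
                                               rep(rating_duration,
                                                   length(ro)),
                                               n_volumes, tr)
    labels <- c(labels, "rating"); interest <- c(interest, FALSE)
  }
  X <- do.call(cbind, cols)
  keep <- seq.int(drop_initial + 1L, n_volumes)
  X <- X[keep, , drop = FALSE]
  if (!is.null(motion)) {
    m <- as.matrix(motion)
    if (nrow(m) == n_volumes) m <- m[keep, , drop = FALSE]
    X <- cbind(X, m)
    labels <- c(labels, paste0("motion", seq_len(ncol(m))))
    interest <- c(interest, rep(FALSE, ncol(m)))
  }
  if (!is.null(wm_drift)) {
    w <- as.numeric(wm_drift)
    if (length(w) == n_volumes) w <- w[keep]
    X <- cbind(X, w)
    labels <- c(labels, "wm_drift"); interest <- c(interest, FALSE)
  }
  X <- cbind(X, 1)
  labels <- c(labels, "intercept"); interest <- c(interest, FALSE)
  colnames(X) <- labels
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- labels[qr_X$pivot[seq.int(qr_X$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  kappa_x <- kappa(X, exact = FALSE)
  if (kappa_x > 1e8)
    warning("design matrix poorly conditioned (kappa = ",
            format(kappa_x, digits = 3), ")")
  trial_idx <- grep("^trial_", labels)
  list(X = X, labels = labels, interest = interest,
       trials = trials, trial_columns = trial_idx,
       drop_initial = drop_initial)
}

#' Per-trial t-statistic pattern maps from one run
#'
#' Ordinary least squares per voxel; for each trial-of-interest column,
#' `t = beta / SE(beta)` with residual degrees of freedom
#' `rows - columns`. Cue columns are estimated but not returned. Residual
#' variance is floored at a tiny constant so that noise-free simulations
#' yield well-defined (beta-proportional) maps instead of 0/0.
#'
#' @param series volumes-by-voxels matrix over the full grid (all volumes
#'   acquired; the initial ones are discarded here), or a 4D array.
#' @param design output of [build_design_matrix()].
#' @param mask analysis [brain_mask()].
#' @return A [pattern_set()] with one t-map row per trial of interest.
#' @export
fit_trial_tmaps <- function(series, design, mask) {
  if (is.array(series) && length(dim(series)) == 4L) {
    d <- dim(series)
    series <- t(matrix(series, prod(d[1:3]), d[4]))
  }
  X <- design$X
  keep <- seq.int(design$drop_initial + 1L, nrow(series))
  Y <- series[keep, mask_indices(mask), drop = FALSE]
  if (nrow(Y) != nrow(X))
    stop("volume count after discarding initial volumes (", nrow(Y),
         ") does not match design rows (", nrow(X), ")")
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) stop("rank-deficient design")
  beta <- qr.coef(qr_X, Y)
  resid <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- pmax(colSums(resid^2) / df, 1e-12)
  XtX_inv <- solve(crossprod(X))
  tcols <- design$trial_columns
  tmaps <- matrix(NA_real_, length(tcols), ncol(Y))
  for (k in seq_along(tcols)) {
    j <- tcols[k]
    se <- sqrt(sigma2 * XtX_inv[j, j])
    tmaps[k, ] <- beta[j, ] / se
  }
  trials <- design$trials
  # order of trial columns follows trial rows (retrieval split keeps order)
  pattern_set(mask$grid, mask, trials, tmaps)
}
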