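stack_subject_maps <- function(maps) {
  if (inherits(maps, "stat_map")) maps <- list(maps)
  grid <- maps[[1]]$grid
  X <- t(vapply(maps, function(m) {
    if (!grids_equal(m$grid, grid)) stop("subject maps on different grids")
    as.numeric(m$values)
  }, numeric(prod(grid$shape))))
  list(X = X, grid = grid)
}

#' One-sample t map across subjects
#'
#' Voxelwise `t = mean / (SD / sqrt(n))` with `df = n - 1` against a null
#' of zero. Voxels where any subject is `NaN` are `NaN`; zero-variance
#' voxels yield signed infinity and are counted in the `flagged_infinite`
#' attribute.
#'
#' @param maps list of per-subject [stat_map()] objects on one grid.
#' @return A [stat_map()] of kind `t`.
#' @export
one_sample_t_map <- function(maps) {
  st <- stack_subject_maps(maps)
  n <- nrow(st$X)
  if (n < 3L) stop("need at least 3 subjects")
  m <- colMeans(st$X)
  s <- apply(st$X, 2, stats::sd)
  t_val <- m / (s / sqrt(n))
  zero_sd <- is.finite(m) & s == 0
  t_val[zero_sd] <- sign(m[zero_sd]) * Inf
  out <- stat_map(st$grid, t_val, "t", df = n - 1L)
  attr(out, "flagged_infinite") <- sum(zero_sd & m != 0)
  out
}

#' Paired t map across subjects
#'
#' One-sample t map of the per-subject difference maps (`a - b`).
#' @param maps_a,maps_b lists of per-subject [stat_map()] objects, same
#'   subjects in the same order.
#' @return A [stat_map()] of kind `t`.
#' @export
paired_t_map <- function(maps_a, maps_b) {
  if (length(maps_a) != length(maps_b))
    stop("subject mismatch between the two conditions")
  diffs <- mapply(function(a, b) {
    if (!grids_equal(a$grid, b$grid)) stop("grids differ between conditions")
    stat_map(a$grid, a$values - b$values, "z")
  }, maps_a, maps_b, SIMPLIFY = FALSE)
  one_sample_t_map(diffs)
}

#' Cluster-extent FWE correction by sign-flip permutation
#'
#' Forms clusters of supra-threshold voxels of the group t map at the
#' cluster-defining threshold (`p < cdt_p`, one-tailed positive by default;
#' two-tailed uses `|t|`), then derives the null distribution of the
#' maximum cluster size by randomly sign-flipping whole subject maps
#' (exact enumeration when `2^n <= n_permutations`, otherwise seeded random
#' draws including the identity flip). The corrected p of a cluster is the
#' proportion of permutation maxima at least as large
#' (`(1 + count) / (n_permutations + 1)` with the identity included).
#' Supplying an ROI restricts thresholding and the permutation maxima to
#' the ROI (small-volume correction).
#'
#' @param maps list of per-subject [stat_map()] objects.
#' @param cdt_p cluster-defining voxelwise p threshold.
#' @param fwe_p family-wise alpha for reporting significance.
#' @param connectivity 6, 18 or 26 neighbour connectivity.
#' @param n_permutations number of sign-flip permutations.
#' @param seed integer seed for the permutation draws.
#' @param roi optional [brain_mask()] for small-volume correction.
#' @param tail `"one"` (positive) or `"two"`.
#' @return An object of class `cluster_result`: a data frame `clusters`
#'   (peak voxel xyz 0-based, peak world coordinates, peak t, size,
#'   corrected p, significance), a `cluster_map` volume labelling each
#'   cluster by its row number, the group `t_map`, and the call
#'   parameters.
#' @export
cluster_fwe <- function(maps, cdt_p = 0.001, fwe_p = 0.05,
                        connectivity = 18L, n_permutations = 5000L,
                        seed = 1L, roi = NULL,
                        tail = c("one", "two")) {
  tail <- match.arg(tail)
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  st <- stack_subject_maps(maps)
  n <- nrow(st$X)
  if (n < 6L) warning("fewer than 6 subjects: permutation null is coarse")
  grid <- st$grid
  shape <- grid$shape
  analysis <- colSums(is.finite(st$X)) == n
  if (!is.null(roi)) {
    if (!grids_equal(roi$grid, grid)) stop("ROI grid mismatch")
    analysis <- analysis & as.logical(roi$voxels)
  }
  X <- st$X[, analysis, drop = FALSE]
  vox_lin <- which(analysis)          # 1-based linear indices
  df <- n - 1L
  t_crit <- if (tail == "one") stats::qt(1 - cdt_p, df) else
    stats::qt(1 - cdt_p / 2, df)

  t_from_signs <- function(signs) {    # signs: vector of +-1 per subject
    xs <- signs %*% X                  # 1 x V sums
    m <- xs / n
    v <- (ss2 - n * m^2) / (n - 1)
    as.numeric(m / sqrt(v / n))
  }
  ss2 <- colSums(X^2)

  t_obs <- t_from_signs(rep(1, n))
  supra_of <- function(tv) {
    if (tail == "one") which(tv > t_crit) else which(abs(tv) > t_crit)
  }
  # observed clusters (for two-tailed, positive and negative separately)
  observed_components <- function(tv) {
    if (tail == "one") {
      s <- which(tv > t_crit)
      list(list(idx = s, lab = cpp_label_clusters(vox_lin[s] - 1L, shape,
                                                  connectivity)))
    } else {
      sp <- which(tv > t_crit); sn <- which(tv < -t_crit)
      list(list(idx = sp, lab = cpp_label_clusters(vox_lin[sp] - 1L, shape,
                                                   connectivity)),
           list(idx = sn, lab = cpp_label_clusters(vox_lin[sn] - 1L, shape,
                                                   connectivity)))
    }
  }

  # permutation null of the max cluster size
  set.seed(seed)
  if (2^n <= n_permutations) {
    signs_mat <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    n_perm <- nrow(signs_mat)
  } else {
    n_perm <- n_permutations
    signs_mat <- matrix(sample(c(1, -1), (n_perm - 1L) * n, replace = TRUE),
                        n_perm - 1L, n)
    signs_mat <- rbind(rep(1, n), signs_mat)   # identity always included
  }
  max_sizes <- numeric(n_perm)
  block <- 500L
  for (b in seq(1L, n_perm, by = block)) {
    rows <- b:min(b + block - 1L, n_perm)
    S <- signs_mat[rows, , drop = FALSE] %*% X
    M <- S / n
    Vv <- sweep(-n * M^2, 2, ss2, "+") / (n - 1)
    Tm <- M / sqrt(Vv / n)
    for (k in seq_along(rows)) {
      tv <- Tm[k, ]
      s <- supra_of(tv)
      max_sizes[rows[k]] <- if (length(s))
        cpp_max_cluster(vox_lin[s] - 1L, shape, connectivity) else 0L
    }
  }

  comps <- observed_components(t_obs)
  rows <- list()
  cluster_map <- array(0L, shape)
  for (side in comps) {
    if (!length(side$idx)) next
    for (lab in seq_len(max(side$lab))) {
      members <- side$idx[side$lab == lab]
      cluster_map[vox_lin[members]] <- length(rows) + 1L
      size <- length(members)
      pk <- members[which.max(abs(t_obs[members]))]
      co <- voxel_coords(vox_lin[pk], shape)
      world <- grid$affine %*% c(as.numeric(co), 1)
      p_fwe <- (1 + sum(max_sizes >= size)) / (n_perm + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        peak_x = co[1], peak_y = co[2], peak_z = co[3],
        peak_mm_x = world[1], peak_mm_y = world[2], peak_mm_z = world[3],
        peak_t = t_obs[pk], size = size, p_fwe = p_fwe,
        significant = p_fwe < fwe_p)
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak_x = integer(), peak_y = integer(), peak_z = integer(),
               peak_mm_x = numeric(), peak_mm_y = numeric(),
               peak_mm_z = numeric(), peak_t = numeric(),
               size = integer(), p_fwe = numeric(),
               significant = logical())
  ord <- order(-clusters$size)
  clusters <- clusters[ord, , drop = FALSE]
  relabel <- integer(length(ord)); relabel[ord] <- seq_along(ord)
  cluster_map[cluster_map > 0] <- relabel[cluster_map[cluster_map > 0]]
  rownames(clusters) <- NULL
  tvol <- array(NaN, shape)
  tvol[vox_lin] <- t_obs
  structure(list(clusters = clusters,
                 cluster_map = cluster_map,
                 t_map = stat_map(grid, tvol, "t", df = df),
                 cdt_p = cdt_p, fwe_p = fwe_p,
                 connectivity = connectivity, n_permutations = n_perm,
                 seed = seed, tail = tail,
                 max_cluster_null = max_sizes),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d cluster(s), %d significant at FWE p<%g>\n",
              nrow(x$clusters), sum(x$clusters$significant), x$fwe_p))
  if (nrow(x$clusters)) print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Repeated-measures interaction for correlation type by phase pair
#'
#' Two-way fully within-subject ANOVA on ROI Fisher-z averages with factors
#' correlation type (same-video, different-video) and phase pair
#' (Enc/ImRet, Enc/DelRet, ImRet/DelRet); returns the type-by-phase
#' interaction F with its exact degrees of freedom
#' `(df1, df2) = ((a-1)(b-1), (a-1)(b-1)(n-1))` computed from the data.
#'
#' @param roi_values data frame with columns `subject`, `corr_type`
#'   (2 levels), `phase_pair` (3 levels) and `value`; one complete cell per
#'   subject x type x phase.
#' @return A list with `F`, `df1`, `df2` and `p`.
#' @export
interaction_anova_2x3 <- function(roi_values) {
  req <- c("subject", "corr_type", "phase_pair", "value")
  if (!all(req %in% names(roi_values)))
    stop("roi_values must have columns subject, corr_type, phase_pair, value")
  d <- roi_values
  d$subject <- factor(d$subject)
  d$corr_type <- factor(d$corr_type)
  d$phase_pair <- factor(d$phase_pair)
  tab <- table(d$subject, d$corr_type, d$phase_pair)
  if (any(tab != 1L)) stop("missing or duplicated cells in the 2x3 table")
  fit <- stats::aov(value ~ corr_type * phase_pair +
                      Error(subject / (corr_type * phase_pair)), data = d)
  strat <- summary(fit)[["Error: subject:corr_type:phase_pair"]][[1]]
  row <- grep("corr_type:phase_pair", rownames(strat))
  F_val <- strat[row, "F value"]
  df1 <- strat[row, "Df"]
  df2 <- strat[nrow(strat), "Df"]
  list(F = unname(F_val), df1 = unname(df1), df2 = unname(df2),
       p = unname(stats::pf(F_val, df1, df2, lower.tail = FALSE)))
}
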