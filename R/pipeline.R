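config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

phase_pair_label <- function(pp) paste(pp[1], pp[2], sep = "_")

write_cluster_table <- function(res, path) {
  utils::write.table(res$clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic study analysis end to end
#'
#' Simulates a study, optionally runs the per-trial GLM on simulated time
#' series, computes within-subject searchlight RSAs (same-versus-different
#' and memory-weighted) for every phase pair, group cluster statistics with
#' sign-flip FWE correction, ROI statistics with the type-by-phase
#' interaction test, pairwise comparisons between phase-pair maps,
#' inter-subject RSAs, and behavioural statistics. All outputs are written
#' under `out_dir` together with a manifest recording parameters, seeds and
#' content hashes. A re-run with an unchanged configuration hash reuses the
#' existing outputs.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory.
#' @param spec a [searchlight_spec()].
#' @param smoothing a [smoothing_spec()] for the inter-subject stage.
#' @param cdt_p,fwe_p,n_permutations,connectivity group-inference settings
#'   (see [cluster_fwe()]).
#' @param rois named list of [brain_mask()] ROIs; defaults to the first
#'   effect region (named `pmc`) when the config has effects, else a
#'   central sphere.
#' @param include_intersubject run the inter-subject stage.
#' @param use_timeseries simulate BOLD series and estimate patterns with
#'   the GLM instead of drawing pattern maps directly.
#' @param variant retrieval model variant for the GLM stage (see
#'   [retrieval_variant()]); with `use_timeseries`, `"both"` additionally
#'   produces the cue-control (first 12 s excluded) outputs.
#' @param force rerun all stages even if a matching manifest exists.
#' @return The manifest, invisibly.
#' @export
run_full_study <- function(config, out_dir,
                           spec = searchlight_spec(),
                           smoothing = smoothing_spec(6),
                           cdt_p = 0.001, fwe_p = 0.05,
                           n_permutations = 1000L, connectivity = 18L,
                           rois = NULL,
                           include_intersubject = TRUE,
                           use_timeseries = FALSE,
                           variant = "full_trial",
                           force = FALSE) {
  params <- list(cdt_p = cdt_p, fwe_p = fwe_p,
                 n_permutations = n_permutations,
                 connectivity = connectivity,
                 radius_voxels = spec$radius_voxels,
                 min_voxels = spec$min_voxels,
                 fwhm_mm = smoothing$fwhm_mm,
                 use_timeseries = use_timeseries, variant = variant,
                 include_intersubject = include_intersubject,
                 seed = config$seed)
  hash <- config_hash(list(config = config, params = params))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(old$config_hash, hash) &&
        all(file.exists(file.path(out_dir, unlist(lapply(old$files,
                                                         `[[`, "path"))))))
      return(invisible(old))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  add_file <- function(p) files <<- c(files, p)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%s] %s",
                                             format(Sys.time(), "%H:%M:%S"),
                                             sprintf(...)))

  # -- simulate -------------------------------------------------------------
  log_stage("simulate: %d subjects, %d videos, grid %s",
            config$n_subjects, config$n_videos,
            paste(config$shape, collapse = "x"))
  variants <- "full_trial"
  if (use_timeseries) {
    ts <- generate_timeseries_study(config)
    variants <- if (identical(variant, "both"))
      c("full_trial", "exclude_first_12s") else variant
    studies <- list()
    for (va in variants) {
      subs <- vector("list", config$n_subjects)
      for (s in seq_len(config$n_subjects)) {
        pats <- list()
        for (run in names(ts$subjects[[s]]$runs)) {
          r <- ts$subjects[[s]]$runs[[run]]
          wmreg <- wm_drift_regressor(r$data, ts$wm_mask)
          des <- build_design_matrix(r$trials, r$n_volumes, config$tr,
                                     motion = r$motion, wm_drift = wmreg,
                                     variant = va,
                                     drop_initial = r$drop_initial,
                                     rating_duration =
                                       config$rating_duration)
          pats[[run]] <- fit_trial_tmaps(r$data, des, ts$gm_mask)
        }
        by_phase <- list()
        for (ph in PHASES) {
          parts <- lapply(pats, function(p) {
            sel <- p$trials$phase == ph
            if (!any(sel)) return(NULL)
            list(trials = p$trials[sel, , drop = FALSE],
                 values = p$values[sel, , drop = FALSE])
          })
          parts <- Filter(Negate(is.null), parts)
          by_phase[[ph]] <- pattern_set(
            ts$grid, ts$gm_mask,
            do.call(rbind, lapply(parts, `[[`, "trials")),
            do.call(rbind, lapply(parts, `[[`, "values")))
        }
        subs[[s]] <- list(trials = ts$subjects[[s]]$trials,
                          patterns = by_phase)
      }
      studies[[va]] <- list(grid = ts$grid, mask = ts$gm_mask,
                            subjects = subs, behavior = ts$behavior,
                            truth = ts$truth)
    }
  } else {
    studies <- list(full_trial = generate_pattern_study(config))
  }
  study <- studies[[1]]
  ns <- config$n_subjects
  if (is.null(rois)) {
    rois <- if (length(config$effects))
      list(pmc = config$effects[[1]]$region)
    else list(pmc = region_sphere(study$mask,
                                  min(300L, sum(study$mask$voxels))))
  }

  # relative memory scores per subject (per-video across-subject centring)
  score_mat <- do.call(rbind, lapply(split(study$behavior,
                                           study$behavior$subject_id),
                                     function(d)
                                       d$detail_score[order(d$video_id)]))
  rel <- relative_performance(score_mat)

  phase_pairs <- list(c("Enc", "ImRet"), c("Enc", "DelRet"),
                      c("ImRet", "DelRet"))
  results <- list()

  for (va in names(studies)) {
    st <- studies[[va]]
    tag <- if (va == "full_trial") "" else "_excl12"
    # -- within-subject searchlights ---------------------------------------
    for (pp in phase_pairs) {
      ppl <- phase_pair_label(pp)
      for (kind in c("same_vs_different", "weighted_diagonal")) {
        log_stage("searchlight%s: %s %s", tag, ppl, kind)
        maps <- vector("list", ns)
        for (s in seq_len(ns)) {
          pa <- st$subjects[[s]]$patterns[[pp[1]]]
          pb <- st$subjects[[s]]$patterns[[pp[2]]]
          w <- if (kind == "same_vs_different")
            build_same_vs_different(pa$trials, pb$trials)
          else build_weighted_diagonal(pa$trials, pb$trials, rel[s, ])
          maps[[s]] <- searchlight_rsa(pa, pb, w, spec)
          p <- file.path(out_dir, sprintf("within%s_%s_%s_sub-%02d.nii",
                                          tag, ppl, kind, s))
          write_stat_map(maps[[s]], p); add_file(p)
        }
        res <- cluster_fwe(maps, cdt_p = cdt_p, fwe_p = fwe_p,
                           connectivity = connectivity,
                           n_permutations = n_permutations,
                           seed = config$seed)
        p <- file.path(out_dir, sprintf("clusters%s_%s_%s.tsv", tag, ppl,
                                        kind))
        write_cluster_table(res, p); add_file(p)
        p <- file.path(out_dir, sprintf("group_t%s_%s_%s.nii", tag, ppl,
                                        kind))
        write_stat_map(res$t_map, p); add_file(p)
        results[[paste0("within", tag)]][[ppl]][[kind]] <-
          list(maps = maps, clusters = res)
      }
    }
  }

  # -- pairwise comparisons of phase-pair maps (two-tailed) -----------------
  within <- results[["within"]]
  if (!is.null(within)) for (kind in c("same_vs_different",
                                       "weighted_diagonal")) {
    for (other in c("Enc_ImRet", "Enc_DelRet")) {
      res <- cluster_fwe_paired(within[["ImRet_DelRet"]][[kind]]$maps,
                                within[[other]][[kind]]$maps,
                                cdt_p = cdt_p, fwe_p = fwe_p,
                                connectivity = connectivity,
                                n_permutations = n_permutations,
                                seed = config$seed)
      p <- file.path(out_dir, sprintf("compare_ImRet_DelRet_vs_%s_%s.tsv",
                                      other, kind))
      write_cluster_table(res, p); add_file(p)
      results$comparisons[[paste0("ImRet_DelRet_vs_", other)]][[kind]] <-
        res
    }
  }

  # -- ROI statistics -------------------------------------------------------
  log_stage("ROI statistics (%s)", paste(names(rois), collapse = ", "))
  roi_stats <- list()
  for (rn in names(rois)) {
    roi <- rois[[rn]]
    per_pair <- list()
    for (pp in phase_pairs) {
      ppl <- phase_pair_label(pp)
      sv <- t(vapply(seq_len(ns), function(s) {
        pa <- study$subjects[[s]]$patterns[[pp[1]]]
        pb <- study$subjects[[s]]$patterns[[pp[2]]]
        w <- build_same_vs_different(pa$trials, pb$trials)
        unlist(roi_rsa(pa, pb, roi, w))
      }, numeric(2)))
      wt <- vapply(seq_len(ns), function(s) {
        pa <- study$subjects[[s]]$patterns[[pp[1]]]
        pb <- study$subjects[[s]]$patterns[[pp[2]]]
        w <- build_weighted_diagonal(pa$trials, pb$trials, rel[s, ])
        roi_rsa(pa, pb, roi, w)$value
      }, numeric(1))
      tt <- stats::t.test(sv[, "mean_same_z"], sv[, "mean_diff_z"],
                          paired = TRUE)
      wt_t <- stats::t.test(wt, mu = 0)
      per_pair[[ppl]] <- list(
        mean_same_z = mean(sv[, "mean_same_z"]),
        mean_diff_z = mean(sv[, "mean_diff_z"]),
        sem_same_z = stats::sd(sv[, "mean_same_z"]) / sqrt(ns),
        sem_diff_z = stats::sd(sv[, "mean_diff_z"]) / sqrt(ns),
        paired_t = unname(tt$statistic), paired_p = tt$p.value,
        weighted_mean = mean(wt), weighted_t = unname(wt_t$statistic),
        weighted_p = wt_t$p.value,
        same_z_by_subject = sv[, "mean_same_z"],
        diff_z_by_subject = sv[, "mean_diff_z"])
    }
    # 2 (type) x 3 (phase pair) repeated-measures interaction
    long <- do.call(rbind, lapply(names(per_pair), function(ppl) {
      pr <- per_pair[[ppl]]
      rbind(data.frame(subject = seq_len(ns), corr_type = "same",
                       phase_pair = ppl, value = pr$same_z_by_subject),
            data.frame(subject = seq_len(ns), corr_type = "different",
                       phase_pair = ppl, value = pr$diff_z_by_subject))
    }))
    per_pair$interaction <- interaction_anova_2x3(long)
    roi_stats[[rn]] <- per_pair
  }
  p <- file.path(out_dir, "roi_stats.json")
  jsonlite::write_json(
    lapply(roi_stats, function(rr) lapply(rr, function(x)
      x[setdiff(names(x), c("same_z_by_subject", "diff_z_by_subject"))])),
    p, auto_unbox = TRUE, digits = NA)
  add_file(p)
  results$roi <- roi_stats

  # -- inter-subject RSAs ---------------------------------------------------
  if (include_intersubject) {
    for (pp in phase_pairs) {
      ppl <- phase_pair_label(pp)
      log_stage("inter-subject searchlight: %s", ppl)
      pa_list <- lapply(study$subjects, function(su)
        su$patterns[[pp[1]]])
      pb_list <- lapply(study$subjects, function(su)
        su$patterns[[pp[2]]])
      w <- build_same_vs_different(pa_list[[1]]$trials,
                                   pb_list[[1]]$trials)
      maps <- intersubject_searchlight(pa_list, pb_list, w, spec,
                                       smoothing)
      for (s in seq_len(ns)) {
        p <- file.path(out_dir, sprintf("intersubject_%s_sub-%02d.nii",
                                        ppl, s))
        write_stat_map(maps[[s]], p); add_file(p)
      }
      res <- cluster_fwe(maps, cdt_p = cdt_p, fwe_p = fwe_p,
                         connectivity = connectivity,
                         n_permutations = n_permutations,
                         seed = config$seed)
      p <- file.path(out_dir, sprintf("clusters_intersubject_%s.tsv", ppl))
      write_cluster_table(res, p); add_file(p)
      results$intersubject[[ppl]] <- list(maps = maps, clusters = res)
    }
  }

  # -- behavior -------------------------------------------------------------
  log_stage("behavioral statistics")
  beh <- list(
    mean_detail_score = mean(study$behavior$detail_score),
    sd_detail_score_by_video =
      mean(apply(score_mat, 2, stats::sd)),
    paired = paired_comparisons(study$behavior),
    vividness_assoc_imret =
      vividness_performance_association(study$behavior, "ImRet"),
    vividness_assoc_delret =
      vividness_performance_association(study$behavior, "DelRet"))
  p <- file.path(out_dir, "behavior_stats.json")
  jsonlite::write_json(
    list(mean_detail_score = beh$mean_detail_score,
         paired = beh$paired,
         vividness_assoc_imret =
           beh$vividness_assoc_imret[c("t", "df", "p",
                                       "n_individually_significant")],
         vividness_assoc_delret =
           beh$vividness_assoc_delret[c("t", "df", "p",
                                        "n_individually_significant")]),
    p, auto_unbox = TRUE, digits = NA)
  add_file(p)
  results$behavior <- beh
  p <- file.path(out_dir, "behavior.tsv")
  utils::write.table(study$behavior, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_file(p)

  # -- manifest -------------------------------------------------------------
  rel_paths <- sub(paste0("^", out_dir, "/?"), "", files)
  manifest <- list(
    package = "reinstatr",
    version = as.character(utils::packageVersion("reinstatr")),
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    seed = config$seed, config_hash = hash, parameters = params,
    files = lapply(seq_along(files), function(i)
      list(path = rel_paths[i], md5 = unname(tools::md5sum(files[i])))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Paired cluster-extent comparison of two map sets
#'
#' Runs [cluster_fwe()] on the per-subject difference maps (`a - b`),
#' two-tailed by default since either direction is of interest.
#' @param maps_a,maps_b lists of per-subject [stat_map()] objects.
#' @param ... passed to [cluster_fwe()].
#' @param tail passed to [cluster_fwe()].
#' @return A `cluster_result`.
#' @export
cluster_fwe_paired <- function(maps_a, maps_b, ..., tail = "two") {
  if (length(maps_a) != length(maps_b)) stop("subject mismatch")
  diffs <- mapply(function(a, b) stat_map(a$grid, a$values - b$values,
                                          "z"),
                  maps_a, maps_b, SIMPLIFY = FALSE)
  cluster_fwe(diffs, ..., tail = tail)
}
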