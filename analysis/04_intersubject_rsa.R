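#!/usr/bin/env Rscript
# Inter-subject RSAs: each subject's smoothed per-video patterns correlated
# with the leave-one-out average of all other subjects, per phase pair,
# with the same searchlight and contrast machinery as the within-subject
# analysis. Requires results/simulated/study.rds.
# Writes per-subject maps and group cluster tables under
# results/intersubject/.

suppressPackageStartupMessages(library(reinstatr))
study <- readRDS("results/simulated/study.rds")
out <- "results/intersubject"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- searchlight_spec(3, 10)
sm <- smoothing_spec(6)
region <- study$truth$effects[[1]]$region

for (pp in list(c("Enc", "ImRet"), c("Enc", "DelRet"),
                c("ImRet", "DelRet"))) {
  ppl <- paste(pp, collapse = "_")
  pa <- lapply(study$subjects, function(su) su$patterns[[pp[1]]])
  pb <- lapply(study$subjects, function(su) su$patterns[[pp[2]]])
  w <- build_same_vs_different(pa[[1]]$trials, pb[[1]]$trials)
  maps <- intersubject_searchlight(pa, pb, w, spec, sm)
  for (s in seq_along(maps))
    write_stat_map(maps[[s]],
                   file.path(out, sprintf("%s_sub-%02d.nii.gz", ppl, s)))
  res <- cluster_fwe(maps, n_permutations = 1000, seed = 2019)
  write.table(res$clusters, file.path(out, sprintf("clusters_%s.tsv", ppl)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  in_region <- nrow(res$clusters) > 0 && any(res$clusters$significant &
    apply(res$clusters, 1, function(cl) {
      lin <- 1 + as.numeric(cl["peak_x"]) +
        dim(res$cluster_map)[1] * (as.numeric(cl["peak_y"]) +
                                     dim(res$cluster_map)[2] *
                                     as.numeric(cl["peak_z"]))
      region$voxels[lin]
    }))
  cat(sprintf("%s: %d cluster(s), %d significant at FWE p < 0.05%s.\n",
              ppl, nrow(res$clusters), sum(res$clusters$significant),
              if (in_region) " (peak inside the shared-effect region)"
              else ""))
}
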