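#!/usr/bin/env Rscript
# Group inference on the within-subject maps: one-sample cluster statistics
# per phase pair, pairwise comparisons between phase pairs (paired,
# two-tailed), small-volume correction inside the effect region, and the
# 2 (correlation type) x 3 (phase pair) repeated-measures interaction in
# the ROI. Requires results/simulated/study.rds and the maps written by
# 03_within_subject_rsa.R. Writes results/group/.

suppressPackageStartupMessages(library(reinstatr))
study <- readRDS("results/simulated/study.rds")
out <- "results/group"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
ns <- length(study$subjects)
region <- study$truth$effects[[1]]$region

read_maps <- function(ppl)
  lapply(seq_len(ns), function(s)
    read_stat_map(sprintf("results/within_subject/%s_same_sub-%02d.nii.gz",
                          ppl, s)))

pairs <- c("Enc_ImRet", "Enc_DelRet", "ImRet_DelRet")
maps <- lapply(pairs, read_maps)
names(maps) <- pairs

for (ppl in pairs) {
  res <- cluster_fwe(maps[[ppl]], n_permutations = 1000, seed = 2020)
  write.table(res$clusters, file.path(out, sprintf("clusters_%s.tsv", ppl)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  svc <- cluster_fwe(maps[[ppl]], n_permutations = 1000, seed = 2020,
                     roi = region)
  cat(sprintf("%s: %d significant cluster(s) whole-brain, %d with small-volume correction in the ROI.\n",
              ppl, sum(res$clusters$significant),
              sum(svc$clusters$significant)))
}

for (other in c("Enc_ImRet", "Enc_DelRet")) {
  cmp <- cluster_fwe_paired(maps$ImRet_DelRet, maps[[other]],
                            n_permutations = 1000, seed = 2021)
  write.table(cmp$clusters,
              file.path(out, sprintf("compare_ImRet_DelRet_vs_%s.tsv",
                                     other)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("ImRet_DelRet vs %s: %d significant difference cluster(s).\n",
              other, sum(cmp$clusters$significant)))
}

# ROI same/different z per phase pair -> interaction test
long <- do.call(rbind, lapply(pairs, function(ppl) {
  pp <- strsplit(ppl, "_")[[1]]
  do.call(rbind, lapply(seq_len(ns), function(s) {
    pa <- study$subjects[[s]]$patterns[[pp[1]]]
    pb <- study$subjects[[s]]$patterns[[pp[2]]]
    w <- build_same_vs_different(pa$trials, pb$trials)
    r <- roi_rsa(pa, pb, region, w)
    data.frame(subject = s, corr_type = c("same", "different"),
               phase_pair = ppl,
               value = c(r$mean_same_z, r$mean_diff_z))
  }))
}))
ia <- interaction_anova_2x3(long)
cat(sprintf("ROI type-by-phase interaction: F(%d, %d) = %.2f, p = %.2f.\n",
            ia$df1, ia$df2, ia$F, ia$p))
write.table(data.frame(F = ia$F, df1 = ia$df1, df2 = ia$df2, p = ia$p),
            file.path(out, "roi_interaction.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
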