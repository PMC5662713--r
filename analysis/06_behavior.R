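#!/usr/bin/env Rscript
# Behavioral statistics: free-recall detail scores, relative (per-video
# centred) memory performance, paired comparisons of retrieval duration and
# vividness across sessions, and the vividness-performance association.
# Requires results/simulated/behavior.tsv. Writes results/behavior/.

suppressPackageStartupMessages(library(reinstatr))
b <- read.delim("results/simulated/behavior.tsv")
out <- "results/behavior"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cat(sprintf("Detail scores: mean %.1f (SD %.1f) per video, %d subjects.\n",
            mean(b$detail_score), sd(b$detail_score),
            length(unique(b$subject_id))))

pc <- paired_comparisons(b)
cat(sprintf("Retrieval duration %.1f s vs %.1f s: t(%d) = %.2f, p = %.3f.\n",
            pc$duration$mean_imret, pc$duration$mean_delret,
            pc$duration$df, pc$duration$t, pc$duration$p))
cat(sprintf("Vividness %.2f vs %.2f: t(%d) = %.2f, p = %.2g.\n",
            pc$vividness$mean_imret, pc$vividness$mean_delret,
            pc$vividness$df, pc$vividness$t, pc$vividness$p))

res <- list()
for (ph in c("ImRet", "DelRet")) {
  va <- vividness_performance_association(b, ph)
  cat(sprintf("Vividness (%s) vs performance: mean r = %.2f, t(%d) = %.2f, p = %.2g; %d/%d subjects individually significant.\n",
              ph, mean(va$per_subject_r), va$df, va$t, va$p,
              va$n_individually_significant, length(va$per_subject_r)))
  res[[ph]] <- data.frame(phase = ph, mean_r = mean(va$per_subject_r),
                          t = va$t, df = va$df, p = va$p,
                          n_indiv_sig = va$n_individually_significant)
}
tab <- rbind(
  data.frame(phase = "duration", mean_r = NA, t = pc$duration$t,
             df = pc$duration$df, p = pc$duration$p, n_indiv_sig = NA),
  data.frame(phase = "vividness_drop", mean_r = NA, t = pc$vividness$t,
             df = pc$vividness$df, p = pc$vividness$p, n_indiv_sig = NA),
  do.call(rbind, res))
write.table(tab, file.path(out, "behavior_stats.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
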