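#' Aggregate free-recall detail marks into a video score
#'
#' Each recalled detail is marked 0 (absent), 0.5 (partially correct) or 1
#' (fully correct); the video's score is the sum, with no maximum.
#'
#' @param detail_marks numeric vector of marks from `{0, 0.5, 1}`.
#' @return The detail score (sum of marks).
#' @export
aggregate_details <- function(detail_marks) {
  if (length(detail_marks) == 0L) return(0)
  if (!all(detail_marks %in% c(0, 0.5, 1)))
    stop("detail marks must be 0, 0.5 or 1")
  sum(detail_marks)
}

#' Relative memory performance (per-video across-subject centring)
#'
#' Subtracts from each subject's score for a video the mean score of that
#' video across all subjects, indexing memory for a video relative to how
#' memorable the video is.
#'
#' @param scores subjects-by-videos numeric matrix, complete.
#' @return Matrix of the same shape with every column centred to mean 0.
#' @export
relative_performance <- function(scores) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("missing entries in the score matrix")
  sweep(scores, 2, colMeans(scores))
}

#' Paired comparisons of retrieval duration and vividness across sessions
#'
#' Two-tailed paired t tests on per-subject means, immediate versus delayed
#' retrieval. Zero-variance differences are flagged as infinite t.
#'
#' @param behavior behavioural table as produced by [generate_behavior()]
#'   (columns `subject_id`, `vividness_imret`, `vividness_delret`,
#'   `retrieval_duration_imret`, `retrieval_duration_delret`).
#' @return A list with elements `duration` and `vividness`, each a list
#'   `(t, df, p, mean_imret, mean_delret)`.
#' @export
paired_comparisons <- function(behavior) {
  subj <- split(behavior, behavior$subject_id)
  if (length(subj) < 3L) stop("need at least 3 subjects")
  one <- function(col_im, col_del) {
    a <- vapply(subj, function(d) mean(d[[col_im]]), numeric(1))
    b <- vapply(subj, function(d) mean(d[[col_del]]), numeric(1))
    dd <- a - b
    if (stats::sd(dd) == 0) {
      tval <- if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf
      p <- if (mean(dd) == 0) 1 else 0
      return(list(t = tval, df = length(dd) - 1L, p = p,
                  mean_imret = mean(a), mean_delret = mean(b),
                  degenerate = TRUE))
    }
    ht <- stats::t.test(a, b, paired = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_imret = mean(a), mean_delret = mean(b),
         degenerate = FALSE)
  }
  list(duration = one("retrieval_duration_imret",
                      "retrieval_duration_delret"),
       vividness = one("vividness_imret", "vividness_delret"))
}

#' Vividness-performance association across the group
#'
#' Per subject, the Pearson correlation between vividness ratings
#' (immediate or delayed retrieval) and detail scores over the videos;
#' correlations are Fisher-transformed and tested against 0 with a
#' one-sample t test across subjects. Also reports how many subjects are
#' individually significant at p < 0.05 (two-tailed).
#'
#' @param behavior behavioural table (see [paired_comparisons()]).
#' @param phase `"ImRet"` or `"DelRet"`: which vividness ratings to use.
#' @return A list with `per_subject_r`, `per_subject_z`, `t`, `df`, `p`
#'   and `n_individually_significant`.
#' @export
vividness_performance_association <- function(behavior,
                                              phase = c("ImRet",
                                                        "DelRet")) {
  phase <- match.arg(phase)
  col <- if (phase == "ImRet") "vividness_imret" else "vividness_delret"
  subj <- split(behavior, behavior$subject_id)
  rs <- ps <- numeric(0)
  excluded <- 0L
  for (d in subj) {
    if (nrow(d) < 3L || stats::sd(d[[col]]) == 0 ||
        stats::sd(d$detail_score) == 0) {
      warning("subject with zero variance excluded from the association")
      excluded <- excluded + 1L
      next
    }
    ct <- stats::cor.test(d[[col]], d$detail_score)
    rs <- c(rs, unname(ct$estimate))
    ps <- c(ps, ct$p.value)
  }
  if (length(rs) < 3L) stop("fewer than 3 subjects with usable variance")
  zs <- fisher_z(rs)
  if (stats::sd(zs) == 0) {
    tval <- if (mean(zs) == 0) 0 else sign(mean(zs)) * Inf
    ht <- list(statistic = tval, parameter = length(zs) - 1L,
               p.value = if (mean(zs) == 0) 1 else 0)
  } else ht <- stats::t.test(zs, mu = 0)
  list(per_subject_r = rs, per_subject_z = zs,
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       n_individually_significant = sum(ps < 0.05),
       n_excluded = excluded)
}
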