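#' Detect bidirectional (divergent) transcription candidates
#'
#' Pairs a minus-strand tag cluster with a plus-strand tag cluster lying
#' downstream of it (divergent orientation: the minus arm transcribes
#' leftward from the left side of the locus, the plus arm rightward from
#' the right side), with peak-to-peak separation at most `window` bases.
#' The candidate midpoint is the signal-weighted midpoint of the two arm
#' peaks.
#'
#' @param pooled pooled TPM data.frame ([pool_tpm()]).
#' @param window maximum peak-to-peak arm separation in bases (default 400).
#' @param slice_threshold,merge_dist clustering parameters used for the
#'   per-strand arms (see [slice_reduce_cluster()]).
#' @return data.frame of candidates: `enhancer_id`, `chrom`, `midpoint`,
#'   `start`, `end`, `minus_arm_tpm`, `plus_arm_tpm`, `balance`, plus arm
#'   cluster ids.
#' @export
detect_bidirectional_candidates <- function(pooled, window = 400,
                                            slice_threshold = 0.1,
                                            merge_dist = 20) {
  arms <- slice_reduce_cluster(pooled, slice_threshold, merge_dist)
  minus <- arms[arms$strand == "-", , drop = FALSE]
  plus <- arms[arms$strand == "+", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(minus))) {
    m <- minus[i, ]
    cand <- plus[plus$chrom == m$chrom & plus$peak > m$peak &
                   plus$peak - m$peak <= window, , drop = FALSE]
    if (!nrow(cand)) next
    p <- cand[which.min(cand$peak - m$peak), ]  # nearest divergent partner
    d <- m$pooled_tpm; u <- p$pooled_tpm
    mid <- as.integer(round((m$peak * d + p$peak * u) / (d + u)))
    out[[length(out) + 1L]] <- data.frame(
      chrom = m$chrom, midpoint = mid,
      start = m$start, end = p$end,
      minus_arm_tpm = d, plus_arm_tpm = u,
      minus_cluster = m$cluster_id, plus_cluster = p$cluster_id,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(enhancer_id = character(), chrom = character(),
                      midpoint = integer(), start = integer(), end = integer(),
                      minus_arm_tpm = numeric(), plus_arm_tpm = numeric(),
                      minus_cluster = character(), plus_cluster = character(),
                      balance = numeric()))
  res <- do.call(rbind, out)
  res$balance <- balance_score(res$minus_arm_tpm, res$plus_arm_tpm)
  res$enhancer_id <- sprintf("ENH_%s_%d", res$chrom, res$midpoint)
  res[, c("enhancer_id", "chrom", "midpoint", "start", "end",
          "minus_arm_tpm", "plus_arm_tpm", "minus_cluster", "plus_cluster",
          "balance")]
}

#' Bhattacharyya balance score of a divergent pair
#'
#' With arm fractions d = D/(D+U) and u = U/(D+U), the score is
#' sqrt(0.5 d) + sqrt(0.5 u): the Bhattacharyya coefficient between the
#' observed arm split and a perfectly balanced one. It equals 1 iff
#' d = u = 0.5 and falls to sqrt(0.5) when all signal is on one arm.
#'
#' @param D minus-arm (upstream) signal sum.
#' @param U plus-arm (downstream) signal sum.
#' @return numeric in `[sqrt(0.5), 1]`.
#' @export
balance_score <- function(D, U) {
  tot <- D + U
  if (any(tot <= 0)) stop("balance_score needs positive total arm signal")
  sqrt(0.5 * D / tot) + sqrt(0.5 * U / tot)
}

#' Call balanced enhancers from bidirectional candidates
#'
#' @param candidates data.frame from [detect_bidirectional_candidates()].
#' @param threshold minimum balance score (default 0.95).
#' @return The subset of candidates with `balance >= threshold`.
#' @export
call_enhancers <- function(candidates, threshold = 0.95) {
  candidates[candidates$balance >= threshold, , drop = FALSE]
}

#' Link enhancers to TSS clusters by distance and expression correlation
#'
#' A link is reported for every (enhancer, cluster) pair whose
#' midpoint-to-peak distance is at most `max_dist` and whose cross-sample
#' expression correlation (Pearson, on log2(TPM+1)) is positive with
#' two-sided p below `alpha`.
#'
#' @param enhancers called enhancer data.frame.
#' @param enh_expr enhancers x samples expression matrix (both arms summed).
#' @param clusters cluster data.frame.
#' @param cl_expr clusters x samples expression matrix.
#' @param max_dist maximum genomic distance in bases (default 50000).
#' @param alpha correlation significance cutoff (default 0.05).
#' @return data.frame: `enhancer_id`, `cluster_id`, `distance`, `pearson_r`,
#'   `p_value`.
#' @export
link_enhancers_to_tss <- function(enhancers, enh_expr, clusters, cl_expr,
                                  max_dist = 50000, alpha = 0.05) {
  if (ncol(enh_expr) < 3) stop("need >= 3 samples for correlation p-values")
  stopifnot(ncol(enh_expr) == ncol(cl_expr))
  le <- log2(enh_expr + 1); lc <- log2(cl_expr + 1)
  out <- list()
  for (i in seq_len(nrow(enhancers))) {
    e <- enhancers[i, ]
    near <- which(clusters$chrom == e$chrom &
                    abs(clusters$peak - e$midpoint) <= max_dist)
    for (j in near) {
      x <- le[i, ]; y <- lc[j, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- stats::cor.test(x, y)
      if (ct$estimate > 0 && ct$p.value < alpha)
        out[[length(out) + 1L]] <- data.frame(
          enhancer_id = e$enhancer_id, cluster_id = clusters$cluster_id[j],
          distance = abs(clusters$peak[j] - e$midpoint),
          pearson_r = unname(ct$estimate), p_value = ct$p.value,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(enhancer_id = character(), cluster_id = character(),
                      distance = integer(), pearson_r = numeric(),
                      p_value = numeric()))
  do.call(rbind, out)
}

#' Fraction of intronic and intergenic clusters explained by eRNAs
#'
#' For each of the `intron` and `intergenic` categories, the fraction of
#' clusters whose span overlaps a called enhancer locus.
#'
#' @param clusters cluster data.frame with a `category` column (see
#'   [assign_genomic_category()]).
#' @param enhancers called enhancer data.frame.
#' @return named numeric vector with entries `intron` and `intergenic`.
#' @export
classify_intergenic_intronic_ernas <- function(clusters, enhancers) {
  res <- c(intron = 0, intergenic = 0)
  for (cat in names(res)) {
    sub <- clusters[clusters$category == cat, , drop = FALSE]
    if (!nrow(sub)) next
    if (!nrow(enhancers)) { res[cat] <- 0; next }
    hit <- vapply(seq_len(nrow(sub)), function(i) {
      any(enhancers$chrom == sub$chrom[i] &
            enhancers$start < sub$end[i] & enhancers$end > sub$start[i])
    }, TRUE)
    res[cat] <- mean(hit)
  }
  res
}
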