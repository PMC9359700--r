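#' Pool TPM tracks into one strand-specific signal
#'
#' Sums per-base TPM values over a set of samples; the pooled signal is the
#' input to clustering.
#'
#' @param tpm_tracks list of `tpm_track`s.
#' @return data.frame with columns `chrom`, `pos`, `strand`, `tpm`.
#' @export
pool_tpm <- function(tpm_tracks) {
  all <- data.table::rbindlist(lapply(tpm_tracks, function(t)
    as.data.frame(t)[c("chrom", "pos", "strand", "tpm")]))
  pooled <- all[, list(tpm = sum(tpm)), by = c("chrom", "pos", "strand")]
  data.table::setorder(pooled, chrom, strand, pos)
  as.data.frame(pooled)
}

#' Slice-reduce tag clustering
#'
#' Builds unidirectional tag clusters from a pooled TPM signal: positions
#' with pooled TPM at or above `slice_threshold` are kept ("slice"), and
#' kept positions on the same chromosome and strand within `merge_dist`
#' bases of each other are merged into one cluster ("reduce"). Opposite
#' strands never merge. The cluster peak is the leftmost position of
#' maximal pooled signal.
#'
#' @param pooled data.frame from [pool_tpm()].
#' @param slice_threshold minimum pooled TPM for a position to seed or join
#'   a cluster (default 0.1).
#' @param merge_dist maximum gap in bases for two kept positions to share a
#'   cluster (default 20).
#' @return data.frame of clusters: `cluster_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open over kept positions), `peak`, `pooled_tpm`,
#'   `iqr_start`, `iqr_end`, `width_iqr`, `shape`.
#' @export
slice_reduce_cluster <- function(pooled, slice_threshold = 0.1, merge_dist = 20) {
  if (merge_dist < 0) stop("merge_dist must be non-negative")
  kept <- pooled[pooled$tpm >= slice_threshold, , drop = FALSE]
  if (!nrow(kept)) return(empty_cluster_df())
  kept <- kept[order(kept$chrom, kept$strand, kept$pos), , drop = FALSE]
  grp <- paste(kept$chrom, kept$strand)
  new_group <- c(TRUE, grp[-1] != grp[-nrow(kept)])
  gap <- c(Inf, diff(kept$pos))
  cl <- cumsum(new_group | gap > merge_dist)
  dt <- data.table::data.table(chrom = kept$chrom, strand = kept$strand,
                               pos = kept$pos, tpm = kept$tpm, cl = cl)
  res <- dt[, {
    pk <- pos[which.max(tpm)]  # leftmost max: which.max takes first
    iqr <- iqr_bounds(pos, tpm)
    list(chrom = chrom[1], strand = strand[1],
         start = min(pos), end = max(pos) + 1L, peak = pk,
         pooled_tpm = sum(tpm),
         iqr_start = iqr[1], iqr_end = iqr[2],
         width_iqr = iqr[2] - iqr[1] + 1L)
  }, by = "cl"]
  res$shape <- classify_shape(res$width_iqr)
  res$cluster_id <- sprintf("TC_%s_%s_%d", res$chrom,
                            ifelse(res$strand == "+", "p", "m"), res$start)
  as.data.frame(res[, c("cluster_id", "chrom", "strand", "start", "end",
                        "peak", "pooled_tpm", "iqr_start", "iqr_end",
                        "width_iqr", "shape")])
}

empty_cluster_df <- function() {
  data.frame(cluster_id = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), peak = integer(),
             pooled_tpm = numeric(), iqr_start = integer(), iqr_end = integer(),
             width_iqr = integer(), shape = character())
}

# Positions covering the central 10-90% of the cumulative pooled signal:
# the bound is the smallest position whose cumulative fraction reaches the
# quantile.
iqr_bounds <- function(pos, val, lower = 0.10, upper = 0.90) {
  o <- order(pos)
  pos <- pos[o]; val <- val[o]
  tot <- sum(val)
  if (tot <= 0) stop("zero-signal cluster has no IQR")
  cf <- cumsum(val) / tot
  c(pos[which(cf >= lower - 1e-12)[1]], pos[which(cf >= upper - 1e-12)[1]])
}

#' Interquartile width of a tag cluster
#'
#' Width of the positional span holding the central `lower`..`upper`
#' fraction (default 10-90%) of pooled signal, trimming tags that extend a
#' cluster without contributing expression.
#'
#' @param pos integer positions within one cluster.
#' @param val pooled signal at each position.
#' @param lower,upper cumulative-fraction bounds (defaults 0.10, 0.90).
#' @return list with `iqr_start`, `iqr_end` (positions) and `width` (bases,
#'   inclusive).
#' @export
compute_iqr_width <- function(pos, val, lower = 0.10, upper = 0.90) {
  b <- iqr_bounds(pos, val, lower, upper)
  list(iqr_start = b[1], iqr_end = b[2], width = b[2] - b[1] + 1L)
}

#' Sharp/broad/wide promoter shape from IQR width
#'
#' Sharp promoters have 10-90% widths of 1-10 bases, broad promoters
#' 11-100 bases; wider clusters are labelled `wide` and excluded from
#' shape-based analyses.
#'
#' @param width_iqr integer vector of IQR widths (bases).
#' @return character vector in `{"sharp","broad","wide"}`.
#' @export
classify_shape <- function(width_iqr) {
  stopifnot(all(width_iqr >= 1))
  ifelse(width_iqr <= 10, "sharp", ifelse(width_iqr <= 100, "broad", "wide"))
}

#' Aggregate per-sample counts and TPM over cluster spans
#'
#' @param clusters cluster data.frame from [slice_reduce_cluster()].
#' @param tracks list of `ctss_track`s (one per sample).
#' @return list with `counts` (clusters x samples integer matrix), `tpm`
#'   (same shape, per-sample cluster TPM = count * 1e6 / library size) and
#'   `lib_sizes`.
#' @export
cluster_sample_counts <- function(clusters, tracks) {
  sample_ids <- vapply(tracks, function(t) attr(t, "sample_id"), "")
  counts <- matrix(0, nrow(clusters), length(tracks),
                   dimnames = list(clusters$cluster_id, sample_ids))
  lib <- numeric(length(tracks)); names(lib) <- sample_ids
  for (j in seq_along(tracks)) {
    tr <- as.data.frame(tracks[[j]])
    lib[j] <- sum(tr$count)
    counts[, j] <- sum_in_spans(clusters, tr, tr$count)
  }
  tpm <- sweep(counts, 2, pmax(lib, 1), "/") * 1e6
  list(counts = counts, tpm = tpm, lib_sizes = lib)
}

# Sum a per-base value over each cluster's [start, end) span, matching
# chromosome and strand.
sum_in_spans <- function(clusters, track_df, value) {
  out <- numeric(nrow(clusters))
  cl_gr <- GenomicRanges::GRanges(clusters$chrom,
                                  IRanges::IRanges(clusters$start + 1L, clusters$end),
                                  strand = clusters$strand)
  tr_gr <- GenomicRanges::GRanges(track_df$chrom,
                                  IRanges::IRanges(track_df$pos + 1L, width = 1L),
                                  strand = track_df$strand)
  hits <- GenomicRanges::findOverlaps(tr_gr, cl_gr)
  if (length(hits)) {
    sums <- tapply(value[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits), sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out
}

#' Low-expression cluster filter
#'
#' A cluster is retained iff there is at least one condition in which all
#' replicates reach `min_tpm` — this keeps condition-specific promoters
#' while removing clusters never reproducibly expressed.
#'
#' @param tpm clusters x samples TPM matrix.
#' @param condition character vector, one entry per column of `tpm`.
#' @param min_tpm threshold in TPM (default 1).
#' @return logical vector: keep each cluster?
#' @export
filter_low_expression <- function(tpm, condition, min_tpm = 1) {
  stopifnot(length(condition) == ncol(tpm))
  keep <- rep(FALSE, nrow(tpm))
  for (cond in unique(condition)) {
    sub <- tpm[, condition == cond, drop = FALSE]
    keep <- keep | apply(sub >= min_tpm, 1, all)
  }
  keep
}
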