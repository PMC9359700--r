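#' CTSS count tracks
#'
#' A `ctss_track` is the basic data unit of the package: strand-specific,
#' per-base counts of capped 5' ends (CAGE tags) for one sample. It is a
#' `data.frame` with columns `chrom`, `pos` (0-based), `strand` (`"+"`/`"-"`)
#' and `count`, carrying the sample metadata (`sample_id`, `condition`,
#' `replicate`, `fraction`) as attributes. For a minus-strand CTSS, `pos` is
#' the 5'-most transcribed base of the transcript, i.e. the highest genomic
#' coordinate of its first base.
#'
#' @param df data.frame with columns `chrom`, `pos`, `strand`, `count`.
#' @param sample_id character scalar identifying the sample.
#' @param condition one of `"WT"`, `"TCL1"`.
#' @param replicate integer replicate index.
#' @param fraction one of `"Total"`, `"Free"`, `"Light"`, `"Heavy"`,
#'   `"Polysomes"`.
#' @return An object of class `ctss_track`.
#' @export
ctss_track <- function(df, sample_id, condition, replicate, fraction) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "pos", "strand", "count")
  if (!all(need %in% names(df)))
    stop("ctss_track needs columns: ", paste(need, collapse = ", "))
  condition <- match.arg(condition, c("WT", "TCL1"))
  fraction <- match.arg(fraction, c("Total", "Free", "Light", "Heavy", "Polysomes"))
  if (any(df$count < 0)) stop("CTSS counts must be non-negative")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            sample_id = sample_id, condition = condition,
            replicate = as.integer(replicate), fraction = fraction,
            class = c("ctss_track", "data.frame"))
}

#' @export
print.ctss_track <- function(x, ...) {
  cat(sprintf("ctss_track '%s' [%s, rep %d, %s]: %d CTSSs, %s tags\n",
              attr(x, "sample_id"), attr(x, "condition"),
              attr(x, "replicate"), attr(x, "fraction"),
              nrow(x), format(sum(x$count), big.mark = ",")))
  invisible(x)
}

track_meta <- function(track) {
  list(sample_id = attr(track, "sample_id"),
       condition = attr(track, "condition"),
       replicate = attr(track, "replicate"),
       fraction  = attr(track, "fraction"))
}

#' Read a CTSS track from a BED6 file
#'
#' The CTSS dialect is BED6 with exactly one record per base
#' (`end - start == 1`), the raw tag count in the score field, and strand
#' `+`/`-`. Multiple records at the same base are summed.
#'
#' @inheritParams ctss_track
#' @param path path to a BED6 file.
#' @return A `ctss_track`.
#' @export
read_ctss_bed <- function(path, sample_id, condition, replicate, fraction) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name", "score", "strand")[1:6],
                          colClasses = list(character = c(1, 4, 6)))
  if (ncol(dt) < 6) stop("not BED6: ", path)
  bad_strand <- which(!dt$strand %in% c("+", "-"))
  if (length(bad_strand))
    stop(sprintf("malformed strand at line %d of %s", bad_strand[1], path))
  bad_score <- which(dt$score < 0 | dt$score != floor(dt$score))
  if (length(bad_score))
    stop(sprintf("score must be a non-negative integer count: line %d of %s",
                 bad_score[1], path))
  bad_width <- which(dt$end - dt$start != 1L)
  if (length(bad_width))
    stop(sprintf("CTSS records must be single-base (end - start == 1): line %d of %s",
                 bad_width[1], path))
  agg <- dt[, list(count = sum(score)), by = c("chrom", "start", "strand")]
  ctss_track(data.frame(chrom = agg$chrom, pos = agg$start,
                        strand = agg$strand, count = agg$count),
             sample_id, condition, replicate, fraction)
}

#' Write a CTSS track as BED6
#'
#' @param track a `ctss_track`.
#' @param path output file.
#' @export
write_ctss_bed <- function(track, path) {
  df <- as.data.frame(track)
  out <- data.frame(df$chrom, df$pos, df$pos + 1L, ".", df$count, df$strand)
  write_atomic(path, function(tmp)
    utils::write.table(out, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE))
  invisible(path)
}

#' Tags-per-million normalization
#'
#' Scales per-base counts by the sample library size so values sum to 1e6.
#'
#' @param track a `ctss_track`.
#' @return A `tpm_track`: like the input with an additional `tpm` column.
#' @export
tpm_normalize <- function(track) {
  total <- sum(track$count)
  if (total <= 0) stop("cannot TPM-normalize an empty track")
  df <- as.data.frame(track)
  df$tpm <- df$count * 1e6 / total
  structure(df,
            sample_id = attr(track, "sample_id"),
            condition = attr(track, "condition"),
            replicate = attr(track, "replicate"),
            fraction  = attr(track, "fraction"),
            library_size = total,
            class = c("tpm_track", "data.frame"))
}

#' Merge Light and Heavy fractions into a Polysomes track
#'
#' The translated pool is represented by the position-wise sum of the Light
#' and Heavy fraction tracks of the same condition and replicate. The
#' Polysomes fraction is always derived, never read from disk.
#'
#' @param light,heavy `ctss_track`s with fractions `"Light"` and `"Heavy"`.
#' @return A `ctss_track` with fraction `"Polysomes"`.
#' @export
merge_fractions <- function(light, heavy) {
  ml <- track_meta(light); mh <- track_meta(heavy)
  if (!identical(ml$condition, mh$condition) ||
      !identical(ml$replicate, mh$replicate))
    stop("Light and Heavy tracks must share condition and replicate")
  if (!(ml$fraction %in% c("Light", "Heavy")) ||
      !(mh$fraction %in% c("Light", "Heavy")))
    stop("merge_fractions expects Light and Heavy fraction tracks")
  both <- rbind(as.data.frame(light)[c("chrom", "pos", "strand", "count")],
                as.data.frame(heavy)[c("chrom", "pos", "strand", "count")])
  dt <- data.table::as.data.table(both)
  agg <- dt[, list(count = sum(count)), by = c("chrom", "pos", "strand")]
  ctss_track(as.data.frame(agg),
             sample_id = paste0(ml$condition, "_Polysomes_r", ml$replicate),
             condition = ml$condition, replicate = ml$replicate,
             fraction = "Polysomes")
}

#' Pairwise Pearson correlation of samples over a shared cluster set
#'
#' @param expr numeric matrix, clusters x samples (e.g. cluster TPM).
#' @param log_transform apply `log2(x + 1)` first (default `TRUE`).
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   samples yield `NA` entries and a warning rather than a silent 0.
#' @export
replicate_correlation <- function(expr, log_transform = TRUE) {
  if (ncol(expr) < 2) stop("need at least 2 samples")
  if (log_transform) expr <- log2(expr + 1)
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance sample(s): ",
            paste(colnames(expr)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(stats::cor(expr))
  r[, sds == 0] <- NA_real_
  r[sds == 0, ] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  r
}

#' Read a sample sheet
#'
#' TSV with header columns `sample_id`, `condition`, `replicate`,
#' `fraction`, `path`. `(condition, replicate, fraction)` must be unique.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate", "fraction", "path")
  if (!all(need %in% names(ss)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  key <- paste(ss$condition, ss$replicate, ss$fraction)
  if (anyDuplicated(key))
    stop("duplicate (condition, replicate, fraction) in sample sheet")
  ss
}

# Atomic write: write to a temp file in the same directory, then rename, so
# interrupted runs never leave truncated tables.
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a data frame as TSV (atomically)
#'
#' @param df data.frame.
#' @param path output path.
#' @param header_comments optional character vector written as `#`-prefixed
#'   provenance lines before the header.
#' @export
write_tsv <- function(df, path, header_comments = NULL) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (length(header_comments))
      writeLines(paste0("# ", header_comments), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}
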