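#' Strand-aware cap-proximal k-mer of a CTSS
#'
#' The first `k` transcribed bases starting at the CTSS: on the plus
#' strand the genomic window `[pos, pos+k)`; on the minus strand the
#' reverse complement of `[pos-k+1, pos]`, since the transcript reads
#' leftward. Out-of-bounds positions or windows containing non-ACGT bases
#' return `NA` (callers log the skip count).
#'
#' @param genome named `DNAStringSet`.
#' @param chrom,pos,strand vectors describing the CTSSs (0-based `pos`).
#' @param k k-mer length.
#' @return character vector of k-mers (uppercase), `NA` where unavailable.
#' @export
extract_start_kmer <- function(genome, chrom, pos, strand, k = 3) {
  n <- length(pos)
  out <- rep(NA_character_, n)
  lens <- vapply(as.character(unique(chrom)), function(ch)
    length(genome[[ch]]), 0L)
  start0 <- ifelse(strand == "+", pos, pos - k + 1L)
  ok <- start0 >= 0 & (start0 + k) <= lens[as.character(chrom)]
  for (ch in unique(chrom[ok])) {
    i <- which(ok & chrom == ch)
    v <- Biostrings::Views(genome[[ch]],
                           start = start0[i] + 1L, width = k)
    s <- as.character(v)
    minus <- strand[i] == "-"
    if (any(minus))
      s[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s[minus])))
    s[grepl("[^ACGT]", s)] <- NA_character_
    out[i] <- s
  }
  out
}

#' Start-nucleotide (or k-mer) frequencies
#'
#' Share of each observed start k-mer among all starts, optionally
#' weighted by expression (TPM) so the distribution describes transcripts
#' rather than distinct genomic positions.
#'
#' @param kmers character vector of start k-mers.
#' @param weights optional numeric weights (e.g. TPM); unweighted when
#'   `NULL`.
#' @return named numeric vector of shares summing to 1.
#' @export
start_nt_frequencies <- function(kmers, weights = NULL) {
  keep <- !is.na(kmers)
  kmers <- kmers[keep]
  if (!length(kmers)) stop("no valid start k-mers")
  if (is.null(weights)) weights <- rep(1, length(kmers)) else weights <- weights[keep]
  tab <- tapply(weights, kmers, sum)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' TE distribution summaries by start k-mer
#'
#' Groups per-CTSS TE values by the cap-proximal k-mer and reports the
#' group size, total TPM, median TE and outer quantiles. Groups with
#' fewer than `min_support` CTSSs are omitted (medians are unstable
#' below that).
#'
#' @param kmers per-CTSS start k-mers.
#' @param te per-CTSS translation efficiency.
#' @param tpm per-CTSS expression weight (optional; defaults to 1).
#' @param min_support minimum CTSSs per k-mer group (default 50).
#' @return data.frame: `kmer`, `n_ctss`, `total_tpm`, `median_te`, `q05`,
#'   `q25`, `q75`, `q95`.
#' @export
te_by_start_kmer <- function(kmers, te, tpm = NULL, min_support = 50) {
  keep <- !is.na(kmers) & is.finite(te)
  kmers <- kmers[keep]; te <- te[keep]
  tpm <- if (is.null(tpm)) rep(1, length(te)) else tpm[keep]
  sp <- split(seq_along(kmers), kmers)
  sp <- sp[vapply(sp, length, 0L) >= min_support]
  if (!length(sp))
    return(data.frame(kmer = character(), n_ctss = integer(),
                      total_tpm = numeric(), median_te = numeric(),
                      q05 = numeric(), q25 = numeric(), q75 = numeric(),
                      q95 = numeric()))
  rows <- lapply(names(sp), function(km) {
    i <- sp[[km]]
    qs <- stats::quantile(te[i], c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(kmer = km, n_ctss = length(i), total_tpm = sum(tpm[i]),
               median_te = qs[3], q05 = qs[1], q25 = qs[2],
               q75 = qs[4], q95 = qs[5], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(res$kmer), , drop = FALSE]
}

#' Is a start trinucleotide a CNY?
#'
#' CNY starts — cytosine first, any base second, pyrimidine (C or T)
#' third — mark transcripts with strongly reduced translation efficiency,
#' reminiscent of 5' TOP-like translational repression.
#'
#' @param trinucleotide character vector of length-3 ACGT strings.
#' @return logical vector.
#' @export
classify_cny <- function(trinucleotide) {
  ok <- !is.na(trinucleotide)
  if (any(nchar(trinucleotide[ok]) != 3) ||
      any(grepl("[^ACGT]", trinucleotide[ok])))
    stop("trinucleotides must be length-3 strings over ACGT")
  out <- rep(NA, length(trinucleotide))
  out[ok] <- substr(trinucleotide[ok], 1, 1) == "C" &
    substr(trinucleotide[ok], 3, 3) %in% c("C", "T")
  out
}

#' Positional nucleotide-frequency matrix of TSS windows
#'
#' Per-position A/C/G/T frequencies over a set of equal-length,
#' strand-oriented sequence windows (e.g. -40..+30 around TSS peaks);
#' columns sum to 1. The matrix is LOGO-ready and supports positional
#' composition tests such as pyrimidine enrichment downstream of the TSS.
#'
#' @param sequences character vector of equal-length ACGT windows.
#' @param weights optional per-sequence weights.
#' @return 4 x L matrix (rows A, C, G, T) of frequencies.
#' @export
positional_frequency_matrix <- function(sequences, weights = NULL) {
  if (!length(sequences)) stop("no sequences")
  L <- unique(nchar(sequences))
  if (length(L) != 1) stop("sequences must have equal length")
  if (is.null(weights)) weights <- rep(1, length(sequences))
  mat <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  chars <- matrix(unlist(strsplit(sequences, "")), ncol = L, byrow = TRUE)
  for (j in seq_len(L)) {
    tab <- tapply(weights, factor(chars[, j], levels = c("A", "C", "G", "T")), sum)
    tab[is.na(tab)] <- 0
    mat[, j] <- tab / sum(tab)
  }
  mat
}

#' Extract strand-oriented windows around TSS peaks
#'
#' @param genome named `DNAStringSet`.
#' @param chrom,peak,strand TSS descriptions (0-based peak).
#' @param upstream,downstream window extent in bases; the window covers
#'   `upstream` bases before the peak through `downstream` bases after it
#'   (peak included), read in transcript orientation.
#' @return character vector of windows (`NA` where out of bounds).
#' @export
tss_windows <- function(genome, chrom, peak, strand,
                        upstream = 40, downstream = 30) {
  w <- upstream + downstream + 1L
  start0 <- ifelse(strand == "+", peak - upstream, peak - downstream)
  n <- length(peak)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    len <- length(genome[[ch]])
    i <- which(chrom == ch & start0 >= 0 & start0 + w <= len)
    if (!length(i)) next
    v <- Biostrings::Views(genome[[ch]], start = start0[i] + 1L, width = w)
    s <- as.character(v)
    minus <- strand[i] == "-"
    if (any(minus))
      s[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s[minus])))
    out[i] <- s
  }
  out
}

#' Per-CTSS translation efficiency table
#'
#' Computes TE at single-base resolution from replicate-pooled Free and
#' Polysomes (Light+Heavy) tracks, keeping CTSSs reaching `min_tpm` in
#' both pooled fraction tracks, and attaches the start k-mer.
#'
#' @param free_tracks,light_tracks,heavy_tracks lists of `ctss_track`s
#'   (replicates of each fraction).
#' @param genome named `DNAStringSet`.
#' @param k start k-mer length (default 3).
#' @param pseudocount TE pseudocount in TPM (default 1).
#' @param min_tpm per-CTSS TPM floor in both pooled tracks (default 1).
#' @return data.frame: `chrom`, `pos`, `strand`, `free_tpm`,
#'   `polysome_tpm`, `te`, `kmer`.
#' @export
ctss_te_table <- function(free_tracks, light_tracks, heavy_tracks, genome,
                          k = 3, pseudocount = 1, min_tpm = 1) {
  pool_counts <- function(tracks) {
    dt <- data.table::rbindlist(lapply(tracks, function(t)
      as.data.frame(t)[c("chrom", "pos", "strand", "count")]))
    as.data.frame(dt[, list(count = sum(count)),
                     by = c("chrom", "pos", "strand")])
  }
  free <- pool_counts(free_tracks)
  poly <- pool_counts(c(light_tracks, heavy_tracks))
  free$free_tpm <- free$count * 1e6 / sum(free$count)
  poly$polysome_tpm <- poly$count * 1e6 / sum(poly$count)
  merged <- merge(free[c("chrom", "pos", "strand", "free_tpm")],
                  poly[c("chrom", "pos", "strand", "polysome_tpm")],
                  by = c("chrom", "pos", "strand"), all = TRUE)
  merged$free_tpm[is.na(merged$free_tpm)] <- 0
  merged$polysome_tpm[is.na(merged$polysome_tpm)] <- 0
  merged <- merged[merged$free_tpm >= min_tpm &
                     merged$polysome_tpm >= min_tpm, , drop = FALSE]
  merged$te <- (merged$polysome_tpm + pseudocount) /
    (merged$free_tpm + pseudocount)
  merged$kmer <- extract_start_kmer(genome, merged$chrom, merged$pos,
                                    merged$strand, k)
  n_skip <- sum(is.na(merged$kmer))
  if (n_skip) message(n_skip, " CTSS(s) skipped: start k-mer unavailable")
  rownames(merged) <- NULL
  merged
}
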