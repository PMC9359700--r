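#' Read a transcript annotation from GTF
#'
#' Imports a standard GTF (1-based, closed intervals) and converts to the
#' package's internal 0-based half-open convention. One transcript per gene
#' is assumed (the first encountered per gene is used).
#'
#' @param path GTF file.
#' @return A `cage_annotation`: list with `features` (data.frame of typed
#'   intervals: `gene_id`, `tx_id`, `type`, `chrom`, `start`, `end`,
#'   `strand`) and `genes` (one row per gene with `tss`, `start_codon`,
#'   `tx_start`, `tx_end`; `start_codon` is the genomic position of the
#'   first base of the annotated ATG in transcript orientation, `NA` for
#'   noncoding genes).
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    tx_id = as.character(gr$transcript_id),
    type = as.character(gr$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  build_annotation(df)
}

#' Build a `cage_annotation` from a feature table
#'
#' @param features data.frame of typed intervals (0-based half-open) with
#'   columns `gene_id`, `tx_id`, `type`, `chrom`, `start`, `end`, `strand`;
#'   `type` uses GTF vocabulary (`transcript`, `exon`, `CDS`,
#'   `start_codon`, `five_prime_utr`).
#' @return A `cage_annotation` object.
#' @export
build_annotation <- function(features) {
  tx <- features[features$type == "transcript", , drop = FALSE]
  tx <- tx[!duplicated(tx$gene_id), , drop = FALSE]
  sc <- features[features$type == "start_codon", , drop = FALSE]
  genes <- data.frame(
    gene_id = tx$gene_id, tx_id = tx$tx_id, chrom = tx$chrom,
    strand = tx$strand, tx_start = tx$start, tx_end = tx$end,
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
  m <- match(genes$gene_id, sc$gene_id)
  genes$start_codon <- ifelse(is.na(m), NA_integer_,
                              ifelse(genes$strand == "+", sc$start[m], sc$end[m] - 1L))
  structure(list(features = features, genes = genes),
            class = "cage_annotation")
}

#' @export
print.cage_annotation <- function(x, ...) {
  cat(sprintf("cage_annotation: %d genes, %d features\n",
              nrow(x$genes), nrow(x$features)))
  invisible(x)
}

category_precedence <- c("promoter", "fiveUTR", "CDS", "exon", "intron",
                         "antisense", "intergenic")

#' Assign a gene-structure category to each cluster
#'
#' The cluster peak is tested against same-strand transcript features with
#' precedence promoter > fiveUTR > CDS > exon > intron; failing those, an
#' opposite-strand transcript overlap gives `antisense`, otherwise
#' `intergenic`. The promoter is the annotated TSS plus/minus
#' `promoter_pad` bases. Ties across transcripts are broken by precedence,
#' then smallest absolute distance to the annotated TSS, then gene id, so
#' calls never depend on record order.
#'
#' @param clusters cluster data.frame (needs `chrom`, `strand`, `peak`).
#' @param annotation a `cage_annotation`.
#' @param promoter_pad half-width of the promoter window in bases
#'   (default 100).
#' @return The clusters with added `category`, `gene_id`, `tx_id` and
#'   `distance_to_tss` (signed, positive downstream in transcript
#'   orientation) columns.
#' @export
assign_genomic_category <- function(clusters, annotation, promoter_pad = 100) {
  genes <- annotation$genes
  feats <- annotation$features
  n <- nrow(clusters)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n); tx_id <- rep(NA_character_, n)
  dist_tss <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pk <- clusters$peak[i]; ch <- clusters$chrom[i]; st <- clusters$strand[i]
    same <- genes[genes$chrom == ch & genes$strand == st, , drop = FALSE]
    cand <- NULL
    for (g in seq_len(nrow(same))) {
      gn <- same[g, ]
      cat_g <- peak_category(pk, gn, feats, promoter_pad)
      if (is.na(cat_g)) next
      d <- if (gn$strand == "+") pk - gn$tss else gn$tss - pk
      cand <- rbind(cand, data.frame(gene_id = gn$gene_id, tx_id = gn$tx_id,
                                     category = cat_g, d = d,
                                     stringsAsFactors = FALSE))
    }
    if (!is.null(cand) && nrow(cand)) {
      cand$prec <- match(cand$category, category_precedence)
      cand <- cand[order(cand$prec, abs(cand$d), cand$gene_id), , drop = FALSE]
      category[i] <- cand$category[1]; gene_id[i] <- cand$gene_id[1]
      tx_id[i] <- cand$tx_id[1]; dist_tss[i] <- cand$d[1]
    } else {
      anti <- genes[genes$chrom == ch & genes$strand != st &
                      genes$tx_start <= pk & pk < genes$tx_end, , drop = FALSE]
      if (nrow(anti)) {
        anti <- anti[order(anti$gene_id), , drop = FALSE]
        category[i] <- "antisense"
        gene_id[i] <- anti$gene_id[1]; tx_id[i] <- anti$tx_id[1]
      }
    }
  }
  clusters$category <- category
  clusters$gene_id <- gene_id
  clusters$tx_id <- tx_id
  clusters$distance_to_tss <- dist_tss
  clusters
}

# Category of one peak against one same-strand gene, or NA if unrelated.
peak_category <- function(pk, gene, feats, promoter_pad) {
  if (abs(pk - gene$tss) <= promoter_pad) return("promoter")
  inside <- gene$tx_start <= pk & pk < gene$tx_end
  if (!inside) return(NA_character_)
  f <- feats[feats$gene_id == gene$gene_id, , drop = FALSE]
  in_type <- function(type) {
    sub <- f[f$type == type, , drop = FALSE]
    nrow(sub) && any(sub$start <= pk & pk < sub$end)
  }
  if (in_type("five_prime_utr")) return("fiveUTR")
  if (in_type("CDS")) return("CDS")
  if (in_type("exon")) return("exon")
  "intron"
}

#' Designate canonical and alternative TSSs per gene
#'
#' Clusters assigned to a gene (categories promoter/fiveUTR/CDS/exon/
#' intron) are converted to expression shares of the gene total; clusters
#' below `min_share` are discarded from the multi-TSS analysis. The
#' canonical TSS is the retained cluster overlapping the annotated
#' promoter if any (highest expression among several), otherwise the
#' highest-expressed retained cluster; expression ties are broken by the
#' transcript-5'-most peak. A gene is multi-TSS iff it retains at least
#' two clusters.
#'
#' @param annotated clusters with `category`, `gene_id` and `pooled_tpm`
#'   columns ([assign_genomic_category()]).
#' @param min_share minimum share of gene expression (default 0.10).
#' @return data.frame with one row per retained (gene, cluster):
#'   `gene_id`, `cluster_id`, `category`, `share`, `is_canonical`,
#'   `multi_tss`.
#' @export
designate_canonical_and_alternatives <- function(annotated, min_share = 0.10) {
  genic <- annotated[annotated$category %in%
                       c("promoter", "fiveUTR", "CDS", "exon", "intron") &
                       !is.na(annotated$gene_id), , drop = FALSE]
  out <- list()
  for (g in unique(genic$gene_id)) {
    sub <- genic[genic$gene_id == g, , drop = FALSE]
    tot <- sum(sub$pooled_tpm)
    if (tot <= 0) next
    sub$share <- sub$pooled_tpm / tot
    sub <- sub[sub$share >= min_share, , drop = FALSE]
    if (!nrow(sub)) next
    # transcript-5'-most peak first for deterministic tie-breaks
    five_most <- if (sub$strand[1] == "+") sub$peak else -sub$peak
    prom <- sub$category == "promoter"
    ord <- order(!prom, -sub$share, five_most, sub$cluster_id)
    sub <- sub[ord, , drop = FALSE]
    sub$is_canonical <- seq_len(nrow(sub)) == 1L
    sub$multi_tss <- nrow(sub) >= 2L
    out[[g]] <- sub[, c("gene_id", "cluster_id", "category", "peak",
                        "strand", "share", "is_canonical", "multi_tss")]
  }
  if (!length(out))
    return(data.frame(gene_id = character(), cluster_id = character(),
                      category = character(), peak = integer(),
                      strand = character(), share = numeric(),
                      is_canonical = logical(), multi_tss = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' ORF effect of an alternative TSS
#'
#' An alternative TSS retains the annotated ORF iff its peak lies at or
#' upstream (in transcript orientation) of the annotated start codon;
#' peaks downstream of it (CDS, intron) produce N-terminally truncated or
#' modified isoforms. A peak exactly at the first base of the start codon
#' is classified truncating (downstream-inclusive boundary: the complete
#' start codon is no longer part of the transcript body upstream of it).
#'
#' @param peak cluster peak position(s).
#' @param strand `"+"` or `"-"` (recycled).
#' @param start_codon genomic position of the first base of the annotated
#'   ATG; `NA` (noncoding) is an error.
#' @return character vector in `{"retaining","truncating"}`.
#' @export
classify_orf_effect <- function(peak, strand, start_codon) {
  if (any(is.na(start_codon)))
    stop("ORF effect undefined for transcripts without an annotated CDS")
  downstream <- ifelse(strand == "+", peak >= start_codon, peak <= start_codon)
  ifelse(downstream, "truncating", "retaining")
}

#' 5' UTR length and upstream-AUG count for a retaining TSS
#'
#' The 5' UTR runs from the TSS peak to the base before the annotated
#' start codon along the transcript's exonic (spliced) path. AUGs are
#' counted in all frames, overlapping occurrences allowed.
#'
#' @param peak TSS position (0-based).
#' @param gene one row of `annotation$genes`.
#' @param annotation a `cage_annotation`.
#' @param genome named `DNAStringSet`.
#' @return list with `utr_length` (bases, spliced) and `n_uaug`.
#' @export
count_uaug_and_utr_length <- function(peak, gene, annotation, genome) {
  if (is.na(gene$start_codon)) stop("gene has no annotated CDS")
  if (classify_orf_effect(peak, gene$strand, gene$start_codon) == "truncating")
    stop("TSS peak lies downstream of the start codon; 5' UTR undefined")
  exons <- annotation$features[annotation$features$gene_id == gene$gene_id &
                                 annotation$features$type == "exon", , drop = FALSE]
  if (gene$strand == "+") {
    lo <- peak; hi <- gene$start_codon          # [peak, start_codon)
  } else {
    lo <- gene$start_codon + 1L; hi <- peak + 1L  # (start_codon, peak]
  }
  segs <- exons[exons$end > lo & exons$start < hi, , drop = FALSE]
  if (!nrow(segs)) return(list(utr_length = 0L, n_uaug = 0L))
  segs$start <- pmax(segs$start, lo); segs$end <- pmin(segs$end, hi)
  segs <- segs[order(segs$start), , drop = FALSE]
  seq <- paste(vapply(seq_len(nrow(segs)), function(i)
    as.character(Biostrings::subseq(genome[[gene$chrom]],
                                    segs$start[i] + 1L, segs$end[i])), ""),
    collapse = "")
  if (gene$strand == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  n_uaug <- count_overlapping(seq, "ATG")
  list(utr_length = nchar(seq), n_uaug = n_uaug)
}

count_overlapping <- function(seq, pat) {
  if (nchar(seq) < nchar(pat)) return(0L)
  length(Biostrings::matchPattern(pat, Biostrings::DNAString(seq)))
}
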