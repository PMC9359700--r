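#' Simulation configuration
#'
#' Parameters of the synthetic polysome-CAGE dataset. The defaults encode
#' the study design the package analyses: two conditions (WT and TCL1)
#' with two replicates of total-RNA CAGE each, and Free/Light/Heavy
#' polysome fractions (two replicates each) for the disease condition,
#' with negative binomial replicate noise, multi-TSS genes carrying
#' ORF-retaining (5' UTR) or ORF-truncating (intronic) alternative
#' promoters, balanced divergent enhancers, and polysome partitioning
#' driven by 5' UTR length, upstream AUGs and the cap-proximal
#' trinucleotide (CNY starts have their polysome odds multiplied by
#' `cny_te_multiplier`).
#'
#' @param seed integer; fully determines all outputs.
#' @param n_genes number of genes (default 80).
#' @param n_multi_tss_genes genes carrying an alternative TSS (default 32).
#' @param n_enhancers balanced divergent enhancer loci (default 16).
#' @param frac_truncating_atss fraction of alternative TSSs placed inside
#'   the CDS/intron (truncating) rather than the 5' UTR (default 0.5).
#' @param replicates_per_condition replicates per condition and fraction
#'   (default 2).
#' @param nb_dispersion NB dispersion of replicate counts (default 0.05).
#' @param cny_te_multiplier multiplier on the polysome odds of
#'   CNY-initiating CTSSs (default 0.25).
#' @param dtu_logfc planted condition shift (log2) of alternative TSSs
#'   (default 1.5).
#' @param sharp_frac fraction of sharp (1-10 bp) tag clusters
#'   (default 0.6).
#' @param genome_length genome size in bases; computed from the layout
#'   when `NULL`, and an explicit sizing error is raised when too small
#'   for the requested gene/enhancer counts.
#' @param frac_up_dtu fraction of planted shifts that are upward
#'   (default 0.6).
#' @param frac_de_genes fraction of single-TSS genes given a gene-level
#'   condition effect (default 0.25).
#' @param de_logfc magnitude (log2) of planted gene-level effects
#'   (default 1.5; 60% of them upward).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 80, n_multi_tss_genes = 32,
                       n_enhancers = 16, frac_truncating_atss = 0.5,
                       replicates_per_condition = 2, nb_dispersion = 0.05,
                       cny_te_multiplier = 0.25, dtu_logfc = 1.5,
                       sharp_frac = 0.6, genome_length = NULL,
                       frac_up_dtu = 0.6, frac_de_genes = 0.25,
                       de_logfc = 1.5) {
  stopifnot(n_genes >= 1, n_multi_tss_genes >= 0, n_enhancers >= 0,
            replicates_per_condition >= 1,
            frac_truncating_atss >= 0, frac_truncating_atss <= 1,
            sharp_frac >= 0, sharp_frac <= 1,
            nb_dispersion > 0, cny_te_multiplier > 0,
            frac_up_dtu >= 0, frac_up_dtu <= 1)
  if (n_multi_tss_genes > n_genes)
    stop("n_multi_tss_genes cannot exceed n_genes")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_multi_tss_genes = as.integer(n_multi_tss_genes),
              n_enhancers = as.integer(n_enhancers),
              frac_truncating_atss = frac_truncating_atss,
              replicates_per_condition = as.integer(replicates_per_condition),
              nb_dispersion = nb_dispersion,
              cny_te_multiplier = cny_te_multiplier,
              dtu_logfc = dtu_logfc, sharp_frac = sharp_frac,
              genome_length = genome_length, frac_up_dtu = frac_up_dtu,
              frac_de_genes = frac_de_genes, de_logfc = de_logfc)
  class(cfg) <- "sim_config"
  cfg
}

GENE_SLOT <- 7000L
ENH_SLOT <- 2000L
MARGIN <- 1000L
# consensus planted into upregulated alternative promoters; matches the
# SYNM01 fixture motif in inst/extdata/synthetic_motifs.jaspar
PLANTED_MOTIF_CONSENSUS <- "TGACGTCAGC"

required_genome_length <- function(cfg) {
  2L * MARGIN + cfg$n_genes * GENE_SLOT + cfg$n_enhancers * ENH_SLOT
}

# transcript offset interval [a, b) -> genomic 0-based half-open interval
tx2gen <- function(tss, strand, a, b) {
  if (strand == "+") c(tss + a, tss + b) else c(tss - b + 1L, tss - a + 1L)
}

#' Generate the synthetic reference (genome + gene models)
#'
#' Builds a single-chromosome random genome and one transcript per gene,
#' each with a 5' UTR, a spliced CDS (start codon annotated) and two
#' introns. Multi-TSS genes carry a second planted promoter: upstream of
#' the start codon inside the 5' UTR (ORF-retaining) or inside the first
#' intron (ORF-truncating), split by `frac_truncating_atss`. Upregulated
#' alternative promoters receive a planted copy of the SYNM01 motif
#' consensus 60 bp upstream of the alternative TSS.
#'
#' @param config a [sim_config()].
#' @return list: `genome` (named `DNAStringSet`), `features` (0-based
#'   feature table), `annotation` (`cage_annotation`), `genes_truth`,
#'   `atss_truth`, `enhancers_truth`.
#' @export
generate_reference <- function(config) {
  need <- required_genome_length(config)
  glen <- if (is.null(config$genome_length)) need else as.integer(config$genome_length)
  if (glen < need)
    stop(sprintf("genome_length %d too small: need %d for %d genes and %d enhancers",
                 glen, need, config$n_genes, config$n_enhancers))
  set.seed(config$seed)
  gseq <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)

  n_multi <- config$n_multi_tss_genes
  n_trunc <- round(config$frac_truncating_atss * n_multi)
  trunc_flags <- rep(FALSE, n_multi)
  if (n_trunc > 0) trunc_flags[sample(n_multi, n_trunc)] <- TRUE

  feat <- list(); genes_truth <- list(); atss_truth <- list()
  for (g in seq_len(config$n_genes)) {
    S <- MARGIN + (g - 1L) * GENE_SLOT
    strand <- if (g %% 2L == 1L) "+" else "-"
    gid <- sprintf("gene%03d", g); tid <- paste0(gid, ".t1")
    multi <- g <= n_multi
    u <- if (multi) sample(250:450, 1) else sample(80:400, 1)
    tss <- if (strand == "+") S + 2000L else S + 5000L
    A <- u + 300L  # end of exon 1 in transcript coordinates
    ex <- list(c(0L, A), c(A + 400L, A + 700L), c(A + 1100L, A + 1520L))
    cds <- list(c(u, A), c(A + 400L, A + 700L), c(A + 1100L, A + 1400L))
    tx_iv <- c(0L, A + 1520L)
    add <- function(type, iv) {
      gg <- tx2gen(tss, strand, iv[1], iv[2])
      feat[[length(feat) + 1L]] <<- data.frame(
        gene_id = gid, tx_id = tid, type = type, chrom = "chr1",
        start = gg[1], end = gg[2], strand = strand,
        stringsAsFactors = FALSE)
    }
    add("gene", tx_iv); add("transcript", tx_iv)
    for (e in ex) add("exon", e)
    for (cc in cds) add("CDS", cc)
    add("start_codon", c(u, u + 3L))
    add("five_prime_utr", c(0L, u))
    # plant the ATG (reverse strand: genomic CAT reads ATG on the transcript)
    cg <- tx2gen(tss, strand, u, u + 3L)
    codon <- if (strand == "+") c("A", "T", "G") else c("C", "A", "T")
    gseq[(cg[1] + 1L):cg[2]] <- codon

    atss_pos <- NA_integer_; orf_effect <- NA_character_
    planted_l2fc <- NA_real_; atss_class <- NA_character_
    if (multi) {
      truncating <- trunc_flags[g]
      off <- if (truncating) A + 150L else as.integer(round(u * 0.5))
      atss_pos <- if (strand == "+") tss + off else tss - off
      orf_effect <- if (truncating) "truncating" else "retaining"
      atss_class <- if (truncating) "intron" else "fiveUTR"
      dir_up <- stats::runif(1) < config$frac_up_dtu
      planted_l2fc <- if (dir_up) config$dtu_logfc else -config$dtu_logfc
      if (dir_up) {  # plant motif 60 bp upstream of the alternative TSS
        cons <- strsplit(PLANTED_MOTIF_CONSENSUS, "")[[1]]
        L <- length(cons)
        mg <- tx2gen(tss, strand, off - 60L - L, off - 60L)
        ins <- if (strand == "+") cons else
          rev(chartr("ACGT", "TGCA", cons))
        gseq[(mg[1] + 1L):mg[2]] <- ins
      }
      atss_truth[[length(atss_truth) + 1L]] <- data.frame(
        gene_id = gid, atss_pos = atss_pos, strand = strand,
        location_class = atss_class, orf_effect = orf_effect,
        planted_log2_fc = planted_l2fc, motif_planted = dir_up,
        stringsAsFactors = FALSE)
    }
    # gene-level condition effects on single-TSS genes, so the DE stage
    # has true positives beyond the planted promoter shifts
    gene_l2fc <- 0
    if (!multi && stats::runif(1) < config$frac_de_genes)
      gene_l2fc <- if (stats::runif(1) < 0.6) config$de_logfc else -config$de_logfc
    genes_truth[[g]] <- data.frame(
      gene_id = gid, chrom = "chr1", strand = strand, tss = tss,
      start_codon = unname(if (strand == "+") tss + u else tss - u),
      utr_length = u, multi_tss = multi, planted_gene_log2_fc = gene_l2fc,
      stringsAsFactors = FALSE)
  }

  enh_truth <- list()
  if (config$n_enhancers > 0) {
    base <- MARGIN + config$n_genes * GENE_SLOT
    for (e in seq_len(config$n_enhancers)) {
      mid <- base + (e - 1L) * ENH_SLOT + ENH_SLOT %/% 2L
      enh_truth[[e]] <- data.frame(
        enhancer_id = sprintf("enh%03d", e), chrom = "chr1",
        midpoint = mid, minus_arm_peak = mid - 90L,
        plus_arm_peak = mid + 90L, stringsAsFactors = FALSE)
    }
  }

  genome <- Biostrings::DNAStringSet(paste(gseq, collapse = ""))
  names(genome) <- "chr1"
  features <- do.call(rbind, feat)
  list(config = config, genome = genome, features = features,
       annotation = build_annotation(features),
       genes_truth = do.call(rbind, genes_truth),
       atss_truth = if (length(atss_truth)) do.call(rbind, atss_truth) else
         data.frame(gene_id = character(), atss_pos = integer(),
                    strand = character(), location_class = character(),
                    orf_effect = character(), planted_log2_fc = numeric(),
                    motif_planted = logical()),
       enhancers_truth = if (length(enh_truth)) do.call(rbind, enh_truth) else
         data.frame(enhancer_id = character(), chrom = character(),
                    midpoint = integer(), minus_arm_peak = integer(),
                    plus_arm_peak = integer()))
}

# per-position weights of a planted cluster, peaked at its centre; the
# decay is gentle enough that the 10-90% span of a broad cluster stays in
# the broad width range
cluster_weights <- function(width) {
  off <- seq_len(width) - 1L - (width %/% 2L)
  w <- exp(-abs(off) / max(1, width / 2))
  list(offsets = off, weights = w / sum(w))
}

#' Generate CTSS count tracks and the per-CTSS truth layer
#'
#' Realizes the expectation layer of the planted promoters and enhancers
#' into per-sample, per-base NB counts. For every planted CTSS the start
#' trinucleotide is read off the simulated genome (strand-aware), and the
#' polysome partitioning odds are `exp(b0 - log(utr_len) - 0.5 n_uaug)`
#' times `cny_te_multiplier` for CNY starts; Light and Heavy split the
#' polysome probability equally, and the three fraction expectations sum
#' to the CTSS's total-transcript expectation. Enhancer CTSSs are 90%
#' polysome-free. Fraction tracks are produced for the TCL1 condition
#' (the profiled disease condition).
#'
#' @param config a [sim_config()].
#' @param reference output of [generate_reference()].
#' @return list: `tracks` (named list of `ctss_track`s), `ctss_truth`
#'   (per-CTSS expectation table).
#' @export
generate_ctss_tracks <- function(config, reference) {
  if (is.null(reference$genome)) stop("reference must be generated first")
  set.seed(config$seed + 1L)
  genome <- reference$genome
  gt <- reference$genes_truth
  at <- reference$atss_truth
  # baseline polysome log-odds, centred so a typical transcript (UTR ~250
  # bases, ~4 upstream AUGs in random sequence) is about two-thirds
  # polysomal; with a lower baseline the 1-TPM per-CTSS filter of the
  # cap-proximal analysis starts censoring the polysome side of
  # repressed starts
  b0 <- log(250) + 0.5 * 4 + log(2)

  units <- list()
  add_unit <- function(unit_id, type, peak, strand, mean_wt, mean_tcl1,
                       utr_len, n_uaug, erna = FALSE) {
    sharp <- stats::runif(1) < config$sharp_frac
    width <- if (sharp) sample(1:8, 1) else sample(12:35, 1)
    cw <- cluster_weights(width)
    pos <- peak + cw$offsets
    units[[length(units) + 1L]] <<- data.frame(
      unit_id = unit_id, type = type, chrom = "chr1", pos = pos,
      strand = strand, weight = cw$weights,
      mean_wt = mean_wt * cw$weights, mean_tcl1 = mean_tcl1 * cw$weights,
      utr_len = utr_len, n_uaug = n_uaug, erna = erna,
      stringsAsFactors = FALSE)
  }

  for (g in seq_len(nrow(gt))) {
    gn <- gt[g, ]
    M <- stats::rlnorm(1, log(3000), 0.5)
    uaug_can <- count_aug_span(genome, gn$chrom, gn$tss, gn$start_codon,
                               gn$strand)
    add_unit(paste0(gn$gene_id, ":canonical"), "gene_canonical",
             gn$tss, gn$strand, M, M * 2^gn$planted_gene_log2_fc,
             gn$utr_length, uaug_can)
    ai <- which(at$gene_id == gn$gene_id)
    if (length(ai)) {
      aa <- at[ai, ]
      mult <- 2^aa$planted_log2_fc
      if (aa$orf_effect == "retaining") {
        Ma <- stats::rlnorm(1, log(2000), 0.5)
        ul <- abs(gn$start_codon - aa$atss_pos)
        ua <- count_aug_span(genome, gn$chrom, aa$atss_pos, gn$start_codon,
                             gn$strand)
      } else {
        # intra-genic starts vary widely in prominence, so measured
        # polysome ratios straddle the truncation-impact boundary
        Ma <- stats::rlnorm(1, log(1000), 0.8)
        ul <- 30L; ua <- 0L
      }
      add_unit(paste0(gn$gene_id, ":alt"), "gene_alt", aa$atss_pos,
               aa$strand, Ma, Ma * mult, ul, ua)
    }
  }
  et <- reference$enhancers_truth
  for (e in seq_len(nrow(et))) {
    Me <- stats::rlnorm(1, log(600), 0.4)
    add_unit(paste0(et$enhancer_id[e], ":minus"), "enhancer_arm",
             et$minus_arm_peak[e], "-", Me, Me, NA, NA, erna = TRUE)
    add_unit(paste0(et$enhancer_id[e], ":plus"), "enhancer_arm",
             et$plus_arm_peak[e], "+", Me, Me, NA, NA, erna = TRUE)
  }
  truth <- do.call(rbind, units)

  truth$trinuc <- extract_start_kmer(genome, truth$chrom, truth$pos,
                                     truth$strand, 3)
  truth$is_cny <- classify_cny(truth$trinuc)
  odds <- exp(b0 - log(pmax(truth$utr_len, 1)) - 0.5 * truth$n_uaug) *
    ifelse(truth$is_cny %in% TRUE, config$cny_te_multiplier, 1)
  p_poly <- odds / (1 + odds)
  p_poly[truth$erna] <- 0.10
  truth$p_free <- 1 - p_poly
  truth$p_light <- p_poly / 2
  truth$p_heavy <- p_poly / 2

  nb <- function(mu) stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$nb_dispersion)
  mk_track <- function(counts, sample_id, condition, rep, fraction) {
    keep <- counts > 0
    ctss_track(data.frame(chrom = truth$chrom[keep], pos = truth$pos[keep],
                          strand = truth$strand[keep], count = counts[keep]),
               sample_id, condition, rep, fraction)
  }
  tracks <- list()
  R <- config$replicates_per_condition
  for (r in seq_len(R)) {
    id <- sprintf("WT_Total_r%d", r)
    tracks[[id]] <- mk_track(nb(truth$mean_wt), id, "WT", r, "Total")
  }
  for (r in seq_len(R)) {
    id <- sprintf("TCL1_Total_r%d", r)
    tracks[[id]] <- mk_track(nb(truth$mean_tcl1), id, "TCL1", r, "Total")
  }
  for (fr in c("Free", "Light", "Heavy")) {
    pcol <- switch(fr, Free = truth$p_free, Light = truth$p_light,
                   Heavy = truth$p_heavy)
    for (r in seq_len(R)) {
      id <- sprintf("TCL1_%s_r%d", fr, r)
      tracks[[id]] <- mk_track(nb(truth$mean_tcl1 * pcol), id, "TCL1", r, fr)
    }
  }
  list(tracks = tracks, ctss_truth = truth)
}

# AUGs in the genomic span between a TSS and the start codon (transcript
# orientation); the simulated 5' UTRs are unspliced so the genomic span
# is the UTR.
count_aug_span <- function(genome, chrom, tss, start_codon, strand) {
  if (strand == "+") { lo <- tss; hi <- start_codon } else {
    lo <- start_codon + 1L; hi <- tss + 1L
  }
  if (hi - lo < 3) return(0L)
  s <- Biostrings::subseq(genome[[chrom]], lo + 1L, hi)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  length(Biostrings::matchPattern("ATG", s))
}

#' Simulate a complete synthetic polysome-CAGE dataset
#'
#' Runs [generate_reference()] and [generate_ctss_tracks()] and optionally
#' writes everything to disk: genome FASTA, annotation GTF, per-sample
#' CTSS BED6 files, a sample sheet, truth tables as TSV and a JSON echo of
#' the configuration. The same configuration and seed always produce
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created); in-memory only when `NULL`.
#' @return list: `config`, `genome`, `features`, `annotation`, `tracks`,
#'   truth tables, and `dir` when written.
#' @export
simulate_polysome_cage <- function(config = sim_config(), dir = NULL) {
  ref <- generate_reference(config)
  tr <- generate_ctss_tracks(config, ref)
  out <- c(ref, tr)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
    write_gtf(ref$features, file.path(dir, "annotation.gtf"))
    ss <- list()
    for (id in names(tr$tracks)) {
      t <- tr$tracks[[id]]
      f <- file.path(dir, paste0(id, ".ctss.bed"))
      write_ctss_bed(t, f)
      ss[[id]] <- data.frame(sample_id = id,
                             condition = attr(t, "condition"),
                             replicate = attr(t, "replicate"),
                             fraction = attr(t, "fraction"),
                             path = basename(f), stringsAsFactors = FALSE)
    }
    write_tsv(do.call(rbind, ss), file.path(dir, "samples.tsv"))
    write_tsv(ref$genes_truth, file.path(dir, "truth_genes.tsv"))
    write_tsv(ref$atss_truth, file.path(dir, "truth_atss.tsv"))
    write_tsv(ref$enhancers_truth, file.path(dir, "truth_enhancers.tsv"))
    write_tsv(tr$ctss_truth, file.path(dir, "truth_ctss.tsv"))
    cfg <- config; cfg$genome_length <- length(ref$genome[[1]])
    writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, pretty = TRUE,
                                null = "null"),
               file.path(dir, "config.json"))
    out$dir <- dir
  }
  out
}

#' Write a feature table as GTF (1-based, closed intervals)
#'
#' @param features 0-based half-open feature table (see
#'   [build_annotation()]).
#' @param path output file.
#' @export
write_gtf <- function(features, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   features$gene_id, features$tx_id)
  lines <- paste(features$chrom, "polycage_sim", features$type,
                 features$start + 1L, features$end, ".", features$strand,
                 ".", attrs, sep = "\t")
  write_atomic(path, function(tmp) writeLines(lines, tmp))
  invisible(path)
}

#' Load a simulated (or compatible) dataset from disk
#'
#' Reads the sample sheet, CTSS BED files, genome FASTA and annotation
#' GTF written by [simulate_polysome_cage()] — or any dataset following
#' the same layout.
#'
#' @param dir dataset directory.
#' @return list with `tracks`, `genome`, `annotation`.
#' @export
load_dataset <- function(dir) {
  ss <- read_sample_sheet(file.path(dir, "samples.tsv"))
  tracks <- list()
  for (i in seq_len(nrow(ss))) {
    tracks[[ss$sample_id[i]]] <- read_ctss_bed(
      file.path(dir, ss$path[i]), ss$sample_id[i], ss$condition[i],
      ss$replicate[i], ss$fraction[i])
  }
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  list(tracks = tracks, genome = genome,
       annotation = read_annotation_gtf(file.path(dir, "annotation.gtf")))
}
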