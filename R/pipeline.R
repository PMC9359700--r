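#' Default pipeline parameters
#'
#' All stage parameters of [run_all()] with their defaults: slice-reduce
#' clustering (`slice_threshold` 0.1 TPM, `merge_dist` 20 bp), the 1-TPM
#' expression filter, enhancer geometry (400 bp window, balance 0.95,
#' 50 kbp linking), the 10% alternative-promoter share rule, DE/DTU FDR
#' alpha 0.05, TE pseudocount 1 TPM with the twofold High/Low rule and
#' the 50% truncation-impact threshold, start k-mer support 50, and the
#' motif scan (-1000..+100 windows, relative score 0.85).
#'
#' @return named list of parameters.
#' @export
default_params <- function() {
  list(slice_threshold = 0.1, merge_dist = 20, min_tpm = 1,
       enhancer_window = 400, balance_threshold = 0.95,
       link_max_dist = 50000, alpha = 0.05, min_share = 0.10,
       promoter_pad = 100, te_pseudocount = 1, te_min_total = 1,
       te_fold = 2, trunc_threshold = 0.5, kmer_k = 3, min_support = 50,
       motif_rel_threshold = 0.85, motif_up = 1000, motif_down = 100,
       run_motifs = TRUE, run_startseq = TRUE, run_translation = TRUE,
       motif_file = NULL)
}

tracks_by <- function(tracks, fraction = NULL, condition = NULL) {
  keep <- vapply(tracks, function(t) {
    (is.null(fraction) || attr(t, "fraction") %in% fraction) &&
      (is.null(condition) || attr(t, "condition") %in% condition)
  }, TRUE)
  tracks[keep]
}

#' Run the full polysome-CAGE analysis
#'
#' Orchestrates the stages end to end on an in-memory dataset (from
#' [simulate_polysome_cage()] or [load_dataset()]): TPM normalization and
#' pooling, enhancer candidate detection and balanced-enhancer calling,
#' slice-reduce TSS clustering (enhancer arms are removed from the TSS
#' cluster set so one locus is never double-typed), the expression
#' filter, genomic category assignment, canonical/alternative TSS
#' designation, differential expression and differential TSS usage,
#' sample QC (replicate correlation, PCA), enhancer-TSS linking,
#' translation efficiency with High/Low-TE pairing and truncation
#' impact, cap-proximal start-sequence analysis, and motif enrichment.
#' The pipeline is deterministic: the same dataset and parameters always
#' give the same report.
#'
#' @param dataset list with `tracks`, `genome`, `annotation`.
#' @param params named list overriding [default_params()].
#' @return list of stage results plus a `summary` list of headline
#'   counts.
#' @export
run_all <- function(dataset, params = list()) {
  p <- utils::modifyList(default_params(), params)
  tracks <- dataset$tracks
  total <- tracks_by(tracks, fraction = "Total")
  if (length(total) < 4) stop("need Total-RNA tracks for both conditions")
  cond <- vapply(total, function(t) attr(t, "condition"), "")
  tpm_tracks <- lapply(total, tpm_normalize)
  pooled <- pool_tpm(tpm_tracks)

  cand <- detect_bidirectional_candidates(pooled, p$enhancer_window,
                                          p$slice_threshold, p$merge_dist)
  enhancers <- call_enhancers(cand, p$balance_threshold)

  clusters <- slice_reduce_cluster(pooled, p$slice_threshold, p$merge_dist)
  # category calls over the full cluster set feed the eRNA fractions;
  # enhancer arms are then removed so one locus is never double-typed
  all_annotated <- assign_genomic_category(clusters, dataset$annotation,
                                           p$promoter_pad)
  arm_ids <- c(enhancers$minus_cluster, enhancers$plus_cluster)
  arm_clusters <- clusters[clusters$cluster_id %in% arm_ids, , drop = FALSE]
  tss_clusters <- clusters[!clusters$cluster_id %in% arm_ids, , drop = FALSE]

  cc <- cluster_sample_counts(tss_clusters, total)
  keep <- filter_low_expression(cc$tpm, cond, p$min_tpm)
  tss_clusters <- tss_clusters[keep, , drop = FALSE]
  counts <- cc$counts[keep, , drop = FALSE]
  tpm_mat <- cc$tpm[keep, , drop = FALSE]

  annotated <- all_annotated[match(tss_clusters$cluster_id,
                                   all_annotated$cluster_id), , drop = FALSE]
  atss <- designate_canonical_and_alternatives(annotated, p$min_share)

  de <- de_test(counts, cond, p$alpha)
  dtu <- dtu_test(counts, cond, atss, p$alpha)
  qc <- list(correlation = replicate_correlation(tpm_mat),
             pca = sample_pca(tpm_mat))

  links <- NULL; erna_frac <- c(intron = NA_real_, intergenic = NA_real_)
  if (nrow(enhancers)) {
    acc <- cluster_sample_counts(arm_clusters, total)
    im <- match(enhancers$minus_cluster, arm_clusters$cluster_id)
    ip <- match(enhancers$plus_cluster, arm_clusters$cluster_id)
    enh_tpm <- acc$tpm[im, , drop = FALSE] + acc$tpm[ip, , drop = FALSE]
    rownames(enh_tpm) <- enhancers$enhancer_id
    links <- link_enhancers_to_tss(enhancers, enh_tpm, annotated, tpm_mat,
                                   p$link_max_dist, p$alpha)
    erna_frac <- classify_intergenic_intronic_ernas(all_annotated, enhancers)
  }

  genes <- dataset$annotation$genes
  alt <- atss[!atss$is_canonical, , drop = FALSE]
  if (nrow(alt)) {
    gm <- match(alt$gene_id, genes$gene_id)
    alt$orf_effect <- classify_orf_effect(alt$peak, alt$strand,
                                          genes$start_codon[gm])
  } else alt$orf_effect <- character(0)

  translation <- NULL
  free_tr <- tracks_by(tracks, fraction = "Free")
  light_tr <- tracks_by(tracks, fraction = "Light")
  heavy_tr <- tracks_by(tracks, fraction = "Heavy")
  have_fracs <- length(free_tr) && length(light_tr) && length(heavy_tr)
  if (p$run_translation && have_fracs) {
    frac_tpm <- function(trs) {
      s <- cluster_sample_counts(tss_clusters, trs)
      cnt <- rowSums(s$counts)
      cnt * 1e6 / max(sum(s$lib_sizes), 1)
    }
    ftpm <- frac_tpm(free_tr); ltpm <- frac_tpm(light_tr)
    htpm <- frac_tpm(heavy_tr)
    names(ftpm) <- names(ltpm) <- names(htpm) <- tss_clusters$cluster_id
    te_tab <- compute_te(ftpm, ltpm, htpm, p$te_pseudocount, p$te_min_total)
    pairs <- build_te_pairs(atss, te_tab, p$te_fold)
    trunc <- NULL
    talt <- alt[alt$orf_effect == "truncating", , drop = FALSE]
    if (nrow(talt)) {
      can <- atss[atss$is_canonical, , drop = FALSE]
      cm <- match(talt$gene_id, can$gene_id)
      poly <- ltpm + htpm
      r <- truncation_impact(poly[talt$cluster_id],
                             poly[can$cluster_id[cm]], p$trunc_threshold)
      # promoter-shift magnitude folding in the within-disease prominence
      tcl1_tpm <- rowMeans(tpm_mat[, cond == "TCL1", drop = FALSE])
      de_m <- match(talt$cluster_id, de$unit_id)
      ratio_l2 <- log2((tcl1_tpm[talt$cluster_id] + 1) /
                         (tcl1_tpm[can$cluster_id[cm]] + 1))
      trunc <- data.frame(gene_id = talt$gene_id,
                          alt_cluster_id = talt$cluster_id,
                          canonical_cluster_id = can$cluster_id[cm],
                          r, condition_log2_fc = de$log2_fc[de_m],
                          alt_vs_canonical_log2 = ratio_l2,
                          inclusive_log2_fc =
                            inclusive_log_fc(de$log2_fc[de_m], ratio_l2),
                          stringsAsFactors = FALSE)
    }
    occ <- fraction_occupancy_by_category(
      ftpm[te_tab$cluster_id], ltpm[te_tab$cluster_id],
      htpm[te_tab$cluster_id],
      annotated$category[match(te_tab$cluster_id, annotated$cluster_id)])
    translation <- list(te = te_tab, pairs = pairs, truncation = trunc,
                        occupancy = occ)
  }

  startseq <- NULL
  if (p$run_startseq && have_fracs) {
    ct <- ctss_te_table(free_tr, light_tr, heavy_tr, dataset$genome,
                        p$kmer_k, p$te_pseudocount, p$min_tpm)
    # cap-proximal analysis covers mRNA starts: keep CTSSs inside the TSS
    # cluster set, excluding enhancer arms (eRNAs are analysed separately)
    ct_gr <- GenomicRanges::GRanges(ct$chrom,
                                    IRanges::IRanges(ct$pos + 1L, width = 1L),
                                    strand = ct$strand)
    cl_gr <- GenomicRanges::GRanges(tss_clusters$chrom,
                                    IRanges::IRanges(tss_clusters$start + 1L,
                                                     tss_clusters$end),
                                    strand = tss_clusters$strand)
    ct <- ct[S4Vectors::queryHits(GenomicRanges::findOverlaps(ct_gr, cl_gr)), ,
             drop = FALSE]
    w <- ct$free_tpm + ct$polysome_tpm
    startseq <- list(
      ctss_te = ct,
      nt_freq = start_nt_frequencies(substr(ct$kmer, 1, 1), w),
      kmer_te = te_by_start_kmer(ct$kmer, ct$te, w, p$min_support),
      nt_te = te_by_start_kmer(substr(ct$kmer, 1, 1), ct$te, w,
                               p$min_support))
  }

  motifs <- NULL
  if (p$run_motifs && nrow(alt)) {
    mf <- if (is.null(p$motif_file))
      system.file("extdata", "synthetic_motifs.jaspar", package = "polycage")
    else p$motif_file
    pfms <- read_jaspar_pfm(mf)
    de_up <- de$unit_id[de$status == "up"]
    fg_ids <- intersect(alt$cluster_id, de_up)
    bg_ids <- setdiff(de_up, fg_ids)
    if (length(fg_ids) >= 2 && length(bg_ids) >= 2) {
      cl <- annotated[match(c(fg_ids, bg_ids), annotated$cluster_id), ]
      win <- tss_windows(dataset$genome, cl$chrom, cl$peak, cl$strand,
                         p$motif_up, p$motif_down)
      names(win) <- cl$cluster_id
      occm <- motif_occurrence(win[!is.na(win)], pfms,
                               p$motif_rel_threshold)
      fg_occ <- occm[rownames(occm) %in% fg_ids, , drop = FALSE]
      bg_occ <- occm[rownames(occm) %in% bg_ids, , drop = FALSE]
      if (nrow(fg_occ) && nrow(bg_occ))
        motifs <- list(enrichment = enrichment_fisher(fg_occ, bg_occ),
                       occurrence = occm)
    }
  }

  summary <- list(
    n_clusters = nrow(tss_clusters),
    category_counts = table(annotated$category),
    shape_counts = table(annotated$shape),
    n_enhancers = nrow(enhancers),
    erna_fractions = erna_frac,
    n_links = if (is.null(links)) 0L else nrow(links),
    de_up = sum(de$status == "up"), de_down = sum(de$status == "down"),
    n_genes_expressed = length(unique(atss$gene_id)),
    n_multi_tss_genes = length(unique(atss$gene_id[atss$multi_tss])),
    multi_tss_fraction = if (nrow(atss))
      length(unique(atss$gene_id[atss$multi_tss])) /
        length(unique(atss$gene_id)) else NA_real_,
    dtu_up = sum(dtu$significant & dtu$direction == "up" & !dtu$is_canonical),
    dtu_down = sum(dtu$significant & dtu$direction == "down" & !dtu$is_canonical),
    te_class_counts = if (!is.null(translation))
      table(factor(translation$pairs$te_class,
                   c("diff_high", "diff_low", "neutral"))) else NULL,
    truncation_counts = if (!is.null(translation) &&
                              !is.null(translation$truncation))
      table(factor(translation$truncation$impact,
                   c("substantial", "sparse"))) else NULL,
    nt_te_medians = if (!is.null(startseq))
      stats::setNames(startseq$nt_te$median_te, startseq$nt_te$kmer) else NULL,
    n_enriched_motifs = if (!is.null(motifs))
      sum(motifs$enrichment$fdr < p$alpha) else NA_integer_,
    pca_var_explained = qc$pca$var_explained)

  list(params = p, clusters = annotated, atss = atss, alt = alt,
       enhancers = enhancers, links = links, de = de, dtu = dtu, qc = qc,
       counts = counts, tpm = tpm_mat, translation = translation,
       startseq = startseq, motifs = motifs, summary = summary)
}

# Pair each retained alternative TSS with its gene's canonical TSS and
# apply the twofold High/Low-TE rule.
build_te_pairs <- function(atss, te_tab, fold = 2) {
  can <- atss[atss$is_canonical & atss$multi_tss, , drop = FALSE]
  alt <- atss[!atss$is_canonical, , drop = FALSE]
  cm <- match(alt$gene_id, can$gene_id)
  te <- stats::setNames(te_tab$te, te_tab$cluster_id)
  te_alt <- te[alt$cluster_id]; te_can <- te[can$cluster_id[cm]]
  ok <- !is.na(te_alt) & !is.na(te_can)
  data.frame(gene_id = alt$gene_id[ok],
             canonical_cluster_id = can$cluster_id[cm][ok],
             alt_cluster_id = alt$cluster_id[ok],
             te_canonical = unname(te_can[ok]), te_alt = unname(te_alt[ok]),
             te_class = classify_differential_te(te_alt[ok], te_can[ok], fold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Arithmetic summaries of differential-usage counts
#'
#' Small helpers for headline figures derived from count pairs: the
#' percentage excess of upregulated over downregulated events, the
#' percentage of multi-promoter genes, the purine share of start
#' nucleotides and the total of differentially translated events.
#'
#' @param n_up,n_down event counts.
#' @return percentage (numeric scalar).
#' @export
pct_excess <- function(n_up, n_down) 100 * (n_up - n_down) / n_down

#' @rdname pct_excess
#' @param n_multi,n_total gene counts.
#' @export
pct_of_total <- function(n_multi, n_total) 100 * n_multi / n_total

#' @rdname pct_excess
#' @param freq named frequency vector over `A`,`C`,`G`,`T` (shares or
#'   percentages).
#' @export
purine_share <- function(freq) unname(freq["A"] + freq["G"])
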