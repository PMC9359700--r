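#' Per-cluster translation efficiency from polysome fractions
#'
#' TE is the ratio of translated to untranslated signal:
#' `(polysome_tpm + eps) / (free_tpm + eps)` with `polysome = light +
#' heavy` and a pseudocount `eps` in TPM. Each fraction is TPM-normalized
#' within itself so differing fraction sequencing depths cancel. Clusters
#' whose summed TPM over the three fractions falls below `min_total_tpm`
#' are excluded.
#'
#' @param free_tpm,light_tpm,heavy_tpm numeric vectors of per-unit TPM in
#'   each fraction (same order; names = unit ids).
#' @param pseudocount `eps` in TPM (default 1).
#' @param min_total_tpm expression floor over the three fractions
#'   (default 1).
#' @return data.frame: `cluster_id`, `free_tpm`, `light_tpm`, `heavy_tpm`,
#'   `polysome_tpm`, `te`.
#' @export
compute_te <- function(free_tpm, light_tpm, heavy_tpm,
                       pseudocount = 1, min_total_tpm = 1) {
  if (is.null(free_tpm) || is.null(light_tpm) || is.null(heavy_tpm))
    stop("all three fraction tracks (Free, Light, Heavy) are required")
  stopifnot(length(free_tpm) == length(light_tpm),
            length(free_tpm) == length(heavy_tpm))
  ids <- names(free_tpm)
  if (is.null(ids)) ids <- as.character(seq_along(free_tpm))
  poly <- light_tpm + heavy_tpm
  keep <- (free_tpm + poly) >= min_total_tpm
  data.frame(cluster_id = ids[keep],
             free_tpm = free_tpm[keep], light_tpm = light_tpm[keep],
             heavy_tpm = heavy_tpm[keep], polysome_tpm = poly[keep],
             te = (poly[keep] + pseudocount) / (free_tpm[keep] + pseudocount),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential High/Low-TE classification of paired isoforms
#'
#' Within a gene's (canonical, alternative) TSS pair, the alternative is
#' `diff_high` iff its TE is at least `fold` times the canonical TE,
#' `diff_low` iff at most the canonical TE divided by `fold`, otherwise
#' `neutral`.
#'
#' @param te_alt,te_canonical numeric TE vectors (paired).
#' @param fold fold-change rule (default 2).
#' @return character vector in `{"diff_high","diff_low","neutral"}`.
#' @export
classify_differential_te <- function(te_alt, te_canonical, fold = 2) {
  ifelse(te_alt >= fold * te_canonical, "diff_high",
         ifelse(te_alt <= te_canonical / fold, "diff_low", "neutral"))
}

#' Translated truncation impact of an intra-genic alternative TSS
#'
#' The polysome-fraction signal of an ORF-truncating alternative TSS is
#' compared with its gene's canonical TSS: when the alternative reaches at
#' least `threshold` (default 50%) of the canonical polysome signal, the
#' truncated isoform is considered to substantially affect the function of
#' the full-length protein; below it the truncation is sparse. A zero
#' canonical polysome signal yields an infinite ratio, labelled
#' substantial and flagged.
#'
#' @param alt_polysome_tpm,canonical_polysome_tpm polysome-fraction TPM of
#'   the alternative and canonical clusters (vectors, paired).
#' @param threshold impact threshold on the ratio (default 0.5).
#' @return data.frame: `polysome_ratio`, `impact`, `flagged`.
#' @export
truncation_impact <- function(alt_polysome_tpm, canonical_polysome_tpm,
                              threshold = 0.5) {
  ratio <- ifelse(canonical_polysome_tpm > 0,
                  alt_polysome_tpm / canonical_polysome_tpm, Inf)
  data.frame(polysome_ratio = ratio,
             impact = ifelse(ratio >= threshold, "substantial", "sparse"),
             flagged = !is.finite(ratio))
}

#' Inclusive log fold change of a promoter shift
#'
#' Combines the magnitude of a promoter shift with the within-condition
#' prominence of the new isoform: the condition log2 fold change of the
#' alternative TSS plus the log2 ratio of alternative to canonical
#' expression in the disease condition. Both addends are additive on the
#' log scale, so the score is linear in each.
#'
#' @param condition_log2_fc condition (disease vs control) log2 FC of the
#'   alternative TSS.
#' @param alt_vs_canonical_log2 log2 of the alternative/canonical TPM
#'   ratio within the disease condition.
#' @return numeric: the inclusive log2 fold change.
#' @export
inclusive_log_fc <- function(condition_log2_fc, alt_vs_canonical_log2) {
  condition_log2_fc + alt_vs_canonical_log2
}

#' Fraction occupancy (Free/Light/Heavy shares) by genomic category
#'
#' For each gene-structure category, the share of each polysome fraction
#' in the category's total TPM. Rows sum to 1.
#'
#' @param free_tpm,light_tpm,heavy_tpm per-cluster fraction TPM vectors.
#' @param category per-cluster category labels.
#' @return matrix categories x fractions of shares.
#' @export
fraction_occupancy_by_category <- function(free_tpm, light_tpm, heavy_tpm,
                                           category) {
  cats <- sort(unique(category))
  out <- t(vapply(cats, function(cc) {
    i <- category == cc
    tot <- c(Free = sum(free_tpm[i]), Light = sum(light_tpm[i]),
             Heavy = sum(heavy_tpm[i]))
    if (sum(tot) == 0) rep(NA_real_, 3) else tot / sum(tot)
  }, numeric(3)))
  rownames(out) <- cats
  colnames(out) <- c("Free", "Light", "Heavy")
  out
}
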