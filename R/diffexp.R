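#' Median-of-ratios size factors
#'
#' Library-size normalization: for each sample, the median ratio of its
#' counts to the per-unit geometric mean, computed over units positive in
#' every sample. Falls back to total-count scaling when no unit is
#' all-positive.
#'
#' @param counts units x samples integer matrix.
#' @return numeric size factor per sample, geometric mean 1.
#' @export
size_factors_mor <- function(counts) {
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (any(use)) {
    sf <- apply(counts[use, , drop = FALSE], 2, function(k)
      exp(stats::median(log(k) - loggeo[use])))
  } else {
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(pmax(tot, 1))))
  }
  sf / exp(mean(log(sf)))
}

#' Per-unit NB dispersion estimates with common-value shrinkage
#'
#' Method-of-moments dispersions on size-factor-normalized counts: for
#' each unit, the residual variance around per-condition means is
#' decomposed into a Poisson part and an overdispersion part
#' (`Var = mu/sf + alpha mu^2`). Per-unit estimates are shrunk toward the
#' common (median) dispersion by a weighted average, reflecting their low
#' degrees of freedom at small replicate numbers, and floored at 1e-8.
#'
#' @param counts units x samples matrix.
#' @param condition character/factor per sample (>= 2 levels, >= 2
#'   replicates each).
#' @param shrink_weight weight on the common dispersion in `[0,1]`
#'   (default 0.8).
#' @param sf optional size factors (computed if missing).
#' @return list: `dispersion` (shrunk, per unit), `raw`, `common`.
#' @export
estimate_dispersions <- function(counts, condition, shrink_weight = 0.8,
                                 sf = NULL) {
  condition <- as.character(condition)
  tab <- table(condition)
  if (any(tab < 2)) stop("need >= 2 replicates per condition")
  if (is.null(sf)) sf <- size_factors_mor(counts)
  q <- sweep(counts, 2, sf, "/")
  G <- length(tab); n <- ncol(counts)
  fitted <- matrix(0, nrow(counts), n)
  for (g in names(tab)) {
    idx <- condition == g
    fitted[, idx] <- rowMeans(q[, idx, drop = FALSE])
  }
  resid2 <- (q - fitted)^2
  var_hat <- rowSums(resid2) / (n - G)
  mu_bar <- rowMeans(fitted)
  inv_sf <- mean(1 / sf)
  raw <- (var_hat - mu_bar * inv_sf) / pmax(mu_bar, 1e-8)^2
  raw <- pmax(raw, 1e-8)
  # the mean (not median) of the low-df moment estimates is unbiased for
  # the common dispersion; a median would sit ~30% low at 2 residual df
  expressed <- mu_bar > 1
  common <- if (any(expressed)) mean(raw[expressed]) else mean(raw)
  common <- max(common, 1e-8)
  disp <- pmax(shrink_weight * common + (1 - shrink_weight) * raw, 1e-8)
  list(dispersion = disp, raw = raw, common = common)
}

# Group means, log2 fold change and its Wald standard error for one or
# more units under the NB model with known dispersion and size factors.
# The SE is evaluated at the pooled mean (score-test style) and inflated
# by 5% as a finite-replicate correction; both choices keep the test
# calibrated at two replicates per group.
nb_group_stats <- function(counts, condition, sf, disp,
                           ref = "WT", alt = "TCL1") {
  counts <- rbind(counts)  # keep matrix form for single units
  q <- sweep(counts, 2, sf, "/")
  i1 <- condition == ref; i2 <- condition == alt
  n1 <- sum(i1); n2 <- sum(i2)
  mu1 <- rowMeans(q[, i1, drop = FALSE])
  mu2 <- rowMeans(q[, i2, drop = FALSE])
  mu0 <- (mu1 + mu2) / 2
  var_mu1 <- (mu0 * sum(1 / sf[i1]) + disp * mu0^2 * n1) / n1^2
  var_mu2 <- (mu0 * sum(1 / sf[i2]) + disp * mu0^2 * n2) / n2^2
  eps <- 0.5  # moderation offset on normalized scale
  l2fc <- log2(mu2 + eps) - log2(mu1 + eps)
  se <- 1.05 * sqrt(var_mu1 + var_mu2) / ((mu0 + eps) * log(2))
  list(mu1 = mu1, mu2 = mu2, l2fc = l2fc, se = se)
}

#' Negative binomial Wald test for two-group differential expression
#'
#' Tests each unit (tag cluster or gene) for a condition effect under an
#' NB model with shrunk moment dispersions, after median-of-ratios
#' normalization. P-values from a two-sided Wald z statistic on the log2
#' fold change; Benjamini-Hochberg FDR; status called at `fdr < alpha`.
#' All-zero units are excluded with a message.
#'
#' @param counts units x samples matrix with rownames.
#' @param condition per-sample condition labels.
#' @param alpha FDR cutoff for up/down status (default 0.05).
#' @param ref,alt condition labels; fold changes are `alt` vs `ref`.
#' @param shrink_weight passed to [estimate_dispersions()].
#' @return data.frame: `unit_id`, `base_mean`, `log2_fc`, `p_value`,
#'   `fdr`, `status`.
#' @export
de_test <- function(counts, condition, alpha = 0.05,
                    ref = "WT", alt = "TCL1", shrink_weight = 0.8) {
  condition <- as.character(condition)
  nz <- rowSums(counts) > 0
  if (any(!nz))
    message(sum(!nz), " all-zero unit(s) excluded from DE testing")
  counts <- counts[nz, , drop = FALSE]
  sf <- size_factors_mor(counts)
  disp <- estimate_dispersions(counts, condition, shrink_weight, sf)$dispersion
  st <- nb_group_stats(counts, condition, sf, disp, ref, alt)
  z <- st$l2fc / st$se
  p <- 2 * stats::pnorm(-abs(z))
  fdr <- stats::p.adjust(p, "BH")
  status <- ifelse(fdr < alpha & st$l2fc > 0, "up",
                   ifelse(fdr < alpha & st$l2fc < 0, "down", "unchanged"))
  data.frame(unit_id = rownames(counts),
             base_mean = (st$mu1 + st$mu2) / 2,
             log2_fc = st$l2fc, p_value = p, fdr = fdr, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential TSS usage (promoter shifting) within multi-TSS genes
#'
#' For every retained cluster of a multi-TSS gene, the shift effect is the
#' cluster's condition log2 fold change minus the gene-level fold change
#' (counts summed over the gene's retained clusters): a nonzero value
#' means the cluster's share of the gene moved between conditions. The
#' Wald p-value contrasts the cluster against the rest of the gene (the
#' two are independent under the NB model), with variances from the
#' shrunk-dispersion fits; BH FDR is applied over all tested clusters.
#' Genes with fewer than two retained clusters are skipped.
#'
#' @param counts clusters x samples count matrix (rownames = cluster ids).
#' @param condition per-sample condition labels.
#' @param atss data.frame from [designate_canonical_and_alternatives()].
#' @param alpha FDR cutoff (default 0.05).
#' @param ref,alt condition labels.
#' @return data.frame: `gene_id`, `cluster_id`, `is_canonical`,
#'   `atss_log2_fc`, `p_value`, `fdr`, `direction`.
#' @export
dtu_test <- function(counts, condition, atss, alpha = 0.05,
                     ref = "WT", alt = "TCL1") {
  condition <- as.character(condition)
  multi <- atss[atss$multi_tss, , drop = FALSE]
  multi <- multi[multi$cluster_id %in% rownames(counts), , drop = FALSE]
  genes <- unique(multi$gene_id)
  sf <- size_factors_mor(counts)
  disp_all <- estimate_dispersions(counts, condition, sf = sf)
  out <- list()
  for (g in genes) {
    rows <- multi$cluster_id[multi$gene_id == g]
    if (length(rows) < 2) next
    sub <- counts[rows, , drop = FALSE]
    gene_tot <- colSums(sub)
    st_gene <- nb_group_stats(gene_tot, condition, sf,
                              disp_all$common, ref, alt)
    for (cid in rows) {
      ci <- sub[cid, ]
      rest <- gene_tot - ci
      d <- disp_all$dispersion[match(cid, rownames(counts))]
      st_c <- nb_group_stats(ci, condition, sf, d, ref, alt)
      st_r <- nb_group_stats(rest, condition, sf, disp_all$common, ref, alt)
      effect <- st_c$l2fc - st_gene$l2fc
      zstat <- (st_c$l2fc - st_r$l2fc) / sqrt(st_c$se^2 + st_r$se^2)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, cluster_id = cid,
        is_canonical = multi$is_canonical[multi$cluster_id == cid][1],
        atss_log2_fc = unname(effect),
        p_value = unname(2 * stats::pnorm(-abs(zstat))),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), cluster_id = character(),
                      is_canonical = logical(), atss_log2_fc = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      direction = character()))
  res <- do.call(rbind, out)
  res$fdr <- stats::p.adjust(res$p_value, "BH")
  res$direction <- ifelse(res$atss_log2_fc > 0, "up", "down")
  res$significant <- res$fdr < alpha
  res
}

#' Sample-level PCA on variance-stabilized expression
#'
#' Singular value decomposition of the sample x unit matrix of centered
#' log2(TPM+1) values. Returns sample coordinates and the fraction of
#' variance explained per component.
#'
#' @param expr units x samples matrix (TPM or counts).
#' @param log_transform apply log2(x+1) first (default TRUE).
#' @return list: `scores` (samples x components), `var_explained`.
#' @export
sample_pca <- function(expr, log_transform = TRUE) {
  if (ncol(expr) < 3) stop("need >= 3 samples for PCA")
  x <- t(if (log_transform) log2(expr + 1) else expr)
  x <- sweep(x, 2, colMeans(x))
  if (all(abs(x) < 1e-12)) stop("constant matrix has no principal components")
  sv <- svd(x)
  k <- min(nrow(x) - 1L, ncol(x))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- colnames(expr)
  colnames(scores) <- paste0("PC", seq_len(k))
  ve <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  list(scores = scores, var_explained = ve)
}
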