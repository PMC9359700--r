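#' Read position frequency matrices in JASPAR text format
#'
#' Parses the JASPAR 2016+ flat format: a `>ID NAME` header followed by
#' four count rows labelled `A`, `C`, `G`, `T` (any order), each of the
#' form `A  [ 4 19 0 ... ]`. Rows are reordered to A,C,G,T by their
#' labels.
#'
#' @param path JASPAR-format text file.
#' @return named list of `pfm` objects (4 x L count matrices with
#'   attributes `motif_id`, `name`).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR records in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (h in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[h]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    motif_id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else motif_id
    body <- lines[(heads[h] + 1L):(bounds[h + 1L] - 1L)]
    rows <- list()
    for (ln in body) {
      m <- regmatches(ln, regexec("^\\s*([ACGT])\\s*\\[?\\s*([0-9. \\t]+)\\]?\\s*$", ln))[[1]]
      if (length(m) != 3)
        stop("unparseable PFM row for motif ", motif_id, ": '", ln, "'")
      rows[[m[2]]] <- as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]])
    }
    if (!all(c("A", "C", "G", "T") %in% names(rows)))
      stop("motif ", motif_id, " is missing a base row (need A,C,G,T)")
    lens <- vapply(rows, length, 0L)
    if (length(unique(lens)) != 1)
      stop("motif ", motif_id, " has rows of unequal length")
    mat <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
    if (any(mat < 0) || any(colSums(mat) <= 0))
      stop("motif ", motif_id, " has invalid counts")
    out[[motif_id]] <- structure(mat, motif_id = motif_id, name = name,
                                 class = "pfm")
  }
  out
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("pfm %s (%s), length %d\n", attr(x, "motif_id"),
              attr(x, "name"), ncol(x)))
  print(unclass(x))
  invisible(x)
}

#' Convert a PFM to a log-odds position weight matrix
#'
#' Per cell: `log2(((count + pc * bg) / (colsum + pc)) / bg)` with
#' pseudocount `pc` distributed by the background frequencies.
#'
#' @param pfm a 4 x L count matrix (rows A,C,G,T).
#' @param pseudocount total pseudocount per column (default 0.8).
#' @param background base frequencies (default uniform); must be
#'   positive.
#' @return 4 x L numeric log2-odds matrix.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (any(background <= 0)) stop("background frequencies must be positive")
  cs <- colSums(pfm)
  prob <- sweep(pfm + pseudocount * background, 2, cs + pseudocount, "/")
  log2(prob / background)
}

#' Scan a sequence window for a motif
#'
#' Scores every offset of `pwm` on both strands of the window and reports
#' the best relative score `(score - min) / (max - min)`, where min/max
#' are the lowest and highest scores the matrix can produce. The motif is
#' present iff the best relative score reaches `rel_threshold`. Windows
#' shorter than the motif are reported absent and flagged.
#'
#' @param sequence character scalar (ACGT window).
#' @param pwm log-odds matrix from [pfm_to_pwm()].
#' @param rel_threshold relative-score presence cutoff (default 0.85).
#' @return list: `present`, `best_relative_score`, `best_offset` (0-based,
#'   forward-strand coordinates), `best_strand`, `flagged`.
#' @export
scan_window <- function(sequence, pwm, rel_threshold = 0.85) {
  L <- ncol(pwm)
  if (is.na(sequence) || nchar(sequence) < L)
    return(list(present = FALSE, best_relative_score = NA_real_,
                best_offset = NA_integer_, best_strand = NA_character_,
                flagged = TRUE))
  smin <- sum(apply(pwm, 2, min)); smax <- sum(apply(pwm, 2, max))
  fwd <- pwm_scores(sequence, pwm)
  rev <- pwm_scores(revcomp_chr(sequence), pwm)
  best_f <- max(fwd); best_r <- max(rev)
  if (best_f >= best_r) {
    best <- best_f; strand <- "+"; off <- which.max(fwd) - 1L
  } else {
    best <- best_r; strand <- "-"
    off <- nchar(sequence) - L - (which.max(rev) - 1L)
  }
  rel <- (best - smin) / (smax - smin)
  list(present = rel >= rel_threshold, best_relative_score = rel,
       best_offset = off, best_strand = strand, flagged = FALSE)
}

# Sliding-window PWM scores over one strand of a sequence. Non-ACGT
# positions contribute the column minimum (conservative).
pwm_scores <- function(sequence, pwm) {
  base_idx <- match(strsplit(sequence, "")[[1]], c("A", "C", "G", "T"))
  L <- ncol(pwm); n <- length(base_idx)
  nw <- n - L + 1L
  scores <- numeric(nw)
  colmin <- apply(pwm, 2, min)
  for (l in seq_len(L)) {
    idx <- base_idx[l:(l + nw - 1L)]
    contrib <- pwm[cbind(idx, l)]
    contrib[is.na(idx)] <- colmin[l]
    scores <- scores + contrib
  }
  scores
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Motif occurrence matrix over a set of windows
#'
#' Batch equivalent of [scan_window()]: scans every window with every
#' motif on both strands (the reverse strand is scored by applying the
#' reverse-complemented matrix to the forward sequence) and calls
#' presence at the relative-score threshold.
#'
#' @param windows character vector of promoter/enhancer windows (equal
#'   length; `NA` entries are reported absent).
#' @param pfms list of PFMs ([read_jaspar_pfm()]).
#' @param rel_threshold presence cutoff (default 0.85).
#' @param pseudocount passed to [pfm_to_pwm()].
#' @return logical matrix windows x motifs of presence calls.
#' @export
motif_occurrence <- function(windows, pfms, rel_threshold = 0.85,
                             pseudocount = 0.8) {
  pwms <- lapply(pfms, pfm_to_pwm, pseudocount = pseudocount)
  out <- matrix(FALSE, length(windows), length(pfms),
                dimnames = list(names(windows), names(pfms)))
  ok <- !is.na(windows)
  if (!any(ok)) return(out)
  W <- unique(nchar(windows[ok]))
  if (length(W) != 1) stop("windows must have equal length")
  idx <- matrix(match(unlist(strsplit(windows[ok], ""), use.names = FALSE),
                      c("A", "C", "G", "T")),
                nrow = sum(ok), ncol = W, byrow = TRUE)
  for (m in seq_along(pwms)) {
    pwm <- pwms[[m]]
    rc <- pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
    best <- pmax(batch_best_scores(idx, pwm), batch_best_scores(idx, rc))
    smin <- sum(apply(pwm, 2, min)); smax <- sum(apply(pwm, 2, max))
    out[ok, m] <- (best - smin) / (smax - smin) >= rel_threshold
  }
  out
}

# best sliding-window PWM score per row of a base-index matrix
batch_best_scores <- function(idx, pwm) {
  n <- nrow(idx); W <- ncol(idx); L <- ncol(pwm)
  nw <- W - L + 1L
  if (nw < 1L) return(rep(-Inf, n))
  colmin <- apply(pwm, 2, min)
  sc <- matrix(0, n, nw)
  for (l in seq_len(L)) {
    sub <- idx[, l:(l + nw - 1L), drop = FALSE]
    v <- pwm[, l][sub]
    v[is.na(v)] <- colmin[l]
    sc <- sc + matrix(v, n, nw)
  }
  sc[cbind(seq_len(n), max.col(sc, ties.method = "first"))]
}

#' Motif enrichment by one-sided Fisher's exact test
#'
#' For each motif, tests whether presence is enriched in the foreground
#' window set relative to the background set (one-sided, greater), with
#' BH FDR across motifs and a Haldane-corrected odds ratio when a zero
#' cell occurs.
#'
#' @param fg_occ,bg_occ logical occurrence matrices (windows x motifs,
#'   same motif columns). The background should exclude foreground
#'   windows.
#' @return data.frame per motif: `motif_id`, `a`, `b`, `c`, `d`
#'   (fg with/without, bg with/without), `odds_ratio`, `p_value`, `fdr`.
#' @export
enrichment_fisher <- function(fg_occ, bg_occ) {
  if (!nrow(fg_occ)) stop("empty foreground set")
  stopifnot(identical(colnames(fg_occ), colnames(bg_occ)))
  rows <- lapply(colnames(fg_occ), function(m) {
    a <- sum(fg_occ[, m]); b <- nrow(fg_occ) - a
    cc <- sum(bg_occ[, m]); d <- nrow(bg_occ) - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    or <- if (any(c(a, b, cc, d) == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    else (a * d) / (b * cc)
    data.frame(motif_id = m, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p_value, "BH")
  res[order(res$p_value), , drop = FALSE]
}

#' PCA of motif occurrence percentages across window groups
#'
#' @param occ_pct groups x motifs matrix of occurrence percentages.
#' @return list: `scores` (groups x components), `var_explained`,
#'   `loadings`.
#' @export
occurrence_pca <- function(occ_pct) {
  if (nrow(occ_pct) < 3) stop("need >= 3 groups")
  x <- sweep(occ_pct, 2, colMeans(occ_pct))
  if (all(abs(x) < 1e-12)) stop("constant occurrence matrix")
  sv <- svd(x)
  k <- min(nrow(x) - 1L, ncol(x))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(occ_pct)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
       loadings = sv$v[, seq_len(k), drop = FALSE])
}
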