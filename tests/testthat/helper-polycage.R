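# shared fixtures, built in code and memoized across test files

.fixture_env <- new.env(parent = emptyenv())

# standard small synthetic dataset + pipeline run (seed fixed)
std_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_polysome_cage(sim_config(seed = 101))
  .fixture_env$sim
}

std_run <- function() {
  if (is.null(.fixture_env$run))
    .fixture_env$run <- run_all(std_sim())
  .fixture_env$run
}

make_track <- function(pos, count, strand = "+", chrom = "chr1",
                       sample_id = "s1", condition = "WT", replicate = 1,
                       fraction = "Total") {
  ctss_track(data.frame(chrom = chrom, pos = pos, strand = strand,
                        count = count),
             sample_id, condition, replicate, fraction)
}

# one-gene annotation with an explicit UTR sequence; genome is
# utr5 + ATG + padding, gene on the plus strand starting at position 10
toy_gene_annotation <- function(utr5 = "AAATGCC") {
  u <- nchar(utr5)
  tss <- 10L
  seqs <- paste0(strrep("G", tss), utr5, "ATG", strrep("CCA", 40))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- "chr1"
  tx_end <- tss + u + 3L + 90L
  features <- data.frame(
    gene_id = "g1", tx_id = "g1.t1",
    type = c("transcript", "exon", "five_prime_utr", "start_codon", "CDS"),
    chrom = "chr1",
    start = c(tss, tss, tss, tss + u, tss + u),
    end = c(tx_end, tx_end, tss + u, tss + u + 3L, tx_end),
    strand = "+", stringsAsFactors = FALSE)
  list(annotation = build_annotation(features), genome = genome, tss = tss,
       start_codon = tss + u)
}

tracks_by_fraction <- function(tracks, fr) {
  tracks[vapply(tracks, function(t) attr(t, "fraction") == fr, TRUE)]
}

random_windows <- function(n, width, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n),
         function(i) paste(sample(alphabet, width, TRUE), collapse = ""), "")
}
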