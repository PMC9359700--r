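test_that("start k-mer extraction is strand-aware with CAGE 5' semantics", {
  genome <- Biostrings::DNAStringSet("AACGTA")
  names(genome) <- "chr1"
  expect_equal(extract_start_kmer(genome, "chr1", 2L, "+", 3), "CGT")
  expect_equal(extract_start_kmer(genome, "chr1", 4L, "-", 3), "ACG")
  expect_equal(extract_start_kmer(genome, "chr1", 0L, "+", 1), "A")
  # out of bounds in transcript direction
  expect_true(is.na(extract_start_kmer(genome, "chr1", 5L, "+", 3)))
  expect_true(is.na(extract_start_kmer(genome, "chr1", 1L, "-", 3)))
})

test_that("planted trinucleotides round-trip through the generator on both strands", {
  sim <- std_sim()
  tr <- sim$ctss_truth
  re <- extract_start_kmer(sim$genome, tr$chrom, tr$pos, tr$strand, 3)
  expect_equal(re, tr$trinuc)
  expect_true(any(tr$strand == "-"))
})

test_that("start nucleotide frequencies sum to one and respect weights", {
  expect_equal(start_nt_frequencies(c("A", "A", "A")), c(A = 1))
  f <- start_nt_frequencies(c("A", "G"), weights = c(5, 5))
  expect_equal(unname(f), c(0.5, 0.5))
  f2 <- start_nt_frequencies(c("A", "G", "C"), weights = c(6, 3, 1))
  expect_equal(sum(f2), 1)
  expect_equal(f2[["A"]] + f2[["G"]], 0.9)  # purine share is the sum
})

test_that("CNY means C-initiating with a third-position pyrimidine", {
  expect_true(classify_cny("CAC"))
  expect_true(classify_cny("CAT"))
  expect_true(classify_cny("CCT"))
  expect_false(classify_cny("CTG"))  # third base purine
  expect_false(classify_cny("AAC"))  # non-C start
  expect_equal(classify_cny(c("CGC", "GCC")), c(TRUE, FALSE))
  expect_error(classify_cny("CN"), "length-3")
  expect_error(classify_cny("CNX"), "ACGT")
})

test_that("TE-by-kmer summaries are permutation invariant and support-filtered", {
  set.seed(4)
  km <- sample(c("CAC", "AGG", "GTT"), 300, TRUE)
  te <- runif(300, 0.1, 4)
  s1 <- te_by_start_kmer(km, te, min_support = 50)
  o <- sample(300)
  s2 <- te_by_start_kmer(km[o], te[o], min_support = 50)
  expect_equal(s1, s2)
  expect_true(all(s1$q05 <= s1$q25 & s1$q25 <= s1$median_te &
                    s1$median_te <= s1$q75 & s1$q75 <= s1$q95))
  # all-equal TE: all medians equal
  s3 <- te_by_start_kmer(km, rep(2, 300), min_support = 50)
  expect_true(all(s3$median_te == 2))
  # below-support groups omitted
  s4 <- te_by_start_kmer(c(rep("AAA", 60), rep("CCC", 10)),
                         runif(70), min_support = 50)
  expect_equal(s4$kmer, "AAA")
})

test_that("k=1 summaries marginalize the k=3 groups consistently", {
  run <- std_run()
  ct <- run$startseq$ctss_te
  s3 <- te_by_start_kmer(ct$kmer, ct$te, min_support = 1)
  s1 <- te_by_start_kmer(substr(ct$kmer, 1, 1), ct$te, min_support = 1)
  for (nt in s1$kmer) {
    sub <- s3[substr(s3$kmer, 1, 1) == nt, ]
    expect_equal(sum(sub$n_ctss), s1$n_ctss[s1$kmer == nt])
  }
})

test_that("bases after a CNY start do not stratify TE under the null generator", {
  sim <- std_sim()
  ct <- suppressMessages(ctss_te_table(
    tracks_by_fraction(sim$tracks, "Free"),
    tracks_by_fraction(sim$tracks, "Light"),
    tracks_by_fraction(sim$tracks, "Heavy"),
    sim$genome, k = 5))
  cny <- ct[!is.na(ct$kmer) & classify_cny(substr(ct$kmer, 1, 3)), ]
  grp <- substr(cny$kmer, 4, 5)
  keep <- grp %in% names(which(table(grp) >= 5))
  kw <- stats::kruskal.test(cny$te[keep], factor(grp[keep]))
  expect_gt(kw$p.value, 0.01)
})

test_that("positional frequency matrices are column-normalized and localized", {
  m <- positional_frequency_matrix(c("ACGT", "ACGT"))
  expect_equal(unname(m["A", 1]), 1)
  expect_equal(unname(m["T", 4]), 1)
  expect_equal(colSums(m), rep(1, 4))
  set.seed(6)
  # planted poly-pyrimidine insert elevates C+T exactly there
  base <- random_windows(200, 30)
  planted <- paste0(substr(base, 1, 10),
                    vapply(1:200, function(i)
                      paste(sample(c("C", "T"), 11, TRUE), collapse = ""), ""),
                    substr(base, 22, 30))
  mp <- positional_frequency_matrix(planted)
  py <- mp["C", ] + mp["T", ]
  expect_true(all(py[11:21] == 1))
  expect_true(all(py[c(1:10, 22:30)] < 1))
  expect_error(positional_frequency_matrix(c("AC", "ACG")), "equal length")
})
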