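test_that("genomic categories follow the precedence and promoter pad", {
  ref <- generate_reference(sim_config(seed = 2, n_genes = 6,
                                       n_multi_tss_genes = 2,
                                       n_enhancers = 0))
  ann <- ref$annotation
  g1 <- ann$genes[1, ]  # plus strand
  g2 <- ann$genes[2, ]  # minus strand
  mk <- function(peak, strand) data.frame(cluster_id = "x", chrom = "chr1",
                                          strand = strand, peak = peak)
  # 20 bp upstream of the annotated TSS: inside the promoter pad
  r <- assign_genomic_category(mk(g1$tss - 20L, "+"), ann)
  expect_equal(r$category, "promoter")
  expect_equal(r$gene_id, g1$gene_id)
  # inside the 5' UTR
  expect_equal(assign_genomic_category(mk(g1$tss + 150L, "+"), ann)$category,
               "fiveUTR")
  # inside the first intron (downstream of exon 1, same strand)
  u1 <- g1$tss + (g1$start_codon - g1$tss) + 300L + 50L
  expect_equal(assign_genomic_category(mk(u1, "+"), ann)$category, "intron")
  # opposite strand only: antisense
  r2 <- assign_genomic_category(mk(g2$tss - 100L, "+"), ann)
  expect_equal(r2$category, "antisense")
  # outside every gene: intergenic
  expect_equal(assign_genomic_category(mk(10L, "+"), ann)$category,
               "intergenic")
})

test_that("category calls are invariant to transcript record order", {
  ref <- generate_reference(sim_config(seed = 3, n_genes = 8,
                                       n_multi_tss_genes = 4,
                                       n_enhancers = 0))
  peaks <- data.frame(cluster_id = paste0("c", 1:6), chrom = "chr1",
                      strand = rep(c("+", "-"), 3),
                      peak = ref$annotation$genes$tss[1:6] + c(0L, 0L, 60L, 60L, 700L, 700L) *
                        ifelse(ref$annotation$genes$strand[1:6] == "+", 1L, -1L))
  a1 <- assign_genomic_category(peaks, ref$annotation)
  set.seed(1)
  shuf <- ref$features[sample(nrow(ref$features)), ]
  a2 <- assign_genomic_category(peaks, build_annotation(shuf))
  expect_equal(a1$category, a2$category)
  expect_equal(a1$gene_id, a2$gene_id)
})

test_that("canonical designation applies the 10% share rule and tie-breaks", {
  base <- data.frame(
    gene_id = "g", chrom = "chr1", strand = "+",
    cluster_id = c("a", "b", "c"),
    category = c("promoter", "fiveUTR", "intron"),
    peak = c(100L, 300L, 900L))
  # shares (0.85, 0.09, 0.06): only one retained -> uni-TSS gene
  d1 <- cbind(base, pooled_tpm = c(85, 9, 6))
  r1 <- designate_canonical_and_alternatives(d1)
  expect_equal(nrow(r1), 1)
  expect_false(r1$multi_tss)
  # annotated-promoter cluster is canonical even when not the largest
  d2 <- cbind(base, pooled_tpm = c(45, 55, 0))
  r2 <- designate_canonical_and_alternatives(d2)
  expect_equal(r2$cluster_id[r2$is_canonical], "a")
  expect_true(all(r2$multi_tss))
  # expression tie without a promoter cluster: transcript-5'-most peak wins,
  # independent of row order
  d3 <- base
  d3$category <- c("fiveUTR", "fiveUTR", "intron")
  d3 <- cbind(d3, pooled_tpm = c(50, 50, 0))
  r3 <- designate_canonical_and_alternatives(d3)
  r3s <- designate_canonical_and_alternatives(d3[c(3, 1, 2), ])
  expect_equal(r3$cluster_id[r3$is_canonical], "a")
  expect_equal(r3s$cluster_id[r3s$is_canonical], "a")
})

test_that("ORF effect splits at the start codon, downstream-inclusive", {
  expect_equal(classify_orf_effect(90L, "+", 100L), "retaining")
  expect_equal(classify_orf_effect(150L, "+", 100L), "truncating")
  expect_equal(classify_orf_effect(100L, "+", 100L), "truncating")
  expect_equal(classify_orf_effect(110L, "-", 100L), "retaining")
  expect_equal(classify_orf_effect(90L, "-", 100L), "truncating")
  expect_error(classify_orf_effect(90L, "+", NA_integer_), "CDS")
})

test_that("5' UTR length and overlapping uAUG counts match direct counting", {
  toy <- toy_gene_annotation("AAATGCC")
  g <- toy$annotation$genes[1, ]
  r <- count_uaug_and_utr_length(toy$tss, g, toy$annotation, toy$genome)
  expect_equal(r$utr_length, 7L)
  expect_equal(r$n_uaug, 1L)

  toy2 <- toy_gene_annotation("ATGATGATG")
  r2 <- count_uaug_and_utr_length(toy2$tss, toy2$annotation$genes[1, ],
                                  toy2$annotation, toy2$genome)
  expect_equal(r2$n_uaug, 3L)  # overlap convention: all occurrences

  toy3 <- toy_gene_annotation("CCGGTTCC")
  r3 <- count_uaug_and_utr_length(toy3$tss, toy3$annotation$genes[1, ],
                                  toy3$annotation, toy3$genome)
  expect_equal(r3$n_uaug, 0L)

  # a shorter 5' UTR from a downstream TSS
  r4 <- count_uaug_and_utr_length(toy$tss + 4L, g, toy$annotation, toy$genome)
  expect_equal(r4$utr_length, 3L)
  expect_error(count_uaug_and_utr_length(g$start_codon + 5L, g,
                                         toy$annotation, toy$genome),
               "downstream")
})

test_that("GTF round-trips through write and read", {
  ref <- generate_reference(sim_config(seed = 4, n_genes = 4,
                                       n_multi_tss_genes = 0,
                                       n_enhancers = 0))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ref$features, f)
  ann <- read_annotation_gtf(f)
  expect_equal(ann$genes$tss, ref$annotation$genes$tss)
  expect_equal(ann$genes$start_codon, ref$annotation$genes$start_codon)
  expect_equal(nrow(ann$features), nrow(ref$features))
})
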