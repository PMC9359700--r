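cond4 <- c("WT", "WT", "TCL1", "TCL1")

test_that("dispersion estimation recovers the simulation regime", {
  set.seed(21)
  # Poisson counts: dispersions near zero
  kp <- matrix(rpois(500 * 4, 200), 500, 4)
  dp <- estimate_dispersions(kp, cond4)
  expect_lt(dp$common, 0.01)
  # NB with dispersion 0.2: common estimate within +-50% at 500 units
  kn <- matrix(rnbinom(500 * 4, mu = 200, size = 1 / 0.2), 500, 4)
  dn <- estimate_dispersions(kn, cond4)
  expect_gt(dn$common, 0.1)
  expect_lt(dn$common, 0.3)
  # identical counts across samples: floored
  ki <- matrix(50, 20, 4)
  expect_equal(unique(estimate_dispersions(ki, cond4)$raw), 1e-8)
  expect_error(estimate_dispersions(kp[, c(1, 3)], c("WT", "TCL1")),
               "2 replicates")
})

test_that("NB Wald test is calibrated, powered, and antisymmetric", {
  set.seed(100)
  mu <- rlnorm(2000, log(200), 1)
  k <- matrix(rnbinom(2000 * 4, mu = rep(mu, 4), size = 1 / 0.1), 2000, 4)
  rownames(k) <- paste0("u", 1:2000)
  de <- de_test(k, cond4)
  # null type-I error at nominal 0.05
  expect_gte(mean(de$p_value < 0.05), 0.03)
  expect_lte(mean(de$p_value < 0.05), 0.07)

  # identical counts in both groups: exact null identity
  k0 <- cbind(k[, 1], k[, 2], k[, 1], k[, 2])
  rownames(k0) <- rownames(k)
  de0 <- de_test(k0, cond4)
  expect_equal(de0$log2_fc, rep(0, nrow(de0)))
  expect_true(all(de0$p_value > 0.99))

  # planted 4-fold units at mean 200, dispersion 0.05: >= 90% power
  set.seed(7)
  k2 <- matrix(rnbinom(2000 * 4, mu = rep(mu, 4), size = 1 / 0.1), 2000, 4)
  k2[1:200, 1:2] <- rnbinom(400, mu = 200, size = 1 / 0.05)
  k2[1:200, 3:4] <- rnbinom(400, mu = 800, size = 1 / 0.05)
  rownames(k2) <- paste0("u", 1:2000)
  de2 <- de_test(k2, cond4)
  expect_gte(mean(de2$fdr[1:200] < 0.05 & de2$log2_fc[1:200] > 0), 0.9)

  # swapping condition labels negates every fold change exactly
  de_sw <- de_test(k2, c("TCL1", "TCL1", "WT", "WT"))
  expect_equal(de_sw$log2_fc, -de2$log2_fc)
  expect_equal(de_sw$p_value, de2$p_value, tolerance = 1e-12)

  # BH: FDR monotone in p and bounded
  o <- order(de2$p_value)
  expect_true(all(diff(de2$fdr[o]) >= -1e-12))
  expect_true(all(de2$fdr <= 1 & de2$fdr >= de2$p_value - 1e-12))
})

make_dtu_fixture <- function(n_genes = 60, n_shift = 20, seed = 11) {
  set.seed(seed)
  cnt <- NULL; atss <- NULL
  for (g in seq_len(n_genes)) {
    shift <- g <= n_shift
    tcA <- if (shift) 900 else 500; tcB <- if (shift) 100 else 500
    rows <- rbind(rnbinom(4, mu = c(500, 500, tcA, tcA), size = 20),
                  rnbinom(4, mu = c(500, 500, tcB, tcB), size = 20))
    rownames(rows) <- paste0("g", g, c("_A", "_B"))
    cnt <- rbind(cnt, rows)
    atss <- rbind(atss, data.frame(
      gene_id = paste0("g", g), cluster_id = paste0("g", g, c("_A", "_B")),
      is_canonical = c(TRUE, FALSE), multi_tss = TRUE))
  }
  list(counts = cnt, atss = atss)
}

test_that("DTU detects planted promoter shifts and respects shift invariance", {
  fx <- make_dtu_fixture()
  d <- dtu_test(fx$counts, cond4, fx$atss)
  alt <- d[!d$is_canonical, ]
  planted <- match(paste0("g", 1:20, "_B"), alt$cluster_id)
  # 50:50 -> 90:10 at constant gene total: alternative down, detected
  expect_gte(mean(alt$significant[planted] &
                    alt$direction[planted] == "down"), 0.9)
  # null genes stay at an FDR-consistent level
  expect_lte(mean(alt$significant[-planted]), 0.1)

  # multiplying a gene's two TSSs by a shared condition factor changes nothing
  k <- fx$counts
  k[c("g30_A", "g30_B"), 3:4] <- k[c("g30_A", "g30_B"), 3:4] * 4
  d2 <- dtu_test(k, cond4, fx$atss)
  expect_lt(abs(d2$atss_log2_fc[d2$cluster_id == "g30_B"]), 0.3)
  expect_false(d2$significant[d2$cluster_id == "g30_B"])

  # identical twofold change on both TSSs: zero shift effect
  k0 <- rbind(gA = rep(c(200, 400), each = 2), gB = rep(c(300, 600), each = 2))
  a0 <- data.frame(gene_id = "g", cluster_id = c("gA", "gB"),
                   is_canonical = c(TRUE, FALSE), multi_tss = TRUE)
  d0 <- dtu_test(k0, cond4, a0)
  expect_equal(d0$atss_log2_fc, rep(0, 2), tolerance = 1e-6)
})

test_that("permuting condition labels collapses the DTU signal", {
  fx <- make_dtu_fixture()
  # a label permutation that mixes conditions within each pseudo-group
  d_perm <- dtu_test(fx$counts, c("WT", "TCL1", "WT", "TCL1"), fx$atss)
  alt <- d_perm[!d_perm$is_canonical, ]
  expect_lte(mean(alt$significant), 0.1)
})

test_that("sample PCA matches the covariance eigendecomposition oracle", {
  set.seed(2)
  x <- matrix(rnorm(24, 10), 4, 6)  # 4 units x 6 samples
  p <- sample_pca(x, log_transform = FALSE)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  # oracle: eigendecomposition of the sample covariance
  xc <- t(x) - colMeans(t(x))[col(t(x))]
  xc <- scale(t(x), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc))
  ve_oracle <- ev$values / sum(ev$values)
  k <- length(p$var_explained)
  expect_equal(p$var_explained,
               (ev$values * (nrow(xc) - 1) / sum(ev$values * (nrow(xc) - 1)))[1:k],
               tolerance = 1e-10)
  # scores match up to sign
  sc_oracle <- xc %*% ev$vectors
  for (j in 1:2)
    expect_equal(abs(unname(p$scores[, j])), abs(unname(sc_oracle[, j])),
                 tolerance = 1e-8)

  # samples varying along one axis only: PC1 explains everything
  v <- rnorm(4)
  x1 <- outer(v, c(1, 2, 3, 4, 5, 6))
  p1 <- sample_pca(x1, log_transform = FALSE)
  expect_equal(p1$var_explained[1], 1)
  expect_error(sample_pca(matrix(5, 3, 4), log_transform = FALSE),
               "constant")
})

test_that("the NB Wald test agrees with an established NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  mu <- rlnorm(300, log(300), 1)
  fc <- rep(1, 300); fc[1:60] <- 2^runif(60, -2, 2)
  k <- cbind(rnbinom(300, mu = mu, size = 10),
             rnbinom(300, mu = mu, size = 10),
             rnbinom(300, mu = mu * fc, size = 10),
             rnbinom(300, mu = mu * fc, size = 10))
  rownames(k) <- paste0("u", 1:300)
  mine <- de_test(k, cond4)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    k, data.frame(condition = factor(cond4, c("WT", "TCL1"))), ~condition)
  res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  expect_gt(cor(mine$log2_fc, res$log2FoldChange, use = "complete.obs"),
            0.99)
  ok <- !is.na(res$padj)
  both <- mine$fdr < 0.05 & ok & res$padj < 0.05
  either <- mine$fdr < 0.05 | (ok & res$padj < 0.05)
  expect_gt(sum(both), 10)
  expect_gt(sum(both) / sum(either), 0.8)  # the two tests call the same units
  expect_equal(sign(mine$log2_fc[both]), sign(res$log2FoldChange[both]))
})
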