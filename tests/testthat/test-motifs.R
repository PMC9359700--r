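fixture_pfms <- function() {
  read_jaspar_pfm(system.file("extdata", "synthetic_motifs.jaspar",
                              package = "polycage"))
}

test_that("JASPAR text parsing honors labels, lengths and errors", {
  pfms <- fixture_pfms()
  expect_equal(length(pfms), 5)
  expect_equal(ncol(pfms$SYNM02), 8)
  expect_equal(rownames(pfms$SYNM01), c("A", "C", "G", "T"))

  f <- withr::local_tempfile(fileext = ".jaspar")
  # rows out of order are reordered by their labels
  writeLines(c(">M1 test",
               "T  [ 0 10 ]",
               "A  [ 10 0 ]",
               "G  [ 0 0 ]",
               "C  [ 0 0 ]"), f)
  m <- read_jaspar_pfm(f)$M1
  expect_equal(unname(m["A", ]), c(10, 0))
  expect_equal(unname(m["T", ]), c(0, 10))

  writeLines(c(">M2 broken", "A  [ 1 2 ]", "C  [ 1 2 ]", "G  [ 1 2 ]"), f)
  expect_error(read_jaspar_pfm(f), "M2")
  writeLines(c(">M3 ragged", "A  [ 1 2 ]", "C  [ 1 2 3 ]", "G  [ 1 2 ]",
               "T  [ 1 2 ]"), f)
  expect_error(read_jaspar_pfm(f), "M3")
})

test_that("PFM to log-odds conversion matches hand arithmetic", {
  # uniform columns: zero log-odds everywhere
  u <- matrix(25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(max(abs(pfm_to_pwm(u))), 0)
  # one-hot column: positive for the base, negative elsewhere
  oh <- matrix(c(100, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  pw <- pfm_to_pwm(oh)
  expect_gt(pw["A", 1], 0)
  expect_lt(pw["C", 1], 0)
  # two-column example against the stated formula
  m <- matrix(c(4, 3, 2, 1, 0, 0, 5, 5), 4, 2,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pw2 <- pfm_to_pwm(m, pseudocount = 0.8)
  expect_equal(unname(pw2["A", 1]), log2(((4 + 0.8 * 0.25) / (10 + 0.8)) / 0.25))
  expect_equal(unname(pw2["C", 2]), log2(((0 + 0.8 * 0.25) / (10 + 0.8)) / 0.25))
  expect_error(pfm_to_pwm(m, background = c(0, 0.5, 0.25, 0.25)),
               "positive")
})

test_that("window scanning finds consensus hits on either strand", {
  pfms <- fixture_pfms()
  pwm <- pfm_to_pwm(pfms$SYNM01)
  cons <- "TGACGTCAGC"
  set.seed(12)
  win <- paste0(random_windows(1, 40), cons, random_windows(1, 40))
  hit <- scan_window(win, pwm)
  expect_true(hit$present)
  expect_equal(hit$best_relative_score, 1.0)
  expect_equal(hit$best_offset, 40L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
  hit_rc <- scan_window(rc, pwm)
  expect_equal(hit_rc$best_relative_score, hit$best_relative_score)
  expect_true(hit_rc$present)
  # window shorter than the motif: absent, flagged
  short <- scan_window("ACGT", pwm)
  expect_false(short$present)
  expect_true(short$flagged)
  # random sequence vs a strict one-hot PWM of length 12: absent
  strict <- matrix(1, 4, 12, dimnames = list(c("A", "C", "G", "T"), NULL))
  strict[cbind(sample(4, 12, TRUE), 1:12)] <- 500
  spwm <- pfm_to_pwm(strict)
  rand_hits <- vapply(random_windows(50, 200),
                      function(w) scan_window(w, spwm)$present, TRUE)
  expect_lte(sum(rand_hits), 1)
})

test_that("batch occurrence equals per-window scanning", {
  pfms <- fixture_pfms()
  set.seed(3)
  wins <- random_windows(40, 120)
  wins[5] <- paste0(substr(wins[5], 1, 50), "TGACGTCAGC",
                    substr(wins[5], 61, 120))
  occ <- motif_occurrence(wins, pfms)
  pwms <- lapply(pfms, pfm_to_pwm)
  for (i in c(1, 5, 17)) for (m in seq_along(pwms))
    expect_equal(unname(occ[i, m]), scan_window(wins[i], pwms[[m]])$present)
  expect_true(occ[5, "SYNM01"])
})

test_that("Fisher enrichment equals the hypergeometric enumeration oracle", {
  # brute-force enumeration of the one-sided tail over all tables with
  # fixed margins
  oracle_p <- function(a, b, cc, d) {
    n_fg <- a + b; n_bg <- cc + d; k <- a + cc
    amin <- max(0, k - n_bg); amax <- min(k, n_fg)
    probs <- vapply(amin:amax, function(x)
      choose(n_fg, x) * choose(n_bg, k - x) / choose(n_fg + n_bg, k), 0)
    sum(probs[(amin:amax) >= a])
  }
  mk_occ <- function(n, with) {
    m <- matrix(c(rep(TRUE, with), rep(FALSE, n - with)), ncol = 1,
                dimnames = list(NULL, "M"))
    m
  }
  for (tab in list(c(8, 12, 10, 90), c(5, 5, 5, 5), c(12, 0, 3, 15),
                   c(0, 10, 5, 25), c(20, 0, 0, 30))) {
    e <- enrichment_fisher(mk_occ(tab[1] + tab[2], tab[1]),
                           mk_occ(tab[3] + tab[4], tab[3]))
    expect_equal(e$p_value, oracle_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
  # equal presence proportions: null table
  e0 <- enrichment_fisher(mk_occ(20, 8), mk_occ(100, 40))
  expect_gte(e0$p_value, 0.5)
  expect_lt(abs(e0$odds_ratio - 1), 0.2)
  expect_error(enrichment_fisher(mk_occ(20, 8)[0, , drop = FALSE],
                                 mk_occ(10, 1)), "foreground")
})

test_that("a motif planted in 40% of foreground vs 5% of background ranks first", {
  pfms <- fixture_pfms()
  cons <- "TGACGTCAGC"
  set.seed(31)
  plant <- function(w) paste0(substr(w, 1, 95), cons,
                              substr(w, 106, nchar(w)))
  fg <- random_windows(200, 200)
  bg <- random_windows(1000, 200)
  fg[1:80] <- vapply(fg[1:80], plant, "")          # 40%
  bg[1:50] <- vapply(bg[1:50], plant, "")          # 5%
  occ_fg <- motif_occurrence(fg, pfms)
  occ_bg <- motif_occurrence(bg, pfms)
  enr <- enrichment_fisher(occ_fg, occ_bg)
  expect_equal(enr$motif_id[1], "SYNM01")
  expect_lt(enr$p_value[1], 1e-10)
  expect_lt(enr$fdr[1], min(enr$fdr[-1]))
})

test_that("occurrence PCA separates a distinct group and matches the oracle", {
  occ <- rbind(g1 = c(10, 20, 30, 40), g2 = c(10, 20, 30, 40),
               g3 = c(80, 5, 60, 2))
  p <- occurrence_pca(occ)
  expect_gt(abs(p$scores["g3", 1] - p$scores["g1", 1]), 10)
  expect_equal(p$scores["g1", 1], p$scores["g2", 1])
  expect_true(all(diff(p$var_explained) <= 1e-12))
  set.seed(9)
  x <- matrix(runif(40, 0, 100), 4, 10)
  p2 <- occurrence_pca(x)
  ev <- eigen(stats::cov(x) * (nrow(x) - 1) / (nrow(x) - 1))
  expect_equal(p2$var_explained,
               (ev$values / sum(ev$values))[seq_along(p2$var_explained)],
               tolerance = 1e-10)
  expect_error(occurrence_pca(matrix(3, 3, 4)), "constant")
})
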