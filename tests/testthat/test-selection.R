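tab5 <- codon_table(5)
code5 <- tab5$codon_to_aa
NONSTOP <- names(code5)[code5 != "*"]

test_that("codon site counts match neighbour enumeration and conserve 3", {
  expect_equal(unname(codon_sites("TTT", tab5)), c(1 / 3, 8 / 3))
  expect_equal(unname(codon_sites("GGA", tab5)), c(1, 2))  # 4-fold third position
  for (cd in NONSTOP) {
    s <- codon_sites(cd, tab5)
    expect_equal(unname(s), ng86_sites_oracle(cd, code5),
                 tolerance = 1e-12, label = cd)
    expect_equal(sum(s), 3, tolerance = 1e-12)
  }
  expect_error(codon_sites("TAA", tab5), "stop")
  expect_error(codon_sites("TNA", tab5), "unambiguous")
})

test_that("pathway-averaged differences match the brute-force enumerator on all codon pairs", {
  for (a in NONSTOP) {
    for (b in NONSTOP) {
      d <- codon_differences(a, b, tab5)
      oracle <- ng86_diff_oracle(a, b, code5)
      expect_equal(unname(d), oracle, tolerance = 1e-12,
                   label = paste(a, b))
      k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      expect_equal(sum(d), k, tolerance = 1e-12)
    }
  }
})

test_that("pairwise Ka/Ks behaves at the identities and signs", {
  s <- "ATGAAACCCGGGTTTCTA"
  p0 <- pairwise_kaks(s, s, tab5)
  expect_equal(p0$Ka, 0); expect_equal(p0$Ks, 0)
  expect_equal(p0$S + p0$N, 3 * p0$n_codons)

  # one synonymous change: TTT -> TTC
  s2 <- sub("TTT", "TTC", s)
  p1 <- pairwise_kaks(s, s2, tab5)
  expect_equal(p1$Ka, 0)
  expect_gt(p1$Ks, 0)

  # symmetry
  set.seed(20)
  a <- paste(sample(NONSTOP, 30, replace = TRUE), collapse = "")
  b <- paste(sample(NONSTOP, 30, replace = TRUE), collapse = "")
  expect_identical(pairwise_kaks(a, b, tab5)[, 1:8],
                   pairwise_kaks(b, a, tab5)[, 1:8])

  # codons with N are skipped
  a_n <- paste0("NNN", substr(a, 4, nchar(a)))
  expect_equal(pairwise_kaks(a_n, b, tab5)$n_codons, 29)
})

test_that("pairwise Ka/Ks matches a direct NG86 reference computation", {
  # Independent route: accumulate sites and differences codon by codon with
  # the oracle helpers, then apply the correction by hand.
  set.seed(21)
  for (rep in 1:5) {
    a <- paste(sample(NONSTOP, 30, replace = TRUE), collapse = "")
    b_cod <- sample(NONSTOP, 30, replace = TRUE)
    # keep divergence moderate: copy most codons from a
    keep <- runif(30) < 0.7
    b_cod[keep] <- split_codons(a)[keep]
    b <- paste(b_cod, collapse = "")
    S <- 0; Sd <- 0; Nd <- 0
    for (i in 1:30) {
      ca <- substr(a, 3 * i - 2, 3 * i); cb <- substr(b, 3 * i - 2, 3 * i)
      S <- S + (ng86_sites_oracle(ca, code5)[1] +
                  ng86_sites_oracle(cb, code5)[1]) / 2
      d <- ng86_diff_oracle(ca, cb, code5)
      Sd <- Sd + d[1]; Nd <- Nd + d[2]
    }
    N <- 90 - S
    exp_Ks <- -0.75 * log(1 - 4 * (Sd / S) / 3)
    exp_Ka <- -0.75 * log(1 - 4 * (Nd / N) / 3)
    got <- pairwise_kaks(a, b, tab5)
    expect_equal(got$Ks, exp_Ks, tolerance = 1e-9)
    expect_equal(got$Ka, exp_Ka, tolerance = 1e-9)
  }
})

test_that("Jukes-Cantor correction is monotone and vanishes at p = 0", {
  p <- seq(0, 0.74, by = 0.01)
  d <- jukes_cantor(p)
  expect_true(all(diff(d) > 0))
  expect_equal(d[1], 0)
  expect_true(is.na(jukes_cantor(0.75)))
  expect_equal(jukes_cantor(1e-6), 1e-6, tolerance = 1e-3)
})

test_that("gene-level summaries aggregate pairs with sane degenerate policy", {
  aln <- as_alignment(c(a = "ATGAAACCC", b = "ATGAAACCC", c = "ATGAAACCC"))
  kk <- gene_kaks(aln, tab5)
  expect_equal(kk$mean_Ka, 0)
  expect_equal(kk$mean_Ks, 0)
  expect_true(is.na(kk$ratio))  # 0/0 is undefined, not 0 or 1
  expect_equal(nrow(kk$pairs), 3)
})

test_that("omega = 0 simulations yield essentially zero Ka", {
  # Pure-synonymous evolution leaves a trace of apparent Ka: NG86 pathway
  # averaging splits multi-hit codon pairs (e.g. TTA vs CTC, both Leu) over
  # orderings that pass through another amino acid. Ka must therefore be
  # tiny relative to Ks, not identically zero.
  set.seed(22)
  tr <- simulate_tree(8, "yule")
  aln <- simulate_codon_alignment(tr, 120, omega = 0)
  kk <- gene_kaks(aln, tab5)
  expect_lt(kk$mean_Ka, 0.005)
  expect_gt(kk$mean_Ks, 0.05)
  expect_lt(kk$mean_Ka, kk$mean_Ks / 20)
})

test_that("simulated omega contrasts preserve the Ka/Ks ordering", {
  hits <- 0
  for (i in 1:10) {
    set.seed(300 + i)
    tr <- simulate_tree(8, "yule")
    low <- gene_kaks(simulate_codon_alignment(tr, 150, omega = 0.1))$ratio
    high <- gene_kaks(simulate_codon_alignment(tr, 150, omega = 0.5))$ratio
    if (low < high) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
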