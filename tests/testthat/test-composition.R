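test_that("skew follows its definition and symmetry properties", {
  expect_equal(skew(1, 0), 1)
  expect_equal(skew(0, 0), 0)
  expect_equal(skew(7, 7), 0)
  expect_error(skew(-1, 2), "non-negative")
  set.seed(1)
  for (i in 1:50) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 100)
    expect_equal(skew(a, b), -skew(b, a))
    expect_lte(abs(skew(a, b)), 1)
  }
})

test_that("composition stats count, normalise and skew correctly", {
  cs <- composition_stats("AATT")
  expect_equal(unname(cs$fractions[c("A", "T")]), c(0.5, 0.5))
  expect_equal(cs$at_content, 1)
  expect_equal(cs$at_skew, 0)

  expect_equal(composition_stats("GGGC")$gc_skew, 0.5)

  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
             collapse = "")
  expect_equal(sum(composition_stats(s)$fractions), 1, tolerance = 1e-9)

  # N excluded from denominators
  cs2 <- composition_stats("AANN")
  expect_equal(unname(cs2$fractions["A"]), 1)
  expect_equal(unname(cs2$counts[["N"]]), 2)
  expect_error(composition_stats(""), "empty")
})

test_that("codon position extraction respects frame and truncation", {
  p2 <- codon_position_stats("ATGATG", 2)
  expect_equal(p2$at_skew, -1)  # position-2 residues are "TT"
  p1 <- codon_position_stats("ATGA", 1)  # incomplete tail dropped -> "A"
  expect_equal(unname(p1$fractions[["A"]]), 1)
  # partition: pooled positions equal the full codon region
  cds <- "ATGAAACCCGGGTTTTAG"
  full <- composition_stats(cds)$counts
  pooled <- Reduce(`+`, lapply(1:3, function(p)
    codon_position_stats(cds, p)$counts))
  expect_equal(pooled, full)
})

test_that("stop classification covers complete and incomplete stops", {
  expect_identical(classify_stop("ATGAAATAA"), "TAA")
  expect_identical(classify_stop("ATGAAATAG"), "TAG")
  expect_identical(classify_stop("ATGAAAT"), "T")      # len %% 3 == 1
  expect_identical(classify_stop("ATGAAATA"), "TA")    # len %% 3 == 2
  expect_identical(classify_stop("ATGAAAGG"), "other") # len %% 3 == 2, not TA
  expect_identical(classify_stop("ATGAAACCC"), "other")
  expect_identical(trim_incomplete_stop("ATGAAAT"), "ATGAAA")
})

test_that("RSCU matches the hand-applied formula and family invariants", {
  tab <- codon_table(5)
  # Phe family {TTT, TTC}: counts 3 and 1
  r <- rscu("TTTTTTTTTTTC", tab)
  expect_equal(r$rscu[r$codon == "TTT"], 1.5)
  expect_equal(r$rscu[r$codon == "TTC"], 0.5)

  # single codon of the 6-codon Leu family (CTN + TTA/TTG under table 5)
  r2 <- rscu("CTACTACTA", tab)
  expect_equal(r2$rscu[r2$codon == "CTA"], 6)

  # equal use within a family gives RSCU 1 everywhere
  r3 <- rscu("GGAGGCGGGGGT", tab)
  expect_true(all(abs(r3$rscu[r3$aa == "G"] - 1) < 1e-12))

  # family sums equal family sizes on random codon soup
  set.seed(3)
  soup <- paste(sample(names(tab$codon_to_aa)[tab$codon_to_aa != "*"],
                       600, replace = TRUE), collapse = "")
  r4 <- rscu(soup, tab)
  sums <- tapply(r4$rscu, r4$aa, sum)
  sizes <- tapply(r4$rscu, r4$aa, length)
  pos <- tapply(r4$count, r4$aa, sum) > 0
  expect_equal(as.numeric(sums[pos]), as.numeric(sizes[pos]),
               tolerance = 1e-9)
  # serine has 8 codons under the invertebrate mitochondrial code
  expect_equal(unname(sizes["S"]), 8L)
})

test_that("amino-acid usage translates under the invertebrate code", {
  au <- amino_acid_usage("ATGTGA")
  expect_equal(au$count[au$aa == "M"], 1L)
  expect_equal(au$count[au$aa == "W"], 1L)  # TGA is Trp, not stop
  expect_equal(attr(au, "total"), 2L)
  set.seed(4)
  tab <- codon_table(5)
  soup <- paste(sample(names(tab$codon_to_aa)[tab$codon_to_aa != "*"],
                       500, replace = TRUE), collapse = "")
  expect_equal(sum(amino_acid_usage(soup)$percent), 100, tolerance = 0.01)
})

test_that("the invertebrate code differs from the standard code at exactly four codons", {
  t5 <- codon_table(5)$codon_to_aa
  t1 <- codon_table(1)$codon_to_aa
  diff <- names(t5)[t5 != t1]
  expect_setequal(diff, c("ATA", "TGA", "AGA", "AGG"))
  expect_identical(unname(t5[c("ATA", "TGA", "AGA", "AGG")]),
                   c("M", "W", "S", "S"))
})

test_that("per-gene codon summaries agree with pooled tallies", {
  gb <- make_toy_genbank(toy_genbank_config(seed = 8))
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tf)
  rec <- read_genbank(tf)
  cu <- codon_usage_summary(rec)
  expect_equal(nrow(cu), 3)  # three planted CDS
  expect_setequal(cu$stop_status[cu$gene %in% c("nad2", "cytb")], "TAA")
  expect_identical(cu$stop_status[cu$gene == "cox1"], "T")
  rep <- run_composition_report(list(rec))
  expect_equal(sum(rep$stop_tally$percent), 100)
  expect_equal(sum(rep$stop_tally$count), nrow(cu))
})
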