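test_that("toy GenBank records round-trip through the parser", {
  gb <- make_toy_genbank(toy_genbank_config(seed = 11))
  truth <- attr(gb, "truth")
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tf)
  rec <- read_genbank(tf)

  expect_s3_class(rec, "mitogenome_record")
  expect_identical(rec$length_bp, 2000L)
  expect_true(rec$is_circular)
  expect_identical(rec$sequence, truth$genome)
  expect_length(rec$features, 5)

  # every planted feature is recovered exactly (coding strand)
  for (g in c("cox1", "nad2", "rrnL", "trnS2", "cytb"))
    expect_identical(extract_gene(rec, g), truth[[g]]$coding)

  # hand-splice the origin-spanning join: suffix + prefix of the genome
  expect_identical(extract_gene(rec, "cytb"),
                   paste0(substr(truth$genome, 1901, 2000),
                          substr(truth$genome, 1, 98)))
  # hand-splice the complement feature
  expect_identical(extract_gene(rec, "nad2"),
                   reverse_complement(substr(truth$genome, 601, 912)))
})

test_that("feature intervals follow the 0-based half-open convention", {
  gb <- make_toy_genbank(toy_genbank_config(seed = 3))
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tf)
  rec <- read_genbank(tf)
  for (f in rec$features) {
    spans <- f$intervals[, "end"] - f$intervals[, "start"]
    expect_identical(nchar(extract_feature(rec, f)), as.integer(sum(spans)))
    # round trip through GenBank 1-based inclusive printing
    gb1 <- cbind(f$intervals[, "start"] + 1L, f$intervals[, "end"])
    back <- cbind(gb1[, 1] - 1L, gb1[, 2])
    expect_identical(unname(back), unname(f$intervals))
  }
})

test_that("records without features parse to an empty feature list", {
  lines <- c(
    "LOCUS       BARE0001              30 bp    DNA     linear INV 01-JAN-2024",
    "ACCESSION   BARE0001",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac",
    "//")
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(lines, tf)
  rec <- read_genbank(tf)
  expect_length(rec$features, 0)
  expect_identical(rec$length_bp, 30L)
  expect_false(rec$is_circular)
})

test_that("malformed GenBank input fails with a located parse error", {
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("not a genbank file"), tf)
  expect_error(read_genbank(tf), "line 1")

  lines <- c(
    "LOCUS       BAD00001              20 bp    DNA     linear INV 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..40",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt",
    "//")
  writeLines(lines, tf)
  expect_error(suppressWarnings(read_genbank(tf)), "coordinate error")
})

test_that("gene labels normalize across common synonyms", {
  expect_identical(normalize_gene_name("COI", "PCG"), "cox1")
  expect_identical(normalize_gene_name("COX1", "PCG"), "cox1")
  expect_identical(normalize_gene_name("cytochrome c oxidase subunit II", "PCG"),
                   "cox2")
  expect_identical(normalize_gene_name("ND2", "PCG"), "nad2")
  expect_identical(normalize_gene_name("ND4L", "PCG"), "nad4L")
  expect_identical(normalize_gene_name("NADH dehydrogenase subunit 5", "PCG"),
                   "nad5")
  expect_identical(normalize_gene_name("CYTB", "PCG"), "cytb")
  expect_identical(normalize_gene_name("COB", "PCG"), "cytb")
  expect_identical(normalize_gene_name("ATPase8", "PCG"), "atp8")
  expect_identical(normalize_gene_name("12S ribosomal RNA", "rRNA"), "rrnS")
  expect_identical(normalize_gene_name("l-rRNA", "rRNA"), "rrnL")
  expect_identical(normalize_gene_name("tRNA-Ala", "tRNA"), "trnA")
  expect_identical(normalize_gene_name("tRNA-Ser", "tRNA", anticodon = "TGA"),
                   "trnS2")
  expect_identical(normalize_gene_name("tRNA-Ser", "tRNA", anticodon = "GCT"),
                   "trnS1")
  expect_identical(normalize_gene_name("trnL2", "tRNA"), "trnL2")
  expect_warning(out <- normalize_gene_name("hypothetical ORF", "other"),
                 "unrecognized")
  expect_identical(out, "other")
})

test_that("reverse complement is a length-preserving involution", {
  set.seed(42)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:50, 1), replace = TRUE),
               collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(nchar(reverse_complement(s)), nchar(s))
  }
  expect_identical(reverse_complement("ATGC"), "GCAT")
})

test_that("FASTA writing and reading round-trips sequences and names", {
  seqs <- c(alpha = "ACGTACGTACGT", beta = "TTTTAAAACCCC",
            gamma = strrep("ACGT", 40))
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, tf)
  back <- read_fasta(tf)
  expect_identical(back, seqs)
})

test_that("alignment reading enforces rectangular unique-taxon input", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(a = "ACGTACGTAC", b = "ACGTACGTA"), tf)
  expect_error(read_alignment(tf), "ragged")

  writeLines(c(">dup", "ACGT", ">dup", "ACGT"), tf)
  expect_error(read_fasta(tf), "duplicate")

  writeLines(character(0), tf)
  expect_error(read_fasta(tf), "empty")
})

test_that("duplicated genes are kept with copy suffixes", {
  genes <- data.frame(
    name = c("cox1", "cox1"), raw_label = c("COI", "COI"),
    key = c("CDS", "CDS"), start0 = c(100L, 600L), len = c(300L, 300L),
    strand = c("plus", "plus"), stop_tail = c("TAA", "TAA"),
    anticodon = c(NA, NA), stringsAsFactors = FALSE)
  gb <- make_toy_genbank(toy_genbank_config(seed = 5, genes = genes))
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tf)
  rec <- read_genbank(tf)
  nms <- vapply(rec$features, function(f) f$canonical_name, character(1))
  expect_setequal(nms, c("cox1", "cox1_copy2"))
  expect_no_error(extract_gene(rec, "cox1"))
})
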