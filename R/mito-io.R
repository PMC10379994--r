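# ---------------------------------------------------------------------------
# Gene nomenclature
# ---------------------------------------------------------------------------

#' Canonical mitochondrial gene names
#'
#' The 37-gene complement of a typical metazoan mitogenome: 13 protein-coding
#' genes, 2 rRNAs and 22 tRNAs (with the two serine and two leucine tRNAs
#' distinguished as trnS1/trnS2 and trnL1/trnL2).
#'
#' @return Character vector of canonical names.
#' @export
canonical_gene_names <- function() {
  pcg <- c("nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
           "cox1", "cox2", "cox3", "atp6", "atp8", "cytb")
  rrna <- c("rrnS", "rrnL")
  aa1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "M", "N", "P",
           "Q", "R", "T", "V", "W", "Y")
  trna <- c(paste0("trn", aa1), "trnS1", "trnS2", "trnL1", "trnL2")
  c(pcg, rrna, sort(trna))
}

#' Canonical names of the 13 mitochondrial protein-coding genes
#' @return Character vector.
#' @export
pcg_names <- function() {
  c("nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
    "cox1", "cox2", "cox3", "atp6", "atp8", "cytb")
}

# three-letter -> one-letter amino-acid codes used in tRNA product labels
.aa3to1 <- c(
  ala = "A", arg = "R", asn = "N", asp = "D", cys = "C", gln = "Q",
  glu = "E", gly = "G", his = "H", ile = "I", leu = "L", lys = "K",
  met = "M", phe = "F", pro = "P", ser = "S", thr = "T", trp = "W",
  tyr = "Y", val = "V"
)

#' Normalize a gene label to its canonical name
#'
#' Maps the many synonyms found in GenBank records (COI/COX1/CO1, ND2, CYTB
#' or COB, 12S rRNA, "tRNA-Ser" ...) to the canonical nomenclature returned
#' by [canonical_gene_names()]. Serine and leucine tRNAs are disambiguated by
#' the anticodon when one is supplied: anticodon GCT (AGN family) gives
#' trnS1, TGA (UCN family) trnS2, TAG (CUN family) trnL1 and TAA (UUR
#' family) trnL2. Labels that cannot be normalized return `"other"` with a
#' warning.
#'
#' @param raw_label label as read from the file (gene or product qualifier).
#' @param feature_type one of `"PCG"`, `"tRNA"`, `"rRNA"`, `"other"`.
#' @param anticodon optional anticodon sequence (DNA, 3 letters) for tRNA
#'   disambiguation.
#' @param quiet suppress the unknown-label warning.
#' @return A canonical gene name, or `"other"`.
#' @examples
#' normalize_gene_name("COI", "PCG")       # "cox1"
#' normalize_gene_name("ND4L", "PCG")      # "nad4L"
#' normalize_gene_name("tRNA-Ser", "tRNA", anticodon = "TGA")  # "trnS2"
#' @export
normalize_gene_name <- function(raw_label, feature_type = "other",
                                anticodon = NULL, quiet = FALSE) {
  stopifnot(is.character(raw_label), length(raw_label) == 1L,
            nzchar(raw_label))
  lab <- tolower(trimws(raw_label))

  # protein-coding genes ----------------------------------------------------
  if (grepl("nad4l|nd4l|nadh4l|nadh dehydrogenase subunit 4l", lab))
    return("nad4L")
  m <- regmatches(lab, regexec("^(?:mt-)?(?:nad|nadh|nd)[ -]?([1-6])", lab))[[1]]
  if (length(m)) return(paste0("nad", m[2]))
  if (grepl("nadh dehydrogenase subunit ([1-6])", lab))
    return(paste0("nad", sub(".*nadh dehydrogenase subunit ([1-6]).*", "\\1", lab)))
  if (grepl("^(?:mt-)?co(?:x)?[ -]?(i{1,3}|[1-3])\\b|cytochrome c? ?oxidase", lab)) {
    num <- if (grepl("iii|3", lab)) "3" else if (grepl("ii|2", lab)) "2" else "1"
    return(paste0("cox", num))
  }
  if (grepl("atp(?:ase)?[ -]?8|atp synthase.*(subunit )?8", lab)) return("atp8")
  if (grepl("atp(?:ase)?[ -]?6|atp synthase.*(subunit )?6", lab)) return("atp6")
  if (grepl("^cytb$|^cob$|^cyt[ -]?b\\b|cytochrome b", lab)) return("cytb")

  # rRNAs --------------------------------------------------------------------
  if (grepl("rrns|12s|s-?rrna|small subunit|ssu", lab)) return("rrnS")
  if (grepl("rrnl|16s|l-?rrna|large subunit|lsu", lab)) return("rrnL")

  # tRNAs --------------------------------------------------------------------
  tm <- regmatches(lab, regexec(
    "^trn([a-z])([12])?$|trna[ -]?([a-z]{3})|^trn([a-z])([12])?\\b", lab))[[1]]
  is_trna <- length(tm) > 0 || grepl("^trn", lab) || grepl("trna", lab)
  if (is_trna) {
    aa <- NA_character_
    suffix <- ""
    m2 <- regmatches(lab, regexec("trna[ -]?([a-z]{3})", lab))[[1]]
    if (length(m2) && m2[2] %in% names(.aa3to1)) {
      aa <- .aa3to1[[m2[2]]]
    } else {
      m1 <- regmatches(lab, regexec("^trn([a-z])([12]?)\\b", lab))[[1]]
      if (length(m1)) {
        aa <- toupper(m1[2]); suffix <- m1[3]
      }
    }
    if (!is.na(aa) && aa %in% c("S", "L")) {
      if (nzchar(suffix)) return(paste0("trn", aa, suffix))
      fam <- .trna_family_from_label(lab, anticodon)
      if (!is.na(fam)) return(paste0("trn", aa, fam))
      if (!quiet)
        warning(sprintf(
          "tRNA label %s lacks an anticodon or codon-family tag; cannot assign %s1/%s2",
          raw_label, aa, aa), call. = FALSE)
      return("other")
    }
    if (!is.na(aa) && paste0("trn", aa) %in% canonical_gene_names())
      return(paste0("trn", aa))
  }

  if (grepl("d-?loop|control region|^cr$|putative control", lab)) return("other")
  if (!quiet)
    warning(sprintf("unrecognized gene label: %s (mapped to 'other')",
                    raw_label), call. = FALSE)
  "other"
}

# Ser/Leu isoacceptor family from an anticodon or a codon-family tag in the
# label. Returns "1", "2" or NA.
.trna_family_from_label <- function(lab, anticodon) {
  if (!is.null(anticodon) && nzchar(anticodon)) {
    ac <- toupper(gsub("U", "T", anticodon))
    fam <- switch(ac, GCT = "1", TGA = "2", TAG = "1", TAA = "2", NA)
    if (!is.na(fam)) return(fam)
  }
  if (grepl("agn|agy|agc|agu", lab)) return("1")
  if (grepl("ucn|tcn|uca|ucu", lab)) return("2")
  if (grepl("cun|ctn|cua", lab)) return("1")
  if (grepl("uur|ttr|uaa|uag\\)", lab) && grepl("leu", lab)) return("2")
  NA_character_
}

# ---------------------------------------------------------------------------
# GeneFeature / MitogenomeRecord constructors
# ---------------------------------------------------------------------------

#' Construct a gene feature
#'
#' Intervals are 0-based half-open on the plus-strand frame of the stored
#' sequence; multi-interval features (joins across the origin of a circular
#' molecule) keep their intervals in splice order.
#'
#' @param canonical_name canonical gene name or `"other"`.
#' @param feature_type `"PCG"`, `"tRNA"`, `"rRNA"` or `"other"`.
#' @param intervals integer matrix with columns `start`, `end` (0-based
#'   half-open), one row per interval, in splice order.
#' @param strand `"plus"` or `"minus"`.
#' @param raw_label the label as read from the file.
#' @return An object of class `gene_feature`.
#' @export
gene_feature <- function(canonical_name, feature_type, intervals,
                         strand = "plus", raw_label = canonical_name) {
  intervals <- matrix(as.integer(intervals), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
  stopifnot(nrow(intervals) >= 1, all(intervals[, 1] < intervals[, 2]),
            strand %in% c("plus", "minus"),
            feature_type %in% c("PCG", "tRNA", "rRNA", "other"))
  if (feature_type == "PCG" && sum(intervals[, 2] - intervals[, 1]) < 3)
    stop("PCG feature spans fewer than 3 bases")
  structure(
    list(canonical_name = canonical_name, feature_type = feature_type,
         intervals = intervals, strand = strand, raw_label = raw_label),
    class = "gene_feature"
  )
}

#' Construct a mitogenome record
#'
#' @param accession accession string (non-empty).
#' @param taxon organism name.
#' @param sequence residue string over A/C/G/T/N (other ambiguity codes are
#'   mapped to N with a warning).
#' @param is_circular logical.
#' @param features list of [gene_feature()] objects.
#' @return An object of class `mitogenome_record`.
#' @export
mitogenome_record <- function(accession, taxon, sequence,
                              is_circular = TRUE, features = list()) {
  stopifnot(is.character(accession), nzchar(accession))
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    warning("ambiguity codes other than N mapped to N", call. = FALSE)
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  len <- nchar(sequence)
  for (f in features) {
    if (any(f$intervals[, 2] > len) || any(f$intervals[, 1] < 0))
      stop(sprintf("feature %s extends beyond sequence of length %d",
                   f$raw_label, len))
  }
  structure(
    list(accession = accession, taxon = taxon, sequence = sequence,
         is_circular = isTRUE(is_circular), features = features,
         length_bp = len),
    class = "mitogenome_record"
  )
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat(sprintf("<mitogenome_record> %s (%s), %d bp, %s, %d features\n",
              x$accession, x$taxon, x$length_bp,
              if (x$is_circular) "circular" else "linear",
              length(x$features)))
  invisible(x)
}

#' @export
print.gene_feature <- function(x, ...) {
  iv <- paste(apply(x$intervals, 1, function(r)
    sprintf("[%d,%d)", r[1], r[2])), collapse = "+")
  cat(sprintf("<gene_feature> %s (%s, %s strand) %s\n",
              x$canonical_name, x$feature_type, x$strand, iv))
  invisible(x)
}

# ---------------------------------------------------------------------------
# GenBank flat-file reader
# ---------------------------------------------------------------------------

# Parse a GenBank location string into intervals (0-based half-open, splice
# order) and a strand. Handles n..m, single positions, join(...),
# complement(...), complement(join(...)) and partial markers (< >). An
# interval with start > end on a circular molecule is unwrapped across the
# origin into two intervals.
.parse_location <- function(loc, seq_len, circular, line_no) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "plus"
  if (grepl("^complement\\(", loc)) {
    strand <- "minus"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  ivs <- list()
  for (p in parts) {
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      se <- c(as.integer(p), as.integer(p))
    } else {
      stop(sprintf("GenBank parse error at line %d: bad location '%s'",
                   line_no, p), call. = FALSE)
    }
    start1 <- se[1]; end1 <- se[2]
    if (start1 > end1) {
      # single span written across the origin of a circular molecule
      if (!circular)
        stop(sprintf(
          "coordinate error at line %d: start > end on a linear record",
          line_no), call. = FALSE)
      ivs <- c(ivs, list(c(start1 - 1L, seq_len), c(0L, end1)))
    } else {
      ivs <- c(ivs, list(c(start1 - 1L, end1)))  # 1-based incl -> 0-based half-open
    }
  }
  m <- do.call(rbind, ivs)
  colnames(m) <- c("start", "end")
  list(intervals = m, strand = strand)
}

# Pull /qualifier="value" (or bare /qualifier=value) from a feature's lines.
.get_qualifier <- function(lines, name) {
  pat <- sprintf("^/%s=", name)
  hit <- grep(pat, lines)
  if (!length(hit)) return(NA_character_)
  val <- sub(pat, "", lines[hit[1]])
  gsub("\"", "", val)
}

.gb_key_to_type <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     `D-loop` = "other", misc_feature = "other")

#' Read a GenBank flat file into a mitogenome record
#'
#' Converts CDS, tRNA, rRNA, D-loop and misc_feature entries into gene
#' features. GenBank 1-based inclusive coordinates become 0-based half-open;
#' `complement()` sets the minus strand; `join()` spans across the origin of
#' a circular record are kept as ordered intervals that splice to the feature
#' sequence. Gene labels are normalized with [normalize_gene_name()];
#' duplicated canonical names get a `_copy2` (`_copy3`, ...) suffix.
#'
#' @param path path to a GenBank flat file (single record).
#' @param quiet suppress normalization warnings.
#' @return A [mitogenome_record()].
#' @export
read_genbank <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("GenBank parse error at line 1: missing LOCUS line")

  locus <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  seq_len <- suppressWarnings(as.integer(locus[3]))
  if (is.na(seq_len))
    stop("GenBank parse error at line 1: cannot read sequence length")
  circular <- any(grepl("circular", lines[1], ignore.case = TRUE))

  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  ver_line <- grep("^VERSION", lines, value = TRUE)
  accession <- if (length(ver_line)) {
    strsplit(trimws(ver_line[1]), "[[:space:]]+")[[1]][2]
  } else if (length(acc_line)) {
    strsplit(trimws(acc_line[1]), "[[:space:]]+")[[1]][2]
  } else locus[2]

  org_line <- grep("^  ORGANISM", lines, value = TRUE)
  taxon <- if (length(org_line)) trimws(sub("^  ORGANISM", "", org_line[1]))
           else NA_character_

  # ORIGIN block -------------------------------------------------------------
  o_start <- grep("^ORIGIN", lines)
  o_end <- grep("^//", lines)
  if (!length(o_start))
    stop("GenBank parse error: no ORIGIN block")
  o_end <- if (length(o_end)) o_end[o_end > o_start[1]][1] else length(lines) + 1L
  seq_lines <- lines[(o_start[1] + 1L):(o_end - 1L)]
  sequence <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != seq_len)
    warning(sprintf("LOCUS declares %d bp but ORIGIN holds %d bp",
                    seq_len, nchar(sequence)), call. = FALSE)
  seq_len <- nchar(sequence)

  # FEATURES block -----------------------------------------------------------
  f_start <- grep("^FEATURES", lines)
  features <- list()
  if (length(f_start)) {
    f_lines_idx <- (f_start[1] + 1L):(o_start[1] - 1L)
    i <- 1L
    idx <- f_lines_idx
    txt <- lines[idx]
    is_key <- grepl("^ {1,10}[A-Za-z'0-9_-]+ +\\S", txt) &
      !grepl("^ {11,}", txt)
    key_pos <- which(is_key)
    for (k in seq_along(key_pos)) {
      first <- key_pos[k]
      last <- if (k < length(key_pos)) key_pos[k + 1] - 1L else length(txt)
      block <- txt[first:last]
      head_parts <- strsplit(trimws(block[1]), "[[:space:]]+")[[1]]
      key <- head_parts[1]
      if (!key %in% names(.gb_key_to_type)) next
      rest <- trimws(block[-1])
      # location may continue over lines until the first qualifier
      qual_at <- grep("^/", rest)
      loc_extra <- if (length(qual_at)) rest[seq_len_safe(qual_at[1] - 1L)] else rest
      loc <- paste0(paste(head_parts[-1], collapse = ""),
                    paste(loc_extra, collapse = ""))
      quals <- if (length(qual_at)) .collapse_qualifiers(rest[qual_at[1]:length(rest)])
               else character(0)
      parsed <- .parse_location(loc, seq_len, circular, idx[first])
      if (any(parsed$intervals[, 2] > seq_len))
        stop(sprintf("coordinate error at line %d: feature beyond sequence end",
                     idx[first]), call. = FALSE)
      ftype <- .gb_key_to_type[[key]]
      label <- .get_qualifier(quals, "gene")
      if (is.na(label)) label <- .get_qualifier(quals, "product")
      if (is.na(label)) label <- key
      ac <- .get_qualifier(quals, "anticodon")
      ac_seq <- if (!is.na(ac)) sub(".*seq:([a-zA-Z]+).*", "\\1", ac) else NULL
      cname <- if (ftype == "other") "other"
               else normalize_gene_name(label, ftype, anticodon = ac_seq,
                                        quiet = quiet)
      features[[length(features) + 1L]] <-
        gene_feature(cname, ftype, parsed$intervals, parsed$strand, label)
    }
  }

  # suffix duplicated canonical names in genome order
  cn <- vapply(features, function(f) f$canonical_name, character(1))
  for (nm in unique(cn[cn != "other"])) {
    at <- which(cn == nm)
    if (length(at) > 1) {
      for (j in seq_along(at)[-1]) {
        features[[at[j]]]$canonical_name <- sprintf("%s_copy%d", nm, j)
      }
    }
  }

  mitogenome_record(accession, taxon, sequence, circular, features)
}

# seq_len that tolerates 0 without the base-R pitfall of 1:0
seq_len_safe <- function(n) if (n < 1L) integer(0) else seq_len(n)

# join continuation lines of multi-line qualifiers
.collapse_qualifiers <- function(lines) {
  out <- character(0)
  for (l in lines) {
    if (grepl("^/", l) || !length(out)) out <- c(out, l)
    else out[length(out)] <- paste0(out[length(out)], l)
  }
  out
}

# ---------------------------------------------------------------------------
# Gene extraction
# ---------------------------------------------------------------------------

#' Extract a gene's coding-strand sequence from a record
#'
#' Splices multi-interval features in order and reverse-complements
#' minus-strand features, returning the 5'-to-3' coding-strand sequence.
#'
#' @param record a [mitogenome_record()].
#' @param name canonical gene name (exact match against the record's
#'   features).
#' @return Residue string.
#' @export
extract_gene <- function(record, name) {
  hits <- which(vapply(record$features,
                       function(f) f$canonical_name == name, logical(1)))
  if (!length(hits))
    stop(sprintf("gene '%s' not found in %s", name, record$accession))
  if (length(hits) > 1)
    stop(sprintf("gene '%s' matches %d features in %s (positions %s)",
                 name, length(hits), record$accession,
                 paste(hits, collapse = ", ")))
  extract_feature(record, record$features[[hits]])
}

#' Extract the sequence of a gene feature
#' @param record a [mitogenome_record()].
#' @param feature a [gene_feature()] belonging to `record`.
#' @return Residue string (coding strand).
#' @export
extract_feature <- function(record, feature) {
  pieces <- apply(feature$intervals, 1, function(iv)
    substr(record$sequence, iv[1] + 1L, iv[2]))
  s <- paste(pieces, collapse = "")
  if (feature$strand == "minus") s <- reverse_complement(s)
  s
}

# ---------------------------------------------------------------------------
# FASTA / alignment / Newick IO
# ---------------------------------------------------------------------------

#' Read sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences (names are full headers up to
#'   the first whitespace).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm))
    stop("duplicate FASTA identifiers: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  setNames(toupper(as.character(x)), nm)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70 columns).
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build an alignment from equal-length gapped sequences
#'
#' The alignment container is a character matrix: one row per taxon (unique
#' rownames), one column per alignment column, entries in
#' \{A,C,G,T,N,-\}.
#'
#' @param seqs named character vector of equal-length gapped sequences.
#' @return Character matrix of class `mito_alignment`.
#' @export
as_alignment <- function(seqs) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon identifiers in alignment")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop(sprintf("ragged alignment: row lengths %s",
                 paste(unique(lens), collapse = ", ")))
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  class(m) <- c("mito_alignment", class(m))
  m
}

#' Collapse an alignment back to gapped strings
#' @param aln a `mito_alignment` matrix.
#' @return Named character vector of gapped sequences.
#' @export
alignment_strings <- function(aln) {
  setNames(apply(aln, 1, paste, collapse = ""), rownames(aln))
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned FASTA file.
#' @return A `mito_alignment` character matrix; ragged input is an error.
#' @export
read_alignment <- function(path) {
  as_alignment(read_fasta(path))
}

#' Read raw Newick text from a file
#'
#' @param path path to a Newick file.
#' @return Character scalar with the tree text (first tree in the file).
#' @export
read_newick_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) stop("empty Newick file: ", path)
  txt
}
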