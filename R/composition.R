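# ---------------------------------------------------------------------------
# Base composition and strand-asymmetry statistics
# ---------------------------------------------------------------------------

#' Strand-asymmetry skew
#'
#' `skew(a, t)` gives the AT skew (a - t)/(a + t) and `skew(g, c)` the GC
#' skew; both lie in \[-1, 1\] and are antisymmetric under argument swap.
#' Arguments may be counts or percentages. When both are zero the skew is
#' defined as 0.
#'
#' @param x_count,y_count non-negative numbers.
#' @return (x - y) / (x + y), or 0 when both are zero.
#' @examples
#' skew(14.1, 14.7)   # GC skew of a G=14.1%, C=14.7% genome: -0.0208...
#' @export
skew <- function(x_count, y_count) {
  if (any(x_count < 0) || any(y_count < 0))
    stop("skew is defined for non-negative counts only")
  tot <- x_count + y_count
  ifelse(tot == 0, 0, (x_count - y_count) / tot)
}

#' Base composition, AT content and skews of a sequence
#'
#' N residues are counted but excluded from the denominators of the base
#' fractions, the AT content and both skews.
#'
#' @param sequence residue string over A/C/G/T/N (case-insensitive; gaps are
#'   ignored).
#' @return A list of class `composition_stats`: `counts` (A, C, G, T, N),
#'   `fractions` (A, C, G, T over non-N residues), `at_content`, `at_skew`,
#'   `gc_skew`.
#' @export
composition_stats <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(gsub("-", "", sequence))
  if (!nzchar(s)) stop("empty sequence")
  ch <- strsplit(s, "")[[1]]
  counts <- c(A = sum(ch == "A"), C = sum(ch == "C"),
              G = sum(ch == "G"), T = sum(ch == "T"), N = sum(ch == "N"))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  fractions <- if (acgt > 0) counts[c("A", "C", "G", "T")] / acgt
               else c(A = NA_real_, C = NA_real_, G = NA_real_, T = NA_real_)
  structure(
    list(counts = counts,
         fractions = fractions,
         at_content = unname(fractions["A"] + fractions["T"]),
         at_skew = skew(counts[["A"]], counts[["T"]]),
         gc_skew = skew(counts[["G"]], counts[["C"]])),
    class = "composition_stats"
  )
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "A %.1f%%  C %.1f%%  G %.1f%%  T %.1f%%  (AT %.1f%%)  AT-skew %.3f  GC-skew %.3f\n",
    100 * x$fractions["A"], 100 * x$fractions["C"], 100 * x$fractions["G"],
    100 * x$fractions["T"], 100 * x$at_content, x$at_skew, x$gc_skew))
  invisible(x)
}

#' Composition at one codon position of a coding sequence
#'
#' Extracts every third residue starting at the requested codon position
#' (frame 0) and summarises it with [composition_stats()]. A trailing
#' incomplete codon is excluded.
#'
#' @param cds in-frame coding sequence, length >= 3.
#' @param position codon position, 1, 2 or 3.
#' @return A `composition_stats` object.
#' @export
codon_position_stats <- function(cds, position) {
  stopifnot(position %in% 1:3)
  if (nchar(cds) < 3) stop("coding sequence shorter than one codon")
  n3 <- nchar(cds) - nchar(cds) %% 3L
  idx <- seq(position, n3, by = 3L)
  composition_stats(paste(strsplit(substr(cds, 1, n3), "")[[1]][idx],
                          collapse = ""))
}

# ---------------------------------------------------------------------------
# Start / stop codon usage
# ---------------------------------------------------------------------------

#' Classify the stop codon of an annotated coding region
#'
#' Mitochondrial coding regions often end in an incomplete stop (TA or lone
#' T) completed to TAA by post-transcriptional polyadenylation. The
#' classification is purely positional: a complete final codon TAA or TAG
#' when the length is a multiple of 3; the tail "TA" when length mod 3 is 2;
#' the tail "T" when length mod 3 is 1; anything else is `"other"`.
#'
#' @param cds the annotated coding region (from start codon to annotated
#'   end), length >= 4.
#' @param annotated_end_flush unused flag kept for interface stability;
#'   classification relies on the sequence alone.
#' @return One of `"TAA"`, `"TAG"`, `"TA"`, `"T"`, `"other"`.
#' @export
classify_stop <- function(cds, annotated_end_flush = TRUE) {
  n <- nchar(cds)
  if (n < 4) stop("coding region too short to classify a stop")
  s <- toupper(cds)
  r <- n %% 3L
  if (r == 0L) {
    last <- substr(s, n - 2L, n)
    if (last %in% c("TAA", "TAG")) return(last)
  } else if (r == 2L) {
    if (substr(s, n - 1L, n) == "TA") return("TA")
  } else if (r == 1L) {
    if (substr(s, n, n) == "T") return("T")
  }
  "other"
}

#' Start codon of an annotated coding region
#' @param cds coding region, length >= 3.
#' @return The first codon (uppercase).
#' @export
start_codon <- function(cds) {
  if (nchar(cds) < 3) stop("coding sequence shorter than one codon")
  toupper(substr(cds, 1, 3))
}

#' Trim an incomplete terminal stop codon
#'
#' Removes the trailing T or TA identified by [classify_stop()], leaving a
#' sequence whose length is a multiple of 3.
#'
#' @param cds coding region.
#' @return The trimmed sequence.
#' @export
trim_incomplete_stop <- function(cds) {
  n <- nchar(cds)
  substr(cds, 1, n - n %% 3L)
}

# ---------------------------------------------------------------------------
# Codon usage / RSCU / amino-acid usage
# ---------------------------------------------------------------------------

# Count in-frame codons over a set of CDS, excluding stop codons and any
# codon containing a non-ACGT character. Returns list(counts, skipped,
# internal_stop_warnings).
.count_codons <- function(cds_set, table) {
  codons <- unlist(lapply(cds_set, split_codons), use.names = FALSE)
  ok <- grepl("^[ACGT]{3}$", codons)
  skipped <- sum(!ok)
  codons <- codons[ok]
  is_stop <- table$codon_to_aa[codons] == "*"
  # a stop before the final codon of a CDS would be internal; we only warn
  # when stops appear anywhere, since pooled counting has no per-CDS frame
  counts <- table(factor(codons[!is_stop], levels = names(table$codon_to_aa)))
  list(counts = counts, skipped = skipped, n_stops = sum(is_stop))
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c is its observed count divided by the mean count of its
#' synonymous family: `n_c * k / sum(family counts)` where k is the family
#' size under the code (e.g. serine has 8 codons under the invertebrate
#' mitochondrial code). Stop codons are excluded; start codons are counted
#' as ordinary codons. Families with zero total get `NA`.
#'
#' @param cds_set character vector (or list) of in-frame coding sequences.
#'   Trailing incomplete codons are dropped; codons containing N are skipped.
#' @param table a [codon_table()].
#' @return A data.frame of class `rscu_table` with columns `codon`, `aa`,
#'   `count`, `rscu`, plus attributes `aa_usage` (per-amino-acid counts and
#'   percentages) and `n_skipped`.
#' @export
rscu <- function(cds_set, table = codon_table(5)) {
  cc <- .count_codons(cds_set, table)
  counts <- cc$counts
  aa <- table$codon_to_aa[names(counts)]
  sense <- aa != "*"
  df <- data.frame(codon = names(counts)[sense],
                   aa = unname(aa[sense]),
                   count = as.integer(counts[sense]),
                   stringsAsFactors = FALSE)
  fam_tot <- tapply(df$count, df$aa, sum)
  fam_size <- tapply(df$count, df$aa, length)
  df$rscu <- ifelse(fam_tot[df$aa] > 0,
                    df$count * fam_size[df$aa] / fam_tot[df$aa],
                    NA_real_)
  df <- df[order(df$aa, df$codon), ]
  rownames(df) <- NULL
  usage <- data.frame(aa = names(fam_tot),
                      count = as.integer(fam_tot),
                      percent = 100 * as.integer(fam_tot) / sum(fam_tot),
                      stringsAsFactors = FALSE)
  attr(df, "aa_usage") <- usage
  attr(df, "n_skipped") <- cc$skipped
  class(df) <- c("rscu_table", "data.frame")
  df
}

#' Amino-acid usage of a set of coding sequences
#'
#' Translates the pooled codons under the table (stop codons excluded from
#' numerator and denominator) and reports counts and percentages per amino
#' acid; leucine and serine are each pooled across their codon families.
#'
#' @inheritParams rscu
#' @return A data.frame with columns `aa`, `count`, `percent`, plus
#'   attribute `total` (the translated residue count).
#' @export
amino_acid_usage <- function(cds_set, table = codon_table(5)) {
  out <- attr(rscu(cds_set, table), "aa_usage")
  attr(out, "total") <- sum(out$count)
  out
}

#' Per-gene start and stop codon summary of a record
#'
#' @param record a [mitogenome_record()].
#' @return A data.frame with one row per protein-coding gene: `gene`,
#'   `start`, `stop_status`, `length_bp`.
#' @export
codon_usage_summary <- function(record) {
  pcgs <- Filter(function(f) f$feature_type == "PCG", record$features)
  if (!length(pcgs)) {
    return(data.frame(gene = character(0), start = character(0),
                      stop_status = character(0), length_bp = integer(0)))
  }
  rows <- lapply(pcgs, function(f) {
    s <- extract_feature(record, f)
    data.frame(gene = f$canonical_name, start = start_codon(s),
               stop_status = classify_stop(s), length_bp = nchar(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
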