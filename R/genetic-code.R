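#' Codon translation tables
#'
#' Builds a codon table object from an NCBI translation-table id. The default
#' (id 5) is the invertebrate mitochondrial code, under which ATA encodes Met,
#' TGA encodes Trp, and AGA/AGG encode Ser, leaving TAA and TAG as the only
#' stop codons.
#'
#' @param table_id NCBI genetic-code id (integer or string). Default `5`.
#' @return An object of class `codon_table`: a list with `table_id`,
#'   `codon_to_aa` (named character vector over the 64 codons, `"*"` for
#'   stop), `start_codons`, and `stop_codons`.
#' @examples
#' tab <- codon_table(5)
#' tab$codon_to_aa[c("ATA", "TGA", "AGA", "AGG")]
#' @export
codon_table <- function(table_id = 5) {
  code <- Biostrings::getGeneticCode(as.character(table_id))
  # NCBI initiator sets: Biostrings records alternative initiators only;
  # ATG is always a start, and table 5 additionally allows ATA.
  starts <- unique(c("ATG", attr(code, "alt_init_codons")))
  if (as.character(table_id) == "5") starts <- unique(c(starts, "ATA"))
  structure(
    list(
      table_id = as.integer(table_id),
      codon_to_aa = code[order(names(code))],
      start_codons = sort(starts),
      stop_codons = sort(names(code)[code == "*"])
    ),
    class = "codon_table"
  )
}

#' @export
print.codon_table <- function(x, ...) {
  cat(sprintf(
    "codon table %d: %d sense codons, stops {%s}, starts {%s}\n",
    x$table_id, sum(x$codon_to_aa != "*"),
    paste(x$stop_codons, collapse = ","),
    paste(x$start_codons, collapse = ",")
  ))
  invisible(x)
}

#' Translate an in-frame coding sequence
#'
#' @param cds coding sequence (character scalar over A/C/G/T/N), frame 0.
#'   A trailing incomplete codon is dropped.
#' @param table a [codon_table()].
#' @return Character vector of single-letter amino acids (`"*"` for stop,
#'   `NA` for codons containing N or other non-ACGT characters).
#' @export
translate_cds <- function(cds, table = codon_table(5)) {
  cods <- split_codons(cds)
  aa <- unname(table$codon_to_aa[cods])
  aa
}

# Split a sequence into complete codons, dropping any incomplete tail.
split_codons <- function(cds) {
  n <- nchar(cds)
  n3 <- n - n %% 3L
  if (n3 < 3L) return(character(0))
  substring(cds, seq(1L, n3 - 2L, by = 3L), seq(3L, n3, by = 3L))
}

#' Reverse complement of a nucleotide sequence
#'
#' Ambiguity codes other than N are not expected; gaps (`-`) and N map to
#' themselves.
#'
#' @param x character scalar over A/C/G/T/N/-.
#' @return The reverse complement, same length.
#' @export
reverse_complement <- function(x) {
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }
  vapply(x, rc1, character(1), USE.NAMES = FALSE)
}
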