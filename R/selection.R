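# ---------------------------------------------------------------------------
# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
# ---------------------------------------------------------------------------

.BASES <- c("A", "C", "G", "T")

# per-table cache of site counts and pathway-averaged difference matrices
.ng86_cache <- new.env(parent = emptyenv())

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the nine single-nucleotide neighbours of the codon, a change
#' is synonymous when it preserves the encoded amino acid; changes producing
#' a stop codon count as nonsynonymous, so the two site counts always sum
#' to 3.
#'
#' @param codon a 3-mer over A/C/G/T that is not a stop under the table.
#' @param table a [codon_table()].
#' @return Named numeric vector `c(s_sites =, n_sites =)`.
#' @export
codon_sites <- function(codon, table = codon_table(5)) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon))
    stop("codon_sites needs an unambiguous A/C/G/T codon")
  aa0 <- table$codon_to_aa[[codon]]
  if (aa0 == "*") stop("codon_sites is undefined for stop codons")
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    for (alt in setdiff(.BASES, base)) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      aa1 <- table$codon_to_aa[[mut]]
      if (aa1 != "*" && aa1 == aa0) s <- s + 1 / 3
    }
  }
  c(s_sites = s, n_sites = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' For codons differing at k positions, all k! orderings of the single-base
#' steps are enumerated; orderings passing through a stop codon are
#' discarded and the synonymous/nonsynonymous step counts are averaged over
#' the rest. If every ordering passes through a stop, the average is taken
#' over all orderings (steps producing or leaving a stop count as
#' nonsynonymous), which keeps the pair usable.
#'
#' @param c1,c2 3-mers over A/C/G/T, neither a stop under the table.
#' @param table a [codon_table()].
#' @return Named numeric vector `c(sd =, nd =)`; `sd + nd` equals the
#'   Hamming distance between the codons.
#' @export
codon_differences <- function(c1, c2, table = codon_table(5)) {
  c1 <- toupper(c1); c2 <- toupper(c2)
  if (!grepl("^[ACGT]{3}$", c1) || !grepl("^[ACGT]{3}$", c2))
    stop("codon_differences needs unambiguous A/C/G/T codons")
  if (table$codon_to_aa[[c1]] == "*" || table$codon_to_aa[[c2]] == "*")
    stop("codon_differences is undefined for stop codons")
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orderings <- .permutations(diff_pos)
  tally <- function(skip_stop_paths) {
    res <- matrix(NA_real_, nrow = nrow(orderings), ncol = 2)
    for (r in seq_len(nrow(orderings))) {
      cur <- c1
      sd <- 0; nd <- 0; hit_stop <- FALSE
      for (pos in orderings[r, ]) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        aa_cur <- table$codon_to_aa[[cur]]
        aa_nxt <- table$codon_to_aa[[nxt]]
        if (aa_nxt == "*") hit_stop <- TRUE
        if (aa_cur != "*" && aa_nxt != "*" && aa_cur == aa_nxt) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      if (!(skip_stop_paths && hit_stop)) res[r, ] <- c(sd, nd)
    }
    res[!is.na(res[, 1]), , drop = FALSE]
  }
  kept <- tally(skip_stop_paths = TRUE)
  if (!nrow(kept)) kept <- tally(skip_stop_paths = FALSE)
  c(sd = mean(kept[, 1]), nd = mean(kept[, 2]))
}

# all permutations of a small vector (k <= 3 here)
.permutations <- function(x) {
  k <- length(x)
  if (k == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_len(k)) {
    sub <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], sub))
  }
  out
}

# Precompute (once per table) the 64-codon site vector and 64x64 sd/nd
# matrices used by the vectorised pairwise estimator.
.ng86_tables <- function(table) {
  key <- as.character(table$table_id)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  codons <- names(table$codon_to_aa)
  nonstop <- codons[table$codon_to_aa != "*"]
  s_sites <- setNames(rep(NA_real_, 64), codons)
  for (cd in nonstop) s_sites[cd] <- codon_sites(cd, table)[["s_sites"]]
  SD <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  ND <- SD
  for (a in nonstop) {
    for (b in nonstop) {
      d <- codon_differences(a, b, table)
      SD[a, b] <- d[["sd"]]; ND[a, b] <- d[["nd"]]
    }
  }
  res <- list(s_sites = s_sites, SD = SD, ND = ND)
  .ng86_cache[[key]] <- res
  res
}

#' Jukes-Cantor distance from a proportion of differences
#'
#' d = -(3/4) log(1 - (4/3) p); undefined (NA) at or beyond the saturation
#' point p = 3/4.
#'
#' @param p proportion of differing sites.
#' @return Corrected distance, or `NA` where `p >= 0.75`.
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Ka and Ks for two aligned coding sequences (NG86)
#'
#' Codon pairs containing a gap, N, or a stop codon in either sequence are
#' skipped. S and N site totals are averaged between the two sequences;
#' substitution counts are pathway-averaged ([codon_differences()]); the
#' Jukes-Cantor correction converts the proportions pS and pN into Ks and
#' Ka (saturated proportions >= 3/4 give `NA`).
#'
#' @param cds1,cds2 equal-length aligned coding rows, frame 0, length a
#'   multiple of 3 (trim incomplete terminal stops first, see
#'   [trim_incomplete_stop()]).
#' @param table a [codon_table()].
#' @param jc_correction apply the Jukes-Cantor correction (default TRUE);
#'   when FALSE, Ka and Ks are the raw proportions pN and pS.
#' @return A one-row data.frame: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`,
#'   `Ka`, `n_codons` (countable codon pairs).
#' @export
pairwise_kaks <- function(cds1, cds2, table = codon_table(5),
                          jc_correction = TRUE) {
  if (nchar(cds1) != nchar(cds2))
    stop("aligned coding rows must have equal length")
  if (nchar(cds1) %% 3 != 0)
    stop("coding length must be a multiple of 3 (frame 0)")
  tabs <- .ng86_tables(table)
  k1 <- split_codons(toupper(cds1))
  k2 <- split_codons(toupper(cds2))
  ok <- grepl("^[ACGT]{3}$", k1) & grepl("^[ACGT]{3}$", k2)
  ok[ok] <- table$codon_to_aa[k1[ok]] != "*" & table$codon_to_aa[k2[ok]] != "*"
  k1 <- k1[ok]; k2 <- k2[ok]
  n_codons <- length(k1)
  if (n_codons == 0L)
    return(data.frame(S = NA_real_, N = NA_real_, Sd = NA_real_,
                      Nd = NA_real_, pS = NA_real_, pN = NA_real_,
                      Ks = NA_real_, Ka = NA_real_, n_codons = 0L))
  S1 <- sum(tabs$s_sites[k1]); S2 <- sum(tabs$s_sites[k2])
  S <- (S1 + S2) / 2
  N <- 3 * n_codons - S
  idx <- cbind(match(k1, rownames(tabs$SD)), match(k2, colnames(tabs$SD)))
  Sd <- sum(tabs$SD[idx]); Nd <- sum(tabs$ND[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  if (jc_correction) {
    Ks <- jukes_cantor(pS); Ka <- jukes_cantor(pN)
  } else {
    Ks <- pS; Ka <- pN
  }
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             Ks = Ks, Ka = Ka, n_codons = n_codons)
}

#' Gene-level Ka/Ks over all sequence pairs of an alignment
#'
#' Evaluates [pairwise_kaks()] for every pair of rows and summarises:
#' `mean_Ka` and `mean_Ks` are means over pairs with defined values, and the
#' gene ratio is `mean_Ka / mean_Ks` (undefined when `mean_Ks` is 0 or no
#' pair is defined). The ratio of means is preferred over the mean of
#' per-pair ratios, which explodes for pairs with tiny Ks; per-pair values
#' are returned for inspection.
#'
#' @param aln a `mito_alignment` of an in-frame coding gene (>= 2 rows;
#'   trailing columns beyond the last complete codon are dropped).
#' @param table a [codon_table()].
#' @param jc_correction see [pairwise_kaks()].
#' @param gene optional gene name recorded in the result.
#' @return A list of class `kaks_result`: `gene`, `mean_Ka`, `mean_Ks`,
#'   `ratio`, `n_pairs` (pairs with both Ka and Ks defined), `pairs` (the
#'   per-pair table with taxon columns).
#' @export
gene_kaks <- function(aln, table = codon_table(5), jc_correction = TRUE,
                      gene = NA_character_) {
  if (nrow(aln) < 2) stop("gene_kaks needs at least 2 sequences")
  nc <- ncol(aln) - ncol(aln) %% 3L
  strs <- alignment_strings(aln[, seq_len(nc), drop = FALSE])
  taxa <- names(strs)
  n <- length(strs)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      pr <- pairwise_kaks(strs[[i]], strs[[j]], table, jc_correction)
      pr$taxon1 <- taxa[i]; pr$taxon2 <- taxa[j]
      rows[[length(rows) + 1L]] <- pr
    }
  }
  pairs <- do.call(rbind, rows)
  defined <- !is.na(pairs$Ka) & !is.na(pairs$Ks)
  mean_Ka <- if (any(!is.na(pairs$Ka))) mean(pairs$Ka, na.rm = TRUE) else NA_real_
  mean_Ks <- if (any(!is.na(pairs$Ks))) mean(pairs$Ks, na.rm = TRUE) else NA_real_
  ratio <- if (is.na(mean_Ka) || is.na(mean_Ks) || mean_Ks == 0) NA_real_
           else mean_Ka / mean_Ks
  structure(
    list(gene = gene, mean_Ka = mean_Ka, mean_Ks = mean_Ks, ratio = ratio,
         n_pairs = sum(defined), pairs = pairs),
    class = "kaks_result"
  )
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "<kaks_result> %s: mean Ka %.4f, mean Ks %.4f, Ka/Ks %s (%d pairs)\n",
    ifelse(is.na(x$gene), "(unnamed gene)", x$gene),
    x$mean_Ka, x$mean_Ks,
    ifelse(is.na(x$ratio), "undefined", sprintf("%.4f", x$ratio)),
    x$n_pairs))
  invisible(x)
}
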