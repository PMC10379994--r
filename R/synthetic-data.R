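# ---------------------------------------------------------------------------
# Seeded simulators: trees, alignments, codon alignments, toy GenBank records
# ---------------------------------------------------------------------------

#' Simulate a phylogeny
#'
#' `"yule"` draws a pure-birth tree (exponential waiting times between
#' speciations) and rescales it so the maximum root-to-tip depth equals
#' `depth`; `"balanced"` builds the symmetric topology (n a power of 2) with
#' equal branch lengths summing to `depth` along each root-to-tip path;
#' `"fixed"` parses the supplied Newick string.
#'
#' @param n_taxa number of leaves (>= 4 for yule/balanced).
#' @param shape `"yule"`, `"balanced"` or `"fixed"`.
#' @param depth root-to-tip depth in expected substitutions per site at rate
#'   multiplier 1 (default 0.25, a moderate divergence at which distances
#'   are informative but far from saturated).
#' @param newick Newick text, required for `shape = "fixed"`.
#' @param seed optional integer seed (reproducible draws).
#' @return An `ape::phylo` tree with positive branch lengths, leaf labels
#'   `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, shape = c("yule", "balanced", "fixed"),
                          depth = 0.25, newick = NULL, seed = NULL) {
  shape <- match.arg(shape)
  if (!is.null(seed)) set.seed(seed)
  if (shape == "fixed") {
    stopifnot(!is.null(newick))
    return(parse_newick(newick))
  }
  stopifnot(n_taxa >= 4)
  if (shape == "balanced") {
    k <- log2(n_taxa)
    if (k != round(k)) stop("balanced shape needs n_taxa a power of 2")
    tr <- ape::stree(n_taxa, type = "balanced")
    tr$edge.length <- rep(depth / k, nrow(tr$edge))
    tr$tip.label <- paste0("t", seq_len(n_taxa))
    return(tr)
  }
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  depths <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * depth / max(depths)
  tr
}

# stationary base frequencies for a given AT bias, order A C G T
.at_freqs <- function(at_bias) {
  c(A = at_bias / 2, C = (1 - at_bias) / 2,
    G = (1 - at_bias) / 2, T = at_bias / 2)
}

#' Simulate a nucleotide alignment on a tree
#'
#' Sites evolve independently under an equal-exchangeability substitution
#' process with unequal stationary frequencies (an F81-type model): the
#' root sequence is drawn from the stationary distribution
#' (fA = fT = at_bias/2, fG = fC = (1 - at_bias)/2) and along a branch of
#' length t each site either retains its state or is redrawn from the
#' stationary distribution, calibrated so the expected number of
#' substitutions per site is `rate_multiplier * t`. The output contains no
#' gaps.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param length sequence length (>= 1).
#' @param rate_multiplier gene-specific rate scaling (> 0, or 0 for an
#'   invariant alignment).
#' @param at_bias stationary A+T fraction in \[0, 1\] (default 0.7,
#'   an AT-rich mitochondrial composition).
#' @param seed optional integer seed.
#' @return A `mito_alignment` matrix (tips x sites).
#' @export
simulate_nt_alignment <- function(tree, length, rate_multiplier = 1,
                                  at_bias = 0.7, seed = NULL) {
  stopifnot(length >= 1, rate_multiplier >= 0)
  if (!is.null(seed)) set.seed(seed)
  freqs <- .at_freqs(at_bias)
  norm <- 1 - sum(freqs^2)  # expected flow per redraw event
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- sample(names(freqs), length, replace = TRUE, prob = freqs)
  edges <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    parent <- edges$edge[e, 1]; child <- edges$edge[e, 2]
    t_len <- edges$edge.length[e] * rate_multiplier
    beta <- if (norm > 0) t_len / norm else 0
    redraw <- stats::runif(length) >= exp(-beta)
    s <- seqs[[parent]]
    if (any(redraw))
      s[redraw] <- sample(names(freqs), sum(redraw), replace = TRUE,
                          prob = freqs)
    seqs[[child]] <- s
  }
  m <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(m) <- tree$tip.label
  class(m) <- c("mito_alignment", class(m))
  m
}

#' Simulate an in-frame codon alignment with a target Ka/Ks
#'
#' Root codons are drawn uniformly from the non-stop codons of the table.
#' Along each branch, substitution events are proposed at the nucleotide
#' level (uniform over sites and alternative bases, at `mut_rate` proposals
#' per site per unit branch length); proposals creating a stop codon are
#' rejected, synonymous proposals are always accepted, and nonsynonymous
#' proposals are accepted with probability `omega`. The simulated rows
#' therefore contain no internal stop codons, and the realised
#' nonsynonymous/synonymous rate ratio approximates `omega`.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param n_codons number of codons (>= 1).
#' @param omega nonsynonymous acceptance probability (>= 0).
#' @param seed optional integer seed.
#' @param table a [codon_table()].
#' @param mut_rate proposal rate per nucleotide site per unit branch length
#'   (default 1).
#' @return A `mito_alignment` matrix (tips x 3*n_codons).
#' @export
simulate_codon_alignment <- function(tree, n_codons, omega, seed = NULL,
                                     table = codon_table(5), mut_rate = 1) {
  stopifnot(n_codons >= 1, omega >= 0)
  if (!is.null(seed)) set.seed(seed)
  codons <- names(table$codon_to_aa)[table$codon_to_aa != "*"]
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  L <- 3L * n_codons
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- unlist(strsplit(sample(codons, n_codons, replace = TRUE), ""))
  edges <- ape::reorder.phylo(tree, "cladewise")
  aa_of <- table$codon_to_aa
  for (e in seq_len(nrow(edges$edge))) {
    parent <- edges$edge[e, 1]; child <- edges$edge[e, 2]
    s <- seqs[[parent]]
    n_events <- stats::rpois(1, mut_rate * L * edges$edge.length[e])
    if (n_events > 0) {
      sites <- sample.int(L, n_events, replace = TRUE)
      us <- stats::runif(n_events)
      for (ev in seq_len(n_events)) {
        site <- sites[ev]
        alt <- sample(setdiff(.BASES, s[site]), 1L)
        cod_i <- (site - 1L) %/% 3L
        idx <- cod_i * 3L + 1:3
        old_codon <- paste(s[idx], collapse = "")
        new <- s[idx]
        new[site - cod_i * 3L] <- alt
        new_codon <- paste(new, collapse = "")
        if (aa_of[[new_codon]] == "*") next           # stop: reject
        syn <- aa_of[[new_codon]] == aa_of[[old_codon]]
        if (syn || us[ev] < omega) s[site] <- alt
      }
    }
    seqs[[child]] <- s
  }
  m <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(m) <- tree$tip.label
  class(m) <- c("mito_alignment", class(m))
  m
}

#' Perturb a tree by random SPR moves and branch-length jitter
#'
#' Applies `n_spr_moves` random subtree-prune-regraft moves (via
#' `phangorn::rSPR`) and then multiplies every branch length by
#' `exp(N(0, sd^2))`. With 0 moves and 0 jitter the tree is returned
#' unchanged.
#'
#' @param tree an `ape::phylo` tree.
#' @param n_spr_moves number of SPR moves (>= 0).
#' @param length_jitter_sd standard deviation of the log-normal branch
#'   multiplier (>= 0).
#' @param seed optional integer seed.
#' @return The perturbed tree.
#' @export
perturb_tree <- function(tree, n_spr_moves = 0, length_jitter_sd = 0,
                         seed = NULL) {
  stopifnot(n_spr_moves >= 0, length_jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n_spr_moves == 0 && length_jitter_sd == 0) return(tree)
  if (n_spr_moves > 0 && ape::Ntip(tree) < 4)
    stop("SPR perturbation needs at least 4 leaves")
  out <- tree
  if (n_spr_moves > 0) {
    # SPR moves operate on the unrooted view (rooted input can otherwise
    # yield a basal polytomy mid-move); scoring unroots anyway
    if (ape::is.rooted(out)) out <- ape::unroot(out)
    out <- phangorn::rSPR(out, moves = n_spr_moves)
  }
  if (length_jitter_sd > 0)
    out$edge.length <- out$edge.length *
      exp(stats::rnorm(length(out$edge.length), 0, length_jitter_sd))
  out
}

# ---------------------------------------------------------------------------
# Toy annotated GenBank records
# ---------------------------------------------------------------------------

#' Configuration for a toy GenBank record
#'
#' Describes a small circular annotated genome whose features are planted at
#' known coordinates with known coding content, so a parser round trip can
#' be checked exactly. The default plants five genes: a plus-strand CDS with
#' an incomplete lone-T stop, a minus-strand (complement) CDS, an rRNA, a
#' tRNA-Ser(UCN) with an anticodon qualifier, and a CDS join spanning the
#' origin.
#'
#' @param accession,taxon record identifiers.
#' @param length_bp genome length (default 2000).
#' @param at_bias background A+T fraction of intergenic sequence.
#' @param seed integer seed for the background and coding sequence draws.
#' @param genes data.frame with columns `name` (canonical), `raw_label`,
#'   `key` (GenBank feature key), `start0` (0-based), `len`, `strand`
#'   (`"plus"`/`"minus"`), `stop_tail` (`"TAA"`, `"TAG"`, `"TA"`, `"T"` or
#'   NA for non-CDS), `anticodon` (or NA).
#' @return A list of class `toy_genbank_config`.
#' @export
toy_genbank_config <- function(accession = "TOY00001",
                               taxon = "Toyus exemplaris",
                               length_bp = 2000, at_bias = 0.7, seed = 1,
                               genes = NULL) {
  if (is.null(genes)) {
    genes <- data.frame(
      name = c("cox1", "nad2", "rrnL", "trnS2", "cytb"),
      raw_label = c("COI", "ND2", "16S ribosomal RNA", "tRNA-Ser", "CYTB"),
      key = c("CDS", "CDS", "rRNA", "tRNA", "CDS"),
      start0 = c(100L, 600L, 1000L, 1300L, 1900L),
      len = c(301L, 312L, 200L, 66L, 198L),
      strand = c("plus", "minus", "plus", "plus", "plus"),
      stop_tail = c("T", "TAA", NA, NA, "TAA"),
      anticodon = c(NA, NA, NA, "tga", NA),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(genes$len >= 1), all(genes$len <= length_bp))
  structure(list(accession = accession, taxon = taxon,
                 length_bp = as.integer(length_bp), at_bias = at_bias,
                 seed = seed, genes = genes),
            class = "toy_genbank_config")
}

# a random coding sequence: start codon + non-stop body codons + stop tail
.plant_cds <- function(len, stop_tail, table, at_bias) {
  tail_len <- nchar(stop_tail)
  body_len <- len - 3L - tail_len
  if (body_len < 0 || body_len %% 3 != 0)
    stop(sprintf("CDS length %d incompatible with stop tail '%s'",
                 len, stop_tail))
  sense <- names(table$codon_to_aa)[table$codon_to_aa != "*"]
  body <- paste(sample(sense, body_len / 3, replace = TRUE), collapse = "")
  paste0("ATG", body, stop_tail)
}

.random_seq <- function(n, at_bias) {
  paste(sample(names(.at_freqs(at_bias)), n, replace = TRUE,
               prob = .at_freqs(at_bias)), collapse = "")
}

#' Emit a toy annotated GenBank flat file
#'
#' Generates the genome sequence, plants each configured gene at its
#' coordinates (reverse-complemented into the genome for minus-strand
#' features; split across the origin when `start0 + len` exceeds the genome
#' length), and renders a syntactically valid GenBank flat file.
#'
#' @param config a [toy_genbank_config()].
#' @return Character vector of file lines, with attribute `truth`: a list
#'   with the genome string and, per gene, the planted coding-strand
#'   sequence and 0-based intervals.
#' @export
make_toy_genbank <- function(config = toy_genbank_config()) {
  stopifnot(inherits(config, "toy_genbank_config"))
  set.seed(config$seed)
  table <- codon_table(5)
  L <- config$length_bp
  genome <- strsplit(.random_seq(L, config$at_bias), "")[[1]]
  truth <- list()
  locs <- character(nrow(config$genes))
  for (i in seq_len(nrow(config$genes))) {
    g <- config$genes[i, ]
    if (g$start0 + g$len > 2L * L)
      stop("gene extends beyond genome length even after wrapping")
    coding <- if (g$key == "CDS") .plant_cds(g$len, g$stop_tail, table,
                                             config$at_bias)
              else .random_seq(g$len, config$at_bias)
    placed <- if (g$strand == "minus") reverse_complement(coding) else coding
    pos <- ((g$start0 + seq_len(g$len) - 1L) %% L) + 1L
    genome[pos] <- strsplit(placed, "")[[1]]
    wraps <- g$start0 + g$len > L
    if (wraps) {
      iv <- rbind(c(g$start0, L), c(0L, (g$start0 + g$len) %% L))
      span <- sprintf("join(%d..%d,%d..%d)", g$start0 + 1L, L, 1L,
                      (g$start0 + g$len) %% L)
    } else {
      iv <- rbind(c(g$start0, g$start0 + g$len))
      span <- sprintf("%d..%d", g$start0 + 1L, g$start0 + g$len)
    }
    locs[i] <- if (g$strand == "minus") sprintf("complement(%s)", span)
               else span
    truth[[g$name]] <- list(coding = coding, intervals = iv,
                            strand = g$strand)
  }
  genome_str <- paste(genome, collapse = "")

  lines <- c(
    sprintf("LOCUS       %s            %d bp    DNA     circular INV 01-JAN-2024",
            config$accession, L),
    "DEFINITION  synthetic toy mitogenome (generated fixture).",
    sprintf("ACCESSION   %s", config$accession),
    sprintf("VERSION     %s.1", config$accession),
    sprintf("SOURCE      %s", config$taxon),
    sprintf("  ORGANISM  %s", config$taxon),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L)
  )
  for (i in seq_len(nrow(config$genes))) {
    g <- config$genes[i, ]
    lines <- c(lines,
      sprintf("     %-16s%s", g$key, locs[i]),
      sprintf("                     /gene=\"%s\"", g$raw_label))
    if (!is.na(g$anticodon))
      lines <- c(lines, sprintf(
        "                     /anticodon=\"(pos:%d..%d,aa:Ser,seq:%s)\"",
        g$start0 + 30L, g$start0 + 32L, g$anticodon))
  }
  lines <- c(lines, "ORIGIN")
  low <- tolower(genome_str)
  for (s in seq(1L, L, by = 60L)) {
    chunk <- substr(low, s, min(s + 59L, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(groups, collapse = " ")))
  }
  lines <- c(lines, "//")
  attr(lines, "truth") <- c(list(genome = genome_str), truth)
  lines
}
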