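# ---------------------------------------------------------------------------
# Newick trees, bipartitions and the K tree score
# ---------------------------------------------------------------------------

#' Parse a Newick string into an unrooted tree
#'
#' Wraps `ape::read.tree` and normalises the result for branch-length
#' comparison: internal (support) labels are discarded, missing branch
#' lengths become 0 with a warning, and a rooted input is unrooted by
#' suppressing the degree-2 root (its two incident lengths are summed).
#' Polytomies are preserved.
#'
#' @param text Newick string.
#' @return An unrooted `ape::phylo` tree.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error in: ", substr(text, 1, 60))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr$node.label <- NULL
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; using 0", call. = FALSE)
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths set to 0", call. = FALSE)
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (ape::is.rooted(tr) && ape::Ntip(tr) > 2) tr <- ape::unroot(tr)
  tr
}

#' Write a tree as Newick text
#' @param tree an `ape::phylo` tree.
#' @return Newick string.
#' @export
write_newick <- function(tree) ape::write.tree(tree)

#' Bipartitions of an unrooted tree with their branch lengths
#'
#' Every edge of the tree induces a split of the leaf set; the split is
#' canonicalized to the side not containing the lexicographically smallest
#' leaf, so the representation is side-invariant. Trivial (pendant) splits
#' are included. When several edges induce the same split (which cannot
#' happen on a tree without degree-2 vertices) lengths would be summed.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return Named numeric vector: names are canonical split keys
#'   (semicolon-joined sorted leaf names), values are branch lengths.
#'   Attribute `leaves` holds the leaf set; attribute `is_trivial` flags
#'   pendant splits.
#' @export
bipartitions <- function(tree) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  ref_leaf <- sort(tips)[1]
  n_node <- tree$Nnode
  # leaves below each edge's child, via one pass over edges sorted so that
  # children precede parents (postorder)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) below[[i]] <- tips[i]
  keys <- character(nrow(po$edge))
  lens <- numeric(nrow(po$edge))
  triv <- logical(nrow(po$edge))
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2]
    parent <- po$edge[e, 1]
    cl <- below[[child]]
    below[[parent]] <- c(below[[parent]], cl)
    side <- if (ref_leaf %in% cl) setdiff(tips, cl) else cl
    keys[e] <- paste(sort(side), collapse = ";")
    lens[e] <- po$edge.length[e]
    triv[e] <- length(cl) == 1L || length(cl) == n_tip - 1L
  }
  agg <- tapply(lens, keys, sum)
  out <- as.numeric(agg)
  names(out) <- names(agg)
  attr(out, "leaves") <- sort(tips)
  attr(out, "is_trivial") <-
    tapply(triv, keys, any)[names(agg)]
  out
}

#' K tree score between a comparison tree and a reference tree
#'
#' Both trees are pruned to their shared leaf set (pruning contracts removed
#' edges and sums lengths along merged paths) and unrooted. Over the union
#' of their splits (trivial splits included; a split absent from one tree
#' contributes length 0 there), the scale factor
#' `K = sum(l_ref * l_comp) / sum(l_comp^2)` rescales the comparison tree
#' toward the reference, and the score is
#' `sqrt(sum((l_ref - K * l_comp)^2))`. A score of 0 means the trees are
#' identical in topology and, up to the global scale K, in branch lengths;
#' high scores indicate a poor match. The score is not symmetric in its
#' arguments.
#'
#' @param reference reference tree (`ape::phylo`).
#' @param comparison comparison (e.g. single-gene) tree.
#' @return A list of class `kscore_result`: `k_factor`, `k_score`,
#'   `n_shared_splits`, `n_ref_only`, `n_comp_only` (counts of nontrivial
#'   splits), `shared_leaves`, `pruned_leaf_count`.
#' @export
k_tree_score <- function(reference, comparison) {
  shared <- intersect(reference$tip.label, comparison$tip.label)
  if (length(shared) < 4)
    stop(sprintf("only %d shared leaves; need at least 4", length(shared)))
  pruned <- (ape::Ntip(reference) - length(shared)) +
    (ape::Ntip(comparison) - length(shared))
  ref <- reference; comp <- comparison
  if (ape::Ntip(ref) > length(shared)) ref <- ape::keep.tip(ref, shared)
  if (ape::Ntip(comp) > length(shared)) comp <- ape::keep.tip(comp, shared)
  if (ape::is.rooted(ref)) ref <- ape::unroot(ref)
  if (ape::is.rooted(comp)) comp <- ape::unroot(comp)
  br <- bipartitions(ref)
  bc <- bipartitions(comp)
  keys <- union(names(br), names(bc))
  lr <- ifelse(keys %in% names(br), br[keys], 0)
  lc <- ifelse(keys %in% names(bc), bc[keys], 0)
  denom <- sum(lc^2)
  k <- if (denom > 0) sum(lr * lc) / denom else 0
  score <- sqrt(sum((lr - k * lc)^2))
  nt_r <- names(br)[!attr(br, "is_trivial")]
  nt_c <- names(bc)[!attr(bc, "is_trivial")]
  structure(
    list(k_factor = k, k_score = score,
         n_shared_splits = length(intersect(nt_r, nt_c)),
         n_ref_only = length(setdiff(nt_r, nt_c)),
         n_comp_only = length(setdiff(nt_c, nt_r)),
         shared_leaves = length(shared),
         pruned_leaf_count = pruned),
    class = "kscore_result"
  )
}

#' @export
print.kscore_result <- function(x, ...) {
  cat(sprintf(
    "<kscore_result> K = %.4f, score = %.4f (%d shared leaves, %d pruned; splits: %d shared, %d ref-only, %d comp-only)\n",
    x$k_factor, x$k_score, x$shared_leaves, x$pruned_leaf_count,
    x$n_shared_splits, x$n_ref_only, x$n_comp_only))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Distances and neighbor joining (used to build test gene trees)
# ---------------------------------------------------------------------------

#' Pairwise distance matrix of an alignment
#'
#' p-distances (proportion of differing sites among pairwise-comparable
#' A/C/G/T sites) or their Jukes-Cantor correction.
#'
#' @param aln a `mito_alignment` matrix.
#' @param distance `"p"` or `"jukes_cantor"`.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
alignment_distances <- function(aln, distance = c("p", "jukes_cantor")) {
  distance <- match.arg(distance)
  n <- nrow(aln)
  v <- .valid_base(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- v[i, ] & v[j, ]
      nc <- sum(comp)
      p <- if (nc > 0) sum(aln[i, comp] != aln[j, comp]) / nc else NA_real_
      if (distance == "jukes_cantor") {
        if (!is.na(p) && p >= 0.75)
          stop(sprintf("saturated distance between %s and %s (p = %.3f)",
                       rownames(aln)[i], rownames(aln)[j], p))
        p <- jukes_cantor(p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from an alignment
#'
#' Saitou-Nei neighbor joining (via `ape::nj`) on p or Jukes-Cantor
#' distances; negative branch-length estimates are clamped to 0. This is a
#' convenience builder for exercising tree-scoring end to end; it is not a
#' substitute for model-based phylogenetic inference.
#'
#' @param aln a `mito_alignment` matrix with >= 3 rows.
#' @param distance `"p"` or `"jukes_cantor"`.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(aln, distance = c("p", "jukes_cantor")) {
  if (nrow(aln) < 3) stop("neighbor joining needs at least 3 taxa")
  d <- alignment_distances(aln, distance)
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree from a distance matrix
#' @param d symmetric distance matrix or `dist` object.
#' @return An unrooted `ape::phylo` tree (negative estimates clamped to 0).
#' @export
nj_from_distances <- function(d) {
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Score a set of gene trees against one reference tree
#'
#' @param gene_trees named list of `ape::phylo` trees (names are gene
#'   names).
#' @param reference the reference tree.
#' @param aln_lengths optional named vector of alignment lengths to report.
#' @return Data.frame with one row per gene (`gene`, `k_factor`, `k_score`,
#'   `shared_leaves`, `pruned_leaf_count`, `aln_length`, `note`), sorted by
#'   descending k_score; per-gene failures leave NA cells and a note.
#' @export
score_gene_trees <- function(gene_trees, reference, aln_lengths = NULL) {
  stopifnot(length(gene_trees) >= 1, !is.null(names(gene_trees)))
  rows <- lapply(names(gene_trees), function(g) {
    res <- tryCatch(k_tree_score(reference, gene_trees[[g]]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(gene = g, k_factor = NA_real_, k_score = NA_real_,
                 shared_leaves = NA_integer_, pruned_leaf_count = NA_integer_,
                 aln_length = .lookup_len(aln_lengths, g),
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, k_factor = res$k_factor, k_score = res$k_score,
                 shared_leaves = res$shared_leaves,
                 pruned_leaf_count = res$pruned_leaf_count,
                 aln_length = .lookup_len(aln_lengths, g),
                 note = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$k_score, out$gene, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

.lookup_len <- function(aln_lengths, g) {
  if (is.null(aln_lengths) || !g %in% names(aln_lengths)) NA_integer_
  else as.integer(aln_lengths[[g]])
}
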