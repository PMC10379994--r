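test_that("Newick parsing unroots and preserves split lengths", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(ape::Ntip(tr), 4)
  b <- bipartitions(tr)
  nontrivial <- b[!attr(b, "is_trivial")]
  expect_length(nontrivial, 1)
  expect_equal(unname(nontrivial[["C;D"]]), 2)  # root suppression sums 1+1

  star <- parse_newick("(A:1,B:2,C:3);")
  bs <- bipartitions(star)
  expect_length(bs[!attr(bs, "is_trivial")], 0)

  expect_error(parse_newick("((A:1,B:1);"), "parse")
  expect_error(parse_newick("((A:1,A:1):1,(C:1,D:1):1);"), "duplicate")
})

test_that("parse-write round trip preserves the bipartition-length map", {
  set.seed(30)
  for (i in 1:10) {
    tr <- random_binary_tree(sample(5:10, 1))
    back <- parse_newick(write_newick(tr))
    b1 <- bipartitions(tr); b2 <- bipartitions(back)
    expect_setequal(names(b1), names(b2))
    expect_equal(as.numeric(b1[names(b2)]), as.numeric(b2),
                 tolerance = 1e-9)
  }
})

test_that("bipartition counts follow the n - 3 rule", {
  bal <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_length(bipartitions(bal), 5)  # 4 trivial + 1 nontrivial
  cat5 <- parse_newick("((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
  b5 <- bipartitions(cat5)
  expect_length(b5[!attr(b5, "is_trivial")], 2)
  set.seed(31)
  t10 <- random_binary_tree(10)
  b10 <- bipartitions(t10)
  expect_length(b10[!attr(b10, "is_trivial")], 7)
})

test_that("K score is zero for identical trees and absorbs global scaling", {
  set.seed(32)
  for (i in 1:20) {
    tr <- random_binary_tree(sample(5:10, 1))
    self <- k_tree_score(tr, tr)
    expect_equal(self$k_factor, 1, tolerance = 1e-12)
    expect_equal(self$k_score, 0, tolerance = 1e-12)
    c_scale <- runif(1, 0.2, 5)
    scaled <- tr; scaled$edge.length <- scaled$edge.length * c_scale
    res <- k_tree_score(tr, scaled)
    expect_equal(res$k_factor, 1 / c_scale, tolerance = 1e-9)
    expect_equal(res$k_score, 0, tolerance = 1e-9)
  }
})

test_that("the analytic scale factor matches the grid-search oracle", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    ref <- random_binary_tree(n)
    comp <- random_binary_tree(n)
    got <- k_tree_score(ref, comp)
    br <- bipartitions(ape::unroot(ref)); bc <- bipartitions(ape::unroot(comp))
    keys <- union(names(br), names(bc))
    lr <- ifelse(keys %in% names(br), br[keys], 0)
    lc <- ifelse(keys %in% names(bc), bc[keys], 0)
    oracle <- kscore_grid_oracle(lr, lc)
    expect_equal(got$k_score, oracle$score, tolerance = 1e-6)
    expect_equal(got$k_factor, oracle$k, tolerance = 1e-4)
  }
})

test_that("K score is asymmetric and invariant to comparison rescaling", {
  set.seed(34)
  ref <- random_binary_tree(8)
  comp <- random_binary_tree(8)
  ab <- k_tree_score(ref, comp)
  ba <- k_tree_score(comp, ref)
  expect_false(isTRUE(all.equal(ab$k_score, ba$k_score)))
  comp2 <- comp; comp2$edge.length <- comp2$edge.length * 3.7
  expect_equal(k_tree_score(ref, comp2)$k_score, ab$k_score,
               tolerance = 1e-9)
})

test_that("trees are pruned to the shared leaf set before scoring", {
  set.seed(35)
  ref <- random_binary_tree(10)
  comp <- ape::drop.tip(ref, c("t1", "t2"))
  res <- k_tree_score(ref, comp)
  expect_equal(res$shared_leaves, 8)
  expect_equal(res$pruned_leaf_count, 2)
  expect_equal(res$k_score, 0, tolerance = 1e-9)  # comp is ref restricted
  tiny <- parse_newick("(A:1,B:1,C:1);")
  expect_error(k_tree_score(ref, tiny), "shared leaves")
})

test_that("neighbor joining reproduces additive distances exactly", {
  set.seed(36)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr <- random_binary_tree(n)
    d <- ape::cophenetic.phylo(tr)
    est <- nj_from_distances(d)
    d2 <- ape::cophenetic.phylo(est)[rownames(d), colnames(d)]
    expect_equal(d2, d, tolerance = 1e-9)
    expect_equal(k_tree_score(tr, est)$k_score, 0, tolerance = 1e-6)
  }
})

test_that("NJ trees from alignments are order-invariant and clamped", {
  set.seed(37)
  tr <- simulate_tree(8, "yule")
  aln <- simulate_nt_alignment(tr, 500, 1)
  nj1 <- nj_tree(aln, "jukes_cantor")
  perm <- aln[sample(nrow(aln)), ]
  class(perm) <- class(aln)
  nj2 <- nj_tree(perm, "jukes_cantor")
  b1 <- bipartitions(nj1); b2 <- bipartitions(nj2)
  expect_setequal(names(b1), names(b2))
  expect_true(all(nj1$edge.length >= 0))
  # saturation is flagged with the offending pair
  sat <- as_alignment(c(x = strrep("A", 40), y = strrep("C", 40),
                        z = strrep("G", 40)))
  expect_error(alignment_distances(sat, "jukes_cantor"), "saturated")
})

test_that("gene-tree score tables rank concordant trees lower", {
  set.seed(38)
  ref <- simulate_tree(10, "yule")
  same <- list(g1 = ref, g2 = ref)
  tab <- score_gene_trees(same, ref)
  expect_equal(tab$k_score, c(0, 0))

  scrambled <- lapply(1:5, function(i) perturb_tree(ref, 4, 0.3))
  names(scrambled) <- paste0("bad", 1:5)
  noisy <- lapply(1:5, function(i) perturb_tree(ref, 0, 0.1))
  names(noisy) <- paste0("good", 1:5)
  tab2 <- score_gene_trees(c(scrambled, noisy), ref)
  mean_bad <- mean(tab2$k_score[grepl("bad", tab2$gene)])
  mean_good <- mean(tab2$k_score[grepl("good", tab2$gene)])
  expect_lt(mean_good, mean_bad)

  # a gene tree missing taxa still yields a row with pruning recorded
  partial <- ape::drop.tip(ref, c("t1", "t9"))
  tab3 <- score_gene_trees(list(part = partial), ref)
  expect_equal(tab3$pruned_leaf_count, 2)
  expect_equal(tab3$note, "")
})
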