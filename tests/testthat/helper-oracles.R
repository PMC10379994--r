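# Independent oracles and small generators used across the test files.
# These are deliberately written from the definitions, not by calling the
# package's own code paths.

# --- Nei's pi: all-pairs Hamming proportion ---------------------------------
pi_oracle <- function(strings, gap_mode = "complete") {
  rows <- strsplit(toupper(strings), "")
  m <- do.call(rbind, rows)
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  if (gap_mode == "complete") {
    keep <- apply(valid, 2, all)
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  pairs <- utils::combn(nrow(m), 2)
  ds <- apply(pairs, 2, function(ij) {
    ok <- valid[ij[1], ] & valid[ij[2], ]
    if (!sum(ok)) return(NA_real_)
    mean(m[ij[1], ok] != m[ij[2], ok])
  })
  if (all(is.na(ds))) return(NA_real_)
  sum(ds, na.rm = TRUE) / ncol(pairs)
}

# --- NG86 pathway brute force ----------------------------------------------
# Enumerates substitution orderings recursively (a different mechanism from
# the package's permutation matrix) and averages syn/nonsyn step counts over
# orderings avoiding stops, falling back to all orderings.
ng86_diff_oracle <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd, through_stop) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd, through_stop)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      syn <- code[[cur]] != "*" && code[[nxt]] != "*" && code[[cur]] == code[[nxt]]
      walk(nxt, setdiff(remaining, p),
           sd + as.numeric(syn), nd + as.numeric(!syn),
           through_stop || code[[nxt]] == "*")
    }
  }
  walk(c1, pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(mean(m[ok, 1]), mean(m[ok, 2]))
}

ng86_sites_oracle <- function(codon, code) {
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (code[[mut]] != "*" && code[[mut]] == code[[codon]]) s <- s + 1
    }
  }
  c(s / 3, 3 - s / 3)
}

# --- K tree score: grid-search minimisation over the scale factor -----------
# Takes the two split-length vectors over the union of splits and finds the
# scale minimising the score by dense grid search plus local refinement.
kscore_grid_oracle <- function(lr, lc) {
  score <- function(k) sqrt(sum((lr - k * lc)^2))
  ks <- seq(0, 10, by = 1e-4)
  sc2 <- colSums((outer(lc, ks) - lr)^2)  # (k*lc - lr)^2 summed
  k0 <- ks[which.min(sc2)]
  opt <- stats::optimize(score, c(max(0, k0 - 1e-3), k0 + 1e-3),
                         tol = 1e-12)
  list(k = opt$minimum, score = opt$objective)
}

# --- random generators ------------------------------------------------------
random_alignment_strings <- function(n_taxa, n_cols, gap_p = 0.1,
                                     alphabet = c("A", "C", "G", "T")) {
  sapply(seq_len(n_taxa), function(i) {
    ch <- sample(alphabet, n_cols, replace = TRUE)
    miss <- runif(n_cols) < gap_p
    ch[miss] <- sample(c("-", "N"), sum(miss), replace = TRUE)
    paste(ch, collapse = "")
  }) |> setNames(paste0("t", seq_len(n_taxa)))
}

random_binary_tree <- function(n_taxa, min_len = 0.05, max_len = 1) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) runif(n, min_len, max_len))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}
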