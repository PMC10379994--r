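# ---------------------------------------------------------------------------
# Nucleotide diversity (Nei's pi) and sliding windows
# ---------------------------------------------------------------------------

# Columns considered comparable: A/C/G/T. Gaps and N are missing data.
.valid_base <- function(m) m == "A" | m == "C" | m == "G" | m == "T"

#' Nucleotide diversity of an alignment
#'
#' Nei's pi: the mean, over all sequence pairs, of the proportion of
#' compared sites at which the two sequences differ. Under
#' `gap_mode = "complete"` any column containing a gap or N in any row is
#' removed before comparison; under `"pairwise"` sites are dropped per pair.
#'
#' @param aln a `mito_alignment` matrix (>= 2 rows), see [as_alignment()].
#' @param gap_mode `"complete"` (default) or `"pairwise"`.
#' @return pi in \[0, 1\], or `NA` when no comparable sites remain.
#' @export
nucleotide_diversity <- function(aln, gap_mode = c("complete", "pairwise")) {
  gap_mode <- match.arg(gap_mode)
  if (nrow(aln) < 2) stop("nucleotide diversity needs at least 2 sequences")
  v <- .valid_base(aln)
  if (gap_mode == "complete") {
    keep <- colSums(v) == nrow(aln)
    aln <- aln[, keep, drop = FALSE]
    v <- v[, keep, drop = FALSE]
  }
  n <- nrow(aln)
  dsum <- 0
  npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- v[i, ] & v[j, ]
      nc <- sum(comp)
      if (nc == 0L) next
      dsum <- dsum + sum(aln[i, comp] != aln[j, comp]) / nc
      npairs <- npairs + 1L
    }
  }
  if (npairs == 0L) return(NA_real_)
  dsum / choose(n, 2)
}

#' Sliding-window nucleotide diversity
#'
#' Windows of `window` alignment columns advance by `step` columns starting
#' at the first column; only full windows are reported. Each window's pi is
#' computed with [nucleotide_diversity()] under the given gap mode; windows
#' with fewer than `min_valid` comparable columns report `NA`. The window's
#' value is indexed at its midpoint (start + window/2, in 1-based alignment
#' columns).
#'
#' @param aln a `mito_alignment` matrix.
#' @param window window width in columns (default 200).
#' @param step step size in columns (default 20).
#' @param min_valid minimum comparable columns for a window to report a
#'   value (default 10).
#' @param gap_mode see [nucleotide_diversity()].
#' @return A data.frame of class `sliding_window_pi`: `start`, `midpoint`
#'   (1-based columns), `n_valid_sites`, `pi`.
#' @export
sliding_window_pi <- function(aln, window = 200, step = 20, min_valid = 10,
                              gap_mode = c("complete", "pairwise")) {
  gap_mode <- match.arg(gap_mode)
  nc <- ncol(aln)
  if (window > nc) stop("window exceeds alignment length")
  if (step < 1) stop("step must be >= 1")
  starts <- seq.int(0L, nc - window, by = step)  # 0-based starts
  v <- .valid_base(aln)
  res <- lapply(starts, function(s) {
    cols <- (s + 1L):(s + window)
    sub <- aln[, cols, drop = FALSE]
    n_valid <- sum(colSums(v[, cols, drop = FALSE]) == nrow(aln))
    pi <- if (n_valid < min_valid) NA_real_
          else nucleotide_diversity(sub, gap_mode)
    data.frame(start = s + 1L, midpoint = s + window / 2,
               n_valid_sites = n_valid, pi = pi)
  })
  out <- do.call(rbind, res)
  class(out) <- c("sliding_window_pi", "data.frame")
  out
}

#' Drop alignment columns with too much missing data
#'
#' Keeps columns whose combined gap + N fraction is at most
#' `max_gap_fraction`. This is a plain column filter for removing poorly
#' covered regions before diversity or distance computations; it makes no
#' attempt to judge alignment ambiguity.
#'
#' @param aln a `mito_alignment` matrix.
#' @param max_gap_fraction threshold in \[0, 1\]; 1 keeps everything.
#' @return The filtered alignment, with attribute `kept_columns` giving the
#'   original indices of the surviving columns.
#' @export
filter_columns <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  frac <- colMeans(!.valid_base(aln))
  keep <- which(frac <= max_gap_fraction)
  out <- aln[, keep, drop = FALSE]
  attr(out, "kept_columns") <- keep
  class(out) <- c("mito_alignment", "matrix", "array")
  out
}
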