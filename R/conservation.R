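## First-order conservation and hydrophobic preference.

#' Per-column conservation (relative entropy)
#'
#' First-order conservation of each alignment column,
#' \deqn{C_i = \sum_{a=1}^{20} f_i^a \ln(f_i^a / q^a),}
#' the Kullback-Leibler divergence (in nats) of the observed amino-acid
#' frequencies from the background distribution, with \eqn{0\ln 0 := 0}.
#'
#' @param fm A [estimate_frequencies()] result.
#' @return Numeric vector of \eqn{C_i}, one per column.
#' @export
position_conservation <- function(fm) {
  stopifnot(inherits(fm, "frequency_model"))
  q <- fm$background
  f <- fm$f_single
  term <- f * log(sweep(f, 2L, q, "/"))
  term[f == 0] <- 0
  rowSums(term)
}

#' Per-column hydrophobic preference
#'
#' Fraction of sequences carrying a hydrophobic residue at each column,
#' counted over the non-gap residues of the column.
#'
#' @param aln A [paired_alignment()].
#' @param hydrophobic_set Character vector of hydrophobic amino acids
#'   (default the packaged classification).
#' @return Numeric vector in `[0, 1]`, one value per column.
#' @export
hydrophobic_preference <- function(aln, hydrophobic_set = hydrophobic_residues()) {
  stopifnot(inherits(aln, "paired_alignment"))
  if (length(hydrophobic_set) == 0L ||
      !all(hydrophobic_set %in% AA_ALPHABET))
    stop("hydrophobic_set must be a non-empty subset of the 20 amino acids")
  h <- matrix(aln$seqs %in% hydrophobic_set, nrow = nrow(aln$seqs))
  non_gap <- aln$seqs != GAP
  m <- colSums(non_gap)
  if (any(m == 0L)) stop("degenerate-column error: all-gap column")
  colSums(h) / m
}

#' Select scores above a threshold
#'
#' For a numeric vector, returns the indices with score `>= threshold`.
#' For a coupling matrix, returns the upper-triangle pairs above threshold
#' together with the set of distinct columns they touch.
#'
#' @param x Numeric vector of per-column scores, or a `coupling_matrix`.
#' @param threshold Selection threshold (inclusive).
#' @return For vectors, an integer index vector. For coupling matrices, a
#'   list with `pairs` (data frame `i`, `j`, `c_ij`, decreasing),
#'   `n_pairs`, and `columns` (sorted distinct touched columns).
#' @export
select_top <- function(x, threshold) UseMethod("select_top")

#' @export
select_top.default <- function(x, threshold) {
  which(x >= threshold)
}

#' @export
select_top.coupling_matrix <- function(x, threshold) {
  C2 <- x$C2
  ut <- upper.tri(C2)
  idx <- which(ut & C2 >= threshold, arr.ind = TRUE)
  pairs <- data.frame(i = idx[, 1], j = idx[, 2],
                      c_ij = C2[idx])
  pairs <- pairs[order(-pairs$c_ij), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, n_pairs = nrow(pairs),
       columns = sort(unique(c(pairs$i, pairs$j))))
}
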