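## Single-site and pairwise amino-acid frequency estimation.

#' Estimate single-site and pairwise frequencies from an alignment
#'
#' Gaps are excluded from both numerator and denominator: \eqn{f_i^a} is
#' the frequency of residue \eqn{a} among the non-gap residues of column
#' \eqn{i}, and pair frequencies \eqn{f_{ij}^{ab}} are computed over the
#' sequences that are non-gapped at both columns. A pseudocount is added
#' per amino-acid cell (per pair cell for joints) before normalization.
#'
#' Pairwise counts are held as a sparse cross-product of residue
#' indicators, so the full column-pair table is never materialized; use
#' [pair_frequencies()] to extract one 20x20 joint table.
#'
#' @param aln A [paired_alignment()].
#' @param background Length-20 background distribution (default the
#'   packaged table); strictly positive, renormalized.
#' @param pseudocount Nonnegative per-cell pseudocount (default 1e-4; use 0
#'   for pure counting checks).
#' @return Object of class `frequency_model` with elements `f_single`
#'   (columns x 20), `background`, `pseudocount`, `effective_counts`
#'   (non-gap residues per column), and internal count matrices.
#' @export
estimate_frequencies <- function(aln, background = background_frequencies(),
                                 pseudocount = 1e-4) {
  stopifnot(inherits(aln, "paired_alignment"), pseudocount >= 0)
  if (length(background) != 20L) stop("background must have 20 entries")
  if (is.null(names(background))) names(background) <- AA_ALPHABET
  background <- background[AA_ALPHABET]
  if (anyNA(background) || any(background <= 0))
    stop("configuration error: background must be strictly positive over ",
         "all 20 amino acids")
  background <- background / sum(background)

  L <- aln$column_count
  n <- nrow(aln$seqs)
  code <- match(aln$seqs, AA_ALPHABET)       # NA at gaps
  dim(code) <- dim(aln$seqs)
  eff <- colSums(!is.na(code))
  if (any(eff == 0L))
    stop("degenerate-column error: column(s) ",
         paste(which(eff == 0L), collapse = ", "), " are entirely gaps")

  # counts[i, a]: occurrences of residue a at column i
  counts <- matrix(0L, L, 20L)
  for (a in 1:20) counts[, a] <- colSums(code == a, na.rm = TRUE)
  f_single <- (counts + pseudocount) / (eff + 20 * pseudocount)
  colnames(f_single) <- AA_ALPHABET

  # sparse indicator over (column, residue) super-index for pair counts
  obs <- which(!is.na(code))
  row_i <- ((obs - 1L) %% n) + 1L
  col_i <- ((obs - 1L) %/% n) + 1L
  super <- (col_i - 1L) * 20L + code[obs]
  X <- Matrix::sparseMatrix(i = row_i, j = super, x = 1,
                            dims = c(n, 20L * L))
  NG <- Matrix::sparseMatrix(i = row_i, j = col_i, x = 1, dims = c(n, L))

  structure(list(f_single = f_single, background = background,
                 pseudocount = pseudocount, effective_counts = eff,
                 counts = counts, X = X, NG = NG,
                 n_sequences = n, n_columns = L),
            class = "frequency_model")
}

#' @export
print.frequency_model <- function(x, ...) {
  cat("<frequency_model> ", x$n_columns, " columns, ", x$n_sequences,
      " sequences, pseudocount ", x$pseudocount, "\n", sep = "")
  invisible(x)
}

#' Joint frequency table of one column pair
#'
#' @param fm A `frequency_model`.
#' @param i,j 1-based column indices.
#' @return 20x20 matrix of \eqn{f_{ij}^{ab}} (rows: residue at `i`),
#'   normalized over sequences non-gapped at both columns, with the model's
#'   pseudocount applied per cell.
#' @export
pair_frequencies <- function(fm, i, j) {
  stopifnot(inherits(fm, "frequency_model"))
  Xi <- fm$X[, (i - 1L) * 20L + 1:20, drop = FALSE]
  Xj <- fm$X[, (j - 1L) * 20L + 1:20, drop = FALSE]
  cnt <- as.matrix(Matrix::crossprod(Xi, Xj))
  nij <- sum(Matrix::rowSums(Xi) * Matrix::rowSums(Xj) > 0)
  if (nij == 0L) stop("no sequence is non-gapped at both columns ",
                      i, " and ", j)
  out <- (cnt + fm$pseudocount) / (nij + 400 * fm$pseudocount)
  dimnames(out) <- list(AA_ALPHABET, AA_ALPHABET)
  out
}
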