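## Second-order (coupling) conservation and its random-sequence null.

#' Coupling conservation between all column pairs
#'
#' Second-order conservation
#' \deqn{C_{ij} = \sqrt{\sum_{a,b} k_i^a k_j^b (f_{ij}^{ab} - f_i^a f_j^b)^2}}
#' with conservation-derived coefficients
#' \deqn{k_i^a = \ln\frac{f_i^a (1 - q^a)}{q^a (1 - f_i^a)}.}
#'
#' The coefficients use the model's pseudocounted single-site frequencies,
#' clamped away from 0 and 1 (the logit diverges there), so the model must
#' be built with `pseudocount > 0`. Inside the squared deviation, the
#' product term uses the marginals of the pair-restricted joint table, so
#' two independent columns give \eqn{C_{ij} = 0} up to pseudocount
#' resolution. Because the weights \eqn{k_i^a k_j^b} are signed, the inner
#' sum can dip below zero at noise level; it is floored at zero before the
#' square root.
#'
#' @param fm A [estimate_frequencies()] result with positive pseudocount.
#' @return Object of class `coupling_matrix`: list with `C2` (symmetric
#'   columns x columns matrix, diagonal `NA`), `C2_signed`, `k` (columns x
#'   20 coefficient matrix) and `n_pair_obs` (per-pair non-gap sequence
#'   counts).
#' @export
coupling_conservation <- function(fm) {
  stopifnot(inherits(fm, "frequency_model"))
  if (fm$pseudocount <= 0)
    stop("coupling_conservation requires pseudocount > 0 (k diverges at ",
         "boundary frequencies)")
  L <- fm$n_columns
  pc <- fm$pseudocount
  q <- fm$background
  eps <- pc / (max(fm$effective_counts) + 20 * pc)
  f <- pmin(pmax(fm$f_single, eps), 1 - eps)
  if (any(f <= 0 | f >= 1))
    stop("numeric-guard error: frequencies at 0 or 1 after pseudocounting")
  k <- log(sweep(f, 2L, 1 - q, "*")) -
    log(sweep(1 - f, 2L, q, "*"))

  # all pair counts at once: crossprod of the (column, residue) indicator
  CC <- Matrix::crossprod(fm$X)                       # (20L) x (20L)
  Nij <- as.matrix(Matrix::crossprod(fm$NG))          # co-observation counts
  if (any(Nij[upper.tri(Nij)] == 0))
    stop("column pair with no co-observed sequences")
  den <- Nij + 400 * pc

  # M[[a]][i, j]: count of sequences with residue a at i and non-gap at j
  Msum <- vector("list", 20L)
  for (a in 1:20) {
    Xa <- fm$X[, seq.int(a, 20L * L, by = 20L), drop = FALSE]
    Msum[[a]] <- as.matrix(Matrix::crossprod(Xa, fm$NG))
  }

  S <- matrix(0, L, L)
  rows <- function(a) seq.int(a, 20L * L, by = 20L)
  for (a in 1:20) {
    FAa <- (Msum[[a]] + 20 * pc) / den        # marginal f_i^a within pair
    CCa <- CC[rows(a), , drop = FALSE]
    for (b in 1:20) {
      Cab <- as.matrix(CCa[, rows(b), drop = FALSE])
      FAb <- (Msum[[b]] + 20 * pc) / den
      D <- (Cab + pc) / den - FAa * t(FAb)
      S <- S + tcrossprod(k[, a], k[, b]) * D * D
    }
  }
  S <- (S + t(S)) / 2
  C2 <- sqrt(pmax(S, 0))
  C2s <- sign(S) * sqrt(abs(S))
  diag(C2) <- NA_real_
  diag(C2s) <- NA_real_
  structure(list(C2 = C2, C2_signed = C2s, k = k, n_pair_obs = Nij,
                 pseudocount = pc),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  v <- coupling_values(x)
  cat("<coupling_matrix> ", nrow(x$C2), " columns; off-diagonal C_ij ",
      sprintf("mean %.4g, max %.4g", mean(v), max(v)), "\n", sep = "")
  invisible(x)
}

#' Off-diagonal coupling values
#'
#' @param cm A `coupling_matrix`.
#' @param signed If `TRUE`, return the signed magnitudes instead of the
#'   zero-floored values.
#' @return Numeric vector of the upper-triangle \eqn{C_{ij}} values.
#' @export
coupling_values <- function(cm, signed = FALSE) {
  stopifnot(inherits(cm, "coupling_matrix"))
  m <- if (signed) cm$C2_signed else cm$C2
  m[upper.tri(m)]
}

#' Random-sequence null of the coupling spectrum
#'
#' Generates `n_seqs` independent sequences of `n_cols` residues, each
#' drawn i.i.d. from the background distribution, and computes the coupling
#' conservation matrix. `mean`, `sd` and the Shapiro-Wilk `shapiro_w`
#' (computed on at most 5000 values) describe the signed off-diagonal
#' magnitudes, which are Gaussian-like around zero under the null; `max`
#' is the largest zero-floored \eqn{C_{ij}}, the quantity compared against
#' selection thresholds.
#'
#' @param n_seqs,n_cols Dimensions of the null alignment.
#' @param seed Integer seed.
#' @param background Length-20 sampling distribution (default packaged).
#' @param pseudocount Passed to [estimate_frequencies()].
#' @return List with `coupling` (the `coupling_matrix`), `mean`, `sd`,
#'   `max`, and `shapiro_w`.
#' @export
coupling_null <- function(n_seqs, n_cols, seed = NULL,
                          background = background_frequencies(),
                          pseudocount = 1e-4) {
  stopifnot(n_seqs >= 2, n_cols >= 2)
  background <- background / sum(background)
  m <- with_seed(seed, matrix(
    sample(AA_ALPHABET, n_seqs * n_cols, replace = TRUE, prob = background),
    nrow = n_seqs))
  aln <- paired_alignment(m, paste0("null", seq_len(n_seqs)),
                          list(all = c(0L, n_cols)))
  cm <- coupling_conservation(
    estimate_frequencies(aln, background, pseudocount))
  v <- coupling_values(cm, signed = TRUE)
  sub <- if (length(v) > 5000) {
    with_seed(if (is.null(seed)) NULL else seed + 1L,
              sample(v, 5000))
  } else v
  list(coupling = cm, mean = mean(v), sd = stats::sd(v),
       max = max(coupling_values(cm)),
       shapiro_w = unname(stats::shapiro.test(sub)$statistic))
}
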