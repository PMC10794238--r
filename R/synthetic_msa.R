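## Planted-signal synthetic alignments and nulls.

#' Specify a synthetic alignment
#'
#' Describes an alignment of independent background-drawn sequences with
#' optional planted signals: conserved columns (a dominant residue drawn
#' with probability `dominance`) and covarying column pairs (two-state
#' 50/50 columns whose states agree with probability `correlation`,
#' otherwise independent). A column may carry at most one planted signal.
#'
#' @param n_seqs,n_cols Alignment dimensions.
#' @param background Length-20 sampling distribution (default packaged).
#' @param conserved List of `list(col, residue, dominance)` entries
#'   (1-based columns).
#' @param coupled List of `list(cols = c(i, j), residues_i = c(a1, a2),
#'   residues_j = c(b1, b2), correlation)` entries.
#' @param gap_rate Independent per-cell gap probability.
#' @param seed Integer seed.
#' @param domain_ranges Optional named 0-based half-open ranges (default a
#'   single domain `all`).
#' @return Object of class `synthetic_msa_spec`.
#' @export
synthetic_msa_spec <- function(n_seqs, n_cols,
                               background = background_frequencies(),
                               conserved = list(), coupled = list(),
                               gap_rate = 0, seed = 1L,
                               domain_ranges = NULL) {
  stopifnot(n_seqs >= 1, n_cols >= 1, gap_rate >= 0, gap_rate < 1)
  planted <- integer(0)
  for (cv in conserved) {
    stopifnot(cv$col >= 1, cv$col <= n_cols,
              cv$residue %in% AA_ALPHABET,
              cv$dominance >= 0, cv$dominance <= 1)
    planted <- c(planted, cv$col)
  }
  for (cp in coupled) {
    stopifnot(length(cp$cols) == 2L, all(cp$cols >= 1),
              all(cp$cols <= n_cols),
              all(cp$residues_i %in% AA_ALPHABET),
              all(cp$residues_j %in% AA_ALPHABET),
              cp$correlation >= 0, cp$correlation <= 1)
    planted <- c(planted, cp$cols)
  }
  if (anyDuplicated(planted))
    stop("spec error: a column may carry only one planted signal")
  structure(list(n_seqs = n_seqs, n_cols = n_cols,
                 background = background / sum(background),
                 conserved = conserved, coupled = coupled,
                 gap_rate = gap_rate, seed = as.integer(seed),
                 domain_ranges = domain_ranges %||%
                   list(all = c(0L, n_cols))),
            class = "synthetic_msa_spec")
}

#' Sample a synthetic alignment
#'
#' @param spec A [synthetic_msa_spec()].
#' @return A [paired_alignment()]; deterministic given the spec's seed.
#' @export
sample_msa <- function(spec) {
  stopifnot(inherits(spec, "synthetic_msa_spec"))
  with_seed(spec$seed, {
    n <- spec$n_seqs; L <- spec$n_cols
    m <- matrix(sample(AA_ALPHABET, n * L, replace = TRUE,
                       prob = spec$background), nrow = n)
    for (cv in spec$conserved) {
      hit <- stats::runif(n) < cv$dominance
      m[hit, cv$col] <- cv$residue
    }
    for (cp in spec$coupled) {
      z <- sample(1:2, n, replace = TRUE)
      agree <- stats::runif(n) < cp$correlation
      z2 <- ifelse(agree, z, sample(1:2, n, replace = TRUE))
      m[, cp$cols[1]] <- cp$residues_i[z]
      m[, cp$cols[2]] <- cp$residues_j[z2]
    }
    if (spec$gap_rate > 0)
      m[stats::runif(n * L) < spec$gap_rate] <- GAP
    paired_alignment(m, sprintf("synth%04d", seq_len(n)),
                     spec$domain_ranges)
  })
}
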