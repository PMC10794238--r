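## Contact-energy evaluation under a 20x20 potential.

.seq_chars <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L)
    seq <- strsplit(seq, "")[[1]]
  toupper(seq)
}

#' Contact energy of a sequence on a contact map
#'
#' \deqn{E = \sum_{(i,j)} \xi(\mu_i, \mu_j) \Delta_{ij}} summed over the
#' contacts of the map. Gapped positions contribute zero for their
#' contacts (with a warning); any other non-canonical residue is an error.
#'
#' @param seq Character vector of one-letter codes (or a single string)
#'   covering all residue indices in the map.
#' @param cmap A `contact_map` (or any list with a `contacts` data frame).
#' @param em An `energy_model`.
#' @return Total contact energy (MJ units).
#' @export
sequence_energy <- function(seq, cmap, em) {
  seq <- .seq_chars(seq)
  ct <- cmap$contacts
  if (nrow(ct) == 0L) return(0)
  if (max(ct$i, ct$j) > length(seq))
    stop("sequence shorter than the contacting indices")
  a <- seq[ct$i]; b <- seq[ct$j]
  gap <- a == GAP | b == GAP
  if (any(!(a[!gap] %in% AA_ALPHABET) | !(b[!gap] %in% AA_ALPHABET)))
    stop("alphabet error: residue outside the 20-letter alphabet")
  if (any(gap))
    warning(sum(gap), " contact(s) involve a gapped position; ",
            "they contribute zero energy")
  sum(em$table[cbind(a[!gap], b[!gap])])
}

#' Energy components of a two-chain complex
#'
#' Partitions the total contact energy \eqn{E = E_1 + E_2 + E_{12}} into
#' the intra-chain energies of the receiver (Rec) and kinase (HK) chains
#' and the inter-chain energy. Under the rigid-binding convention,
#' comparisons across binding decoys use \eqn{E_{12}} only, since
#' \eqn{E_1} and \eqn{E_2} are pose-invariant.
#'
#' @param seq_rec,seq_hk One-letter sequences of the Rec and HK chains, in
#'   residue order.
#' @param cmap A two-chain `contact_map`.
#' @param em An `energy_model`.
#' @param rec_chain,hk_chain Chain labels (defaults: first and second
#'   chain of the map).
#' @param rigid If `TRUE`, the returned total `E` equals `E12`.
#' @return List with `E1`, `E2`, `E12`, `E`.
#' @export
complex_energy <- function(seq_rec, seq_hk, cmap, em,
                           rec_chain = NULL, hk_chain = NULL,
                           rigid = FALSE) {
  chains <- unique(cmap$chain)
  if (length(chains) < 2L) stop("complex_energy needs a two-chain map")
  rec_chain <- rec_chain %||% chains[1]
  hk_chain <- hk_chain %||% chains[2]
  seq_rec <- .seq_chars(seq_rec); seq_hk <- .seq_chars(seq_hk)
  full <- character(cmap$n_res)
  if (sum(cmap$chain == rec_chain) != length(seq_rec) ||
      sum(cmap$chain == hk_chain) != length(seq_hk))
    stop("sequence length does not match chain residue count")
  full[cmap$chain == rec_chain] <- seq_rec
  full[cmap$chain == hk_chain] <- seq_hk
  E1 <- sequence_energy(full, subset_contacts(cmap, paste0("intra_", rec_chain)), em)
  E2 <- sequence_energy(full, subset_contacts(cmap, paste0("intra_", hk_chain)), em)
  E12 <- sequence_energy(full, subset_contacts(cmap, "inter"), em)
  list(E1 = E1, E2 = E2, E12 = E12, E = if (rigid) E12 else E1 + E2 + E12)
}
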