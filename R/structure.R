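## Structures, contact maps and alignment-to-structure mapping.

#' Construct a structure object from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno` (author residue
#'   number), `aa` (one-letter amino-acid code), `elety` (atom name), `x`,
#'   `y`, `z` (Angstrom).
#' @return Object of class `protein_structure` with the atom table and a
#'   derived residue table (one row per residue, in chain-then-resno
#'   order).
#' @export
protein_structure <- function(atoms) {
  need <- c("chain", "resno", "aa", "elety", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  key <- paste(atoms$chain, atoms$resno)
  first <- !duplicated(key)
  res <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                    aa = atoms$aa[first], stringsAsFactors = FALSE)
  res$index <- seq_len(nrow(res))
  atoms$res_index <- match(key, key[first])
  structure(list(atoms = atoms, residues = res),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  ch <- table(x$residues$chain)
  cat("<protein_structure> ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " heavy atoms (",
      paste(names(ch), ch, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' One-letter sequence of one chain
#' @param s A `protein_structure`.
#' @param chain Chain identifier.
#' @return Character vector of one-letter codes in residue order.
#' @export
chain_sequence <- function(s, chain) {
  r <- s$residues[s$residues$chain == chain, , drop = FALSE]
  if (nrow(r) == 0L) stop("selection error: no residues in chain ", chain)
  r$aa
}

#' Read a protein structure from a PDB file
#'
#' Keeps heavy atoms of standard ATOM records only: hydrogens are dropped,
#' HETATM records excluded, and alternate locations resolved to the
#' highest-occupancy conformer.
#'
#' @param path PDB file.
#' @param chains Optional chain identifiers to retain (default all).
#' @return A [protein_structure()].
#' @export
read_structure <- function(path, chains = NULL) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  # hydrogens: element symbol if present, else atom-name heuristic
  if ("elesy" %in% names(at) && any(nzchar(at$elesy), na.rm = TRUE)) {
    at <- at[is.na(at$elesy) | toupper(at$elesy) != "H", , drop = FALSE]
  }
  at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(at$chain))
    if (length(missing))
      stop("selection error: chain(s) not in structure: ",
           paste(missing, collapse = ", "))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  # resolve altlocs: keep highest occupancy per (chain, resno, atom name)
  alt <- !is.na(at$alt) & nzchar(at$alt)
  if (any(alt)) {
    key <- paste(at$chain, at$resno, at$elety)
    o <- order(key, -replace(at$o, is.na(at$o), 1))
    at <- at[o, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), ,
             drop = FALSE]
  }
  aa <- bio3d::aa321(at$resid)
  keep <- aa %in% AA_ALPHABET
  at <- at[keep, , drop = FALSE]
  aa <- aa[keep]
  if (nrow(at) == 0L) stop("input error: no standard residues retained")
  protein_structure(data.frame(
    chain = at$chain, resno = at$resno, aa = aa, elety = at$elety,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

## residue-by-residue minimum heavy-atom distance matrix
.residue_min_dist <- function(s) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  n <- nrow(s$residues)
  idx <- split(seq_len(nrow(s$atoms)), s$atoms$res_index)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      m <- min(D[idx[[i]], idx[[j]], drop = FALSE])
      out[i, j] <- m
      out[j, i] <- m
    }
  }
  out
}

#' Build a residue contact map
#'
#' A contact is recorded between residues whose closest heavy atoms lie
#' strictly below `cutoff`. Within a chain, residues must additionally be
#' at least `min_sep` apart in sequence; inter-chain pairs carry no
#' separation constraint. Contacts are labelled `intra_<chain>` or
#' `inter`.
#'
#' @param s A `protein_structure`.
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @param min_sep Minimum intra-chain sequence separation (default 2).
#' @return Object of class `contact_map`: list with `contacts` (data frame
#'   `i`, `j`, `partition`, `min_distance`; `i < j` over global residue
#'   indices), `n_res`, `chain` (per-residue chain labels), `cutoff`,
#'   `min_sep`.
#' @export
build_contact_map <- function(s, cutoff = 5.0, min_sep = 2L) {
  stopifnot(inherits(s, "protein_structure"))
  n <- nrow(s$residues)
  Dmin <- .residue_min_dist(s)
  chain <- s$residues$chain
  resno <- s$residues$resno
  ii <- which(upper.tri(Dmin), arr.ind = TRUE)
  same <- chain[ii[, 1]] == chain[ii[, 2]]
  sep_ok <- !same | abs(resno[ii[, 1]] - resno[ii[, 2]]) >= min_sep
  hit <- Dmin[ii] < cutoff & sep_ok
  contacts <- data.frame(
    i = ii[hit, 1], j = ii[hit, 2],
    partition = ifelse(same[hit], paste0("intra_", chain[ii[hit, 1]]),
                       "inter"),
    min_distance = Dmin[ii][hit], stringsAsFactors = FALSE)
  contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(contacts = contacts, n_res = n, chain = chain,
                 resno = resno, cutoff = cutoff, min_sep = as.integer(min_sep)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  tab <- table(x$contacts$partition)
  cat("<contact_map> ", x$n_res, " residues, ", nrow(x$contacts),
      " contacts (cutoff ", x$cutoff, " A, min_sep ", x$min_sep, "; ",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Subset a contact map by partition label
#'
#' @param cmap A `contact_map`.
#' @param partitions Partition labels to keep (e.g. `"inter"` or
#'   `"intra_A"`).
#' @return A `contact_map` over the same residue indexing with only the
#'   selected contacts.
#' @export
subset_contacts <- function(cmap, partitions) {
  stopifnot(inherits(cmap, "contact_map"))
  keep <- cmap$contacts$partition %in% partitions
  out <- cmap
  out$contacts <- cmap$contacts[keep, , drop = FALSE]
  rownames(out$contacts) <- NULL
  out
}

#' Extract one chain's contact map with local indexing
#'
#' Subsets the intra-chain contacts of `chain` and re-indexes residues
#' 1..n within the chain, for use as a standalone folding map.
#'
#' @param cmap A `contact_map`.
#' @param chain Chain identifier.
#' @return A `contact_map` over the chain's residues only.
#' @export
chain_contact_map <- function(cmap, chain) {
  stopifnot(inherits(cmap, "contact_map"))
  sel <- which(cmap$chain == chain)
  if (length(sel) == 0L) stop("selection error: no residues in chain ", chain)
  ct <- cmap$contacts
  keep <- ct$partition == paste0("intra_", chain)
  ct <- ct[keep, , drop = FALSE]
  ct$i <- match(ct$i, sel)
  ct$j <- match(ct$j, sel)
  rownames(ct) <- NULL
  structure(list(contacts = ct, n_res = length(sel),
                 chain = rep(chain, length(sel)),
                 resno = cmap$resno[sel], cutoff = cmap$cutoff,
                 min_sep = cmap$min_sep),
            class = "contact_map")
}

#' Minimum heavy-atom distance between two residues
#'
#' @param s A `protein_structure`.
#' @param i,j Global residue indices (see `s$residues$index`).
#' @return Distance in Angstrom (0 for a residue with itself).
#' @export
pair_min_distance <- function(s, i, j) {
  stopifnot(inherits(s, "protein_structure"))
  if (i == j) return(0)
  a <- as.matrix(s$atoms[s$atoms$res_index == i, c("x", "y", "z")])
  b <- as.matrix(s$atoms[s$atoms$res_index == j, c("x", "y", "z")])
  if (nrow(a) == 0L || nrow(b) == 0L) stop("residue index out of range")
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Map alignment columns to structure residues
#'
#' Aligns each domain's consensus sequence (most frequent non-gap residue
#' per column) to the corresponding structure chain with a global
#' pairwise alignment and returns the monotone column-to-residue map.
#' Columns aligned to a gap in the structure are reported unmapped.
#'
#' @param aln A `paired_alignment`.
#' @param s A `protein_structure`.
#' @param domain_chains Named character vector mapping domain names to
#'   chain identifiers, e.g. `c(Rec = "A", DHp = "B")`.
#' @return Data frame with `domain`, `column` (1-based alignment column),
#'   `res_index` (global residue index, `NA` when unmapped), `resno`.
#' @export
map_alignment_to_structure <- function(aln, s, domain_chains) {
  stopifnot(inherits(aln, "paired_alignment"),
            inherits(s, "protein_structure"))
  out <- list()
  for (d in names(domain_chains)) {
    cols <- domain_columns(aln, d)
    cons <- apply(aln$seqs[, cols, drop = FALSE], 2L, function(col) {
      col <- col[col != GAP]
      if (length(col) == 0L) return("A")
      names(which.max(table(col)))
    })
    chain <- domain_chains[[d]]
    saa <- chain_sequence(s, chain)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(paste0(cons, collapse = "")),
      Biostrings::AAString(paste0(saa, collapse = "")),
      type = "global", gapOpening = 10, gapExtension = 0.5)
    p_chars <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s_chars <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ci <- 0L; ri <- 0L
    res_global <- s$residues$index[s$residues$chain == chain]
    map <- rep(NA_integer_, length(cols))
    for (k in seq_along(p_chars)) {
      pc <- p_chars[k] != "-"
      sc <- s_chars[k] != "-"
      if (pc) ci <- ci + 1L
      if (sc) ri <- ri + 1L
      if (pc && sc) map[ci] <- res_global[ri]
    }
    mapped <- map[!is.na(map)]
    if (any(diff(mapped) <= 0)) stop("mapping error: non-monotone mapping")
    out[[d]] <- data.frame(domain = d, column = cols, res_index = map,
                           resno = s$residues$resno[map],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
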