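## Desk-scale toy structures with designated buried / surface / interface
## positions.

#' Generate a toy structure
#'
#' Builds a compact serpentine lattice fold (one pseudo-CA per residue on
#' a jittered cubic grid plus one outward-pointing pseudo-CB), giving the
#' contact-count heterogeneity of a globular domain: interior positions
#' accumulate many non-local contacts, corner/edge positions few. The
#' two-chain variant places a translated copy facing the first chain,
#' offset by half a lattice spacing laterally so the two surfaces
#' interdigitate: the native pose is then at closest complementary
#' approach and rigid-body perturbations lose interface contacts rather
#' than gain them, as in a docked complex. Position classes are derived from
#' the resulting contact map: `interface` positions have at least one
#' inter-chain contact; among the rest, `buried` (`surface`) positions
#' fall in the top (bottom) quartile of intra-chain contact counts.
#'
#' With the default 3.5 Angstrom spacing, both direct and face-diagonal
#' lattice neighbours fall inside the 5 Angstrom contact cutoff, so
#' interior residues reach contact degrees near 11 while corners stay
#' near 2 - the buried/surface contrast a globular domain shows.
#'
#' Unless `native_seq = "alanine"`, each chain receives a heterogeneous
#' native sequence designed by simulated annealing of the full contact
#' energy (see [design_native_like()]), so that fixed-partner energetics
#' (e.g. the inter-chain energy of a binding partner) are
#' position-specific rather than uniform.
#'
#' @param n_res Residues per chain (>= 8).
#' @param chains 1 or 2.
#' @param seed Integer seed for the coordinate jitter and sequence
#'   design.
#' @param spacing Lattice spacing in Angstrom (default 3.5).
#' @param chain_gap Gap between facing chain layers (default 3.4).
#' @param cutoff,min_sep Contact definition passed to
#'   [build_contact_map()].
#' @param native_seq `"designed"` (default) or `"alanine"`.
#' @param em Energy model used for sequence design.
#' @return Object of class `toy_structure`: list with `structure` (a
#'   [protein_structure()]), `cmap` (its `contact_map`), and `classes`
#'   (list `buried`, `surface`, `interface` of global residue indices).
#' @export
make_toy_structure <- function(n_res, chains = 1L, seed = 1L,
                               spacing = 3.5, chain_gap = 3.4,
                               cutoff = 5.0, min_sep = 2L,
                               native_seq = c("designed", "alanine"),
                               em = NULL) {
  native_seq <- match.arg(native_seq)
  stopifnot(n_res >= 8, chains %in% c(1L, 2L))
  nx <- 3L; ny <- 3L
  nz <- ceiling(n_res / (nx * ny))
  path <- matrix(0, n_res, 3)
  r <- 0L
  for (z in seq_len(nz)) {
    ys <- if (z %% 2L) seq_len(ny) else rev(seq_len(ny))
    for (y in ys) {
      xs <- if ((z + y) %% 2L) seq_len(nx) else rev(seq_len(nx))
      for (x in xs) {
        r <- r + 1L
        if (r > n_res) break
        path[r, ] <- c(x, y, z)
      }
      if (r >= n_res) break
    }
    if (r >= n_res) break
  }
  with_seed(seed, {
    ca <- (path - 1) * spacing +
      matrix(stats::runif(3 * n_res, -0.25, 0.25), n_res, 3)
    centroid <- colMeans(ca)
    dir <- sweep(ca, 2L, centroid)
    nrm <- sqrt(rowSums(dir^2))
    dir[nrm < 1e-6, ] <- rep(c(0, 0, 1), each = sum(nrm < 1e-6))
    nrm[nrm < 1e-6] <- 1
    cb <- ca + 1.7 * dir / nrm

    mk_atoms <- function(ca, cb, chain, resno0 = 0L) {
      data.frame(
        chain = chain,
        resno = rep(seq_len(nrow(ca)) + resno0, 2L),
        aa = "A", elety = rep(c("CA", "CB"), each = nrow(ca)),
        x = c(ca[, 1], cb[, 1]), y = c(ca[, 2], cb[, 2]),
        z = c(ca[, 3], cb[, 3]), stringsAsFactors = FALSE)
    }
    atoms <- mk_atoms(ca, cb, "A")
    if (chains == 2L) {
      shift <- c(max(ca[, 1]) - min(ca[, 1]) + chain_gap,
                 spacing / 2, spacing / 2)
      ca2 <- sweep(ca, 2L, shift, "+")
      cb2 <- sweep(cb, 2L, shift, "+")
      atoms <- rbind(atoms, mk_atoms(ca2, cb2, "B"))
    }
    s <- protein_structure(atoms)
    cmap <- build_contact_map(s, cutoff = cutoff, min_sep = min_sep)
    if (native_seq == "designed") {
      if (is.null(em)) em <- mj_energy_model()
      aa <- design_native_like(cmap, em, 1, seed = seed + 7L)[1, ]
      s$residues$aa <- aa
      s$atoms$aa <- aa[s$atoms$res_index]
    }
    ct <- cmap$contacts
    intra <- ct[ct$partition != "inter", , drop = FALSE]
    n_tot <- cmap$n_res
    cnt <- tabulate(c(intra$i, intra$j), nbins = n_tot)
    inter_hit <- rep(FALSE, n_tot)
    inter <- ct[ct$partition == "inter", , drop = FALSE]
    inter_hit[unique(c(inter$i, inter$j))] <- TRUE
    qs <- stats::quantile(cnt, c(0.25, 0.75))
    classes <- list(
      buried = which(cnt >= qs[2] & !inter_hit),
      surface = which(cnt <= qs[1] & !inter_hit),
      interface = which(inter_hit))
    structure(list(structure = s, cmap = cmap, classes = classes,
                   seed = as.integer(seed)),
              class = "toy_structure")
  })
}

#' @export
print.toy_structure <- function(x, ...) {
  cl <- x$classes
  cat("<toy_structure> ", x$cmap$n_res, " residues; buried ",
      length(cl$buried), ", surface ", length(cl$surface),
      ", interface ", length(cl$interface), "\n", sep = "")
  invisible(x)
}
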