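## Residue-level frustration under the contact potential.

.incident_neighbors <- function(cmap, pos) {
  ct <- cmap$contacts
  c(ct$j[ct$i == pos], ct$i[ct$j == pos])
}

#' Residue-level frustration index
#'
#' Z-score of the native incident contact energy of position `pos` against
#' decoys that randomize only the identity at `pos` (contact neighbors
#' fixed):
#' \deqn{F_i = \frac{\langle E_i^U \rangle - E_i^N}
#'   {\sqrt{\frac{1}{N}\sum_k (E_i^U - \langle E_i^U \rangle)^2}}.}
#' With attractive contact energies negative, positive \eqn{F_i} marks a
#' minimally frustrated position (native below the decoy mean).
#'
#' @param seq One-letter sequence covering the map's residue indices.
#' @param pos Residue index whose frustration is evaluated.
#' @param cmap A `contact_map`; the incident contacts of `pos` define
#'   \eqn{E_i}.
#' @param em An `energy_model`.
#' @param n_decoys Number of decoy draws N (default 1000).
#' @param seed Integer seed for the decoy draws.
#' @param composition `"native"` (default) draws decoy identities from the
#'   empirical amino-acid composition of the native sequence; `"uniform"`
#'   draws uniformly over the 20 types.
#' @return Numeric \eqn{F_i} with attributes `native_energy`,
#'   `decoy_mean`, `decoy_sd`.
#' @export
frustration_index <- function(seq, pos, cmap, em, n_decoys = 1000L,
                              seed = NULL,
                              composition = c("native", "uniform")) {
  composition <- match.arg(composition)
  seq <- .seq_chars(seq)
  nb <- .incident_neighbors(cmap, pos)
  if (length(nb) == 0L)
    stop("no-contact error: position ", pos, " has no contacts")
  if (seq[pos] == GAP || any(seq[nb] == GAP))
    stop("gap in the contact neighborhood of position ", pos)
  cand <- rowSums(em$table[, seq[nb], drop = FALSE])
  E_N <- cand[seq[pos]]
  w <- if (composition == "native") {
    obs <- seq[seq != GAP]
    tabulate(match(obs, AA_ALPHABET), nbins = 20L) / length(obs)
  } else rep(1 / 20, 20L)
  # exact decoy variance over the composition distribution
  mu <- sum(w * cand)
  v <- sum(w * (cand - mu)^2)
  if (v <= 0)
    stop("degenerate-decoy error: zero decoy variance at position ", pos)
  draws <- with_seed(seed, sample.int(20L, n_decoys, replace = TRUE,
                                      prob = w))
  E_U <- cand[draws]
  sdU <- sd_pop(E_U)
  if (sdU == 0)
    stop("degenerate-decoy error: sampled decoys have zero variance at ",
         "position ", pos)
  structure((mean(E_U) - E_N) / sdU,
            native_energy = unname(E_N), decoy_mean = mean(E_U),
            decoy_sd = sdU)
}

#' Frustration profile of a sequence set
#'
#' Computes \eqn{F_i} per sequence, then averages per position over the
#' set (sequences whose neighborhood is gapped at a position are skipped
#' there and the contributing count recorded).
#'
#' @param seqs Character matrix (sequences x residues) or vector of
#'   equal-length strings.
#' @param cmap,em,n_decoys,seed,composition As [frustration_index()]; the
#'   decoy-draw stream restarts from `seed` for every sequence, so
#'   duplicated sequences contribute identical values and the profile of
#'   a duplicated set equals that of the deduplicated one.
#' @param positions Residue indices to profile (default: all positions
#'   with at least one contact).
#' @param label Optional condition label (e.g. "FS", "FBS", "NS").
#' @return Object of class `frustration_profile`: data frame with
#'   `position`, `F`, `n` plus a `label` attribute.
#' @export
ensemble_frustration_profile <- function(seqs, cmap, em, n_decoys = 1000L,
                                         seed = NULL,
                                         composition = "native",
                                         positions = NULL, label = NULL) {
  if (!is.matrix(seqs)) {
    seqs <- do.call(rbind, lapply(seqs, .seq_chars))
  }
  if (nrow(seqs) == 0L) stop("input error: empty sequence set")
  ct <- table(factor(c(cmap$contacts$i, cmap$contacts$j),
                     levels = seq_len(cmap$n_res)))
  positions <- positions %||% which(as.integer(ct) > 0L)
  Fmat <- matrix(NA_real_, nrow(seqs), length(positions))
  for (r in seq_len(nrow(seqs))) {
    Fmat[r, ] <- with_seed(seed, vapply(positions, function(pos)
      tryCatch(
        as.numeric(frustration_index(seqs[r, ], pos, cmap, em,
                                     n_decoys, seed = NULL,
                                     composition = composition)),
        error = function(e) NA_real_), 0))
  }
  out <- data.frame(position = positions,
                    F = colMeans(Fmat, na.rm = TRUE),
                    n = colSums(!is.na(Fmat)))
  out$F[out$n == 0L] <- NA_real_
  structure(out, class = c("frustration_profile", "data.frame"),
            label = label)
}

#' Frustration change between two conditions
#'
#' \eqn{\Delta F_i = F_i(\mathrm{p2}) - F_i(\mathrm{p1})}, classified by
#' sign among the positions with \eqn{|\Delta F_i| \ge} `threshold`
#' (positive: became less frustrated in `p2`).
#'
#' @param p1,p2 `frustration_profile` objects over identical position
#'   sets.
#' @param threshold Classification threshold (default 0.70).
#' @return List with `delta` (data frame `position`, `delta_F`),
#'   `less_frustrated`, `more_frustrated` (position vectors), and
#'   `threshold`.
#' @export
frustration_delta <- function(p1, p2, threshold = 0.70) {
  if (!identical(p1$position, p2$position))
    stop("alignment error: profiles cover different position sets")
  dF <- p2$F - p1$F
  big <- !is.na(dF) & abs(dF) >= threshold
  list(delta = data.frame(position = p1$position, delta_F = dF),
       less_frustrated = p1$position[big & dF > 0],
       more_frustrated = p1$position[big & dF < 0],
       threshold = threshold)
}

#' Pearson correlation of two frustration profiles
#'
#' @param p1,p2 `frustration_profile` objects (matched by position).
#' @return List with `r`, `p_value` (two-tailed), `n`.
#' @export
profile_correlation <- function(p1, p2) {
  m <- merge(as.data.frame(p1)[, c("position", "F")],
             as.data.frame(p2)[, c("position", "F")], by = "position")
  ok <- is.finite(m$F.x) & is.finite(m$F.y)
  if (sum(ok) < 3L) stop("need at least 3 shared finite positions")
  if (sd_pop(m$F.x[ok]) == 0 || sd_pop(m$F.y[ok]) == 0)
    stop("undefined-correlation error: constant profile")
  ct <- stats::cor.test(m$F.x[ok], m$F.y[ok], method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
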