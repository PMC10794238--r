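## Folding and binding decoy generators and their energy evaluation.

.as_pairs <- function(contacts) {
  cbind(pmin(contacts$i, contacts$j), pmax(contacts$i, contacts$j))
}

.pair_key <- function(p, n) (p[, 1] - 1) * n + p[, 2]

.new_decoy_set <- function(kind, n_seq_res, native_pairs, decoy_pairs,
                           hk_code = NULL, meta = list()) {
  d_id <- rep.int(seq_along(decoy_pairs),
                  vapply(decoy_pairs, nrow, 0L))
  dp <- do.call(rbind, decoy_pairs)
  structure(list(kind = kind, n_seq_res = as.integer(n_seq_res),
                 native_pairs = native_pairs, decoy_pairs = decoy_pairs,
                 d_i = dp[, 1], d_j = dp[, 2], d_id = d_id,
                 n_decoys = length(decoy_pairs), hk_code = hk_code,
                 meta = meta),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat("<decoy_set> ", x$kind, ": ", x$n_decoys, " decoys over ",
      x$n_seq_res, " evolving residues (native ",
      nrow(x$native_pairs), " contacts)\n", sep = "")
  invisible(x)
}

#' Folding decoy ensemble builder
#'
#' Stand-in for a threading library: alternative intra-chain contact maps
#' against which any sequence's folding energies can be evaluated.
#' `"shuffle"` mode (the evolution track's default) draws each decoy's
#' contacts uniformly from all residue pairs respecting the minimum
#' separation, preserving the native contact count; like threading onto
#' unrelated folds, the decoys have unrelated per-position contact
#' degrees, so sequences that concentrate strong residues at the native
#' map's high-degree (buried) positions gain fitness. `"rewire"` mode
#' produces degree-preserving double-edge-swap randomizations of the
#' native map (note that preserving degrees makes decoy energies blind to
#' where along the chain strong residues sit, which suppresses
#' hydrophobic-core selection). `"thread"` mode takes contact maps of
#' other (fixture) structures truncated to the native length. The native
#' map itself is never among the decoys.
#'
#' @param cmap Native intra-chain `contact_map`.
#' @param n Number of decoys (>= 2).
#' @param mode `"shuffle"`, `"rewire"` or `"thread"`.
#' @param seed Integer seed (shuffle/rewire modes).
#' @param fixtures List of `contact_map`s to thread against (thread mode).
#' @param n_swaps Attempted edge swaps per rewired decoy (default 10 per
#'   contact).
#' @return A `decoy_set` of kind `"folding"`; evaluate with
#'   [decoy_energies()].
#' @export
folding_decoys <- function(cmap, n, mode = c("shuffle", "rewire",
                                             "thread"),
                           seed = NULL, fixtures = NULL, n_swaps = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 2)
  native <- .as_pairs(cmap$contacts)
  n_res <- cmap$n_res
  if (mode == "shuffle") {
    m <- nrow(native)
    allowed <- which(outer(seq_len(n_res), seq_len(n_res), function(i, j)
      j - i >= cmap$min_sep))
    if (length(allowed) <= m)
      stop("native map too dense to shuffle")
    nat_key <- sort(.pair_key(native, n_res))
    decoys <- with_seed(seed, lapply(seq_len(n), function(d) {
      for (attempt in 1:20) {
        pick <- sort(sample(allowed, m))
        # column-major linear index -> (row = i, col = j), i < j ensured
        # by the separation constraint
        p <- cbind((pick - 1L) %% n_res + 1L,
                   (pick - 1L) %/% n_res + 1L)
        if (!identical(sort(.pair_key(p, n_res)), nat_key)) return(p)
      }
      stop("generation error: shuffling failed to leave the native map")
    }))
  } else if (mode == "thread") {
    if (is.null(fixtures)) stop("thread mode needs fixture contact maps")
    decoys <- lapply(fixtures, function(f) {
      p <- .as_pairs(f$contacts)
      p[p[, 1] <= n_res & p[, 2] <= n_res, , drop = FALSE]
    })
    if (length(decoys) < n)
      stop("generation error: only ", length(decoys), " fixtures for ",
           n, " decoys")
    decoys <- decoys[seq_len(n)]
  } else {
    m <- nrow(native)
    if (m < 2L) stop("native map too small to rewire")
    n_swaps <- n_swaps %||% (10L * m)
    nat_key <- sort(.pair_key(native, n_res))
    decoys <- with_seed(seed, {
      out <- vector("list", n)
      for (d in seq_len(n)) {
        for (attempt in 1:20) {
          p <- .rewire_once(native, n_res, cmap$min_sep, n_swaps)
          if (!identical(sort(.pair_key(p, n_res)), nat_key)) break
          p <- NULL
        }
        if (is.null(p))
          stop("generation error: rewiring failed to leave the native map")
        out[[d]] <- p
      }
      out
    })
  }
  .new_decoy_set("folding", n_res, native, decoys,
                 meta = list(mode = mode, seed = seed))
}

## one degree-preserving randomization of a pair list
.rewire_once <- function(pairs, n_res, min_sep, n_swaps) {
  p <- pairs
  m <- nrow(p)
  adj <- matrix(FALSE, n_res, n_res)
  adj[p] <- TRUE
  e1s <- sample.int(m, n_swaps, replace = TRUE)
  e2s <- sample.int(m, n_swaps, replace = TRUE)
  flip <- stats::runif(n_swaps) < 0.5
  for (s in seq_len(n_swaps)) {
    e1 <- e1s[s]; e2 <- e2s[s]
    if (e1 == e2) next
    a <- p[e1, 1]; b <- p[e1, 2]; c <- p[e2, 1]; d <- p[e2, 2]
    # two rewiring orientations of the double-edge swap
    if (flip[s]) { new1 <- c(a, d); new2 <- c(c, b) }
    else { new1 <- c(a, c); new2 <- c(b, d) }
    new1 <- sort(new1); new2 <- sort(new2)
    if (new1[1] == new1[2] || new2[1] == new2[2]) next
    if (new1[2] - new1[1] < min_sep || new2[2] - new2[1] < min_sep) next
    if (adj[new1[1], new1[2]] || adj[new2[1], new2[2]]) next
    if (identical(new1, new2)) next
    adj[a, b] <- FALSE; adj[c, d] <- FALSE
    adj[new1[1], new1[2]] <- TRUE; adj[new2[1], new2[2]] <- TRUE
    p[e1, ] <- new1; p[e2, ] <- new2
  }
  p
}

## random rotation about a uniform axis; angle ~ |N(0, rot_sd)| radians
.random_rotation <- function(rot_sd) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::rnorm(1, 0, rot_sd)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
              3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Binding decoy ensemble builder
#'
#' Stand-in for local-perturbation docking: rigid-body poses of the
#' ligand chain perturbed around its native placement. Each pose rotates
#' the ligand about its centroid (small random axis-angle) and perturbs
#' the centroid position; poses with any inter-chain heavy-atom pair
#' closer than `clash` are rejected, as is any pose whose inter-chain
#' contact set equals the native one. Poses with more inter contacts than
#' the native are also rejected: around a tightly packed native interface
#' no rigid pose can bury additional surface, but the open edges of a
#' finite lattice chain admit unphysical wedged poses, and the rejection
#' removes that artifact. The retained ensemble has the native at its
#' contact-rich end with decoy energies spread broadly above it, as a
#' docking funnel requires. Under the rigid-binding convention, decoy energies are
#' inter-chain (\eqn{E_{12}}) only.
#'
#' @param toy A two-chain [make_toy_structure()] result (chain A receptor
#'   = evolving Rec chain; chain B ligand with fixed native sequence).
#' @param n Number of poses (>= 2).
#' @param seed Integer seed.
#' @param hk_seq One-letter sequence of the fixed partner chain (default:
#'   the toy structure's chain B residues).
#' @param trans_sd Std. dev. (Angstrom) of the centroid perturbation.
#' @param rot_sd Std. dev. (radians) of the rotation angle.
#' @param clash Clash rejection distance (default 2.0 Angstrom).
#' @param max_attempts Attempt budget.
#' @return A `decoy_set` of kind `"binding"`.
#' @export
binding_decoys <- function(toy, n, seed = NULL, hk_seq = NULL,
                           trans_sd = 3.0, rot_sd = 0.5, clash = 2.0,
                           max_attempts = 60L * n) {
  stopifnot(inherits(toy, "toy_structure"), n >= 2)
  s <- toy$structure
  chains <- unique(s$residues$chain)
  if (length(chains) != 2L) stop("binding decoys need a two-chain structure")
  rec_idx <- which(s$residues$chain == chains[1])
  hk_idx <- which(s$residues$chain == chains[2])
  n_rec <- length(rec_idx); n_hk <- length(hk_idx)
  arec <- s$atoms[s$atoms$chain == chains[1], , drop = FALSE]
  ahk <- s$atoms[s$atoms$chain == chains[2], , drop = FALSE]
  xr <- as.matrix(arec[, c("x", "y", "z")])
  xh <- as.matrix(ahk[, c("x", "y", "z")])
  rr <- match(arec$res_index, rec_idx)
  rh <- match(ahk$res_index, hk_idx)
  cutoff <- toy$cmap$cutoff

  inter_pairs <- function(xh_posed) {
    d2 <- outer(rowSums(xr^2), rowSums(xh_posed^2), "+") -
      2 * tcrossprod(xr, xh_posed)
    d2[d2 < 0] <- 0
    if (sqrt(min(d2)) < clash) return(NULL)
    dmin <- sqrt(d2)
    hit <- which(dmin < cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0L)
      return(matrix(integer(), 0L, 2L))
    unique(cbind(rr[hit[, 1]], rh[hit[, 2]]))
  }
  ## native inter map in local (rec, hk) indices
  nat_ct <- toy$cmap$contacts
  nat_ct <- nat_ct[nat_ct$partition == "inter", , drop = FALSE]
  native <- cbind(match(nat_ct$i, rec_idx), match(nat_ct$j, hk_idx))
  nat_key <- sort((native[, 1] - 1) * n_hk + native[, 2])
  centroid <- colMeans(xh)

  decoys <- with_seed(seed, {
    out <- list(); attempts <- 0L
    while (length(out) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      R <- .random_rotation(rot_sd)
      shift <- stats::rnorm(3, 0, trans_sd)
      posed <- sweep(tcrossprod(sweep(xh, 2L, centroid), R), 2L,
                     centroid + shift, "+")
      p <- inter_pairs(posed)
      if (is.null(p)) next
      if (nrow(p) > nrow(native)) next
      if (nrow(p) > 0 &&
          identical(sort((p[, 1] - 1) * n_hk + p[, 2]), nat_key)) next
      out[[length(out) + 1L]] <- p
    }
    if (length(out) < n)
      stop("generation error: only ", length(out), "/", n,
           " clash-free poses in ", max_attempts, " attempts")
    out
  })
  hk_seq <- .seq_chars(hk_seq %||% s$residues$aa[hk_idx])
  if (length(hk_seq) != n_hk) stop("hk_seq length mismatch")
  .new_decoy_set("binding", n_rec, native, decoys,
                 hk_code = match(hk_seq, AA_ALPHABET),
                 meta = list(seed = seed, trans_sd = trans_sd,
                             rot_sd = rot_sd, clash = clash))
}

#' Evaluate a sequence's native and decoy energies
#'
#' For a folding set: intra-chain contact energy of `seq` on the native
#' map and each decoy map. For a binding set: inter-chain energy
#' \eqn{E_{12}} of `seq` against the fixed partner sequence for the native
#' pose and each decoy pose (a pose with no contacts scores 0).
#'
#' @param ds A `decoy_set`.
#' @param seq One-letter sequence (length `ds$n_seq_res`) or its integer
#'   coding over [AA_ALPHABET].
#' @param em An `energy_model`.
#' @return List with `native` (scalar) and `decoys` (length
#'   `ds$n_decoys`).
#' @export
decoy_energies <- function(ds, seq, em) {
  stopifnot(inherits(ds, "decoy_set"))
  code <- if (is.numeric(seq)) as.integer(seq)
  else match(.seq_chars(seq), AA_ALPHABET)
  if (length(code) != ds$n_seq_res || anyNA(code))
    stop("alphabet error: sequence must cover ", ds$n_seq_res,
         " residues over the 20-letter alphabet")
  xi <- em$table
  partner <- function(j) if (ds$kind == "binding") ds$hk_code[j]
  else code[j]
  np <- ds$native_pairs
  native <- sum(xi[cbind(code[np[, 1]], partner(np[, 2]))])
  dec <- numeric(ds$n_decoys)
  if (length(ds$d_id)) {
    vals <- xi[cbind(code[ds$d_i], partner(ds$d_j))]
    rs <- rowsum(vals, ds$d_id)
    dec[as.integer(rownames(rs))] <- rs[, 1]
  }
  list(native = native, decoys = dec)
}

#' Build a decoy ensemble for one sequence
#'
#' @inheritParams decoy_energies
#' @param kT Temperature factor.
#' @return A [decoy_ensemble()] ready for [stability()],
#'   [accessibility()] and [ground_state_check()].
#' @export
build_ensemble <- function(ds, seq, em, kT = 1) {
  e <- decoy_energies(ds, seq, em)
  decoy_ensemble(e$native, e$decoys, kind = ds$kind, kT = kT)
}

#' Export a decoy set to JSON lines
#'
#' One header object (schema, kind, dimensions, fixed partner sequence)
#' followed by one contact-list object per map (native first).
#'
#' @param ds A `decoy_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_decoys <- function(ds, path) {
  hdr <- list(schema = "tcsevol-decoys-1", kind = ds$kind,
              n_seq_res = ds$n_seq_res, n_decoys = ds$n_decoys)
  if (!is.null(ds$hk_code))
    hdr$hk_seq <- paste0(AA_ALPHABET[ds$hk_code], collapse = "")
  lines <- jsonlite::toJSON(hdr, auto_unbox = TRUE)
  ser <- function(p, native) jsonlite::toJSON(
    list(native = native, i = p[, 1], j = p[, 2]), auto_unbox = TRUE)
  lines <- c(lines, ser(ds$native_pairs, TRUE),
             vapply(ds$decoy_pairs, ser, "", native = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Import a decoy set from JSON lines
#'
#' @param path File written by [export_decoys()] (or by external tooling
#'   following the same schema).
#' @return A `decoy_set`.
#' @export
import_decoys <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("format error: need header, native map and ",
                               "at least one decoy")
  parse_line <- function(k) tryCatch(jsonlite::fromJSON(lines[k]),
                                     error = function(e)
                                       stop("format error at line ", k, ": ",
                                            conditionMessage(e)))
  hdr <- parse_line(1L)
  if (!identical(hdr$schema, "tcsevol-decoys-1"))
    stop("format error at line 1: unknown schema")
  maps <- lapply(2:length(lines), function(k) {
    obj <- parse_line(k)
    if (is.null(obj$i) || is.null(obj$j) ||
        length(obj$i) != length(obj$j))
      stop("format error at line ", k, ": contact lists i/j invalid")
    list(native = isTRUE(obj$native),
         pairs = cbind(as.integer(obj$i), as.integer(obj$j)))
  })
  nat <- which(vapply(maps, `[[`, TRUE, "native"))
  if (length(nat) != 1L) stop("format error: exactly one native map required")
  hk_code <- if (!is.null(hdr$hk_seq))
    match(strsplit(hdr$hk_seq, "")[[1]], AA_ALPHABET)
  .new_decoy_set(hdr$kind, hdr$n_seq_res, maps[[nat]]$pairs,
                 lapply(maps[-nat], `[[`, "pairs"), hk_code = hk_code,
                 meta = list(imported_from = path))
}
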