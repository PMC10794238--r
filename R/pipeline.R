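## End-to-end tracks: family-wide MSA statistics and structure-oriented
## evolution, with report writing and a run manifest.

#' Family-wide conservation and coupling track
#'
#' Chains alignment filtering, frequency estimation, first-order
#' conservation, hydrophobic preference, coupling conservation, threshold
#' selections and the power-law spectrum fit.
#'
#' @param input A `paired_alignment`, a `synthetic_msa_spec`, or a path to
#'   an aligned-FASTA file.
#' @param domain_ranges Required when `input` is a path.
#' @param max_seq_gap_frac,max_col_gap_frac Filtering thresholds
#'   (defaults 0.2 / 0.5).
#' @param pseudocount Frequency pseudocount (default 1e-4).
#' @param background Background distribution (default packaged).
#' @param conservation_threshold Selection threshold on \eqn{C_i}
#'   (default 2.0).
#' @param coupling_threshold Selection threshold on \eqn{C_{ij}}
#'   (default 1.10).
#' @param bin_width,fit_range Spectrum-fit controls.
#' @param out_dir Optional directory for tab-separated reports and a JSON
#'   manifest.
#' @return List with `alignment`, `frequencies`, `conservation` (data
#'   frame per column), `coupling`, `top_conserved`, `top_coupled`,
#'   `spectrum`, and `report_paths` (when written).
#' @export
run_family_track <- function(input, domain_ranges = NULL,
                             max_seq_gap_frac = 0.2,
                             max_col_gap_frac = 0.5,
                             pseudocount = 1e-4,
                             background = background_frequencies(),
                             conservation_threshold = 2.0,
                             coupling_threshold = 1.10,
                             bin_width = 0.1, fit_range = NULL,
                             out_dir = NULL) {
  t0 <- Sys.time()
  aln <- if (inherits(input, "paired_alignment")) input
  else if (inherits(input, "synthetic_msa_spec")) sample_msa(input)
  else {
    if (is.null(domain_ranges))
      stop("input error [read]: domain_ranges required for a file input")
    read_paired_alignment(input, domain_ranges)
  }
  aln <- filter_alignment(aln, max_seq_gap_frac, max_col_gap_frac)
  fm <- estimate_frequencies(aln, background, pseudocount)
  Ci <- position_conservation(fm)
  PH <- hydrophobic_preference(aln)
  cm <- coupling_conservation(fm)
  # a near-null spectrum can have too few occupied bins to fit; the track
  # then reports the histogram inputs without a fit
  spectrum <- tryCatch(fit_powerlaw_spectrum(cm, bin_width, fit_range),
                       error = function(e) {
                         warning("spectrum fit skipped: ",
                                 conditionMessage(e))
                         NULL
                       })
  top_cons <- select_top(Ci, conservation_threshold)
  top_coup <- select_top(cm, coupling_threshold)
  cons_tab <- data.frame(column = seq_len(aln$column_count),
                         domain = .column_domains(aln),
                         C_i = Ci, P_H = PH)
  out <- list(alignment = aln, frequencies = fm,
              conservation = cons_tab, coupling = cm,
              top_conserved = top_cons, top_coupled = top_coup,
              spectrum = spectrum)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      conservation = .write_tsv(cons_tab,
                                file.path(out_dir, "conservation.tsv")),
      pairs = .write_tsv(top_coup$pairs,
                         file.path(out_dir, "top_coupled_pairs.tsv")))
    if (!is.null(spectrum))
      paths["spectrum"] <- .write_tsv(
        data.frame(bin_center = spectrum$bin_centers,
                   frequency = spectrum$frequencies),
        file.path(out_dir, "coupling_spectrum.tsv"))
    manifest <- list(
      stage = "family_track",
      n_sequences = nrow(aln$seqs), n_columns = aln$column_count,
      thresholds = list(C_i = conservation_threshold,
                        C_ij = coupling_threshold),
      spectrum_fit = if (!is.null(spectrum))
        list(a = spectrum$a, b = spectrum$b,
             r_squared = spectrum$r_squared),
      n_top_conserved = length(top_cons),
      n_top_coupled = top_coup$n_pairs,
      outputs = as.list(paths),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    mf <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
    out$report_paths <- c(paths, manifest = mf)
  }
  out
}

.column_domains <- function(aln) {
  d <- character(aln$column_count)
  for (nm in names(aln$domain_ranges)) {
    r <- aln$domain_ranges[[nm]]
    d[(r[1] + 1L):r[2]] <- nm
  }
  d
}

.write_tsv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file.rename(tmp, path)
  path
}

#' Design native-like sequences by fixed-composition annealing
#'
#' Synthetic stand-in for natural sequences on a toy structure: each
#' sequence starts from a background-drawn amino-acid composition and is
#' annealed by swapping residue positions (composition-preserving
#' Metropolis moves) to lower the native folding contact energy. Without
#' the composition constraint the contact potential drives sequences to
#' the strongest-interacting residue pair; with it, hydrophobic residues
#' settle into high-contact (buried) positions and polar residues onto
#' the surface, as in natural globular sequences. The machinery is
#' independent of the genetic-algorithm tracks (no decoy ensembles, no
#' selection fitness).
#'
#' @param cmap Native intra-chain `contact_map`.
#' @param em An `energy_model`.
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @param n_steps Annealing swap moves per sequence (default 80 per
#'   designed residue).
#' @param T_hi,T_lo Initial and final temperatures (MJ units).
#' @param background Composition-sampling distribution (default the
#'   packaged background).
#' @param design_positions Residue indices being designed (default all).
#'   Swap moves act only within this set.
#' @param context_seq One-letter identities for the remaining (fixed)
#'   positions, e.g. a binding partner's native sequence; required when
#'   `design_positions` does not cover the map.
#' @return Character matrix (`n` x designed residues) of one-letter
#'   codes, columns in `design_positions` order.
#' @export
design_native_like <- function(cmap, em, n, seed = NULL, n_steps = NULL,
                               T_hi = 2.0, T_lo = 0.3,
                               background = background_frequencies(),
                               design_positions = NULL,
                               context_seq = NULL) {
  L <- cmap$n_res
  design_positions <- design_positions %||% seq_len(L)
  nd <- length(design_positions)
  n_steps <- n_steps %||% (80L * nd)
  xi <- em$table
  pairs <- .as_pairs(cmap$contacts)
  base <- rep(NA_integer_, L)
  if (nd < L) {
    if (is.null(context_seq))
      stop("context_seq required when design_positions do not cover ",
           "the map")
    ctx_code <- match(.seq_chars(context_seq), AA_ALPHABET)
    if (length(ctx_code) != L - nd || anyNA(ctx_code))
      stop("context_seq must cover the non-designed positions")
    base[-design_positions] <- ctx_code
  }
  energy <- function(code) sum(xi[cbind(code[pairs[, 1]],
                                        code[pairs[, 2]])])
  with_seed(seed, {
    out <- matrix("", n, nd)
    temps <- exp(seq(log(T_hi), log(T_lo), length.out = n_steps))
    for (s in seq_len(n)) {
      code <- base
      code[design_positions] <- sample.int(
        20L, nd, replace = TRUE, prob = background / sum(background))
      E <- energy(code)
      for (st in seq_len(n_steps)) {
        ij <- design_positions[sample.int(nd, 2L)]
        if (code[ij[1]] == code[ij[2]]) next
        cand <- code
        cand[ij] <- cand[rev(ij)]
        Enew <- energy(cand)
        if (Enew <= E || stats::runif(1) < exp(-(Enew - E) / temps[st])) {
          code <- cand
          E <- Enew
        }
      }
      out[s, ] <- AA_ALPHABET[code[design_positions]]
    }
    out
  })
}

#' Enrichment of frustration changes at the interface
#'
#' One-sided label-permutation test of whether frustration changes
#' concentrate at designated interface positions, under random
#' relabelling of which positions are interface. Two statistics:
#' `"flagged_count"` counts the interface positions among those flagged
#' by [frustration_delta()] (\eqn{|\Delta F_i| \ge} threshold) — note
#' that with \eqn{k} flagged positions its attainable p-value is bounded
#' below by the hypergeometric tail at \eqn{k}, so on small systems with
#' few flagged positions the count test is floor-limited; `"magnitude"`
#' compares the mean \eqn{|\Delta F_i|} at interface versus
#' non-interface positions over the whole profile and has no such
#' floor.
#'
#' @param delta A [frustration_delta()] result.
#' @param interface_positions Residue indices designated as interface.
#' @param statistic `"flagged_count"` or `"magnitude"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List with `statistic`, `observed`, `n_flagged`, `p_value`.
#' @export
interface_enrichment <- function(delta, interface_positions,
                                 statistic = c("flagged_count",
                                               "magnitude"),
                                 n_perm = 10000L, seed = NULL) {
  statistic <- match.arg(statistic)
  pos <- delta$delta$position
  flagged <- c(delta$less_frustrated, delta$more_frustrated)
  is_int <- pos %in% interface_positions
  if (statistic == "flagged_count") {
    obs <- sum(flagged %in% interface_positions)
    if (length(flagged) == 0L)
      return(list(statistic = statistic, observed = 0L, n_flagged = 0L,
                  p_value = 1))
    k <- length(flagged)
    perm <- with_seed(seed, replicate(n_perm, sum(sample(is_int, k))))
    list(statistic = statistic, observed = obs, n_flagged = k,
         p_value = (1 + sum(perm >= obs)) / (1 + n_perm))
  } else {
    a <- abs(delta$delta$delta_F)
    ok <- is.finite(a)
    a <- a[ok]; is_int <- is_int[ok]
    if (!any(is_int) || all(is_int))
      stop("magnitude statistic needs both interface and non-interface ",
           "positions")
    obs <- mean(a[is_int]) - mean(a[!is_int])
    perm <- with_seed(seed, replicate(n_perm, {
      lab <- sample(is_int)
      mean(a[lab]) - mean(a[!lab])
    }))
    list(statistic = statistic, observed = obs,
         n_flagged = length(flagged),
         p_value = (1 + sum(perm >= obs)) / (1 + n_perm))
  }
}

#' Structure-oriented evolution track
#'
#' Builds folding (and, for FBS, binding) decoy ensembles on a toy
#' complex and runs `n_replicates` independent genetic-algorithm
#' evolutions per condition. Frustration profiles are computed on
#' sequence sets pooled across the replicates (single runs collapse onto
#' run-specific sequence motifs; pooling independent evolutions, as with
#' the independent-replicate protocol the fitness machinery assumes,
#' averages the founder effects out). FS sets are profiled on the
#' intra-chain map; FBS sets include the inter-chain contacts with the
#' partner chain's native sequence fixed. The FS-vs-FBS \eqn{\Delta F}
#' classification, its interface enrichment, and the three-way profile
#' correlations against an annealing-designed native-like (NS) set are
#' reported.
#'
#' @param toy A two-chain [make_toy_structure()] result.
#' @param conditions Subset of `c("FS", "FBS")`.
#' @param cfg A [selection_config()]; replicate seeds are derived from
#'   `cfg$seed`.
#' @param em Energy model.
#' @param n_replicates Independent evolutions per condition (default 5).
#' @param n_fold_decoys,n_bind_decoys Decoy-ensemble sizes.
#' @param n_frust_decoys Decoy draws per frustration index.
#' @param n_profile_seqs Evolved sequences drawn per replicate for the
#'   pooled profiles.
#' @param max_steps,window,tol Passed to [run_evolution()].
#' @param out_dir Optional report directory.
#' @return List with `runs` (per condition, a list of `evolution_trace`
#'   replicates), `pooled` (per condition, the pooled integer sequence
#'   matrix), `profiles` (FS/FBS/NS `frustration_profile`s), `delta`,
#'   `enrichment`, `correlations` (FS_FBS, NS_FS, NS_FBS), `decoys`, and
#'   `report_paths` (when written).
#' @export
run_evolution_track <- function(toy, conditions = c("FS", "FBS"),
                                cfg = selection_config(pop_size = 100L),
                                em = mj_energy_model(),
                                n_replicates = 5L,
                                n_fold_decoys = 50L, n_bind_decoys = 60L,
                                n_frust_decoys = 300L,
                                n_profile_seqs = 50L,
                                max_steps = 8000L, window = 2000L,
                                tol = 1e-3, out_dir = NULL) {
  stopifnot(inherits(toy, "toy_structure"),
            all(conditions %in% c("FS", "FBS")))
  t0 <- Sys.time()
  chains <- unique(toy$structure$residues$chain)
  if ("FBS" %in% conditions && length(chains) < 2L)
    stop("configuration error: FBS requires a two-chain toy structure")
  intra <- chain_contact_map(toy$cmap, chains[1])
  fold <- folding_decoys(intra, n_fold_decoys, mode = "shuffle",
                         seed = cfg$seed + 1000L)
  bind <- if ("FBS" %in% conditions)
    binding_decoys(toy, n_bind_decoys, seed = cfg$seed + 2000L) else NULL
  ctx <- evolution_context(fold, bind, em)
  runs <- list(); pooled <- list()
  for (cond in conditions) {
    runs[[cond]] <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + 100L * match(cond, c("FS", "FBS")) + r
      runs[[cond]][[r]] <- run_evolution(cond, ctx, cfg_r,
                                         max_steps = max_steps,
                                         window = window, tol = tol)
    }
    pooled[[cond]] <- do.call(rbind, lapply(runs[[cond]], function(tr)
      tr$population[seq_len(min(n_profile_seqs, nrow(tr$population))), ,
                    drop = FALSE]))
  }
  n_rec <- fold$n_seq_res
  hk_aa <- if (length(chains) > 1L)
    toy$structure$residues$aa[toy$structure$residues$chain == chains[2]]
  profiles <- list()
  for (cond in names(pooled)) {
    seq_chars <- matrix(AA_ALPHABET[pooled[[cond]]],
                        nrow = nrow(pooled[[cond]]))
    if (cond == "FBS") {
      pmap <- subset_contacts(toy$cmap,
                              c(paste0("intra_", chains[1]), "inter"))
      seq_chars <- cbind(seq_chars,
                         matrix(rep(hk_aa, each = nrow(seq_chars)),
                                nrow = nrow(seq_chars)))
    } else pmap <- intra
    profiles[[cond]] <- ensemble_frustration_profile(
      seq_chars, pmap, em, n_decoys = n_frust_decoys,
      seed = cfg$seed + 3000L + match(cond, c("FS", "FBS")),
      positions = seq_len(n_rec), label = cond)
  }
  # native-like stand-in: designed under folding AND binding energy with
  # the partner fixed, as natural sequences satisfy both requirements;
  # profiled on the intra-chain map like the FS set
  ns_map <- if (length(chains) > 1L)
    subset_contacts(toy$cmap, c(paste0("intra_", chains[1]), "inter"))
  else intra
  ns <- design_native_like(
    ns_map, em, nrow(pooled[[1]]), seed = cfg$seed + 4000L,
    design_positions = seq_len(n_rec),
    context_seq = if (length(chains) > 1L) hk_aa)
  profiles$NS <- ensemble_frustration_profile(
    ns, intra, em, n_decoys = n_frust_decoys, seed = cfg$seed + 3003L,
    positions = seq_len(n_rec), label = "NS")
  out <- list(runs = runs, pooled = pooled, profiles = profiles,
              decoys = list(folding = fold, binding = bind))
  if (all(c("FS", "FBS") %in% names(profiles))) {
    out$delta <- frustration_delta(profiles$FS, profiles$FBS)
    out$enrichment <- interface_enrichment(
      out$delta, toy$classes$interface, seed = cfg$seed + 5000L)
    out$enrichment_magnitude <- interface_enrichment(
      out$delta, toy$classes$interface, statistic = "magnitude",
      seed = cfg$seed + 5001L)
    out$correlations <- c(
      FS_FBS = profile_correlation(profiles$FS, profiles$FBS)$r,
      NS_FS = profile_correlation(profiles$NS, profiles$FS)$r,
      NS_FBS = profile_correlation(profiles$NS, profiles$FBS)$r)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (cond in names(runs)) {
      tr_all <- do.call(rbind, lapply(seq_along(runs[[cond]]),
                                      function(r) {
        cbind(replicate = r, runs[[cond]][[r]]$trace)
      }))
      paths[paste0("trace_", cond)] <- .write_tsv(
        tr_all, file.path(out_dir, paste0("trace_", cond, ".tsv")))
    }
    for (lab in names(profiles))
      paths[paste0("profile_", lab)] <- .write_tsv(
        as.data.frame(profiles[[lab]]),
        file.path(out_dir, paste0("frustration_", lab, ".tsv")))
    if (!is.null(out$delta))
      paths["delta"] <- .write_tsv(out$delta$delta,
                                   file.path(out_dir, "delta_F.tsv"))
    manifest <- list(
      stage = "evolution_track", conditions = conditions,
      seeds = list(base = cfg$seed), n_replicates = n_replicates,
      pop_size = cfg$pop_size,
      decoys = list(folding = n_fold_decoys, binding = n_bind_decoys),
      correlations = as.list(out$correlations),
      outputs = as.list(paths),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    mf <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
    out$report_paths <- c(paths, manifest = mf)
  }
  out
}
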