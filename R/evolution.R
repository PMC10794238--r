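## Rank-wheel genetic-algorithm evolution of sequences on a funneled
## contact-energy landscape, in folding-only (FS) and folding-plus-binding
## (FBS) conditions.

#' Selection configuration
#'
#' @param pop_size Population size (default 500).
#' @param P1 Wheel probability of the best rank before normalization
#'   (default 0.05).
#' @param recurrence `"logistic"` implements the printed recurrence
#'   \eqn{P_{n+1} = P_n (1 - P_n)}; `"geometric"` the variant
#'   \eqn{P_n = P_1 (1-P_1)^{n-1}}.
#' @param mutation_alphabet Residues available to mutation (default all
#'   20).
#' @param seed Integer seed for the whole run (initialization, mutation,
#'   wheel draws, in that order).
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(pop_size = 500L, P1 = 0.05,
                             recurrence = c("logistic", "geometric"),
                             mutation_alphabet = AA_ALPHABET,
                             seed = 1L) {
  recurrence <- match.arg(recurrence)
  if (length(mutation_alphabet) < 2L ||
      !all(mutation_alphabet %in% AA_ALPHABET))
    stop("configuration error: mutation alphabet must contain at least ",
         "two of the 20 amino acids")
  stopifnot(pop_size >= 2, P1 > 0, P1 < 1)
  structure(list(pop_size = as.integer(pop_size), P1 = P1,
                 recurrence = recurrence,
                 mutation_alphabet = mutation_alphabet,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Rank-wheel selection probabilities
#'
#' Raw probabilities follow the configured recurrence from \eqn{P_1} and
#' are then normalized to sum to 1; rank 1 (best combined fitness rank)
#' receives the first slot.
#'
#' @param pop_size Number of ranks.
#' @param cfg A [selection_config()] (or a list with `P1`, `recurrence`).
#' @return Numeric probability vector over ranks 1..`pop_size`.
#' @export
selection_probabilities <- function(pop_size, cfg = selection_config()) {
  stopifnot(pop_size >= 1)
  p <- numeric(pop_size)
  p[1] <- cfg$P1
  if (pop_size > 1) {
    if (cfg$recurrence == "logistic") {
      for (n in 2:pop_size) p[n] <- p[n - 1] * (1 - p[n - 1])
    } else {
      p <- cfg$P1 * (1 - cfg$P1)^(0:(pop_size - 1))
    }
  }
  p / sum(p)
}

#' Evolution fitness context
#'
#' Bundles the decoy ensembles and energy model against which sequences
#' are scored.
#'
#' @param folding A folding `decoy_set`.
#' @param binding A binding `decoy_set`, or `NULL` for folding-only runs.
#' @param em An `energy_model`.
#' @param kT Temperature factor (MJ units).
#' @return Object of class `evolution_context`.
#' @export
evolution_context <- function(folding, binding = NULL,
                              em = mj_energy_model(), kT = 1) {
  stopifnot(inherits(folding, "decoy_set"))
  if (!is.null(binding)) stopifnot(inherits(binding, "decoy_set"))
  structure(list(folding = folding, binding = binding, em = em, kT = kT),
            class = "evolution_context")
}

## fitness components of one integer-coded sequence; NA binding slots in FS
.components <- function(code, ctx, condition) {
  ef <- decoy_energies(ctx$folding, code, ctx$em)
  kT <- ctx$kT
  dG_f <- ef$native + kT * logsumexp(-ef$decoys / kT)
  L_f <- sqrt(1 / (2 * log(length(ef$decoys)))) *
    (mean(ef$decoys) - ef$native) / sd_pop(ef$decoys)
  out <- c(dG_f = dG_f, L_f = L_f, dG_b = NA_real_, L_b = NA_real_)
  if (condition == "FBS") {
    eb <- decoy_energies(ctx$binding, code, ctx$em)
    out["dG_b"] <- eb$native + kT * logsumexp(-eb$decoys / kT)
    out["L_b"] <- sqrt(1 / (2 * log(length(eb$decoys)))) *
      (mean(eb$decoys) - eb$native) / sd_pop(eb$decoys)
  }
  out
}

## strict unique-ground-state test for one integer-coded sequence
.passes_ground_state <- function(code, ctx, condition) {
  ef <- decoy_energies(ctx$folding, code, ctx$em)
  if (ef$native >= min(ef$decoys)) return(FALSE)
  if (condition == "FBS") {
    eb <- decoy_energies(ctx$binding, code, ctx$em)
    if (eb$native >= min(eb$decoys)) return(FALSE)
  }
  TRUE
}

## fast rank-sum over the cached component matrix
.rank_order <- function(comp, condition) {
  cols <- if (condition == "FBS") 1:4 else 1:2
  total <- 0
  for (cn in cols) {
    x <- comp[, cn]
    if (cn %in% c(2L, 4L)) x <- -x
    total <- total + rank(x, ties.method = "first")
  }
  order(total)
}

#' Initialize a ground-state-compatible population
#'
#' Sequences are drawn uniformly over the mutation alphabet and retained
#' only if they take the native conformation as strict unique ground
#' state for the condition's ensembles (rejection sampling). If the
#' attempt budget runs out, remaining slots are filled by mutating
#' already-accepted members (mutants must still pass).
#'
#' @param ctx An [evolution_context()].
#' @param cfg A [selection_config()].
#' @param condition `"FS"` (folding only) or `"FBS"`.
#' @param max_attempts Total draw budget (default 400 per slot).
#' @param prefilter If `FALSE`, skip the ground-state filter (the
#'   constraint then applies only to mutants during evolution).
#' @return Integer-coded population matrix (`pop_size` x residues);
#'   consumes the current RNG stream.
#' @export
initialize_population <- function(ctx, cfg, condition = c("FS", "FBS"),
                                  max_attempts = 400L * cfg$pop_size,
                                  prefilter = TRUE) {
  condition <- match.arg(condition)
  if (condition == "FBS" && is.null(ctx$binding))
    stop("configuration error: FBS condition requires a binding ensemble")
  L <- ctx$folding$n_seq_res
  alpha <- match(cfg$mutation_alphabet, AA_ALPHABET)
  pop <- matrix(NA_integer_, cfg$pop_size, L)
  filled <- 0L; attempts <- 0L
  while (filled < cfg$pop_size && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- sample(alpha, L, replace = TRUE)
    if (!prefilter || .passes_ground_state(cand, ctx, condition)) {
      filled <- filled + 1L
      pop[filled, ] <- cand
    }
  }
  if (filled == 0L)
    stop("initialization error: no sequence passed the ground-state ",
         "check in ", max_attempts, " attempts")
  while (filled < cfg$pop_size) {
    parent <- pop[sample.int(filled, 1L), ]
    mut <- .mutate(parent, alpha)
    if (!prefilter || .passes_ground_state(mut, ctx, condition)) {
      filled <- filled + 1L
      pop[filled, ] <- mut
    }
  }
  pop
}

.mutate <- function(code, alpha) {
  pos <- sample.int(length(code), 1L)
  choices <- alpha[alpha != code[pos]]
  code[pos] <- if (length(choices) == 1L) choices
  else choices[sample.int(length(choices), 1L)]
  code
}

#' Shannon sequence entropy of a population
#'
#' \deqn{H(S) = -\sum_i \sum_a P_{ia} \ln P_{ia}} in nats, summed over all
#' positions and residue types with \eqn{0 \ln 0 := 0}.
#'
#' @param pop Integer-coded population matrix, or character matrix of
#'   one-letter codes.
#' @return Entropy in nats.
#' @export
sequence_entropy <- function(pop) {
  if (is.character(pop)) {
    code <- match(pop, AA_ALPHABET)
    dim(code) <- dim(pop)
    pop <- code
  }
  if (nrow(pop) == 0L) stop("empty population")
  counts <- apply(pop, 2L, tabulate, nbins = 20L)
  P <- counts / nrow(pop)
  -sum(P[P > 0] * log(P[P > 0]))
}

#' One evolution step
#'
#' Draws one population member and one random mutation (new identity
#' differs from the old). If the mutant keeps the native conformation as
#' strict unique ground state for the condition's ensembles, it replaces
#' the original; otherwise the slot is overwritten by a member drawn by
#' rank-wheel selection on the combined fitness ranks. Exactly one slot
#' changes per step.
#'
#' @param state Population state as returned by this function or built
#'   internally by [run_evolution()]: list with `pop` (integer matrix),
#'   `comp` (cached fitness components), `condition`.
#' @param ctx,cfg Context and configuration.
#' @return Updated state; `state$last` records `slot` and `accepted`.
#' @export
evolve_step <- function(state, ctx, cfg) {
  pop <- state$pop
  slot <- sample.int(nrow(pop), 1L)
  alpha <- match(cfg$mutation_alphabet, AA_ALPHABET)
  mut <- .mutate(pop[slot, ], alpha)
  if (.passes_ground_state(mut, ctx, state$condition)) {
    state$pop[slot, ] <- mut
    state$comp[slot, ] <- .components(mut, ctx, state$condition)
    state$last <- list(slot = slot, accepted = TRUE)
  } else {
    ord <- .rank_order(state$comp, state$condition)
    probs <- state$wheel
    pick <- ord[sample.int(length(ord), 1L, prob = probs)]
    state$pop[slot, ] <- pop[pick, ]
    state$comp[slot, ] <- state$comp[pick, ]
    state$last <- list(slot = slot, accepted = FALSE)
  }
  state
}

#' Run one evolution simulation
#'
#' Initializes a ground-state-compatible population and iterates
#' [evolve_step()] until the window-averaged sequence entropy converges
#' (relative change below `tol` between consecutive windows) or `max_steps`
#' is reached. The whole run consumes a single RNG stream seeded from
#' `cfg$seed`, so a fixed seed reproduces the trace bitwise.
#'
#' @param condition `"FS"` (folding-only selection) or `"FBS"` (folding
#'   plus binding).
#' @param ctx An [evolution_context()] (binding set required for FBS).
#' @param cfg A [selection_config()].
#' @param max_steps Step cap (default 2e5).
#' @param window Entropy-averaging window in steps (default 1000).
#' @param tol Relative-change convergence tolerance (default 1e-3).
#' @param prefilter Passed to [initialize_population()].
#' @return Object of class `evolution_trace`: list with `condition`,
#'   `population` (integer matrix), `sequences` (character vector),
#'   `trace` (data frame `step`, `H`, `accepted` cumulative mutant
#'   acceptances), `initial_H`, `final_H`, `converged`, `steps`, `cfg`.
#' @export
run_evolution <- function(condition = c("FS", "FBS"), ctx, cfg,
                          max_steps = 2e5L, window = 1000L, tol = 1e-3,
                          prefilter = TRUE) {
  condition <- match.arg(condition)
  with_seed(cfg$seed, {
    pop <- initialize_population(ctx, cfg, condition,
                                 prefilter = prefilter)
    comp <- t(apply(pop, 1L, .components, ctx = ctx,
                    condition = condition))
    state <- list(pop = pop, comp = comp, condition = condition,
                  wheel = selection_probabilities(cfg$pop_size, cfg))
    H0 <- sequence_entropy(pop)
    steps <- 0L; acc <- 0L
    Hs <- numeric(0); step_ids <- integer(0); accs <- integer(0)
    prev_mean <- NULL; converged <- FALSE
    while (steps < max_steps) {
      steps <- steps + 1L
      state <- evolve_step(state, ctx, cfg)
      if (state$last$accepted) acc <- acc + 1L
      Hs <- c(Hs, sequence_entropy(state$pop))
      step_ids <- c(step_ids, steps)
      accs <- c(accs, acc)
      if (steps %% window == 0L) {
        cur_mean <- mean(Hs[(steps - window + 1L):steps])
        if (!is.null(prev_mean) &&
            abs(cur_mean - prev_mean) <= tol * max(abs(prev_mean), 1e-12)) {
          converged <- TRUE
          break
        }
        prev_mean <- cur_mean
      }
    }
    if (!converged)
      warning("entropy not converged within ", max_steps, " steps")
    structure(list(condition = condition, population = state$pop,
                   sequences = apply(state$pop, 1L, function(r)
                     paste0(AA_ALPHABET[r], collapse = "")),
                   trace = data.frame(step = step_ids, H = Hs,
                                      accepted = accs),
                   initial_H = H0, final_H = Hs[length(Hs)],
                   converged = converged, steps = steps, cfg = cfg),
              class = "evolution_trace")
  })
}

#' @export
print.evolution_trace <- function(x, ...) {
  cat(sprintf(
    "<evolution_trace> %s: %d steps (%sconverged), H %.2f -> %.2f nats, %d/%d mutants accepted\n",
    x$condition, x$steps, if (x$converged) "" else "NOT ",
    x$initial_H, x$final_H,
    utils::tail(x$trace$accepted, 1L), x$steps))
  invisible(x)
}
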