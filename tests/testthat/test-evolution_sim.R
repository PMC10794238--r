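# an evolution context where every sequence passes the ground-state
# check: decoy maps truncate to zero contacts, so decoy energies are 0
# while any native contact energy is negative
all_pass_context <- function(n_res = 12, seed = 1) {
  toy <- make_toy_structure(n_res, seed = seed)
  empty <- cmap_from_pairs(matrix(0L, 0, 2), n_res)
  far <- cmap_from_pairs(cbind(n_res + 1L, n_res + 3L), n_res + 3L)
  fold <- folding_decoys(toy$cmap, 3, mode = "thread",
                         fixtures = list(far, far, far))
  evolution_context(fold, em = mj_energy_model())
}

test_that("wheel probabilities follow the printed recurrence", {
  cfg <- selection_config(pop_size = 10)
  p <- selection_probabilities(10, cfg)
  # one step of the recurrence before normalization: P2 = P1 (1 - P1)
  expect_equal(p[2] / p[1], 1 - 0.05)
  expect_equal(sum(p), 1)
  expect_equal(selection_probabilities(1, cfg), 1)
  p500 <- selection_probabilities(500, cfg)
  expect_equal(sum(p500), 1)
  expect_true(all(diff(p500) < 0))
  cfgg <- selection_config(pop_size = 10, recurrence = "geometric")
  pg <- selection_probabilities(4, cfgg)
  expect_equal(pg / pg[1], (1 - 0.05)^(0:3))
  expect_error(selection_config(mutation_alphabet = character(0)),
               "configuration error")
})

test_that("sequence entropy matches hand computation and its limits", {
  pop <- matrix(1L, 20, 5)
  expect_equal(sequence_entropy(pop), 0)
  # 4 sequences, 2 columns: col1 split 2/2, col2 split 3/1
  popc <- rbind(c("A", "L"), c("A", "L"), c("V", "L"), c("V", "D"))
  hand <- -(2 * (0.5 * log(0.5))) +
    -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(sequence_entropy(popc), hand)
  set.seed(2)
  big <- matrix(sample.int(20L, 3000 * 4, replace = TRUE), 3000, 4)
  expect_equal(sequence_entropy(big), 4 * log(20), tolerance = 0.01)
})

test_that("initialization fills the population or reports impossibility", {
  ctx <- all_pass_context()
  cfg <- selection_config(pop_size = 30, seed = 5)
  pop <- with_seed <- tcsevol:::with_seed(5, initialize_population(ctx, cfg))
  expect_equal(dim(pop), c(30L, 12L))
  # every member passes by construction; verified by re-checking
  for (r in 1:30)
    expect_true(ground_state_check(build_ensemble(ctx$folding, pop[r, ],
                                                  ctx$em)))
  # composition roughly uniform over the alphabet
  tab <- tabulate(pop, 20)
  expect_gt(min(tab), 0)

  # impossible constraint: positive contact energies make the native
  # always above the zero-energy decoys
  em_pos <- mj_energy_model()
  em_pos$table <- abs(em_pos$table)
  ctx_bad <- all_pass_context()
  ctx_bad$em <- em_pos
  expect_error(
    tcsevol:::with_seed(1, initialize_population(ctx_bad, cfg,
                                                 max_attempts = 200L)),
    "initialization error")
})

test_that("one slot changes per step, to the mutant when it passes", {
  ctx <- all_pass_context()
  cfg <- selection_config(pop_size = 15, seed = 3)
  tcsevol:::with_seed(3, {
    pop <- initialize_population(ctx, cfg)
    comp <- t(apply(pop, 1, tcsevol:::.components, ctx = ctx,
                    condition = "FS"))
    state <- list(pop = pop, comp = comp, condition = "FS",
                  wheel = selection_probabilities(15, cfg))
    for (k in 1:20) {
      new <- evolve_step(state, ctx, cfg)
      changed <- which(rowSums(new$pop != state$pop) > 0)
      expect_lte(length(changed), 1L)
      if (length(changed) == 1L) {
        expect_equal(changed, new$last$slot)
        # in the all-pass context the mutant is always accepted and
        # differs from its parent at exactly one position
        expect_true(new$last$accepted)
        expect_equal(sum(new$pop[changed, ] != state$pop[changed, ]), 1L)
      }
      state <- new
    }
  })
})

test_that("fixed seeds reproduce evolution bitwise", {
  toy <- make_toy_structure(18, seed = 4)
  fold <- folding_decoys(toy$cmap, 25, seed = 7)
  ctx <- evolution_context(fold, em = mj_energy_model())
  cfg <- selection_config(pop_size = 30, seed = 11)
  t1 <- suppressWarnings(run_evolution("FS", ctx, cfg, max_steps = 400,
                                       window = 200))
  t2 <- suppressWarnings(run_evolution("FS", ctx, cfg, max_steps = 400,
                                       window = 200))
  expect_identical(t1$population, t2$population)
  expect_identical(t1$trace, t2$trace)
  t3 <- suppressWarnings(run_evolution(
    "FS", ctx, selection_config(pop_size = 30, seed = 12),
    max_steps = 400, window = 200))
  expect_false(identical(t1$population, t3$population))
})

test_that("selection keeps every member ground-state compatible and
           lowers entropy", {
  toy <- make_toy_structure(18, seed = 4)
  fold <- folding_decoys(toy$cmap, 25, seed = 7)
  ctx <- evolution_context(fold, em = mj_energy_model())
  cfg <- selection_config(pop_size = 30, seed = 2)
  tr <- suppressWarnings(run_evolution("FS", ctx, cfg, max_steps = 1500,
                                       window = 500))
  expect_lt(tr$final_H, tr$initial_H)
  for (r in seq_len(nrow(tr$population)))
    expect_true(ground_state_check(
      build_ensemble(fold, tr$population[r, ], ctx$em)))
  # wheel-selection path was exercised (not every mutant passes here)
  expect_lt(max(tr$trace$accepted), tr$steps)
})

test_that("FBS needs a binding ensemble", {
  toy <- make_toy_structure(18, seed = 4)
  fold <- folding_decoys(toy$cmap, 10, seed = 7)
  ctx <- evolution_context(fold, em = mj_energy_model())
  expect_error(suppressWarnings(
    run_evolution("FBS", ctx, selection_config(pop_size = 10, seed = 1),
                  max_steps = 10)),
    "configuration error")
})
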