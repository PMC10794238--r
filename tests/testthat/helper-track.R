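# Toy-complex evolution track at the study conditions (reduced
# population 100, 27-residue chains, 5 replicates); computed once per
# test session and shared by the evolution-property checks.
acceptance_track <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- make_toy_structure(27, chains = 2, seed = 3)
      cache <<- list(
        toy = toy,
        track = suppressWarnings(run_evolution_track(
          toy, cfg = selection_config(pop_size = 100L, seed = 42L),
          n_replicates = 5L, n_fold_decoys = 50L, n_bind_decoys = 60L,
          n_frust_decoys = 300L, n_profile_seqs = 50L,
          max_steps = 8000L, window = 2000L)))
    }
    cache
  }
})
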