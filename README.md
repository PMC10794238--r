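# tcsevol

Interaction-pattern analysis of the bacterial two-component signaling
(TCS) system — a histidine kinase (HK) bound to its cognate response
regulator (RR) — in two tracks:

* **Family track.** From a paired DHp/Rec multiple sequence alignment:
  per-column conservation as relative entropy
  `C_i = Σ_a f_i^a ln(f_i^a / q^a)`, hydrophobic preference `P_i^H`,
  second-order coupling conservation
  `C_ij = sqrt(Σ_ab k_i^a k_j^b (f_ij^ab − f_i^a f_j^b)²)` with
  `k_i^a = ln(f_i^a(1−q^a) / (q^a(1−f_i^a)))`, threshold selections of
  top conserved columns and top coupled pairs, a power-law fit
  `y = a·x^−b` of the coupling magnitude–frequency spectrum, and a
  random-sequence null.
* **Structure track.** On a contact-map Miyazawa–Jernigan energy model:
  residue-level frustration `F_i = (⟨E_i^U⟩ − E_i^N) / sd(E_i^U)`
  against composition decoys; decoy-ensemble selection fitness
  (thermodynamic stability `ΔG = −k_BT ln(P_N/P_D)` and funnel Z-score
  `Λ = sqrt(1/(2S)) · δE/ΔE`); and a rank-wheel genetic algorithm that
  evolves sequences under folding-only (FS) or folding-plus-binding
  (FBS) selection, with pooled frustration profiles and the FS-vs-FBS
  frustration-change (`|ΔF_i| ≥ 0.70`) classification.

Synthetic generators (planted-signal alignments, toy lattice complexes
with designed native sequences, shuffled folding decoys, rigid-body
binding poses) make every stage runnable and testable without external
data. It is intended for computational biologists studying coevolution,
binding specificity and frustration in protein families.

## Worked example

```r
library(tcsevol)

# an alignment with one planted conserved column and one covarying pair
spec <- synthetic_msa_spec(
  n_seqs = 2000, n_cols = 20,
  conserved = list(list(col = 4, residue = "W", dominance = 0.95)),
  coupled = list(list(cols = c(8, 15), residues_i = c("A", "V"),
                      residues_j = c("L", "E"), correlation = 0.9)),
  seed = 1)
fam <- run_family_track(spec)

round(fam$conservation$C_i[4], 2)
#> [1] 4
fam$top_coupled$pairs
#>   i  j    c_ij
#> 1 8 15 1.12535
```

Column 4 carries 4.0 nats of conservation (a 95%-dominant tryptophan
against its 1.1% background frequency), and the planted pair (8, 15) is
the only pair crossing the 1.10 coupling threshold — the family track
recovers exactly the signals that were planted.

```r
# evolve sequences on a toy two-chain complex, folding-only vs
# folding-plus-binding
toy <- make_toy_structure(27, chains = 2, seed = 3)
track <- run_evolution_track(toy, cfg = selection_config(pop_size = 100,
                                                         seed = 42))
track$runs$FS[[1]]
#> <evolution_trace> FS: 8000 steps (NOT converged), H 76.27 -> 65.33 nats, 7345/8000 mutants accepted
track$enrichment_magnitude$p_value  # |dF| concentration at the interface
#> [1] 0.0011
```

Selection shrinks the population's sequence entropy; FBS-evolved
populations reach lower inter-chain energy than FS-evolved ones on the
same complex; and the positions whose frustration changes most when the
binding partner is present concentrate at the designated interface.

Numbered drivers under `analysis/` run the same computations as
narrated reports (`01_family_synthetic.R`, `02_family_reference.R`,
`03_evolve_toy.R`), writing tables under `results/`. The reference
driver expects the published paired HK/RR alignment (4069 pairs) at
`analysis/data/supplementary_dataset4.fasta`; it is not redistributed
here.

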