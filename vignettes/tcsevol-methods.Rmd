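---
title: "Conservation, coupling and structure-oriented evolution: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation, coupling and structure-oriented evolution: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcsevol)
```

`tcsevol` analyses the interaction patterns of the bacterial
two-component signaling (TCS) system — a histidine kinase (HK) bound to
its cognate response regulator (RR) — along two tracks. The *family
track* extracts position-level and pair-level statistics from a paired
multiple sequence alignment of the HK DHp domain and the RR receiver
(Rec) domain. The *structure track* simulates sequence evolution on a
contact-map energy model of the complex and quantifies residue-level
frustration. This vignette states the models, the tunable parameters
with their defaults, and the design decisions the implementation had to
make where the methods left room.

## The family track

### First-order conservation and hydrophobic preference

For each alignment column $i$, conservation is the relative entropy of
the observed amino-acid frequencies $f_i^a$ against background
frequencies $q^a$:

$$C_i = \sum_{a=1}^{20} f_i^a \ln \frac{f_i^a}{q^a} \quad [\mathrm{nats}],$$

with $0 \ln 0 := 0$. A fully conserved column against a uniform
background attains $\ln 20 \approx 3.0$ nats. Hydrophobic preference
$P^H_i$ is the fraction of sequences carrying a hydrophobic residue at
the column.

Gap handling: gaps are excluded from numerator and denominator
everywhere ($f_i^a$ is a distribution over the 20 amino acids among
non-gap residues), because the conservation sum runs over amino-acid
types only; a gap is missing data, not a 21st state. $M$ in the
hydrophobic preference likewise counts non-gap residues. Ambiguous
residue codes (B, Z, X, U, O, J) are normalized to gap on input and
counted.

Filtering applies the sequence filter first (drop sequences with more
than `max_seq_gap_frac` = 0.2 gaps), then the column filter (drop
columns with more than `max_col_gap_frac` = 0.5 gaps) on the surviving
sequences — the order matters and is asserted by a brute-force recount
in the tests.

### Coupling conservation

Covariation between columns $i$ and $j$ is measured by

$$C_{ij} = \sqrt{\sum_{a,b} k_i^a\, k_j^b\,
  \bigl(f_{ij}^{ab} - f_i^a f_j^b\bigr)^2},
\qquad
k_i^a = \ln \frac{f_i^a (1 - q^a)}{q^a (1 - f_i^a)},$$

a conservation-weighted Euclidean-style norm of the deviation of the
joint frequencies from independence. Three numerical decisions:

* **Pseudocounts.** $k_i^a$ diverges at $f_i^a \in \{0, 1\}$, so the
  frequency model must carry a positive pseudocount (default `1e-4` per
  cell); frequencies are additionally clamped away from the boundary at
  the pseudocount's resolution. Pure counting checks may use
  pseudocount 0, but `coupling_conservation()` refuses it.
* **Pair marginals.** Joint frequencies are computed over sequences
  non-gapped at *both* columns; the product term inside the square uses
  the marginals of that same pair-restricted table, so exactly
  independent columns give $C_{ij} = 0$ rather than a gap artifact.
* **Signed magnitude.** Because the weights $k_i^a k_j^b$ are signed,
  the inner sum $S_{ij}$ can be negative at noise level. The coupling
  value used for spectra and threshold selections is
  $\sqrt{\max(S_{ij}, 0)}$; the *signed* magnitude
  $\mathrm{sign}(S_{ij})\sqrt{|S_{ij}|}$ is kept alongside because it —
  not the floored value — is the quantity that is Gaussian-distributed
  around zero for random sequences. For independent background-drawn
  sequences roughly half of all pairs have $S_{ij} < 0$; a zero-floored
  statistic has a point mass at zero and can never look Gaussian. The
  random-sequence null (`coupling_null()`) therefore summarizes the
  signed values (mean, SD, Shapiro–Wilk W) and reports the maximum of
  the floored values for comparison against selection thresholds.

At the reference scale (4069 sequences × 172 columns) the null gives
signed means around $10^{-6}$, maxima around $10^{-3}$ — three orders
of magnitude below the 1.10 selection threshold used for the natural
alignment.

### The coupling spectrum and its power-law fit

The magnitude–frequency spectrum histograms the off-diagonal $C_{ij}$
into linear bins (default width 0.1, starting at the smallest observed
value; the binning is configurable because it is not dictated by the
method) and fits $y = a\,x^{-b}$ by least squares on
$\log_{10}$-frequency versus $\log_{10}$-bin-center over the nonempty
bins, optionally restricted to a `fit_range`. The fit reports $a$, $b$
and $R^2$; near-null spectra with fewer than three occupied bins are
reported without a fit rather than fabricating one.

### Thresholds

The family pipeline's default selections are $C_i \ge 2.0$ for top
conserved columns and $C_{ij} \ge 1.10$ for top coupled pairs — the
working thresholds for the TCS family analysis; both are arguments of
`run_family_track()`.

### Background frequencies and hydrophobicity tables

The shipped background table is an average amino-acid composition of a
large non-redundant protein database and the hydrophobicity table is a
standard binary classification (A, C, F, I, L, M, V, W, Y hydrophobic).
Both are documented stand-ins packaged as plain text under
`inst/extdata/` and overridable per call, so an analysis can substitute
its own reference tables without touching code.

## The structure track

### Contact maps and energies

A contact joins two residues whose closest heavy atoms lie strictly
below 5.0 Å, with at least two residues of chain separation
(inter-chain pairs carry no separation constraint, since separation is
a chain-internal notion). Strict `<` at the cutoff was chosen; at
floating-point resolution the choice is untestable from printed results
and is flagged as configurable. The energy of a sequence on a map is
the Miyazawa–Jernigan (MJ) contact sum

$$E = \sum_{(i,j)\ \in\ \mathrm{contacts}} \xi(\mu_i, \mu_j),$$

with the packaged 20×20 MJ table (attractive contacts negative, RT
units). For a two-chain complex the energy partitions as
$E = E_1 + E_2 + E_{12}$ over intra-Rec, intra-HK and inter-chain
contacts; under the rigid-binding convention pose comparisons use
$E_{12}$ alone because $E_1$ and $E_2$ are pose-invariant. A gap at a
contacting position contributes zero energy with a warning (an error
variant is available); the alternative — refusing the sequence — would
make whole-alignment energy scans impossible.

### Residue-level frustration

The frustration index of position $i$ is a Z-score of its native
incident energy against decoys that randomize only the identity at
$i$, neighbors fixed:

$$F_i = \frac{\langle E_i^U\rangle - E_i^N}
 {\sqrt{\tfrac{1}{N}\sum_k \bigl(E_i^{U,k} - \langle E_i^U\rangle\bigr)^2}},$$

with $N = 1000$ decoy draws by default. Positive $F_i$ marks a
minimally frustrated position (native below the decoy mean, under
attractive-negative energies). Decoy identities are drawn from the
native sequence's empirical amino-acid composition — the reading most
consistent with single-residue frustration in the frustratometer
lineage; a uniform draw over the 20 types is available via
`composition = "uniform"`. Degenerate cases are errors, not silent
zeros: a position with no contacts, and a zero-variance decoy
distribution.

Because the decoys vary only the identity at $i$ over a fixed contact
set, $F_i$ is exactly invariant to adding a constant to the whole
energy table; the tests assert this. The Monte-Carlo estimate at
$N = 1000$ is checked against exhaustive enumeration over the (at most
20-point) candidate distribution on every fixture position.

Ensemble profiles compute $F_i$ per sequence and average per position.
The decoy-draw stream restarts from the seed for each sequence, so a
duplicated sequence set yields exactly the profile of the deduplicated
set. For profiles of folding-plus-binding sequence sets, incident
contacts include the inter-chain contacts with the partner chain's
native sequence held fixed; folding-only and native-like sets are
profiled on the intra-chain map. The change
$\Delta F_i$ between conditions is classified at $|\Delta F_i| \ge
0.70$ into positions becoming less or more frustrated.

### Selection fitness

For a sequence and a decoy ensemble (native energy $E_N$, decoy
energies $E_d$):

$$\Delta G = -K_BT \ln \frac{P_N}{P_D}, \qquad
P_N = e^{-E_N/K_BT},\quad P_D = \sum_d e^{-E_d/K_BT},$$

evaluated with log-sum-exp so the result is finite whenever the
energies are; and the funnel Z-score

$$\Lambda = \sqrt{\frac{K_B}{2S}}\,\frac{\delta E}{\Delta E},$$

with energy gap $\delta E = \langle E_d \rangle - E_N$, spread
$\Delta E$ the population standard deviation of the decoy energies,
and conformational entropy $S = \ln(\text{number of decoys})$. Three
conventions the formulas do not pin down, fixed here and exposed in
configuration: $K_BT = 1$ in MJ units; $\delta E$ referenced
native-versus-decoy-mean (the standard funnel Z-score reading, positive
for well-designed sequences); $P_D$ as a plain sum over decoys without
density-of-states weighting, native excluded. Both measures are
invariant to an additive shift of all energies, asserted to $10^{-9}$.

A sequence is *ground-state compatible* when $E_N$ is strictly below
every decoy energy — uniqueness fails on ties.

Population fitness is the sum of per-component ranks (rank 1 = most
negative $\Delta G$, largest $\Lambda$), over folding components only
or folding plus binding, with ties broken by input order.

### The genetic algorithm

Each step mutates one random position of one random population member
to a different random identity. A mutant that keeps the native
conformation as unique ground state (for folding, and also for binding
in the FBS condition) replaces the original; otherwise the slot is
overwritten by a member drawn by rank-wheel selection with
probabilities following $P_{n+1} = P_n(1 - P_n)$ from $P_1 = 0.05$,
normalized (a geometric variant is available by configuration).
Sequence entropy

$$H(S) = -\sum_{i=1}^{L} \sum_{a=1}^{20} P_{ia} \ln P_{ia}$$

is tracked every step; the run stops when the window-averaged entropy
changes by less than $10^{-3}$ (relative) between consecutive
1000-step windows, or at a step cap. The printed form of the entropy
lacks the minus sign and sums 30 positions regardless of length; it is
implemented as standard negative-sum Shannon entropy over the full
sequence, treating the 30 as a typo. The initial population is
rejection-sampled to ground-state compatibility (the constraint can be
restricted to mutants via `prefilter = FALSE`, since the description
of the initial population is ambiguous on this point); if the attempt
budget runs out, remaining slots are seeded by mutating accepted
members. One seeded RNG stream drives initialization, mutation and
wheel draws in a documented order, so a fixed seed reproduces a run
bitwise.

### Synthetic data: what it emulates and what it does not

All inputs are generated in code:

* **Planted-signal alignments** draw unplanted cells i.i.d. from the
  background, conserved columns with a dominant residue at a set
  dominance, and covarying pairs as two-state 50/50 columns whose
  states agree with the set correlation. They emulate the statistical
  structure the conservation and coupling statistics detect — not
  phylogenetic relatedness, not the entropy profile of real families.
* **Toy structures** are compact serpentine lattice folds (pseudo-CA on
  a jittered cubic grid plus an outward pseudo-CB) rather than
  helix-like traces: a single helix has no long-range contacts and
  hence no buried/surface contrast to detect. The 3.5 Å spacing puts
  both direct and face-diagonal neighbors inside the 5 Å cutoff, so
  contact degrees span roughly 2–11 and interior positions form a
  genuine high-degree core. The two-chain variant places a copy facing
  the first chain, laterally offset by half a spacing so the surfaces
  interdigitate: the native pose is at closest complementary approach,
  and rigid perturbations lose interface contacts rather than gain
  them. Each chain carries a native sequence designed by
  fixed-composition annealing (swap moves at a background-drawn
  composition; unconstrained annealing of a contact potential
  degenerates to poly-Leu/Phe), so partner-chain energetics are
  position-specific. Position classes are derived from the contact
  map: interface = any inter-chain contact; buried/surface = top or
  bottom quartile of intra-chain contact counts among the rest.
* **Folding decoys** stand in for a threading library. The evolution
  track uses contact-count-preserving *shuffled* maps (contacts drawn
  uniformly over separation-respecting pairs): like threading onto
  unrelated folds, the decoys have unrelated per-position degrees, so
  concentrating strong residues at the native map's high-degree
  positions is selectable. A degree-preserving double-edge-swap mode
  is also provided; note that preserving degrees makes decoy energies
  blind to *where* strong residues sit along the chain, which
  suppresses exactly the hydrophobic-core signal — the reason it is
  not the evolution default. Decoy energies of a random sequence are
  approximately Gaussian (a sum over dozens of effectively random
  contacts).
* **Binding decoys** stand in for local-perturbation docking:
  rigid-body poses of the ligand chain with rotation angle
  $\sim|\mathcal N(0, 0.5\,\mathrm{rad})|$ about a uniform axis and
  centroid perturbation $\mathcal N(0, 3\,\text{Å})$ per coordinate.
  Poses are rejected for heavy-atom clashes below 2.0 Å (a documented
  constant), for duplicating the native contact set, and for carrying
  *more* inter contacts than the native — around a tightly packed
  interface no rigid pose buries additional surface, but the open
  edges of a finite lattice admit unphysical wedged poses. The
  perturbation breadth matters: with much narrower perturbations the
  decoys are all near-native, the ground-state constraint saturates
  binding selection, and folding-plus-binding evolution shows no
  resolvable inter-energy advantage over folding-only evolution. The
  resulting pose energies are unimodal with a modest left skew (around
  −0.6, contributed by the contact-rich near-native tail) and mild
  platykurtosis (bounded contact counts); "Gaussian-like" is asserted
  via moment bounds rather than an omnibus test, which at 500 poses
  rejects these mild deviations. External decoy sets (real threading or docking output)
  can be supplied through the JSON-lines exchange format of
  `import_decoys()`.

Passing tests on these generators show that the statistics and the
selection machinery behave as designed on signals of known ground
truth; they do not certify behavior on real alignments (phylogeny,
gaps, alignment error) or real structures (irregular packing,
side-chain detail).

### Replicates and pooled profiles

`run_evolution_track()` runs five independent evolutions per condition
by default and pools 50 sequences per replicate (250 per condition) for
the frustration profiles. This is not cosmetic: a single run collapses
onto run-specific sequence motifs (founder effects), and its
per-position mean frustration reflects those motifs more than the
structure — two independent single-run folding profiles on the same toy
correlate near zero. Pooling depth matters too: at 20 sequences per
replicate the pooled $|\Delta F|$ profile's noise floor is comparable
to the interface signal and the enrichment test wanders across seeds;
at 50 it is stable. Pooling independent replicates is the
profile-level analogue of running several independent evolutions and
analyzing them together.

### Known limitations

* The toy lattice is far smaller and more regular than a real domain:
  27-residue chains with contact degrees 2–11 versus a 110-residue
  receiver domain with irregular packing. Cross-set frustration-profile
  correlations (evolved folding vs. evolved folding-binding vs.
  designed native-like sets) are large on the designed-native toys
  (roughly 0.8–0.95) but closely spaced — typically within 0.03 of one
  another — so which pair correlates *most* is a qualitative
  observation that can flip between seeds, even though the
  folding/binding *difference* signal (interface-concentrated
  $|\Delta F|$) is stable.
* Threading against real homologous folds and physical docking are out
  of scope; their statistical stand-ins preserve the one property the
  fitness formulas consume — a broad, roughly Gaussian decoy energy
  distribution with a funnel to the native — not structural realism.
* Problem sizes in the packaged tests and drivers (population 100,
  27-residue chains, 8000-step runs, five replicates with 50 pooled
  sequences each, 300 frustration decoys for profiles and 1000 for
  single-position checks) were chosen as the smallest sizes at which
  the qualitative properties stabilize across seeds.
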