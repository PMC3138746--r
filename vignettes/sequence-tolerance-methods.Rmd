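---
title: "Methods: flexible-backbone sequence-tolerance prediction"
author: "SeqTolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flexible-backbone sequence-tolerance prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeqTolerance)
```

# The model

A protein position tolerates a distribution of amino acids, not a single
one, and that distribution depends on small backbone adjustments that a
fixed-backbone calculation cannot see. The protocol implemented here
samples both levels explicitly:

* **Conformational level.** Backrub Monte Carlo perturbs the backbone
  locally: a contiguous segment of 3–12 residues is rotated rigidly about
  the axis through its two end-pivot Cα atoms, leaving everything outside
  the segment untouched. Mixing these with side-chain χ moves (both
  rotamer-prior-biased and uniform) and accepting by Metropolis yields
  trajectories whose lowest-energy snapshots form a near-native ensemble.
* **Sequence level.** For each backbone, sequence space at the designed
  positions is explored by a genetic algorithm over a precomputed
  interaction graph. Because the energy is pairwise additive, the total
  score of any sequence/rotamer assignment decomposes into one-body terms
  (stored on graph vertices) and two-body terms (stored on edges), making
  each of the ~10,000 sequence evaluations per backbone cheap.
* **Profile level.** Per backbone, each distinct scored sequence gets a
  Boltzmann weight $w_i \propto e^{-(F_i - F_{\min})/kT}$ from its
  reweighted fitness $F_i$; the per-position residue frequencies of the
  weighted sequences form a position weight matrix (PWM). Per-backbone
  PWMs are merged by the elementwise median (robust to occasional
  pathological backbones; backbones are never weighted by their total
  score, which is dominated by regions far from the design site) and the
  columns renormalized.

Two scores appear throughout. The **raw score** is the plain sum of all
one-body and two-body terms plus the fixed background; it drives
side-chain packing and the design seed. The **reweighted fitness** is a
linear combination over residue groups (chains),
$F = \sum_g w_{\mathrm{self}}(g)\,E(g,g) + \sum_{g<h}
w_{\mathrm{int}}(g,h)\,E(g,h)$, which lets interface applications
up-weight cross-chain interactions (the benchmark weighting is 0.4
intramolecular / 1 intermolecular). With unit weights the fitness equals
the raw score exactly — a tested identity. Group energy components are
stored with every archive record, so post-processing can re-weight
fitness with new coefficients without re-running the search.

# The energy model

The original protocol runs on Rosetta's all-atom score12 function, which
is out of scope here. The package instead defines an energy *contract* —
pairwise additivity, one-body/two-body decomposition, group
decomposability — and a simplified reference potential implementing it:

* Each residue carries one side-chain pseudo-atom placed from CB along
  the χ1 direction at a per-type distance (0 for ALA/GLY); χ1 takes the
  three canonical rotamers (−60°, 180°, +60°) with prior probabilities
  resembling structure-database populations.
* **One-body term** = per-type reference energy (histidine raised by
  +1.2 score units by default, mirroring the correction the benchmark
  protocol applies) + rotamer prior ($-\ln p$ × weight) + a
  *repulsion-only* clash term (truncated-shifted 6-12, WCA form) of the
  pseudo-atom against backbone heavy atoms of all non-bonded residues
  and the native pseudo-atoms of nonmoving residues. Repulsion-only
  keeps the term exactly zero in the absence of clashes.
* **Two-body term** = full clamped 6-12 interaction between the two
  side-chain pseudo-atoms: minimum $-\varepsilon_{ab}$ at
  $\sigma_{ab}2^{1/6}$, exactly zero beyond the interaction cutoff.
  CB–CB and pseudo-atom–CB contributions are state-independent (CB rides
  on the backbone), so they belong to one-body/background terms, not to
  edges.
* Graph edges exist only between positions whose CB atoms lie within the
  interaction cutoff; nonmoving residues contribute a state-independent
  background, split into per-group components so the unit-weight
  identity holds exactly.

This preserves every structural property the protocol exploits, at desk
scale, and the contract allows a richer potential to be plugged in
through `energyModelParams()` / `readEnergyModelConfig()`. Score units
are arbitrary; the Boltzmann factor *kT* is the only bridge from scores
to frequencies.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| move fractions | 0.75 / 0.225 / 0.025 | — | backrub / biased χ / uniform χ mixture of the protocol |
| Metropolis *kT* | 0.6 | score units | ensemble-generation temperature |
| moves per trajectory | 10,000 | proposals | one ensemble member per trajectory |
| segment length | 3–12 | residues | backrub pivot span; rotation bound ±40° scaled by 3/length |
| ensemble size | 100 (200 for extra robustness) | backbones | recommendation for profiles robust to stochastic variation |
| GA population / generations | 2000 / 5 | — | 2000 + 4×1999 = 9996 scored slots per backbone |
| tournament / crossover / mutation / elite | 2 / 0.5 / 0.5 | — | selection pressure and variation mix |
| fitness weights | intra 0.4, inter 1 | — | interface benchmark weighting; unit weights for monomers |
| Boltzmann *kT* | 0.228 | score units | interface default; 0.59 suggested for monomer stability |
| merge percentile | 0.5 | — | median across backbones |
| interaction cutoff | 12 | Å | exceeds the 10 Å repack shell |
| repulsion clamp | 10 | score units/pair | Monte Carlo stability |
| annealing schedule | kT 30→0.3, ×0.8, 20 iter/state, 3 restarts | — | sized so packing matches exhaustive enumeration on test instances |

Counting convention: the 10,000 moves count *proposals*, not
acceptances (standard Metropolis bookkeeping); the phrase "slightly less
than 10,000 sequences" is realized as the elite member being carried
between generations without re-scoring.

# Design decisions taken where the design was open

* **Positions** are identified as `<chain><PDB number><icode>` (e.g.
  `A5`), 1-based with gaps allowed, so user-facing numbering matches the
  input PDB. Alternate locations resolve to the highest occupancy, ties
  to altloc `A`; multi-model files yield one structure per model.
* **Movemap dialect.** The package defines a minimal line grammar
  (`RESIDUE <key|*> CHI|BBCHI|NO`, `JUMP <chain|*> YES|NO`) with the
  same expressive content as the original option (χ / backbone /
  rigid-body flags).
* **Seed member counts toward the population** (1999 random + 1 design
  seed = 2000), configurable via `gaParams(includeSeed=)`.
* **Mutation may restore the original letter**: "mutated with 50%
  probability" is read as a 50% chance to redraw uniformly from the
  allowed set; `strict = TRUE` forces a change. Tournament draws are
  with replacement.
* **Duplicate sequences are cached** — only distinct sequences are
  packed, and only first-seen records carry profile weight; repeated
  slots remain in the archive for bookkeeping.
* **Boltzmann sign convention**: weights are computed as
  $e^{-(F - F_{\min})/kT}$ — lower fitness is better and scores are
  normalized to the per-backbone minimum, so good sequences get the
  largest finite weights.
* **Renormalization after the percentile merge** is required because
  elementwise percentiles of normalized columns need not sum to 1; the
  median is taken on per-backbone frequencies (already normalized).
* **Metric conventions**: ROC AUC pools all position×letter elements
  into one curve (a per-position average is available via
  `perPosition = TRUE`); predicted-rank ties break alphabetically;
  positions with no experimental letter ≥10% are skipped in Fraction
  Top 5 (the metric is undefined there); information content is averaged
  over positions (consistent with a 4.32-bit dynamic range).
* **Small φ/ψ moves** (±3°, downstream atoms move, no loop closure) are
  available behind `smProb > 0` but default off — experimental, as in
  the source protocol.
* **Tie-breaking** in the packer is deterministic: annealing is followed
  by a greedy sweep that prefers the lowest (type, rotamer) index among
  equal-energy states, so packing is reproducible bit-for-bit under a
  fixed seed.

# What the synthetic fixtures emulate

`makeToyStructure()` builds ideal-geometry helices/strands (one or two
chains) deterministic to the bit; `plantedLandscape()` builds interaction
graphs whose exhaustively enumerable optimum is a planted sequence with a
guaranteed energy margin; `makeExperimentalPWM()` produces
Dirichlet-noised preference profiles standing in for experimentally
measured specificity tables (the real benchmark inputs — crystal
structures and phage-display frequency tables — are external data).
Synthetic fixtures emulate the statistical structure the protocol
assumes: a dominant low-energy sequence neighbourhood with
Boltzmann-distributed alternatives. They do **not** emulate real side-chain
chemistry, experimental noise processes (stop codons, read errors), or
the ruggedness of an all-atom landscape — so passing tests demonstrate
the correctness of the machinery (geometry, bookkeeping, weighting,
metrics, convergence behaviour), not the accuracy of the reference
potential on real proteins.

# Numerical choices and degenerate inputs

Rotations use Rodrigues' formula; atoms are placed from internal
coordinates by the standard NeRF construction. Pair energies are clamped
at 10 score units per pair and cut exactly to zero beyond 12 Å so that
locality tests are exact rather than approximate. Bonded neighbours
(sequence-adjacent residues in a chain) are excluded from the one-body
clash term, which would otherwise be dominated by 1-2/1-3 contacts.
Degenerate inputs are rejected early: structures with no complete
backbone residue, designed positions with empty allowed sets, duplicate
ensemble seeds, non-positive *kT*, mismatched PWM positions. Residues
missing only some atoms are dropped with a warning rather than silently
repaired.

Problem sizes in the shipped tests are chosen for exactness, not
realism: oracle instances stay ≤3 positions × ≤5 states so exhaustive
enumeration is the reference; marginal-recovery landscapes stay ≤4
positions so the exact Boltzmann distribution is enumerable; pipeline
tests run a handful of backbones with tens of GA members. The full-scale
GA (population 2000, 5 generations) is exercised once to verify the
9996-slot bookkeeping.

# Known limitations

* The reference potential has no hydrogen bonding, electrostatics or
  solvation; absolute energies and the derived profiles are not
  comparable to all-atom results, and the published benchmark values
  (which depend on score12 and external phage-display data) are not
  reproduction targets.
* Backrub moves here use a single rotation about the pivot axis; the
  full backrub move set with compensating peptide rotations is not
  implemented.
* No loop closure for φ/ψ moves; no rigid-body ensemble sampling
  (rigid-body freedom appears only in the staged premutation
  minimizer).
* PWMs discard inter-position correlations by construction;
  `covariation()` exposes pairwise co-occurrence from the same weighted
  sequences for users who need it.
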