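---
title: "Predicting engineered disulfide bonds from structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting engineered disulfide bonds from structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssforge)
```

## The problem

A disulfide bond between two cysteine Sγ atoms (~2.05 Å) crosslinks the
chain and removes conformational entropy from the unfolded (and partly
from the folded) ensemble. Introduced at the right position, an
engineered disulfide rigidifies a flexible protein; at the wrong
position it strains the backbone and destabilizes it. Native disulfides
occupy a narrow region of geometry space — χ3 clusters near ±90°, the
Cβ–Cβ distance near 3.8 Å, and the flanking backbone frames adopt
recurring relative orientations — so the geometry of natives is an
effective filter for where an engineered bond can go.

`ssforge` scores every residue pair of a target structure against that
native geometry, combining three probabilities that capture
complementary requirements: local geometric compatibility
(P~Geom~), global similarity to a real native disulfide (P~RMSD~), and a
worthwhile entropy payoff (P~ΔS~).

## Descriptor extraction and virtual mutation

Candidate positions are usually not cysteines, so side chains are
modelled: Cβ is taken from the structure when present (for glycine it is
built from N/Cα/C with standard tetrahedral constants), and Sγ is placed
by ideal internal coordinates — Cβ–Sγ 1.81 Å, Cα–Cβ–Sγ 114.0° — at each
χ1 in a rotamer seed set, default the three staggered minima
{−60°, +60°, 180°}. Of the 9 seed combinations, the one whose Sγ–Sγ
distance is closest to the ideal 2.05 Å is scored; selecting by
closeness to the bond length, rather than the raw minimum distance,
avoids favouring sterically collapsed arrangements. All ideal-geometry
constants live in one exported table, `ss_ideal`.

The descriptor vector of a pair has 44 features:

* 36 cross-residue distances, one per pair of atoms from
  {N, Cα, C, O, Cβ, Sγ} on opposite residues. Intra-residue distances
  are fixed by covalent geometry and carry no signal, so they are
  excluded.
* 3 inter-plane dihedrals between corresponding planes C/Cα/Cβ, Cα/Cβ/N
  and C/Cα/N of the two residues, mapped to [0°, 180°].
* the five cystine torsions χ1 (N–Cα–Cβ–Sγ), χ2 (Cα–Cβ–Sγ–Sγ′),
  χ3 (Cβ–Sγ–Sγ′–Cβ′) and their primed counterparts on the second
  residue.

Torsions follow the IUPAC sign convention and live in (−180°, 180°];
swapping the residue order exchanges χ1↔χ1′ and χ2↔χ2′ and leaves χ3
invariant.

## The native library

`build_library()` detects native disulfides in a corpus (CYS–CYS pairs
with Sγ–Sγ ≤ 2.3 Å — the covalent bond plus coordinate error; greedy
closest-partner matching so no cysteine is used twice), extracts each
descriptor vector from experimental coordinates, and aggregates:

* **Feature histograms.** Distances in 0.25 Å bins over [0, 15] Å,
  angles in 10° bins over (−180°, 180°]. Densities are Laplace-smoothed
  (add-one) *within the occupied range only* and normalized to integrate
  to 1. The support of a feature is the range between its first and last
  occupied bin: inside it the density is never zero (a sampling hole is
  not evidence of impossibility), outside it the density is exactly
  zero. This makes P~Geom~ = 0 a meaningful geometric disqualification,
  which matters because the pipeline removes zero-scored candidates
  outright.
* **Templates.** The 8-atom N/Cα/Cβ/Sγ frame of both residues, kept for
  superposition matching. Since a disulfide is symmetric, matching tries
  both residue orderings and keeps the better fit.
* **Environment profile.** Relative frequencies of a joint class per
  cysteine: secondary-structure region from φ/ψ (helix/strand/other) ×
  burial from the number of neighbouring Cα atoms within 10 Å (>10 =
  buried). This summarizes where natives sit; it is exposed on the
  library for inspection and reporting but deliberately kept out of
  P~Geom~, whose factors are the 44 geometric features.

Libraries serialize to versioned JSON (`save_library()` /
`load_library()`); loading a file with a newer `schema_version` fails
with a version error rather than a silent misread.

## The three probabilities

**P~Geom~** evaluates each feature's smoothed density at the observed
value, divides by that feature's modal density so every factor is in
(0, 1], and combines the 44 factors by geometric mean. The geometric
mean (rather than a product) keeps the score on a fixed scale
independent of the feature count; any single out-of-support feature
forces the score to zero.

**P~RMSD~** superposes the candidate frame on its nearest template with
the Kabsch algorithm (proper rotations only; reflections are never
admitted) and maps the RMSD r through a Gaussian kernel
exp(−r²/2σ²). σ defaults to 0.5 Å: native-like geometry within a few
tenths of an Ångström keeps a high score, and by 1 Å the score has
fallen to 0.14. Since the kernel is a monotone map of r, σ affects the
score scale, not the ranking.

**P~ΔS~** uses the loop-closure entropy of crosslinking a chain segment
of n residues, ΔS = −2.1 − (3/2)·R·ln n cal·mol⁻¹·K⁻¹ with
R = 1.987 cal·mol⁻¹·K⁻¹ and n = ordinal sequence separation + 1.
Ordinal position within the chain, not author numbering, defines the
separation, so numbering gaps do not distort loop lengths. The
probability is the linearly capped magnitude min(1, |ΔS|/25); since any
monotone map preserves the ranking, the cap only sets the feature scale
seen by the classifier. Pairs closer than the minimum separation
(default 4 — sequence-local pairs at helix edges buy little entropy and
tend to distort the backbone) and inter-chain pairs (no covalent loop to
close) get P~ΔS~ = 0, which is disqualifying.

This loop-closure ΔS is a chain-statistics estimate for the
*prospective* crosslink. It is distinct from the ensemble estimate of
the next section, which measures entropy from observed fluctuations;
the package exposes both and never conflates them.

## Filtering, ranking, classification

`rank_candidates()` enumerates all intra-chain pairs (inter-chain
enumeration is available behind a flag), scores them, removes every pair
with P~Geom~ = 0 or P~ΔS~ = 0, and sorts by P~Geom~ descending with ties
broken by ascending template RMSD and then residue order, making the
output deterministic. Filtering counts per stage are attached to the
result.

The combination of the three scores into a positive/negative call is an
RBF-kernel SVM over the triples. The library's choices, all
configurable: per-feature min-max scaling with constants frozen into the
model; hyperparameters from a 5-fold cross-validated grid search over
C ∈ {0.1, 1, 10, 100} × γ ∈ {0.01, 0.1, 1, 10} with stratified,
seed-fixed folds; negatives are random non-disulfide pairs scored with
the same pipeline, balanced 1:1. Ranking stays by P~Geom~ — the SVM
label and margin are reported alongside, not used as the sort key.
Models serialize to JSON with the doubles encoded at full precision
(17 significant digits), so a loaded model predicts bit-identically.

A design note on validating the classifier: the permutation-null check
(label-shuffled data should give chance accuracy) evaluates
cross-validated accuracy at *fixed* default hyperparameters. The
grid-search maximum is biased upward by selection — the maximum of 16
near-chance accuracies is not itself a binomial draw around 0.5 — and
with unstratified folds the class imbalance between training and
held-out folds biases the null *downward*. Stratified folds at fixed
parameters give a clean null centred on 0.5.

## Quasi-harmonic ensemble entropy

For a coordinate ensemble (multi-model PDB or array), each frame is
best-fit superposed onto the mean structure (two passes of mean
refinement) to remove rigid-body motion, the mass-weighted covariance
matrix of the fluctuations is diagonalized, and each eigenvalue
λ (amu·Å²) defines a harmonic mode with ω = √(k~B~T/λ). The per-mode
entropy is the quantum harmonic-oscillator value

s(ω) = k~B~ [ u/(e^u − 1) − ln(1 − e^{−u}) ],  u = ħω/k~B~T,

summed over modes and reported per mole in cal·mol⁻¹·K⁻¹. Schlitter's
determinant bound is available via `method = "schlitter"` and is always
an upper bound on the quantum value. Numerical guards: eigenvalues below
1e−8 amu·Å² are discarded as null space (this also absorbs the residual
rigid-body modes left by the linearized superposition), at most 3N − 6
modes are retained, identical frames raise a zero-fluctuation error
rather than returning −∞-frequency garbage.

`fluctuation_bfactors()` ((8π²/3)·⟨Δr²⟩ per atom) and
`terminal_distance_series()` cover the standard trajectory stability
readouts used alongside the entropy.

## What the synthetic generators emulate

All tests and the acceptance script run on generated data with known
ground truth:

* `make_helix()` — ideal poly-alanine α-helix (φ = −57°, ψ = −47°,
  ω = 180°) built by internal coordinates; the torsions and 3.8 Å
  Cα-step are recoverable from the coordinates, which validates both
  generator and dihedral code.
* `make_cystine_corpus()` — structures with one planted native cystine
  each; χ3 drawn from a ±97° mode mixture (the native cluster
  positions), S–S length from Normal(2.05 Å, 0.02 Å). The recorded
  ground truth lets library mining be checked feature by feature.
* `make_two_helix_bundle()` — two ideal helices on one chain positioned
  so that exactly one cross-helix pair forms an ideal engineered
  disulfide when virtually mutated; the planted site is the known
  correct answer for ranking.
* `make_gaussian_ensemble()` — frames sampled along directions
  orthogonal to the six rigid-body modes of a fixed mean structure, with
  specified variances. Because the rigid subspace carries no variance by
  construction, the specified eigenvalues *are* the ground-truth
  quasi-harmonic spectrum and `analytic_qh_entropy()` is an exact
  oracle up to sampling error.
* `make_training_set()` — separable score-triple clusters for classifier
  sanity checks.

What these fixtures do **not** emulate: real side-chain packing and
clashes, coordinate error and alternate conformations beyond simple
noise, β-sheet and loop environments (the corpus cystines are bare
two-residue structures), anharmonic and multi-basin dynamics in
ensembles. Passing tests therefore demonstrate correctness of the
machinery — mining, scoring, filtering, ranking, entropy — on inputs
with known truth, not predictive performance on real proteins, which
depends on mining a real, redundancy-filtered PDB corpus.

## Problem sizes and numerical choices

The shipped validation uses a 50-structure corpus, a 24-residue target
(276 pairs), 10,000-frame ensembles of 5 atoms, and n = 100 training
sets — sizes chosen so the full suite runs in well under a minute of
compute per module while keeping sampling error far below the asserted
tolerances (e.g. covariance eigenvalues at 10,000 frames are within a
few percent of truth, against a 2% entropy tolerance on the summed
spectrum).

Other numerical decisions, in one place: altloc conformers resolve to
the highest occupancy (ties by letter order); multi-model files use
model 1 for prediction and all models for ensembles; superposition
requires ≥ 3 atoms and equal counts; degenerate (collinear) torsion
inputs raise typed errors rather than returning NaN; candidate-table
scores are written with six decimals and round-trip at that precision.

## Known limitations

* The geometric probability treats features as independent (geometric
  mean of marginals); correlated deviations are over-penalized relative
  to a joint model.
* Virtual mutation keeps the backbone fixed — no relaxation, no clash
  check against neighbouring side chains.
* The environment profile is mined and reported but not yet folded into
  the score.
* mmCIF input is not supported; convert to PDB first.
* The SVM's practical value depends entirely on the negative-set
  construction used for training; the shipped default (random
  non-disulfide pairs, 1:1) is a reasonable convention, not a validated
  optimum.
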