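---
title: "Structural fingerprints and proteo-chemometric potency models: methods"
author: "proteofp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural fingerprints and proteo-chemometric potency models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ligand-based QSAR models predict binding potency for one target at a time
and cannot say anything about a receptor that has never been assayed.
`proteofp` implements a proteo-chemometric alternative: a single
regression model over *pairs* (molecule, protein), in which the protein
enters through a structural fingerprint computed directly from its 3D
coordinates. Because the protein is a feature vector rather than a model
boundary, the fitted model can in principle score molecules against a
target absent from training — the blind and semi-blind regimes below
measure how far that promise carries.

## The protein fingerprint

For a protein structure (one selected chain of a PDB file):

1. **Neighborhoods.** For every atom, collect the set of residues having
   at least one atom within radius $r$ of it (Euclidean distance, cutoff
   inclusive). The central atom's own residue is always a member. The
   default $r = 5.0$ Å captures first-shell side-chain contacts.
2. **Deduplication.** Atoms frequently share exactly the same member set
   (e.g. all atoms of a buried residue); duplicate member-sets are
   removed. Dedup operates on position-annotated sets, before any
   letter-sorting.
3. **Keys.** Each surviving set is reduced to the multiset of one-letter
   residue codes, sorted lexicographically: the neighborhood
   {R27, F24, G25, F27} becomes the key `FFGR` (both phenylalanines
   kept — they are distinct residues).
4. **Hashing.** Each key is hashed to one position of a fixed-length
   binary array with a 32-bit FNV-1a digest of the ASCII key reduced
   modulo the array length. The default length is 16,381 bits, the
   largest prime below $2^{14}$; a prime modulus spreads digests more
   uniformly. Distinct keys may collide; collisions are accepted as a
   (rare) source of noise, not an error.

The resulting bit vector is invariant under rigid rotation, translation
and atom-record order, and needs no alignment or superposition. Jaccard
similarity over on-bits, $|A \cap B| / |A \cup B|$, compares two
proteins; `jaccard(..., use = "keys")` offers the collision-free
pre-hash variant (the default follows the computed fingerprints).

Neighbor search uses a cell-list grid of side $r$ (27-cell sweep) and is
contractually *exact*: the test suite asserts set equality against an
all-pairs $O(N^2)$ scan on dozens of random structures, so the index is
purely an optimization.

### Numerical choices

* The distance cutoff is inclusive ($\le r$); the choice only matters on
  a measure-zero boundary but is fixed for bit-exactness.
* All parsed atoms are swept as centers and neighbor candidates. For
  predicted models that means heavy atoms; `parse_pdb(heavy_only =)`
  controls hydrogen handling for experimental files.
* Chain selection under `largest_chain` counts *distinct residues*, not
  atoms, with ties broken by lexicographically smallest chain id.
  Alternate locations resolve to the highest-occupancy conformer
  (ties prefer altloc `A`). Common nonstandard residues (MSE, SEP, ...)
  map to their parent code; unknown codes are skipped with a warning.
* The hash is seedless and byte-stable, so fingerprints are identical
  across sessions and platforms; any specific bit index (e.g. of `FFGR`)
  is implementation-defined and carries no meaning beyond stability.

## Ligand fingerprints

Molecules enter as SMILES and are encoded as standard folded binary
Morgan fingerprints with bond radius 3 over 2048 bits (ECFP6), computed
by RDKit through a small bundled Python driver. SMILES are used as given
(no salt stripping); multi-fragment inputs are flagged in the report.
The binary bits pass into the model untransformed.

## Activity curation and the spKi score

Raw Ki records are curated per (molecule, target) pair:

* values converted to nM (M, mM, uM, nM, pM recognized; anything else
  excluded with a reason);
* relation `=` with a value → a measurement; `=` without a value, no
  relation and no comment, or an "active" comment without a value →
  excluded;
* only `<`/`<=` records → one upper-bound measurement at the *highest*
  reported value;
* only `>`/`>=` records → the molecule is scored inactive;
* measured values win over censored or inactive relations when both
  exist (the conflict is logged);
* duplicate measurements spanning more than one order of magnitude
  resolve to the most recent (ties: geometric mean of the tied year);
  otherwise to the geometric mean of all values.

The resolved Ki maps to the scaled potency score

$$\mathrm{spKi} = \begin{cases}
0 & K_i \ge 10{,}000\ \mathrm{nM\ or\ inactive} \\
1 & K_i \le 1.0\ \mathrm{nM} \\
(4 - \log_{10} K_i)/4 & \text{otherwise}
\end{cases}$$

which is monotone in $\log K_i$ and continuous at both boundaries.
Targets with fewer than 40 curated activities, or with spKi standard
deviation below 0.01 (the variability floor is configurable; no
principled value exists for it), are dropped with a reasoned report.
Every input record receives exactly one disposition, so
kept + excluded always equals the input count and curation is
idempotent.

## Features and the model

Protein fingerprints of all targets form a binary matrix reduced by
centered PCA; the component count either equals the number of targets
(truncated to rank) or the smallest number capturing 99% of variance.
Sign is fixed per component (largest-magnitude loading positive) for
determinism. PCA is fitted on **all** targets' fingerprints, including
targets later held out blind: the fit uses no activity labels, so no
label information can leak, and held-out targets need projections. A
feature row is the molecule's 2048 bits followed by its target's $k$
component scores, labelled with spKi.

The learner is a random-forest regressor with 200 trees. All other
hyperparameters are regression defaults; feature subsampling uses the
classic regression-forest default $mtry = p/3$. A 5-fold
cross-validation helper exists for model-quality reporting; the defaults
themselves are fixed. Predictions are raw regression outputs (a `clip`
flag offers the [0, 1]-clipped alternative, off by default so that
scoring sees the model as-is).

## Validation regimes

* **Baseline per-target**: one forest per target on that target's rows,
  molecule bits only — no protein features. 80/20 split per target;
  overall metrics are test-size-weighted averages.
* **Unified**: one joint model; random 80/20 split of all rows; repeated
  10 times (seeds $s, s+1, \dots$) and averaged, since the per-target mix
  of a random split varies.
* **Blind**: all rows of the held-out targets are removed from training
  and form the validation set.
* **Semi-blind**: as blind, but held-out targets are chosen from the
  Jaccard similarity matrix: the 15 most similar disjoint pairs are
  taken greedily in descending similarity and one member of each pair is
  held out. When activity counts are available the member with fewer
  activities goes to validation (keeping more data in training);
  otherwise the lexicographically second. Pairs are forced disjoint so
  no validation target doubles as another pair's training partner.

Metrics are RMSE and RVE $= 1 - SS_{res}/SS_{tot}$ on the validation
predictions. RVE of the observed-mean predictor is 0 and the score is
unbounded below, which is essential: worse-than-mean blind predictions
must be visible as negative values, not clipped away.

## The synthetic study generator

Real inputs (ChEMBL exports, predicted structure databases) require
downloads, so the generator builds a complete miniature study with a
known answer:

* **Structures**: Cα-trace random walks (3.8 Å steps, soft
  self-avoidance) confined to a sphere of radius
  $3.0\,n^{1/3}$ Å — compact enough that sequence-nonlocal 5 Å contacts
  are guaranteed, which is what gives the fingerprint its 3D content.
  A rigid-motif facility (`make_motif`) can append a fixed local residue
  arrangement to any structure; because the fingerprint is rigid-motion
  invariant, copies of a motif contribute identical pattern keys
  wherever they are placed.
* **Families**: each family has a template fold; members are generated
  by substituting 3% of template residues (`mutate_residues`),
  yielding fingerprint Jaccard similarity around 0.5 within families
  and near 0 between. This emulates paralogous receptor pairs, whose
  folds are conserved and which the semi-blind regime pairs up. An
  appended-patch design (unrelated cores sharing a small rigid motif)
  was evaluated first and rejected: with member similarity confined to
  a patch (Jaccard 0.1–0.3), forest predictions transferred to held-out
  family members too erratically to represent the regime contrast the
  generator exists to exhibit. The whole-fold homolog design is also
  the more faithful emulation: real paralogs share their fold, not an
  isolated patch. Toy Cα structures are far coarser than all-atom
  inputs, so the *numeric* similarity of real pairs (≈ 0.1 all-atom) is
  not the target; the ordering (family pair ≫ background) is.
* **Signal**: each family owns a baseline intercept (0.5 ± 0.12,
  emulating targets of differing mean druggability) and 4 causal
  molecule bits with signed weights (magnitudes 0.2–0.35, scaled by
  `effect_size`; signs balanced within the family so the response stays
  centered in the score range — an all-negative family would saturate
  its targets at spKi 0, producing exactly the zero-variability targets
  the curation filter drops). The true potency of (molecule, target) is
  the clamped sum of the family intercept and the molecule's active
  weights. Family members share intercept and weights — that is the
  structure–activity coupling the models must discover. Gaussian noise
  (sd 0.05 ≈ 0.2 log units of Ki, typical inter-assay spread) is added
  on the spKi scale. Four bits at these magnitudes keep the interaction
  learnable at a few hundred activities per target; many weak bits
  require far larger panels than the reference conditions provide.
* **Raw table**: true scores convert to Ki through the inverse
  transform; boundary scores are emitted explicitly (0.5 nM at score 1,
  an inactive ">" record at score 0) since the inverse is not unique
  there. Fractions of records are censored ("<" at an inflated value),
  duplicated (re-measured within one order of magnitude, a later
  year), emitted in µM (lossless), or spoiled with nonsense units
  (excluded by curation). With noise and pathologies off, curation
  recovers the ground truth to numerical precision — the generator and
  the curation rules are exact inverses.

Reference conditions (defaults of `synthetic_config()`): 20 targets — 8
families of two plus 4 orphans — of 80 residues; 400 molecules at bit
density 0.05 (causal bits re-sampled at 0.5 so they carry variance);
200 activities per target; 5% censored, 5% duplicated, 2% wrong-unit
records. The regime-contrast experiments use a reduced layout (10
targets of 60 residues, 150 molecules, 100 activities per target, ten
seeds) so the forest fits complete quickly at full tree count; the
paired-vs-orphan comparison trains a single model per seed with both
holdout targets excluded and validates on each separately, so the
contrast is between holdout kinds, not between fits.

### What the generator does and does not emulate

It reproduces the *logical* structure of the problem — binary sparse
ligand features, structure-coupled responses, curation pathologies,
family structure among targets — but not chemistry (random bits, not
real substructures), not real fold geometry (Cα traces, not membrane
receptors), and not the scale (thousands, not hundreds of thousands of
records). Passing tests therefore demonstrate that the machinery is
correct and that the regimes behave as designed when a recoverable
signal exists; they do not calibrate expected performance on real
receptor panels.

## Known limitations

* The fingerprint ignores residue physicochemistry: neighborhoods of
  chemically similar but non-identical residues hash to unrelated bits.
* Hash collisions, though rare at 16,381 bits, merge unrelated patterns.
* mmCIF files, multi-model NMR ensembles (beyond model 1) and structure
  repair are out of scope; predicted single-chain models are the
  intended input.
* The semi-blind pairing is greedy; a globally optimal disjoint pairing
  can differ below the top pair (the top pair itself is provably the
  greedy one).
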