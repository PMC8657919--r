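---
title: "Predicting binned inter-residue distances: models, features, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting binned inter-residue distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distogramr)
```

## The problem and the model

Given a multiple sequence alignment (MSA) for a query protein of length
$L$, the package predicts, for every residue pair $(i, j)$, a categorical
distribution over 10 binned C$\beta$–C$\beta$ distances: $d < 4$ Å, then
2 Å bins up to the final open bin $d \ge 20$ Å (C$\alpha$ substitutes for
glycine, which has no C$\beta$). This *distogram* representation follows
the CASP distance-prediction format; contact probabilities fall out by
summing the first three bins, which jointly cover $d < 8$ Å — the CASP
contact definition.

The predictor is a deep two-dimensional convolutional residual network in
the AlphaFold1 lineage. Its input is an $L \times L \times 547$ pairwise
tensor; its trunk is 220 pre-activation residual blocks, each
BatchNorm → ELU → 1×1 conv → BatchNorm → ELU → 3×3 dilated conv →
BatchNorm → ELU → 1×1 conv → identity addition, with 3×3 dilations cycling
through 1, 2, 4, 8. The first 28 blocks are 256 channels wide, the
remaining 192 use 128. The network operates on 64×64 crops of the pairwise
map; a 1×1 convolution maps the final features to the 10 distance classes,
and full-height/width (64×1 and 1×64) convolutions collapse one spatial
axis to produce per-residue auxiliary predictions: secondary structure
(9 classes), $\phi$ and $\psi$ torsions (36 ten-degree bins plus an
error/gap class), and relative accessible surface area (10 equal bins plus
N/A). The auxiliary tasks exist to regularize the distance task, not as
products in their own right.

Because no deep-learning framework is available to R, the forward pass,
backpropagation (including BatchNorm and dilated-convolution gradients via
im2col), spatial dropout and the Adam optimizer are implemented directly
on BLAS matrix operations. The test suite verifies every layer type's
analytic gradient against central finite differences to $10^{-4}$
relative error.

## The input tensor: a documented channel budget

The published total is 547 channels, of which 442 come from
direct-coupling analysis; the exact composition of the remainder is not
printed anywhere we could find (a plain sum of the named parts gives 546).
This package therefore fixes and documents its own budget, exported as
`INPUT_CHANNELS`:

| block | channels |
|---|---|
| one-hot of residue *i* and *j* (20 aa + gap/unknown) | 2 × 21 |
| integer residue indices *i*, *j* (0-based, unscaled) | 2 |
| HMM profile rows for *i* and *j* | 2 × 30 |
| DCA coupling blocks (21 × 21 per ordered pair) | 441 |
| APC-corrected coupling norm | 1 |
| validity mask (1 on real residues, 0 on crop padding) | 547th |

The mask channel is this artifact's convention for the one unaccounted
channel; it also gives the network an explicit signal for zero-padded crop
cells. Residue indices are raw integers — any scaling is left to the
network's first BatchNorm.

## Direct-coupling analysis

Couplings are estimated by shrinkage-regularized inverse covariance (the
approach of the trRosetta-lineage pipelines), not pseudo-likelihood: rows
are reweighted by the standard rule $w_r = 1/|\{r' : \mathrm{id}(r, r')
\ge 0.8\}|$, the $20L \times 20L$ covariance of one-hot columns (gap state
excluded, re-inserted as zeros afterwards) gets $\lambda = 4.5 /
\sqrt{N_\mathrm{eff} L}$ added to its diagonal, and the precision matrix's
off-diagonal $20\times20$ blocks are the per-pair couplings. The pair
score is the Frobenius norm of the block, average-product corrected
(diagonal excluded from all means) with a zero diagonal. Excluding the gap
state from the inversion avoids gap-driven artifacts while preserving the
printed 21×21 block shape.

The validation oracle for DCA is generative: `potts_sample()` draws
alignments from a 20-state pairwise Potts model whose only nonzero
couplings are planted pairs (separation ≥ 5). Gibbs sampling with 50
burn-in sweeps is used because exact sampling is infeasible at $L = 40$;
a convergence spot-check (column independence at $\beta = 0$, seed purity)
is part of the test suite. Under the default study conditions ($L = 40$,
2000 rows, 8 planted pairs, coupling strength $\beta = 2.5$, field noise
0.5) the APC top-8 recovers at least 6 planted pairs on every seed we
test; $\beta = 2.5$ was chosen once as a clearly-detectable coupling (an
$e^{2.5} \approx 12$-fold conditional preference) representative of
strongly coevolving residue pairs.

## Labels

Distance labels bin the C$\beta$ map with edges at 4, 6, …, 20 Å
(left-closed). Torsions use the IUPAC sign convention (trans = ±180°,
reported in $[-180, 180)$); the first residue's $\phi$ and last residue's
$\psi$ are the error/gap class 36, as is every unresolved residue.
Relative ASA is computed internally by Shrake–Rupley sampling (probe
1.4 Å, a fixed deterministic 960-point golden-spiral sphere, per-element
van der Waals radii) normalized by the Tien et al. (2013) theoretical
maximum-ASA table — the original pipeline delegates to DSSP, but
desk-scale testing must not require the DSSP binary; classic DSSP output
files are parsed and preferred when supplied. Which max-ASA normalization
the original used is unstated; ours is documented and fixed. Secondary
structure likewise parses DSSP text when available and otherwise applies
an internal fallback of the published hydrogen-bond rules
(electrostatic N–H···O=C energy < −0.5 kcal/mol; n-turn patterns for
H/G/I, bridge patterns for E/B, then T and S). The fallback is not
bit-exact DSSP (π-helix and bulge edge cases differ); the tests assert
only robust properties, e.g. that an ideal α-helix interior is ≥ 80% H.
"9 classes" is read as the 8 DSSP codes plus blank/coil, with class 8
reserved for gap/error — a convention, since the grouping is not printed.
Pairs where either residue lacks C$\alpha$ carry an ignore value excluded
from the loss rather than being silently dropped.

## Training

Each epoch applies a freshly offset non-overlapping 64×64 crop grid to
every domain (so the union of crops covers the map exactly once) and
subsamples 50% of each domain's MSA rows (without replacement; the query
is always kept — the original is silent on the query, but features are
undefined without it). Features are recomputed online from the subsample;
for small desk-scale data this costs little, and it matches the stated
augmentation intent. Edge crops are zero-padded with mask 0 and ignore
labels; the original does not describe edge handling.

The loss is the weighted multicomponent cross-entropy
$15\,\mathrm{CE}_{dist} + 0.5\,\mathrm{CE}_{ss} + 0.25\,\mathrm{CE}_{\phi}
+ 0.25\,\mathrm{CE}_{\psi} + 0.5\,\mathrm{CE}_{asa}$, each component a
mean over non-ignored positions (a fully-ignored component contributes 0).
The per-residue components average the row-axis and column-axis head
contributions. Optimization is Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8, no
weight decay — common defaults, recorded here since only the learning
rates are printed) at an initial rate of 0.001 with the three published
decay tables: model A to 0.0005 at epoch 5 and 0.0001 at 15, B at 10/25,
C at 8/20. Validation uses static offset-(0, 0) grids, and the three
checkpoints with lowest validation loss are retained.

Numerical notes: cross-entropies clamp probabilities at $10^{-12}$;
training aborts with diagnostics on a non-finite loss; all randomness
(initialization, crop offsets, subsampling, dropout) derives from one
integer seed, and two runs with the same seed produce identical
trajectories.

The optimization sanity check trains an 8-block/16-channel model for 200
steps on a single synthetic domain ($L = 16$: a random MSA plus
ideal-helix labels) and requires the training loss to at least halve. This
check runs at the constant initial learning rate: the published decay
tables are keyed to epochs over a ~27k-domain corpus, and in a
one-crop-per-epoch overfit exercise they would throttle 185 of the 200
steps for reasons unrelated to what the check probes.

## Inference and ensembling

At prediction time the map is tiled by one base grid plus `n_offsets − 1`
shifted grids (deterministic, evenly spaced shifts by default so runs are
reproducible; random shifts when a seed is supplied — both satisfy the
coverage contract). Softmax is applied per crop *before* averaging, i.e.
aggregation is in probability space; whether the original averaged logits
or probabilities is unstated, and probability averaging keeps every
intermediate object a distribution. Each cell's distribution is the mean
over covering crops (padding excluded), which exactly corrects for
unequal coverage; the distogram is then symmetrized by averaging $(i, j)$
with $(j, i)$, since nothing in the architecture enforces symmetry.
Ensembling across models averages per-cell distributions and renormalizes
(a numerical no-op on the simplex). The published high-accuracy setting
is 10 overlapping offsets and a 3-model ensemble.

## Evaluation

True contacts are pairs with C$\beta$ distance strictly below 8 Å.
Sequence-separation ranges are short = 6–11, mid = 12–23, long = ≥ 24;
pairs closer than 6 are excluded. Within a range, predictions are ranked
by probability — ties broken by ascending $(i, j)$, a documented
deterministic convention — and the top $\min(L, \text{pairs in range})$
are called contacts. The accuracy is normalized as
$\mathrm{TP} / \min(L, T)$ where $T$ is the number of true in-range
contacts: the stated intent is that 100% be achievable even when $T < L$,
and this is the minimal formula achieving it. A range with $T = 0$ is
undefined (NA) and excluded from averages, rather than scored 0 — the
published tables are ambiguous between the two readings. Scores are
invariant under monotone transforms of the probability map.
`accuracy_depth_correlation()` reproduces the cohort analysis: targets are
split at MSA depth 400 and the Pearson correlation of depth with average
accuracy is reported per stratum, plus a length–accuracy correlation
overall.

## What the synthetic generators emulate — and what they do not

`ideal_helix()` builds poly-alanine from fixed internal coordinates
($\phi = -57°$, $\psi = -47°$, $\omega = 180°$, standard bond geometry,
tetrahedral C$\beta$), so recomputing its torsions is a closed-loop
geometry oracle. `lattice_chain()` snakes through a cubic lattice
(5.5 Å spacing) to provide a compact fold with contacts at all sequence
separations. `potts_sample()` provides coevolution signal with known
ground truth; `random_msa()` provides i.i.d. mutated copies of a query.
All are pure functions of their seed.

None of these reproduce real protein data: there is no phylogenetic
correlation between MSA rows, no realistic gap structure, no side chains,
and no native-like fold diversity. Passing tests therefore demonstrate
that the machinery is correct (features computed as specified, gradients
exact, aggregation lossless, scoring faithful) — not that a desk-trained
model reaches the published CASP14 accuracy, which required the full
CATH s35 corpus and roughly two months of GPU training per model. The
published headline accuracies are consequently out of scope here, as is
running the external MSA/profile tools themselves (their output formats
are read, and internal fallbacks are provided).

## Problem sizes used by the checks

The shipped checks run at desk scale, chosen once as the smallest sizes
that exercise each property convincingly: featurization and aggregation
oracles at $L \le 40$; DCA recovery at $L = 40$ with 2000 sequences over
three seeds; the architecture audit builds the full 220-block network and
runs one 64×64 crop forward; the overfit sanity uses an 8-block model for
200 steps; the end-to-end smoke runs tiny networks at $L \in \{16, 40\}$.

## Known limitations

* The channel budget and SS class table are documented conventions, not
  recovered facts; a retrained original checkpoint would not be
  weight-compatible.
* The DSSP fallback diverges from DSSP on edge cases; supply a real DSSP
  file when fidelity matters.
* ASA uses only the atoms present in backbone-level structures, so
  absolute rASA values are lower than side-chain-complete calculations;
  binning semantics are unaffected.
* The pure-R network is CPU-bound: a full-length default-architecture
  forward pass costs tens of seconds per 64×64 crop. The architecture is
  faithful, but production-scale training is out of reach by design.
* Insertion-coded PDB residues are ordered lexicographically after their
  base number — a guess about upstream data that well-formed files
  satisfy.
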