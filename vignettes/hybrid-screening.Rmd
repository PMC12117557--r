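---
title: "Descriptor-integrated graph neural networks for ligand-based virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-integrated graph neural networks for ligand-based virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ligand-based virtual screening ranks a compound library by predicted
activity against a target using only previously assayed actives and
inactives — no target structure. High-throughput screens are severely
imbalanced (hundreds of actives among 10^5–10^6 molecules), and only the
very top of the ranked list can be experimentally confirmed, so the
quantities that matter are *early-recognition* metrics, not global accuracy.

`vshybrid` implements and evaluates a simple but widely used integration
strategy: a graph neural network (GNN) encodes the molecular graph into a
learned representation `h`, which is concatenated with a vector of
expert-crafted molecular descriptors `h_dp` before classification:

```
h  = GNN(m)
p̂  = f([h ‖ h_dp])
```

where `m` is the molecular graph and `f` is an MLP with a sigmoid output,
trained by minimizing binary cross-entropy

```
L = -(1/n) Σ_i [ y_i log p̂_i + (1 - y_i) log(1 - p̂_i) ].
```

The rationale: GNN readouts struggle with *non-additive molecule-level*
properties (total polar surface area is the canonical example), with small
training sets, and with over-smoothing/over-squashing; scalar descriptors
deliver exactly that global information directly. The package provides the
hybrid model plus both ablations (GNN-only, descriptor-only) so the
contribution of each branch can be quantified with paired statistics.

## Model components and defaults

**GCN encoder.** Per layer: add self-loops, aggregate neighbor features with
symmetric normalization `1/sqrt(deg_i · deg_j)` (degrees counted with
self-loops), linear transform, ReLU. Defaults: 3 layers, width 128, mean
readout. The aggregation is implemented as a gather/scatter kernel that is
algebraically identical to multiplying by `D^{-1/2}(A + I)D^{-1/2}`; tests
verify the equivalence against a dense-matrix oracle at 1e-6.

**SchNet-style encoder.** For 3D inputs: per-element learned embeddings,
then interaction blocks in which the inter-atomic distance (radius neighbors
within a 10 Å cutoff) is expanded in 50 Gaussian radial basis functions with
centers uniform on [0, cutoff] and width equal to the spacing; a two-layer
filter network with shifted-softplus maps the expansion to per-channel
weights; the continuous-filter convolution sums neighbor states multiplied
elementwise by those filters; atom-wise layers and a residual update follow.
Sum readout. Because only distances enter, the embedding is invariant under
rigid rotation/translation (checked at 1e-5 relative tolerance). Bond
features are deliberately not used on this path.

**Encoder registry.** Both encoders are registered by name;
`register_encoder()` accepts additional architectures (e.g. spherical
message passing over distance/angle/torsion) without any change to the
training core. No such model ships with the package.

**Descriptors.** The built-in set holds molecule-level scalars only:
heavy-atom count, molecular weight, ring count (circuit rank `E - V + C`),
aromatic ring count, aromatic atom count, H-bond donors/acceptors,
rotatable bonds, topological polar surface area, logP, molar refractivity,
formal charge sum, fraction of sp3 carbons, and per-element atom counts
(23 features). Fragment-based values come from OpenBabel; graph-derived
counts from the package's own perception. Externally computed descriptor
tables (e.g. a 391-column QSAR export) can be substituted through a CSV
importer that enforces exact id matching and imputes missing cells with
training-set feature means (never label-aware). Descriptors are z-scored
with training-set location and *population* scale (ddof = 0); zero-variance
features are flagged and mapped to 0.

**Training protocol.** Adam (lr 1e-3), batch size 128, 30 epochs, dropout
0.2 in the MLP hidden layers ([128, 64]) only. The returned model is always
the final-epoch state: with so few actives, validation-based early stopping
is itself high-variance, and dropout is the regularizer of choice. A single
integer seed drives initialization, shuffling and dropout; two runs with the
same (seed, config, data) are bit-identical. Class reweighting is off by
default (an optional positive-class weight is exposed): ranking quality, not
calibrated probability, is the target, and the unweighted loss already
orders compounds by the learned activity logit.

## Evaluation metrics

All four panels consume a ranked result (score, label) and depend only on
the induced ordering (strictly increasing score transforms change nothing —
property-tested):

* **logAUC[0.001, 0.1]** — area under the ROC curve with FPR on a log10
  axis restricted to [0.001, 0.1], normalized by the log-width. TPR is
  interpolated linearly in FPR between ROC vertices, the curve is anchored
  at (0, 0) so FPRs below the empirical minimum are covered, and the
  integral is a trapezoid rule over ≥ 10,001 log-uniform grid points joined
  with all ROC vertices inside the range. A perfect classifier scores 1;
  a random one scores `∫10^u du / ∫du ≈ 0.0215` over `u ∈ [-3, -1]` — both
  anchors are asserted in the tests.
* **BEDROC(α = 20)** — exponentially weighted early recognition in [0, 1],
  normalized between the all-top and all-bottom placements of the actives.
* **EF_100** — active fraction in the top 100 divided by the global active
  fraction (random expectation 1).
* **CG_100 / DCG_100** — count of actives in the top 100, and the same
  count discounted by `log2(rank + 1)`.

Rank-based metrics break score ties deterministically (score descending,
then stable input order) so all tests are exact; the ROC sweep instead
advances tie blocks as single diagonal segments.

## Splits and statistics

`random_split` permutes ids under a seed and takes the first `floor(0.8 N)`
for training. `scaffold_split` groups molecules by Bemis–Murcko framework
(iteratively pruning terminal atoms, keeping ring systems plus linkers with
atom types retained; canonical SMILES of the framework is the key, `""` for
acyclic molecules) and assigns whole groups largest-first to training until
the target fraction is reached. Large scaffold families therefore land in
training and the test side is enriched for rare chemotypes — the intended
stress test for generalization to novel scaffolds. Equal-size group runs
are shuffled under the seed so replicate scaffold splits differ. The
alternative of giving every acyclic molecule its own group is a flag.

Model pairs are compared per (dataset, metric) with a paired t-test over
replicates evaluated on byte-identical split files, reporting the mean
difference, 95% CI, paired Cohen's d_z, and Benjamini–Hochberg-adjusted
p-values with the family spanning all pairs × metrics × datasets.
Zero-variance difference vectors are flagged degenerate rather than tested.

## The synthetic screen generator

Real HTS benchmarks are external and cluster-scale, so the package ships a
generator that emulates their statistical shape at desk scale: molecules
are assembled by attaching 0–3 substituents (from 16 fragments, including
one designated motif — sulfonamide) onto one of up to 16 ring scaffolds at
valence-safe template sites, deduplicated on canonical SMILES. The latent
activity is

```
w_global · z(TPSA) + w_motif · 1[motif present] + N(0, noise²)
```

and the top `ceil(active_fraction · n)` latent scores are labelled active,
making the class balance exact and the tests deterministic. TPSA is the
global channel precisely because it is in the descriptor set but is a
non-additive, molecule-level quantity that a shallow mean-readout GCN
recovers only indirectly — recreating the asymmetry that motivates
descriptor integration. Substituent counts are drawn with probabilities
(0.10, 0.25, 0.35, 0.30) for 0–3 so the combinatorial space is large enough
to yield thousands of unique structures while bare scaffolds still occur.
Optional 3D coordinates are produced once at generation time by OpenBabel's
seeded builder (hydrogens dropped after embedding), stored in the SDF, and
never regenerated downstream.

What the generator does *not* emulate: real structure–activity landscapes
(activity cliffs, multi-pharmacophore logic), assay noise structure
(frequent hitters, autofluorescence), tautomer/protonation state diversity,
and library-scale chemical diversity. Passing the directional test —
GCN + descriptors beating GCN alone on mean logAUC when part of the signal
is descriptor-visible — therefore demonstrates that the machinery learns
and that the integration recovers planted global signal; it does not
certify improvements on any particular real screen.

## Numerical and design choices

* Scores are clipped to [1e-7, 1 - 1e-7] inside the loss.
* Deduplication keys are OpenBabel canonical SMILES; the duplicate-label
  policy defaults to keep-active (a confirmed active outweighs an inactive
  read), with keep-first and drop-conflict selectable.
* Allowed elements default to {H, C, N, O, S, P, F, Cl, Br, I}.
* Heavy-atom graphs by default; explicit hydrogens are folded into an
  H-count node feature (an explicit-H mode exists).
* Aromaticity is taken from OpenBabel's perception (via a parallel MOL2
  conversion, since V2000 output is kekulized); ring membership from bridge
  analysis; ring counts are circuit ranks. These are documented stand-ins
  for the unpublished curation rules of descriptor packages.
* Implicit hydrogens follow a standard-valence model over kekulized bond
  orders with charge adjustment; bracket atoms whose SMILES declares a
  non-standard hydrogen count are normalized to standard valence on SDF
  round trip (V2000 has no portable zero-H marker that survives
  re-perception).
* The benchmark driver shares one split file per replicate across all
  models, logs every seed, and writes a manifest with config hash and
  output checksums; reruns reproduce `metrics.csv` bit for bit.

## Problem sizes used by the test suite

The automated tests run the full pipeline at sizes chosen to exercise every
code path while completing on a laptop-class single core: unit fixtures of
20–300 molecules; the directional experiment on one 4000-molecule screen
(2% actives, `w_global = w_motif = 1`, noise 0.5) with five seeded 80/20
splits and three model variants at the default 30 epochs; fifty seeded
scaffold splits for the no-straddling property. `scripts/acceptance.R`
re-runs the 4000-molecule benchmark end to end through `run_benchmark()`
and writes the headline numbers as JSON.

## Known limitations

* No spherical message passing model (distance/angle/torsion); the registry
  is the extension point.
* The built-in descriptor set is a compact scalar/2D stand-in, not a
  reimplementation of any large QSAR descriptor engine, and contains no 3D
  descriptors.
* No tautomer or protonation standardization; structures are taken as
  parsed.
* Scaffold definition is atom-typed ring-systems-plus-linkers; generic
  (carbon-skeleton) scaffolds are not offered.
* The metric layer requires at least one active and one inactive in the
  ranked list and raises otherwise; extremely small scaffold-split test
  sides can hit this by construction.
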