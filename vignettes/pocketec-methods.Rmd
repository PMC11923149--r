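---
title: "Classifying enzyme function from binding-site graphs: models and design"
author: "pocketec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying enzyme function from binding-site graphs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Enzyme Commission (EC) numbers classify enzymatic reactions in four
hierarchical levels (main class, subclass, sub-subclass, designation:
`2.7.10.1` is a transferase, transferring phosphorus-containing groups,
as a protein-tyrosine kinase). Predicting the EC number from a 3D
structure with a whole-fold representation risks learning the
topology–function correlation of the training set rather than catalytic
chemistry: structures with the same fold usually share a function in
curated databases, so a fold-recognizing model scores well without
understanding the chemistry, and fails exactly where prediction is most
interesting — similar folds with different functions, or similar
functions on different scaffolds.

`pocketec` follows the opposite premise: the chemistry within a local
neighborhood of the binding site should suffice. The package cuts a
**localized 3D descriptor** around a binding-site center, types its
residues or heavy atoms by chemical environment, builds a radius-limited
graph, and classifies it with message-passing networks whose geometric
features are rigid-motion invariant. Complementary machinery removes
fold leakage from the evaluation (sequence-cluster fold splits), probes
what the model uses (alanine scanning, coordinate jitter, random-center
controls), and explains single predictions (a node softmask).

## The localized descriptor

A binding site is a 3D center with provenance: experimental annotation,
a pocket-prediction table (rank-1 site by default), transfer from
superposed ligand-bearing homologs (`transferSites`: alignment score
strictly above 0.5, common crystallization ligands excluded, mapped
ligand centroids within 4 Å merged and ranked by member count), or — as
a negative control — a random Cα (`randomCenter`).

Three cuts produce the descriptor (`selectAll`, `selectByRadius`,
`selectByCount`). The radius cut keeps every unit within `r` of the
center (inclusive; residues are measured at their Cα). The count cut
expands from the nearest unit outward to exactly `n` units, ties broken
by file order so the cut is deterministic. Defaults follow the scale at
which classification performance plateaus in this family of models:
100 residues or 150 heavy atoms (count mode), 16 Å (radius mode).
Extraction happens in memory at graph-build time; PDB files are never
edited.

## Node typing

Node types are chemical environments, not elements: a backbone carbonyl
oxygen, a serine hydroxyl oxygen and a carboxylate oxygen are different
classes; all α-carbons share one class. The shipped scheme
(`defaultAnnotationScheme`) is a reconstruction from ff19SB-style
force-field groupings, constrained to exactly 21 residue classes (20
standard amino acids + other), 31 heavy-atom classes, and 20 hydrogen
classes. Hydrogens are dropped on reading by default and their
vocabulary is unused by the shipped models — it is carried so atom
tables that include protons can still be typed. Alternative mappings
load from a three-column TSV; the scheme version travels with every
serialized graph and checkpoint, and checkpoints refuse to load against
a different scheme.

## Graphs

`buildGraph` places one node per kept residue (at its Cα) or heavy
atom, and adds a directed edge `j -> i` whenever `d_ij` is at most the
neighbor radius and `j` is among the `maxNeighbors` nearest neighbors
of `i` (ties by node index). The edge cutoff is not part of the
published hyperparameter set, so it is an engineering default here:
15 Å at residue resolution (Cα contact scale) and 6 Å at atom
resolution (covalent + contact scale), both configurable; the in-degree
cap defaults to 32. Graphs carry no edge features — distances and
angles are recomputed from positions inside the networks, which keeps
coordinate augmentation cheap and guarantees that geometric features
and positions never drift apart. Graph sets serialize to a hierarchical
JSON container (`/graph_id/{positions, types, edges, label}`) with
full-precision numbers.

## The two classifiers

**Distances (continuous-filter) network.** Type embeddings
`x_i ∈ R^F` are refined by interaction blocks. Each block expands every
edge length in a Gaussian radial basis
`e_k(d) = exp(−γ (d − μ_k)²)`, feeds it through two dense layers with
shifted-softplus (`ssp(x) = ln(0.5 eˣ + 0.5)`) to generate a filter
`W(d_ij) ∈ R^F`, and convolves
`x_i ← x_i + atomwise(ssp(atomwise(Σ_j x_j ∘ W(d_ij))))`
(Hadamard product, sum over in-neighbors, shared dense "atom-wise"
layers, residual connection). A linear + shifted-softplus readout with
dropout produces per-node class contributions, sum-pooled per graph.
Defaults: 6 interaction blocks, 128 embeddings and filters, 50
Gaussians, dropout 0.25.

Two notes on the radial basis. The published description of the
Gaussian grid (centers every 0.1 Å from 0 to 30 Å, i.e. 301 centers)
conflicts with the stated "50 Gaussians"; the default here is 50
centers evenly spaced on `[0, cutoff]`, with the dense grid available
as `rbfConfig(grid = TRUE)`. And a width "γ = 10 Å" is dimensionally
inconsistent with `exp(−γ d²)`; γ is implemented in Å⁻², matching the
magnitude used in continuous-filter networks.

**Distances + angles (directional) network.** Messages live on
directed edges. An embedding block initializes `m_ji` from both
endpoint embeddings and the radial expansion of `d_ji`; each of 4
interaction blocks updates `m_ji` by aggregating incoming messages
`m_kj` modulated by the radial basis of `d_ji` and a spherical
Fourier–Bessel expansion of `(d_kj, α_(kj,ji))`, the angle taken at
`j`. Seven spherical-harmonic degrees and six radial Bessel functions
build the 2D basis (`j_l(z_ln d/c) P_l(cos α)` with a smooth polynomial
envelope vanishing at the cutoff); Bessel roots are computed once by
root interlacing. Following the efficiency variant of directional
message passing, bases are combined with messages by Hadamard products
after small linear maps (basis embedding 8, interaction embedding 64)
instead of a bilinear form, and every block feeds an output block
(output embedding 256) whose per-node results are summed into the
logits. The published update equation is typographically truncated; the
implementation follows the cited directional-message-passing
construction it names.

Both architectures are invariant to rigid motions by construction
(geometry enters only through distances and angles) and to node
permutation (sum pooling); the test suite asserts both properties on
random graphs, and backpropagation for the distances network is
hand-derived and verified against finite differences. The directional
network ships forward-only — it supports inference, invariance checks
and (finite-difference) explanation, while training targets the
distances network.

Sum pooling (rather than mean) was chosen to match the additive
"sum over blocks" readout; mean pooling is a config switch. Dropout is
applied before the final classifier only.

## Training

The loss is weighted cross-entropy,
`l_n = −Σ_c ω_c log softmax(x_n)_c y_{n,c}`, with inverse-frequency
class weights normalized to mean 1 (the published account states only
that rarer classes get larger weights; the exact form is this package's
choice, configurable). Optimization uses Adam (lr 0.001, β₁ 0.9,
β₂ 0.999), minibatches of concatenated graphs, optional class-balanced
oversampling with replacement, and coordinate jitter of 0.05 Å on
training graphs only. Early stopping monitors validation accuracy with
patience 10; the returned checkpoint is the latest epoch among the
equally best validation accuracies, so a model that reaches its
validation plateau early still finishes fitting the training set.
Training is bit-reproducible under a fixed seed.

## Evaluation

`evaluateClassifier` reports accuracy, the protein-centric F-score in
two conventions — the plain single-label F1 (threshold 0, which reduces
to accuracy for single-label prediction) and F-max over a confidence
threshold sweep, since the benchmark convention this score comes from
does not pin the variant — per-class AUPR by step interpolation with
classes lacking positives excluded, and per-hierarchy-level accuracy by
truncating predicted designations. The AUPR implementation is checked
against an independent threshold-loop reference on random fixtures.

## Fold and temporal splits

`foldSplit` applies the cluster rules per EC: clusters containing
several ECs are first separated by EC; with ≥ 3 clusters, whole
clusters are distributed (greedy largest-first into the partition with
the largest remaining deficit, validation and test guaranteed at least
one cluster); with 2 clusters, one goes entirely to test — the smaller,
to preserve training mass, a policy this package fixes where the rule
is silent — and the other is divided over train and validation; a
single cluster is divided 80/10/10 by item. `verifySplit` reports any
cluster of a multi-cluster EC that spans test and train/validation
(and, for ≥ 3-cluster ECs, any cluster split at all); single-cluster
ECs are exempt because the ratio rule divides them by design.
`temporalSplit` orders by deposition date (ties by id; undated items
excluded with a warning). `clusteringJaccard` compares two clusterings
over co-clustered pairs — the only reading under which "similarity per
enzyme pair" is well defined.

## Softmask explanation

For a trained model and one graph, a per-node mask `F ∈ [0,1]`
multiplies the node's type embedding — the only differentiable
attachment point for categorical nodes — and is optimized to minimize
`l(y, ŷ) + β₁·mean(F) + β₂·mean(H(F))` with the guarded entropy
`H = −F log(F + c) − (1−F) log(1−F + c)`. Edge masks are deliberately
absent: edges encode spatial adjacency, not bonds, so an edge
explanation would not be chemically interpretable. The optimizer is
projected gradient descent on the mask logits with backtracking line
search, so the objective trace is non-increasing by construction; the
defaults (init 0.5, 150 steps, initial step 0.25, β₁ = 0.05,
β₂ = 0.1, c = 1e−15) were fixed once for reliable convergence on
descriptor-sized graphs and all live in `explainerConfig`. The
converged mask is min-max normalized per structure (an unspecified
"normalization" elsewhere; min-max is this package's choice); constant
masks map to 0.5 and are flagged, and atom-level values aggregate to
residues by max.

## The synthetic generator: what it emulates, what it does not

`makeToyStructure` / `makeDataset` exist so every module is testable
without downloading structure databases. Each class is a small residue
motif (default: four classes of six residues — catalytic-triad-like
SER/HIS/ASP, thiol/thioether CYS/MET/TRP, charged LYS/ARG/GLU, and
aromatic-hydroxyl PHE/TYR/THR, each twice) planted on consecutive
positions near the middle of an ideal helix-like chain (Cα spacing
3.8 Å, no self-clashes under 2.5 Å), with the site center at the motif
centroid and all motif residues within the 8 Å placement radius.
Remaining residue types are uniform over the 20 standard amino acids.
Custom motif geometries (a pairwise Cα distance matrix) are embedded by
classical scaling and rejected when not realizable in 3D or when they
would break chain continuity. Side chains are pseudo-atoms at idealized
internal offsets — sufficient for atom typing, alanine truncation and
distance tests, explicitly non-physical. A quarter of structures (the
decoy rate) also carry a wrong-class motif far from the site
(> 2× placement radius), so the label is recoverable only from the
site region; a lineage clustering and pseudo deposition dates are
emitted for the split machinery.

Because the class signal is carried by node *types* near the center,
passing tests show that the pipeline learns and explains local
chemical composition, and that locality, splitting, and perturbation
machinery behave correctly. They do not show sensitivity to fine
side-chain geometry, robustness to real experimental noise, or
performance on real enzymes — the synthetic chains are not folds. One
visible consequence: a well-trained residue-resolution model on these
conditions is almost insensitive to coordinate jitter up to 2.5 Å
(types survive translation), so the translation sweep typically shows a
mild, sometimes noisy, downward trend rather than the sharp degradation
a geometry-dependent model would show.

## Study conditions and problem sizes

The experiment-level tests and `scripts/acceptance.R` use one fixed
configuration, chosen once as a desk-scale instance of the method:
4 classes × 40 structures of ~60 residues (decoy rate 0.25), count-cut
descriptors of 30 residues, graphs with 10 Å edge cutoff and 16 max
neighbors, and a distances classifier with embedding 64, 3 interaction
blocks and 32 Gaussians trained up to 200 epochs (batch 32). The
paper-scale defaults (128/6/50/32) remain the constructor defaults.
The perturbation sweeps run the alanine fraction grid
{0, 0.2, …, 1.0} and the translation grid {0, 0.5, …, 2.5} Å,
averaging three independent perturbation draws per level; explanation
recovery uses ten held-out structures.

## Known limitations

- Only the distances architecture trains (analytic backprop); the
  directional network is inference-only and its explanation gradient
  is finite-difference, hence slow for large graphs.
- The annotation vocabulary is a faithful reconstruction, not the
  original supplementary table; users with the original table can load
  it as a TSV.
- The greedy k-mer clusterer is a fixture utility, not a replacement
  for a production sequence-clustering tool; real workflows should
  ingest cluster TSVs from such a tool.
- Pocket prediction and structure alignment are interfaced (tables,
  transforms), never reimplemented.
- mmCIF, assemblies, protonation and missing-atom repair are out of
  scope for the reader.
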