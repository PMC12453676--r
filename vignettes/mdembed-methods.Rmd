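---
title: "mdembed: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mdembed: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models: what is
computed, under which assumptions, which knobs matter, and where the
design was genuinely open and a choice had to be made. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## 1. From frames to contact graphs

Each trajectory frame is reduced to its Cα trace (one node per residue,
ordered by residue index with atom-name tie-breaks, so node identity is
stable across frames — a property the rest of the pipeline silently
depends on). For a frame with pairwise Cα distances $d_{ij}$ and a cutoff
$c$ (default 10 Å, the conventional residue-contact radius), the contact
graph has an undirected edge $(i,j)$ iff $d_{ij} < c$, weighted

$$w_{ij} = 1 - d_{ij}/c \in (0, 1].$$

Numerical choices:

* **Strict inequality.** Pairs exactly at the cutoff are excluded, so
  zero-weight edges cannot occur and edge presence is equivalent to
  $w_{ij} > 0$.
* **Disconnected graphs are legal.** At small cutoffs a residue can be
  isolated; every embedding method tolerates this (node2vec truncates
  walks, the GNN aggregators see an empty neighborhood) rather than
  erroring.
* **No rounding** of weights until report generation.

Because distances are invariant under rotation and translation, so is the
graph; the test suite asserts this to $10^{-9}$ under random rigid
motions, and the synthetic generator deliberately applies a random rigid
motion to every frame so this invariance is load-bearing in every
end-to-end test.

## 2. Node embeddings

Both embedding families map each frame's graph to a $|V| \times d$ matrix
(default $d = 64$; the choice is a width/compute trade-off, not an
upstream-fixed value — nothing in the pipeline depends on it
structurally, and the acceptance tests use smaller $d$ to stay inside
their time budget).

### 2.1 node2vec

Per frame, `num_walks` (10) biased second-order walks of `walk_length`
(80) start at every node. Standing at $v$ having arrived from $t$, the
probability of stepping to a neighbor $x$ is proportional to
$w_{vx}\cdot\alpha$ with

$$\alpha = \begin{cases} 1/p & x = t \\ 1 & x \in N(t) \\ 1/q &
\text{otherwise,} \end{cases}$$

the classical return/in-out bias. The first step of a walk, which has no
predecessor, uses plain edge-weight-proportional probabilities. A
skip-gram model with negative sampling (window 5, 5 negatives, unigram
distribution raised to 3/4) is then fitted on the walk corpus by
mini-batch SGD with a linearly decaying learning rate.

Two choices address the fact that independently fitted skip-gram spaces
have arbitrary orientation:

* **Warm start.** Frame $t{+}1$'s vectors initialize from frame $t$'s
  fit, keeping consecutive frames in a common orientation without any
  Procrustes step.
* **Content memoization.** A frame whose graph is bit-identical to an
  already-embedded frame reuses that embedding. This makes "identical
  graphs get identical embeddings" hold exactly for node2vec, as it does
  trivially for the GNN encoders; continuing SGD from a warm start on an
  identical corpus would not reproduce the previous matrix bit-for-bit.

### 2.2 GCN / GAT / GraphSAGE

One encoder with shared parameters is trained on a uniformly sampled
subset of frames (default 10%, capped at 64) and then applied to every
frame. A shared encoder is what makes embeddings comparable across
frames; per-frame training would reintroduce the orientation problem.

The objective is unsupervised link prediction: positives are the frame's
edges, negatives are uniformly sampled non-edges (1:1), and the loss is
binary cross-entropy on $\sigma(z_i^\top z_j)$. Unsupervised training was
chosen because state classifiers are trained *after* embedding in this
workflow, which implies the embeddings themselves are not
label-supervised; this is a design decision, not an upstream-documented
fact, and switching to supervised encoders would be a deliberate change.

Node features are the one-hot node identity concatenated with the scaled
weighted degree. Identity features are frame-constant, so all
frame-to-frame signal flows through the edges; the degree column injects
local geometry directly.

Architectures (2 layers, hidden width 64, linear output layer):

* **GCN**: symmetric-normalized weighted adjacency with self-loops,
  $\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}$, ReLU between layers.
* **GAT**: attention logits $e_{ij} =
  \mathrm{LeakyReLU}(a_s^\top W h_i + a_d^\top W h_j)$, softmax-normalized
  over each neighborhood with the edge weight entering multiplicatively;
  2 heads concatenated in the hidden layer, single linear head on output.
* **GraphSAGE**: $h'_v = \mathrm{ReLU}(W_s h_v + W_n \bar h_{N(v)})$
  where $\bar h_{N(v)}$ is the weighted mean over a sampled neighborhood
  (sample size 10 per layer) during training and over the *full*
  neighborhood at inference, which makes inference deterministic.

All gradients are hand-derived and verified against finite differences
(relative error $\sim 10^{-6}$); optimization is Adam. Training aborts
with the offending epoch if the loss turns non-finite. Every stochastic
step draws from the R RNG seeded by `embedding_config$seed`, so reruns
are bit-identical.

## 3. State labeling

The label generator formalizes the usual "basins in the PCA landscape"
procedure:

1. **Superposition.** Every frame is least-squares fitted (Kabsch) onto a
   reference frame (default frame 1). Coordinate PCA without fitting
   mixes rigid-body and internal motion; since the generator applies
   random rigid motions, skipping this step would destroy the landscape.
   This is a necessity-driven addition to the published recipe, which
   does not mention fitting.
2. **PCA** of the $n \times 3m$ flattened coordinates. Signs are fixed so
   each component's largest-magnitude loading is positive (reproducible
   plots). A zero-variance ensemble is flagged degenerate rather than
   erroring.
3. **Density.** 2D Gaussian kernel density (`MASS::kde2d`) of the
   (PC1, PC2) scores on a 128×128 grid, normal-reference bandwidths per
   axis, grid extended by one bandwidth so the density integrates to ≈ 1
   over the grid. The threshold (default 0.02) is interpreted as a value
   of this probability density; since the upstream normalization of
   "units of density" is ambiguous, the threshold is a free parameter.
4. **Regions.** Grid nodes above the threshold are grouped into
   4-connected components. Containment is tested against this grid mask
   (nearest grid node), not against traced polygons: boundary points then
   count as inside by construction, and raising the threshold can only
   shrink regions. Polygons are still traced at the threshold level for
   export and plotting; the two views agree up to grid resolution.
5. **Names.** Regions are named either by *anchors* — one representative
   (PC1, PC2) point per state, making the expert assignment step explicit
   and reproducible (a region without an anchor is an error) — or, when
   only names are given, in order of decreasing peak density. Everything
   outside every region is non-state `N`: "N" means *low density*, never
   "numerical edge case".

## 4. Features, split, classifiers

Flattening is node-major (`node1_dim1 … node1_dimd, node2_dim1 …`), so a
row can be reshaped back to $|V| \times d$; the 1-D CNN relies on this to
convolve along the node axis, the only structured axis that survives
flattening. The split is a single stratified 70/30 partition with
largest-remainder per-class allocation (exact sizes, proportions within
one frame), not cross-validation — matching the single-evaluation
protocol of the upstream study; stratification is on by default but
switchable, since the original protocol does not say.

Classifier implementations are native R behind a uniform
`classifier_spec()` surface (the runtime image provides no tree/boosting
or deep-learning libraries): logistic regression is ridge-regularized
`glmnet` at $\lambda = 10^{-3}$; the random forest bags 100 CART trees
with $\sqrt{p}$ feature sampling; the two boosting presets run multiclass
softmax gradient boosting on regression trees (depth 3, 50% column
sampling for the "xgboost-style" preset; depth 6 and 30% columns for the
"lightgbm-style" one; both 60 rounds, shrinkage 0.1); the neural network
is a one-hidden-layer (64) ReLU MLP and the CNN a width-5, 8-filter
convolution with global average pooling, both trained with Adam; the SVM
is linear one-vs-rest with squared hinge loss. Features are standardized
with training-set statistics for the linear/neural/margin models; tree
ensembles see raw features. Per-class recall is reported as the
"class-specific accuracy", the standard reading of a per-class column
next to an overall-accuracy column.

## 5. The synthetic world

`default_hinge_references()` builds a planar zig-zag Cα trace (3.8 Å
consecutive spacing, 120° pseudo-bond angle) and a "closed" copy with the
second arm rotated 60° about the midpoint hinge. The zig-zag matters: a
perfectly straight trace at this spacing leaves the closest new
cross-hinge pair at 10.05 Å — just outside the default cutoff — so a 60°
bend would change edge *weights* but not the edge *set*; with the
zig-zag's shorter effective axis the bend creates genuinely new contacts,
which is what a hinge closure does in a real protein. Bends that bring
non-consecutive residues within 2 Å are rejected as self-intersecting.

Generator defaults (the stated world of the tests): $m = 40$ residues,
2000 frames, occupancies 0.45/0.45 with a 0.10 transition fraction,
noise $\sigma = 0.5$ Å (a typical Cα thermal fluctuation, and well below
the multi-Å state separation, matching the "separation ≥ 2× noise"
regime the discrimination properties assume), and a random rigid motion
per frame. Transition frames in the middle 60% of the interpolation path
are labeled `I`; the path endpoints fold into their state cores.

What a green test does and does not establish: the generator produces
clean two-basin geometry with isotropic noise and no kinetics, solvent,
or force-field physics. Passing the end-to-end discrimination property
(GraphSAGE + logistic regression ≥ 0.9 test accuracy) shows the pipeline
preserves contact-topology signal through embedding, flattening and
classification; it does not certify accuracy levels on real trajectories,
where state overlap, slow degrees of freedom and label noise dominate —
that is why the acceptance criteria are properties, not reproduction of
the upstream accuracy table, whose 100,000-frame source data is not
available here.

## 6. Conventions and limitations

* Frame indices are 1-based throughout, as idiomatic R.
* Times absent from input are synthesized as frame indices (ps) so that
  striding semantics still work.
* All randomness flows from one global seed through per-stage derived
  seeds; `run_pipeline()` writes the fully resolved config (defaults made
  explicit) to the run log and a checksummed manifest, and identical
  configs reproduce identical manifests.
* XTC/TRR input requires the python MDAnalysis bridge; PDB, GRO and DCD
  are parsed natively. No trajectory imaging/unwrapping is performed —
  inputs are assumed whole and contiguous.
* Not in scope: free-energy reconstruction, time-lagged/kernel PCA,
  Markov state models, automatic basin counting, whole-graph pooling or
  temporal graph embeddings, hyperparameter search, per-residue
  attribution.
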