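---
title: "Separating heterogeneous cryo-EM projection mixtures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating heterogeneous cryo-EM projection mixtures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(projclust)
```

## The problem

Single-particle cryo-EM usually images a purified sample of one
macromolecule. When a heterogeneous cellular extract is imaged instead, the
resulting 2D projection images (or 2D class averages) come from a *mixture*
of different particles, and they must be sorted into per-particle groups
before any 3D reconstruction is possible. `projclust` clusters such a stack
of same-sized grayscale projection images into groups, one group per
underlying 3D structure, using two complementary sources of signal:

1. **Common lines.** By the projection-slice theorem, any two 2D projections
   of the *same* 3D object share a 1D line projection. Images are reduced to
   their stacks of 1D line projections (rows of a Radon transform) over a
   5°-spaced angle grid on `[0°, 175°]`; every image pair is scored by its
   best-matching line pair, and each image is connected to its most similar
   peers in a directed k-nearest-neighbor similarity graph.
2. **Learned image features.** A convolutional backbone embeds each image;
   a Siamese network with a triplet loss fine-tunes those embeddings so
   that projections of the same complex sit closer together than
   projections of different complexes.

Graph structure is turned into vectors by node-embedding methods; image and
node embeddings are fused and reduced; the result is clustered by methods
that do not need the number of clusters in advance. Because the number and
identity of complexes in an extract is unknown but *some* annotated data is
usually available, model selection is semi-supervised: hyperparameters and
the distance measure are chosen on a training subset of complexes, and the
resulting quality is reported on held-out complexes.

## Common-line similarity graph

For image $i$ and angle $\theta$, the line projection is the vector of
column sums of the image rotated by $-\theta$ about its center (bilinear
interpolation, zero padding). A pair of images is scored over all
$36 \times 36$ angle combinations and the best value kept — the minimum for
distance measures (L1, L2, 1D Wasserstein on min-shifted, mass-normalized
signals) or the maximum for similarity measures (cosine, Pearson
correlation). Ties go to the lexicographically smallest angle pair, so
results are reproducible. Degenerate signals (zero variance under
correlation, zero norm under cosine) score 0 and never win the argmax.

Per source node, the $n-1$ candidate scores are Z-scored; distance scores
are negated after Z-scoring so that "larger weight = more similar" holds
for every measure. Each node keeps its 5 largest-weight out-edges (default),
or the graph keeps its `m` globally largest edges (`top_m_edges` mode, used
for larger experimental stacks). Two readings of "Z-score relative to all
edge scores" are possible; the node-relative reading is the default and a
`global_zscore` flag provides the graph-wide alternative.

Two numerical caveats are deliberate:

* **Mass conservation.** Row sums of a line-projection stack equal the
  image's total intensity only for images whose support fits the inscribed
  disk — rotation clips corner content. Particle images produced by the
  generator (and typical class averages) are centered with empty borders,
  so conservation holds to well below 1%; the package does not attempt to
  conserve mass for corner-supported inputs.
* **No translational search.** Images are assumed centered, so 1D signals
  are compared at full length without sliding; a shift search could be
  added in front of the measure but is not part of the default pipeline.

## Image embeddings and the triplet loss

The bundled backbone (`tiny-cnn`) is three 3×3 convolution blocks with
seeded random filters, ReLU, 2×2 average pooling, and a global average
pool. Random convolutional features are a standard, surprisingly strong
baseline and make the package fully self-contained; named ImageNet
backbones (AlexNet, VGG-11, DenseNet, ResNet-18, EfficientNet-B1/B7,
ResNet-50) are accepted at the interface but raise an instructive error
when their weights are not available locally. Images are min-max scaled to
$[0,1]$ per image and replicated to three channels at this boundary.

Fine-tuning trains a dense head of 512, 256 and 256 units — ReLU and batch
normalization on the first two layers — on top of the frozen backbone,
mirroring the common transfer-learning recipe of freezing a pretrained
trunk. Training triples $(A, P, N)$ combine every same-complex image pair
with 10 random negatives from other complexes (or one negative per other
complex in `per_class` mode), and the loss is

$$L(A,P,N) = \max\!\big(\lVert f(A)-f(P)\rVert^2 - \lVert f(A)-f(N)\rVert^2
  + \text{margin},\, 0\big),$$

with margin 0.5, squared Euclidean distances (the FaceNet convention; a
flag switches to unsquared norms), Adam at learning rate $10^{-4}$, 10
epochs, batch size 2 (32 for complex-split training). Triples are split
80/20 into train/validation and per-epoch losses of both are recorded.
Embeddings are not L2-normalized by default; the head's last layer width
fixes the output dimension at 256.

## Node embeddings

Three families are implemented behind one pluggable interface (any
function `(graph, params) -> matrix` is accepted unchanged):

* **node2vec** — second-order biased random walks (return parameter $p$,
  in-out parameter $q$, both 1 by default; 10 walks per node of length 80)
  fed to skip-gram with negative sampling (window 10, 5 negatives,
  unigram$^{3/4}$ table, 5 passes, linearly decaying rate). Walks follow
  edge direction on directed graphs. Z-scored weights can be negative, so
  transition probabilities use the per-node shift $w - \min(w) + 10^{-6}$,
  which preserves neighbor ranking while guaranteeing a valid
  distribution. Nodes that never occur in a walk of length ≥ 2 are
  embedded as zero vectors with a warning.
* **GraphWave** — on the symmetrized graph Laplacian $L = D - A$, the heat
  wavelet $\Psi_s = U\,\mathrm{diag}(e^{-s\lambda})\,U^\top$ is evaluated at
  scales $\{5, 10\}$; each node's features are the real and imaginary parts
  of the empirical characteristic function of its wavelet column, sampled
  at 50 points evenly spaced in $[0, 100]$ (dimension $2 \times 50 \times
  2$). Structure-only: automorphically equivalent nodes receive identical
  rows, which the tests assert on rings and stars.
* **DGI-GCN** — a one-layer graph convolutional encoder
  $H = \mathrm{PReLU}(\hat A X W)$ over the symmetrized, self-looped,
  degree-normalized adjacency, trained with the graph-infomax objective: a
  bilinear discriminator separates true (node, graph-summary) pairs from
  corruptions built by row-shuffling the node attributes (the image
  embeddings). 100 epochs of Adam at $10^{-3}$, all gradients computed
  analytically in-package.

The wider method families these three represent (other random-walk,
attention-based and sampling-based graph encoders) are reachable through
the plug-in interface but are not implemented here.

No embedding hyperparameters are prescribed by the study setting; the
defaults above are the common published defaults of each method and are all
exposed in `node_embedding_params()`.

## Fusion and dimensionality reduction

Image and node blocks are column-standardized (zero mean, unit variance,
zero-variance columns dropped) before concatenation so that a block with
large numeric scale cannot dominate; this is a package choice, exposed as a
flag. Reduction uses PCA for dense matrices and uncentered truncated SVD
when more than half of the entries are exactly zero, keeping every
component whose explained-variance ratio is at least 2% — read per
component, not cumulatively — with a floor of two components. Component
signs are fixed (largest-magnitude loading positive) so repeated runs are
bit-identical. Reduction can run on the concatenation or per block before
concatenation (`concat_then_reduce` vs `reduce_then_concat`).

## Clustering and semi-supervised model selection

Spatial clusterers: DBSCAN, OPTICS, a BIRCH-style clustering-feature
method, and affinity propagation — all free of a preset cluster count.
Hyperparameter grids are exhaustive and fixed: eps / max_eps 0.25–3 by
0.25 with min_samples 2–10; threshold 0.1–1 by 0.1 with branching factor
10–100 by 10; damping 0.5–1 by 0.1. The distance measure is selected from
22 candidates (Bray-Curtis, Canberra, Chebyshev, city-block, correlation,
cosine, Dice, Euclidean, Hamming, Jaccard, Jensen-Shannon, Kulsinski,
Mahalanobis, matching, Minkowski, Rogers-Tanimoto, Russell-Rao,
standardized Euclidean, Sokal-Michener, Sokal-Sneath, squared Euclidean,
Yule) by the best silhouette of the ground-truth *training* classes;
hyperparameters by the best matching-based F-score (FMMF) on the
*training* images. Ties prefer higher silhouette, then fewer clusters,
then the earlier grid point. Test metrics are reported but never drive
selection.

Numerical decisions worth knowing:

* **OPTICS extraction.** The full reachability ordering is computed, and
  clusters are extracted at the `max_eps` threshold (the DBSCAN-equivalent
  extraction) rather than by ξ-steepness. The tuned grid varies `max_eps`,
  which pairs naturally with threshold extraction; the ordering and
  reachability values are returned for inspection.
* **BIRCH variant.** A single-pass clustering-feature method: a point joins
  the nearest subcluster when the merged radius stays within `threshold`,
  otherwise starts a new subcluster; exceeding `branching_factor`
  subclusters triggers a rebuild at a 1.5× larger threshold. There is no
  global clustering step — subclusters are the clusters.
* **Binary measures** (Dice through Yule) operate on the nonzero-indicator
  pattern of the vectors, which is the only meaningful reading on
  real-valued embeddings; Minkowski uses $p = 3$ so it is distinct from
  Euclidean; Jensen-Shannon min-shifts and mass-normalizes each vector.
  Measures undefined on a given matrix (singular covariance, zero-variance
  columns, zero-mass rows) are skipped during selection, with a log entry.
* **Noise points** from density clusterers count as singleton clusters in
  all supervised scores (penalizing precision); `drop_noise` excludes them
  instead.
* **Affinity propagation** runs with the median off-diagonal similarity
  ($-d^2$) as preference; a run that does not stabilize its exemplar set
  for 15 consecutive sweeps is treated as a failed grid point.

Eight graph community methods cluster the similarity graph directly:
strongly/weakly connected components, walktrap with 4 steps, edge
betweenness, greedy modularity, k-clique percolation (default $k = 3$, the
smallest nontrivial choice; nodes outside any community become
singletons), and semi-synchronous (graph-coloring schedule) and
asynchronous label propagation. Methods defined for undirected graphs
symmetrize the input first — the cited label-propagation algorithms are
undirected, so this is the documented fallback for directed graphs. Since
Z-scored weights can be negative, weight-using methods receive
shift-positive weights, and edge betweenness receives them converted to
distances (`max(w) - w + eps`), matching its interpretation of weights as
costs.

## Evaluation

Supervised scores compare predicted and ground-truth partitions:

* **F-similarity** between two clusters: harmonic mean of overlap/|P| and
  overlap/|T|.
* **FMMF** — maximum-weight one-to-one matching between predicted and true
  clusters on the F-similarity matrix; the matched weight divided by the
  number of predicted (precision) or true (recall) clusters; F1 by
  harmonic mean.
* **CMMF** — per-cluster best matches without the one-to-one constraint,
  averaged on each side; never below FMMF.
* **Qi et al. F-score** — a cluster pair matches when
  $|P \cap T|^2 / (|P||T|) \ge 0.25$ (threshold configurable).
* **UnSPA** — geometric mean of sensitivity
  $\sum_T \max_P |T \cap P| / \sum_T |T|$ and unbiased PPV
  $\sum_P \max_T |T \cap P| / \sum_P |P|$.

The defining reference of the F-similarity family lies outside this
package's sources, so the formulas above are fixed here as design
decisions and verified in tests against brute-force matching enumeration.
Unsupervised indices (silhouette under the selected measure,
Calinski-Harabasz, Davies-Bouldin) are computed after removing noise
points and reported as `NA` markers when fewer than two clusters remain.
For experimental stacks with junk particles (images belonging to no
annotated complex), supervised metrics are reported twice: junk as its own
pseudo-complex, and junk excluded.

## Synthetic data generator

The generator emulates the study conditions rather than any specific
deposited dataset: six base 3D shape families (sphere, dumbbell, cube,
torus, rod, L-shape) on a cubic voxel grid with ~1-voxel soft edges;
classes beyond six are seeded random variants (anisotropic axis scaling
plus added spherical lobes) of the base shapes — a geometric stand-in for
structurally distinct macromolecules, not a PDB emulation. Projections are
line integrals of the trilinearly rotated volume at orientations drawn
uniformly on SO(3); per-class projection counts are drawn uniformly from a
range (2–12 for the small regime, 13–20 for the more-projections regime);
images are padded to the common extent and rescaled to 100×100. The noise
model reads the description literally: Gaussian noise whose mean *and*
variance equal the image's own pixel moments (a brightness shift plus
grain; `zero_mean` gives the zero-centered alternative), then exactly
`round(0.01 · H · W)` pixels set to the image extremes, half hot and half
dead.

What passing tests on this generator do **not** show: robustness to CTF
effects, off-center picking, junk contamination, or the texture statistics
of real micrographs — none of which the generator models. Recovery results
on synthetic fixtures are therefore statements about the pipeline's
mechanics, not about absolute accuracy on experimental data.

## Problem sizes and runtime choices

The test suite and examples run on deliberately small instances chosen to
exercise every code path at interactive speed: 24–48 images of 48–100 px
for pipeline tests, a 4-class × 12-projection noisy fixture for the
end-to-end recovery check, 8×8 random images for oracle-equivalence
checks, and 16–20-node synthetic graphs for the embedding methods. The
exact Radon-operator cache makes line projections linear in the number of
images after the first; pair scoring and skip-gram training are native
code. The t-SNE implementation is the exact $O(n^2)$ variant, appropriate
for the hundreds-of-images scale this package targets.

## Known limitations

* The common-line score compares full-length 1D signals of equal-sized,
  centered images; partial-overlap sliding and mixed image sizes are out
  of scope.
* The bundled backbone is randomly initialized; with pretrained weights
  available, the `resnet50-pretrained` configuration reproduces the
  intended transfer-learning setting.
* The k-clique communities can overlap; the partition output assigns
  overlapping nodes to their first community, which loses the overlap
  structure.
* 3D reconstruction from recovered groups, CTF simulation and
  micrograph-level particle picking are downstream/upstream steps that
  this package does not attempt.
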