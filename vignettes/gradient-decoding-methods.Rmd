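---
title: "Methods: segmenting and decoding connectivity gradients"
author: "gradientDecoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting and decoding connectivity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradientDecoding)
```

## The problem

Macroscale gradients summarize a dense vertex-by-vertex functional
connectivity matrix with a few smooth spatial axes: vertices close on an axis
are strongly interconnected, and the principal axis runs from unimodal
sensorimotor cortex to transmodal association cortex. A gradient map by
itself has no behavioral labels. Meta-analytic decoding supplies them: the
axis is cut into segments, each segment becomes a target map, and the target
is correlated against a library of meta-analytic maps, each labeled by a term
or a topic from the neuroimaging literature. This package implements that
whole chain -- gradient decomposition, segmentation, target construction,
meta-analytic map construction, spatially-aware inference, and the metrics
used to compare decoding strategies -- together with a synthetic-data module
that plants known structure so every stage can be validated end to end.

## Gradient decomposition

`connectomeGradients()` chains four steps:

1. **Inverse Fisher transform** (`inverseFisher`): z-valued connectomes are
   mapped back to correlations by `tanh`, bounding values in [-1, 1].
2. **Row sparsification** (`rowSparsify`): each row keeps its top 10% of
   connections (`ceiling(density * n)` entries; ties at the cutoff keep the
   lowest column index, which makes the operation deterministic). The result
   is intentionally asymmetric.
3. **Cosine affinity** (`cosineAffinity`): similarity of sparse connectivity
   profiles; unit diagonal, symmetric. A vertex with an all-zero profile is a
   hard error rather than a silent NaN.
4. **Diffusion map embedding** (`diffusionEmbedding`): the affinity is
   alpha-normalized (`alpha = 0.5`, the standard anisotropic normalization
   that corrects for sampling density), converted to a transition operator,
   and eigendecomposed through its symmetric conjugate. The trivial constant
   eigenvector (detected by coefficient of variation < 1e-6) is dropped.
   Components are scaled by `lambda / (1 - lambda)`, the multi-scale
   weighting corresponding to diffusion time 0.

Choices the procedure leaves open, and how this package resolves them:

* **alpha and diffusion time.** 0.5 and 0 -- standard diffusion-maps
  practice; both are exposed as arguments.
* **Negative affinities** are clipped to 0 before normalization so the
  operator stays row-normalizable.
* **Sign convention.** Eigenvector signs are arbitrary; each component is
  flipped so the vertex with the largest absolute loading is positive.
* **Explained variance** is reported as `lambda / sum(lambda)` over the
  retained non-trivial components. Using squared eigenvalues instead would
  change the printed ratios but not the ordering; the linear form is used
  throughout.

The dense symmetric eigensolver is exact and deterministic; no iterative
eigensolver noise enters the pipeline.

## Segmentation of the gradient axis

Three approaches, all returning a `Segmentation` with labels that partition
the vertices, strictly increasing interior boundaries, and per-segment
anchors:

* **PCT** (`segmentPct`): boundaries at the j·(100/k)-th percentiles (linear
  interpolation); labels are assigned by rank so populations stay balanced
  within one vertex even under ties. Anchors are segment medians.
* **KMeans** (`segmentKmeans`): k-means++ seeded with 10 restarts, clusters
  relabeled in ascending centroid order so labels are monotone along the
  axis. Anchors are the centroids ("centers of inertia").
* **KDE** (`segmentKde`): a Gaussian kernel density estimate of the axis is
  evaluated on a 1024-point uniform grid extended three bandwidths past the
  data range; boundaries are the interior local minima of the curve. The
  bandwidth is tuned by bisection on the log scale over [1e-3, 1] times the
  data range (60 iterations) until exactly k-1 interior minima exist;
  plateaus of the discretized curve count once, at their midpoint. If no
  bandwidth in the range achieves k-1 minima -- or the resulting boundaries
  leave a segment empty -- the function raises rather than returning a
  malformed segmentation. Anchors are the density maxima between consecutive
  minima, which exist by continuity.

`multidimCluster` generalizes the k-means path to the joint space of up to 9
gradients; there are no boundaries in n-D, and anchors are centroids.

Quality metrics (`silhouetteMap`, `clusterQuality`) follow the standard
definitions: per-vertex silhouette (singleton clusters score 0, the common
convention), Calinski-Harabasz variance ratio, Davies-Bouldin cluster
separation. Silhouette is delegated to the `cluster` package; variance ratio
and separation are computed directly and all three are verified against
brute-force oracles in the test suite. `nmi` normalizes mutual information
by the arithmetic mean of the two entropies.

## From segments to pseudo-activation maps

Correlating a binary segment mask throws away the within-segment ordering,
so each segment is converted to a continuous map: the affinity
`A(v, p) = exp(-D^2(v, p) / (2 sigma^2))` of every segment member `v` to the
segment's peak point `p`, with Euclidean distance in gradient space.

* **Peaks** (`computePeaks`): terminal segments take their peak at the
  extreme data value on the side away from the neighboring segment (1-D
  only); interior peaks are the method anchors -- median (PCT), centroid
  (KMeans), density maximum (KDE). In n-D every cluster peak is its
  centroid.
* **sigma** is "the average distance within the segment". That phrase is
  ambiguous; the package defaults to the mean distance of segment members to
  the peak (O(n), peak-centered) and offers the mean pairwise distance
  behind `sigmaMethod = "pairwise"`.
* **Support.** Vertices outside the segment are set to 0 rather than masked,
  so every map in a set shares a fixed full-cortex support and all
  correlations are computed over the same vertices. A flag for
  within-segment support was considered and rejected: fixed support keeps
  the decoding comparable across segments of different sizes.

## Meta-analytic maps

From a coordinate database (`StudyDatabase`: per-study peak coordinates plus
a study-by-term TFIDF feature matrix):

* **Study selection.** `selectByTerm` keeps studies whose TFIDF weight for
  the term exceeds 0.001, eliminating incidental mentions; `selectByTopic`
  keeps studies with p(topic | article) > 0.05. Both thresholds follow the
  conventions of the large automated coordinate databases this mirrors.
* **Modeled activation** (`maMap`): each study's peaks are convolved with a
  binary 10 mm sphere and max-combined, on either a volumetric grid
  (`makeGrid`, default 4 mm spacing) or directly on surface vertex centers --
  the synthetic path uses vertices and needs no volume-to-surface
  resampling. Out-of-grid coordinates are clipped with a warning.
* **Chi-square meta-analysis** (`chi2Meta`): per cell, the 2x2 table of
  selected/unselected by active/inactive, Pearson chi-square without
  continuity correction, reported as `sign(P(active|sel) - P(active|unsel))
  * sqrt(chi2)` (a signed z-like value; the raw chi-square is kept
  alongside). Cells with a zero margin are 0, not NaN.
* **Topics** (`fitTopics`): latent Dirichlet allocation by collapsed Gibbs
  sampling (C++), 200 iterations by default, symmetric priors
  `alpha = 50/K`, `beta = 0.01`, seeded and exactly reproducible. The two
  distributions used downstream, p(word|topic) and p(topic|article), are
  row-normalized from the final state. Topic labels are the top-3 words
  (ties broken lexicographically); three words carry most of a topic's mass
  and keep reports compact.

## Decoding and inference

`decode` correlates every pseudo-activation map with every meta-analytic map
over cortex vertices. Because spatially smooth maps correlate by chance,
significance uses spin permutations (`spinNulls`): a uniformly random
rotation (QR-based, determinant +1) of the spherical projection, mirrored
across hemispheres, followed by a greedy nearest-neighbour reassignment
without replacement, so each null map is a true bijection of the original
values -- the value multiset and the autocorrelation structure are preserved
-- and the medial wall never moves. p is the literal fraction of null
correlations greater than or equal to the observed one (one-sided; a
`(k+1)/(n+1)` estimator is available for users uncomfortable with p = 0),
followed by Benjamini-Hochberg FDR across all (segment, map) pairs of the
run; significance is q < 0.05. By default the meta-analytic maps are spun;
spinning the targets instead is available and is what the calibration tests
use. One-sidedness means negative correlations can never reach
significance -- intentional, since decoding asks which labels match, not
which anti-match.

`correlationProfile` summarizes a family of decodings: per segment the top
correlation located at the segment's peak coordinate, with per-k mean and
standard deviation. On planted data the profile is u-shaped -- terminal
segments decode better than interior ones -- which the tests check
qualitatively.

## Semantic metrics

* **IC**: `-log p(t, d)` (natural log) with p the within-document relative
  frequency; map-level IC averages over the meta-analytic sample, skipping
  documents where the term is absent (their IC is infinite; add-one
  smoothing is available behind a flag). Topic IC sums the top words' ICs.
* **TFIDF**: raw term count times the smooth inverse document frequency
  `ln((1+D)/(1+d_t)) + 1`, averaged over the sample. This is the convention
  of the standard TFIDF transformer; a literal reading of some printed
  formulas in the literature yields negative values for a nonnegative
  quantity and is treated as a typesetting artifact.
* **Categories**: expert votes become p(category | word) by proportion
  (`categoryModel`); a word takes the category with probability strictly
  greater than 0.5, otherwise Non-specific. Topics score each category by
  p(category|word) weighted by p(word|topic), with unannotated words
  contributing Non-specific mass, and the same strict rule applies.
* **SNR**: Functional-to-non-functional label ratio. Its normalization is
  reported as the functional fraction, so `normalized = snr / (1 + snr)`
  whenever the ratio is finite; an all-functional set is flagged infinite.
  SNR counts per-segment top-label occurrences, not unique labels.
* **Report weights** (`reportWeights`): for word clouds, p(topic | word) by
  Bayes under a uniform prior over the retained (significant, functional)
  topics, weighted by each topic map's correlation.

## The synthetic world

`synthWorld` builds a coupled scene with known truth:

* **Mesh** (`synthSphere`): Fibonacci lattice (quasi-uniform; nearest
  neighbour spacing CV < 0.2) on a sphere of radius 100 mm, so millimetre
  kernel radii behave sensibly; a contiguous cap (10% by default) plays the
  medial wall.
* **Axis and connectome** (`synthConnectome`): the normalized z-coordinate
  of the cortex is the latent axis t; connectivity is
  `exp(-|t_i - t_j| / 0.1)` plus symmetrized Gaussian noise (sd 0.02),
  clipped to [-1, 1] with unit diagonal. The lengthscale 0.1 gives one
  global smooth axis; the noise is small relative to the kernel, as in
  group-averaged connectomes, and gradient 1 recovers t with |Spearman rho|
  essentially 1.
* **Database** (`synthDatabase`): topics own disjoint signature-word blocks
  (Dirichlet word distributions putting ~80% of their mass on the block);
  studies draw sparse topic mixtures (Dirichlet 0.1), multinomial token
  counts (~150 tokens), and peak coordinates. Two spatial regimes exist.
  *Cap* sampling scatters peaks isotropically around one focus per topic --
  focal activations, used to validate the spatial accuracy of meta-analytic
  maps against planted centers. *Axis* sampling (used by `synthWorld`)
  assigns each topic a band of the functional axis and draws peaks from
  cortex vertices weighted by a Gaussian band profile (width 0.06 axis
  units, 3 mm jitter) -- distributed networks that follow the axis, the way
  real cognitive systems follow connectivity gradients. The distinction
  matters for inference: a single focal blob can be rotated into any
  favorable position, so spin p-values for blob maps are bounded below by a
  spherical-cap area fraction no decoder can beat; distributed patterns are
  destroyed by rotation, which is exactly the behavior the spin null is
  designed around. Features are TFIDF of the token counts.
* **Annotations** (`synthAnnotations`): each word gets a true category
  (Functional with probability 0.5 by default); raters vote the truth with
  probability `agreement` (0.9) and a uniform other category otherwise.

What the generator does *not* emulate: cortical folding and true geodesic
distances, hemispheric asymmetries, the empirical autocorrelation spectrum
of HCP connectomes, citation- and vocabulary-frequency skew of real
abstracts, and volume-to-surface resampling error. Passing tests therefore
demonstrate correctness of the machinery and recoverability of planted
structure, not performance claims about real connectomes.

## Problem sizes and runtime choices

The validation suite runs dense eigendecompositions at n = 1000 (20 seeds),
end-to-end worlds at 1000-2000 vertices with 200-500 studies and 6 topics,
and spin inference with 1000 permutations (200 for the pure calibration
check, where resolution of extreme p-values is not at stake). Six wide
topic bands are used in the end-to-end recovery runs so that each terminal
segment contains one clearly dominant generating topic; many narrow bands
make the "generating topic" of a half-axis segment ill-defined, which is a
property of the question, not of the decoder. The O(n^2) silhouette oracles
and the greedy spin reassignment (C++) keep these sizes comfortably on one
CPU.

## Known limitations

* The spin null assumes a spherical projection; no variogram-matched or
  generative surrogate nulls are provided.
* The literal p = k/n estimator can return 0; switch to `"plus_one"` if
  downstream tooling dislikes zero p-values.
* GC-LDA-style dot-product decoding is out of scope; externally supplied
  topic map sets can still be decoded through the generic map-set interface.
* The KDE tuner targets exactly k-1 minima; heavily discretized data may
  admit no such bandwidth, and the error reports which counts were
  achievable instead of silently returning a different k.
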