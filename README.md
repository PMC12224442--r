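# gradientDecoding

Segmentation and meta-analytic functional decoding of macroscale
connectivity gradients, on the cortical surface.

## What this solves, and for whom

Diffusion map embedding of a dense functional connectome yields *gradients*:
smooth spatial axes along which vertices with similar connectivity profiles
lie close together. The principal gradient spans unimodal sensorimotor to
transmodal association cortex — but a gradient map carries no behavioral
labels. Researchers label it by **meta-analytic decoding**: cut the axis
into segments, turn each segment into a target map, and correlate the target
against a library of term- or topic-labeled meta-analytic maps built from
coordinate databases of the neuroimaging literature.

This package implements that whole workflow for connectomics researchers:

- **Gradients** — inverse Fisher transform, top-10%-per-row sparsification,
  cosine affinity, diffusion map embedding
  (`A_ij = cos(x_i, x_j)`, operator `D_2^{-1} D^{-α} A D^{-α}` with
  `α = 0.5`, components scaled by `λ/(1−λ)`), explained-variance ratios
  `λ_i / Σλ`.
- **Segmentation** — percentile (PCT), 1-D k-means, and KDE boundary
  detection (boundaries at local minima of the density curve, bandwidth
  tuned by bisection to give exactly k−1 minima), scored by mean silhouette,
  Calinski–Harabasz variance ratio and Davies–Bouldin separation; k-means
  clustering in joint n-D gradient space, compared across dimensionalities
  with normalized mutual information.
- **Pseudo-activation maps** — per segment, the Gaussian RBF affinity
  `A(v,p) = exp(−D²(v,p)/2σ²)` to a peak point `p` (terminal segments peak
  at their far extreme; interior peaks are medians / centroids / density
  maxima), with `σ` the mean within-segment distance to the peak.
- **Meta-analytic maps** — study selection by TFIDF feature threshold
  (terms, 0.001) or `p(topic|article)` threshold (LDA topics, 0.05); 10 mm
  binary-sphere modeled-activation maps (max-combined); per-cell 2×2 Pearson
  chi-square between selection and activation, signed by association
  direction; LDA fitted by a seeded collapsed Gibbs sampler (C++).
- **Decoding and inference** — Pearson correlation of every (segment, map)
  pair; spin-permutation nulls (random sphere rotations followed by greedy
  nearest-neighbour bijection, medial wall fixed); `p = #(r_null ≥ r_obs)/n`;
  Benjamini–Hochberg FDR at q < 0.05; correlation profiles across k.
- **Semantics** — information content `−ln p(t,d)`, smooth-idf TFIDF,
  expert-vote category models with a strict 0.5 classification rule,
  functional/non-functional SNR, and Bayes-inverted word-cloud weights.
- **Synthetic data** — connectomes with a planted latent axis, Fibonacci
  sphere meshes with a medial-wall cap, coordinate databases with planted
  topics (focal or axis-distributed regimes), corpora, and synthetic expert
  annotations — every stage testable with known ground truth.

## Worked example

A planted world: a 1000-vertex sphere whose z-axis is the latent
connectivity axis, 200 studies from 6 topics occupying consecutive bands of
the axis.

```r
library(gradientDecoding)

w     <- synthWorld(nVertices = 1000, nStudies = 200, nTopics = 6,
                    vocabSize = 120, seed = 42)
grads <- connectomeGradients(w$connectome, nComponents = 9)
grads
#> GradientSet: 899 vertices, 9 components
#>   explained variance: 0.140 0.137 0.132 0.125 0.116 0.106 0.094 0.081 0.069

g1 <- gradientComponents(grads)[, 1]
abs(cor(g1, w$truth$latentAxis, method = "spearman"))   # axis recovery
#> [1] 1

seg <- segmentKmeans(g1, 2, seed = 42)
clusterQuality(segmentPoints(seg), segmentLabels(seg))
#> mean silhouette 0.692 | variance ratio 3941 | cluster separation 0.416

cortex  <- which(cortexMask(w$mesh))
centers <- meshCoordinates(w$mesh)[cortex, ]
sm  <- studyActivationMaps(w$db, centers, radius = 10)
tm  <- buildTopicMaps(w$db, list(docTopic = w$truth$docTopic,
                                 wordTopic = w$truth$wordTopic),
                      centers, studyMaps = sm)
tab <- decode(buildMapSet(seg), tm, w$mesh, nPerm = 1000, seed = 43)
head(tab[tab$segment == 1, ], 3)
#>   segment  label      r    p     q significant
#> 1       1 topic1  0.637 0.00 0.000        TRUE
#> 2       1 topic2  0.292 0.00 0.000        TRUE
#> 3       1 topic3 -0.216 0.98 0.999       FALSE
head(tab[tab$segment == 2, ], 3)
#>   segment  label      r     p     q significant
#> 7       2 topic6  0.690 0.000 0.000        TRUE
#> 8       2 topic5  0.347 0.001 0.003        TRUE
#> 9       2 topic4 -0.082 0.787 0.999       FALSE
```

Reading the output: the first gradient explains the largest variance share
and reproduces the planted axis exactly (Spearman ρ = 1). The two-segment
k-means solution splits the axis near its middle with a healthy silhouette
(0.69). Decoding then assigns each terminal segment its generating end
topic — `topic1` for the low end and `topic6` for the high end — with the
strongest correlations (r ≈ 0.64 and 0.69), both surviving spin-permutation
inference and FDR correction, while an unrelated mid-axis topic (`topic3`,
`topic4`) is correctly non-significant.

`runPipeline(pipelineConfig(...))` drives the same chain end to end and
writes TSV/GIFTI artifacts plus a manifest; `evaluateGrid()` crosses
segmentation methods with map sources and summarizes correlation, IC,
TFIDF, SNR and clustering quality per strategy and k, marking top
performers by percentile thresholds (90th for correlation/SNR, 70th for
IC/TFIDF). A thin CLI over these functions lives in
`inst/scripts/gradient-decode.R`.

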