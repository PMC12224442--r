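Package: gradientDecoding
Title: Segmentation and Meta-Analytic Functional Decoding of Connectivity Gradients
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing macroscale gradients of functional
    connectivity on the cortical surface. Builds low-dimensional gradient
    embeddings from dense connectivity matrices by diffusion map embedding of a
    sparsified cosine-affinity matrix; segments the gradient axis with
    percentile, one-dimensional k-means, or kernel-density boundary detection
    and scores segmentations with silhouette, variance-ratio and
    cluster-separation metrics; converts segments to continuous
    pseudo-activation maps with a Gaussian radial-basis transform; builds
    term- and topic-based chi-square meta-analytic maps from coordinate
    databases; decodes maps by spatial correlation with spin-permutation
    (spherical rotation) null models and Benjamini-Hochberg FDR control; and
    evaluates decoding strategies with correlation profiles, information
    content, TFIDF, expert-category classification and signal-to-noise ratio.
    A synthetic-data module generates connectomes, spherical meshes, coordinate
    databases, corpora and annotations with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
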