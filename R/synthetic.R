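## Synthetic inputs with planted ground truth: connectomes with a latent
## 1-D axis, quasi-uniform spherical meshes, coordinate databases with
## planted topics, and expert annotations. Every generator is a pure
## function of (parameters, seed).

#' Synthetic connectome with a planted 1-D latent axis
#'
#' Vertices receive latent positions t in [0, 1]; connectivity decays
#' exponentially with latent distance, \code{exp(-|t_i - t_j| / lengthscale)},
#' plus symmetric Gaussian noise; the diagonal is 1 and values are clipped to
#' [-1, 1]. The principal gradient of this matrix recovers t.
#'
#' @param nVertices number of vertices (>= 50).
#' @param lengthscale decay scale of connectivity along the axis (axis
#'   units); 0.1 gives a smooth global axis across [0, 1].
#' @param noiseSd standard deviation of the additive noise, small relative to
#'   the unit-scale kernel.
#' @param seed RNG seed.
#' @param latent optional externally supplied latent positions (e.g. from a
#'   mesh); length nVertices.
#' @return List with \code{connectome} (r-valued
#'   \linkS4class{DenseConnectome}) and \code{truth} (list with
#'   \code{latentAxis}).
#' @export
synthConnectome <- function(nVertices = 2000, lengthscale = 0.1,
                            noiseSd = 0.02, seed = NULL, latent = NULL) {
  if (nVertices < 50) stopUser("need at least 50 vertices")
  if (noiseSd < 0) stopUser("noiseSd must be >= 0")
  withSeed(seed, {
    t <- if (is.null(latent)) stats::runif(nVertices) else {
      stopifnot(length(latent) == nVertices)
      as.numeric(latent)
    }
    C <- exp(-abs(outer(t, t, "-")) / lengthscale)
    if (noiseSd > 0) {
      E <- matrix(stats::rnorm(nVertices^2, sd = noiseSd), nVertices)
      C <- C + (E + t(E)) / 2
    }
    diag(C) <- 1
    C[C > 1] <- 1; C[C < -1] <- -1
    list(connectome = DenseConnectome(C, valueKind = "r"),
         truth = list(latentAxis = t))
  })
}

#' Quasi-uniform spherical mesh with a medial-wall cap
#'
#' Fibonacci-lattice points on a sphere; a contiguous cap around the +x axis
#' of the requested area fraction is flagged as medial wall. The sphere is
#' scaled to a physical radius (default 100 mm) so millimetre kernel radii
#' are meaningful on it.
#'
#' @param nVertices number of vertices.
#' @param medialFraction area fraction flagged as medial wall, in [0, 1).
#' @param seed RNG seed (used to randomize the lattice phase).
#' @param radius sphere radius in mm.
#' @return A \linkS4class{SphereMesh} (single hemisphere, labelled "L").
#' @export
synthSphere <- function(nVertices = 2000, medialFraction = 0.1, seed = NULL,
                        radius = 100) {
  if (medialFraction < 0 || medialFraction >= 1)
    stopUser("medialFraction must lie in [0, 1)")
  withSeed(seed, {
    i <- seq_len(nVertices)
    z <- 1 - (2 * i - 1) / nVertices
    golden <- pi * (3 - sqrt(5))
    phase <- stats::runif(1, 0, 2 * pi)
    theta <- golden * i + phase
    r <- sqrt(pmax(0, 1 - z^2))
    xyz <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
    # cap around +x of area fraction f: x > 1 - 2f
    medial <- xyz[, "x"] > 1 - 2 * medialFraction
    new("SphereMesh", coordinates = xyz * radius,
        hemisphere = rep("L", nVertices), cortex = !medial, radius = radius)
  })
}

# Dirichlet sample via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Synthetic coordinate database, corpus and topic ground truth
#'
#' Plants \code{nTopics} topics with disjoint-leaning signature-word blocks
#' (Dirichlet word distributions concentrated on each topic's block) and
#' spatial focus centers on a spherical mesh. Each study draws a sparse topic
#' mixture, multinomial word counts, and peak coordinates for topics sampled
#' from its mixture. Study features are the TFIDF of the word counts.
#'
#' Two spatial regimes are available. With \code{sampling = "cap"} (the
#' default when no axis is given) peaks scatter isotropically around each
#' topic's focus center -- a focal activation. With \code{sampling = "axis"}
#' (default when \code{axis} is supplied) each topic occupies a band of the
#' functional axis and peaks are drawn from cortex vertices whose axis value
#' falls in that band -- a distributed network following the axis, the way
#' large-scale cognitive systems follow connectivity gradients. Topic centers
#' are then ordered along the axis, so the first and last topics anchor its
#' two ends.
#'
#' @param nStudies number of studies.
#' @param nTopics number of planted topics.
#' @param vocabSize vocabulary size (>= 5 * nTopics).
#' @param coordsPerStudy peak coordinates per study.
#' @param seed RNG seed.
#' @param mesh optional \linkS4class{SphereMesh} carrying the spatial domain;
#'   a default one is generated.
#' @param axis optional per-vertex axis values used to order topic centers.
#' @param tokensPerDoc expected document length in tokens.
#' @param mixtureConcentration Dirichlet concentration of study topic
#'   mixtures; values < 1 give sparse, dominant-topic mixtures.
#' @param signatureMass probability mass a topic puts on its own signature
#'   block.
#' @param coordNoise angular jitter (radians) of peaks around their topic
#'   center (cap sampling), or the jitter added to a sampled band vertex
#'   (axis sampling).
#' @param sampling \code{"cap"} or \code{"axis"} (see Details); defaults to
#'   axis-band sampling whenever an axis is supplied.
#' @param axisBandwidth width (in normalized axis units) of a topic's band
#'   under axis sampling.
#' @return List with \code{db} (\linkS4class{StudyDatabase}), \code{corpus}
#'   (\linkS4class{Corpus}), \code{mesh}, and \code{truth} (topic centers,
#'   center vertices, word distributions, document mixtures, signature
#'   blocks, end topics).
#' @export
synthDatabase <- function(nStudies = 500, nTopics = 20, vocabSize = 400,
                          coordsPerStudy = 8, seed = NULL, mesh = NULL,
                          axis = NULL, tokensPerDoc = 150,
                          mixtureConcentration = 0.1, signatureMass = 0.8,
                          coordNoise = 0.12,
                          sampling = if (is.null(axis)) "cap" else "axis",
                          axisBandwidth = 0.06) {
  sampling <- match.arg(sampling, c("cap", "axis"))
  if (sampling == "axis" && is.null(axis))
    stopUser("axis sampling requires per-vertex axis values")
  if (vocabSize < 5 * nTopics)
    stopUser("vocabSize must be at least 5 * nTopics")
  withSeed(seed, {
    if (is.null(mesh)) mesh <- synthSphere(2000, seed = deriveSeed(
      if (is.null(seed)) 0 else seed, "sphere"))
    XYZ <- meshCoordinates(mesh)
    cortex <- which(cortexMask(mesh))
    vocab <- sprintf("w%03d", seq_len(vocabSize))
    # topic centers: vertices spread evenly along the axis (or at random)
    centerIdx <- if (!is.null(axis)) {
      stopifnot(length(axis) == nrow(XYZ))
      targets <- (seq_len(nTopics) - 0.5) / nTopics
      rng <- range(axis[cortex])
      vapply(targets, function(u) {
        cortex[which.min(abs(axis[cortex] - (rng[1] + u * diff(rng))))]
      }, integer(1))
    } else {
      sample(cortex, nTopics)
    }
    centers <- XYZ[centerIdx, , drop = FALSE]
    # topic word distributions concentrated on disjoint signature blocks
    blockSize <- vocabSize %/% nTopics
    signature <- lapply(seq_len(nTopics), function(j)
      vocab[((j - 1) * blockSize + 1):(j * blockSize)])
    wordTopicTrue <- t(vapply(seq_len(nTopics), function(j) {
      a <- rep(0.05, vocabSize)
      a[((j - 1) * blockSize + 1):(j * blockSize)] <-
        signatureMass * vocabSize / blockSize * 0.05 / (1 - signatureMass)
      rdirichlet1(a)
    }, numeric(vocabSize)))
    colnames(wordTopicTrue) <- vocab
    studyId <- sprintf("study%04d", seq_len(nStudies))
    docTopicTrue <- t(vapply(seq_len(nStudies), function(d)
      rdirichlet1(rep(mixtureConcentration, nTopics)), numeric(nTopics)))
    rownames(docTopicTrue) <- studyId
    counts <- matrix(0L, nStudies, vocabSize,
                     dimnames = list(studyId, vocab))
    coordRows <- vector("list", nStudies)
    radius <- sqrt(sum(XYZ[1, ]^2))
    bandWeights <- NULL
    if (sampling == "axis") {
      axNorm <- (axis[cortex] - min(axis[cortex])) / diff(range(axis[cortex]))
      bandWeights <- vapply(seq_len(nTopics), function(j)
        exp(-(axNorm - (j - 0.5) / nTopics)^2 / (2 * axisBandwidth^2)),
        numeric(length(cortex)))
    }
    for (d in seq_len(nStudies)) {
      nTok <- stats::rpois(1, tokensPerDoc) + 10L
      pWord <- as.numeric(docTopicTrue[d, ] %*% wordTopicTrue)
      counts[d, ] <- as.integer(stats::rmultinom(1, nTok, pWord))
      topics <- sample.int(nTopics, coordsPerStudy, replace = TRUE,
                           prob = docTopicTrue[d, ])
      pts <- if (sampling == "axis") {
        # draw foci from the cortex vertices in each topic's axis band
        vsel <- vapply(seq_len(coordsPerStudy), function(i) {
          cortex[sample.int(length(cortex), 1,
                            prob = bandWeights[, topics[i]])]
        }, integer(1))
        XYZ[vsel, , drop = FALSE] +
          matrix(stats::rnorm(3 * coordsPerStudy, sd = 0.03 * radius),
                 coordsPerStudy, 3)
      } else {
        centers[topics, , drop = FALSE] +
          matrix(stats::rnorm(3 * coordsPerStudy, sd = coordNoise * radius),
                 coordsPerStudy, 3)
      }
      pts <- pts / sqrt(rowSums(pts^2)) * radius
      coordRows[[d]] <- data.frame(study = studyId[d], x = pts[, 1],
                                   y = pts[, 2], z = pts[, 3])
    }
    coords <- do.call(rbind, coordRows)
    # TFIDF features: relative term frequency times smooth idf
    tf <- counts / pmax(rowSums(counts), 1)
    features <- tf * matrix(corpusIdf(counts), nStudies, vocabSize,
                            byrow = TRUE)
    db <- new("StudyDatabase", studyIds = studyId, coordinates = coords,
              features = features)
    corpus <- new("Corpus", counts = counts)
    truth <- list(topicCenters = centers, centerVertices = centerIdx,
                  wordTopic = wordTopicTrue, docTopic = docTopicTrue,
                  signatureWords = signature,
                  endTopics = c(low = 1L, high = nTopics))
    list(db = db, corpus = corpus, mesh = mesh, truth = truth)
  })
}

#' Smooth random surface map
#'
#' Sum of a few Gaussian bumps at random surface locations, standardized;
#' useful as a spatially autocorrelated null target for decoder calibration.
#'
#' @param mesh a \linkS4class{SphereMesh}.
#' @param nCenters number of bumps.
#' @param lengthscale bump width in mm.
#' @param seed RNG seed.
#' @return Numeric vector over all mesh vertices.
#' @export
synthSmoothMap <- function(mesh, nCenters = 10, lengthscale = 25,
                           seed = NULL) {
  XYZ <- meshCoordinates(mesh)
  withSeed(seed, {
    idx <- sample.int(nrow(XYZ), nCenters, replace = TRUE)
    w <- stats::rnorm(nCenters)
    v <- numeric(nrow(XYZ))
    for (i in seq_len(nCenters)) {
      d2 <- rowSums((XYZ - matrix(XYZ[idx[i], ], nrow(XYZ), 3,
                                  byrow = TRUE))^2)
      v <- v + w[i] * exp(-d2 / (2 * lengthscale^2))
    }
    as.numeric(scale(v))
  })
}

#' Synthetic expert annotations
#'
#' Each word receives a true category (Functional with the stated fraction,
#' the rest split evenly over Anatomical, Clinical, Non-specific); each rater
#' votes the true category with probability \code{agreement} and otherwise a
#' uniformly random other category.
#'
#' @param vocabulary character vector of words to annotate.
#' @param functionalFraction fraction of truly Functional words.
#' @param nRaters number of raters.
#' @param agreement probability a rater votes the true category, in
#'   [0.25, 1].
#' @param seed RNG seed.
#' @return List with \code{votes} (data.frame word, rater, category) and
#'   \code{truth} (named character vector of true categories).
#' @export
synthAnnotations <- function(vocabulary, functionalFraction = 0.5,
                             nRaters = 10, agreement = 0.9, seed = NULL) {
  if (functionalFraction < 0 || functionalFraction > 1)
    stopUser("functionalFraction must lie in [0, 1]")
  if (agreement < 0.25 || agreement > 1)
    stopUser("agreement must lie in [0.25, 1]")
  withSeed(seed, {
    V <- length(vocabulary)
    others <- setdiff(semanticCategories, "Functional")
    truth <- ifelse(stats::runif(V) < functionalFraction, "Functional",
                    sample(others, V, replace = TRUE))
    names(truth) <- vocabulary
    votes <- do.call(rbind, lapply(seq_len(V), function(i) {
      vote <- vapply(seq_len(nRaters), function(r) {
        if (stats::runif(1) < agreement) truth[i]
        else sample(setdiff(semanticCategories, truth[i]), 1)
      }, character(1))
      data.frame(word = vocabulary[i], rater = seq_len(nRaters),
                 category = vote, stringsAsFactors = FALSE)
    }))
    list(votes = votes, truth = truth)
  })
}

#' Coupled synthetic world for end-to-end runs
#'
#' Builds a spherical mesh, takes the z coordinate of the cortex as the
#' latent connectivity axis, generates the matching connectome, a coordinate
#' database whose topic centers are ordered along that axis, and expert
#' annotations -- everything an end-to-end segmentation/decoding run needs,
#' with ground truth attached.
#'
#' @param nVertices mesh vertices.
#' @param nStudies,nTopics,vocabSize database dimensions.
#' @param seed root RNG seed, split deterministically per component.
#' @param ... further parameters passed to \code{\link{synthDatabase}}.
#' @return List with \code{mesh}, \code{connectome}, \code{db},
#'   \code{corpus}, \code{annotations}, \code{truth}.
#' @export
synthWorld <- function(nVertices = 2000, nStudies = 500, nTopics = 20,
                       vocabSize = 400, seed = 1, ...) {
  mesh <- synthSphere(nVertices, seed = deriveSeed(seed, "sphere"))
  cortex <- which(cortexMask(mesh))
  z <- meshCoordinates(mesh)[, 3]
  axisFull <- (z - min(z)) / diff(range(z))
  conn <- synthConnectome(length(cortex), seed = deriveSeed(seed, "connectome"),
                          latent = axisFull[cortex])
  dbout <- synthDatabase(nStudies = nStudies, nTopics = nTopics,
                         vocabSize = vocabSize,
                         seed = deriveSeed(seed, "database"), mesh = mesh,
                         axis = axisFull, ...)
  ann <- synthAnnotations(colnames(studyFeatures(dbout$db)),
                          seed = deriveSeed(seed, "annotations"))
  truth <- c(dbout$truth, list(latentAxis = conn$truth$latentAxis,
                               axisFull = axisFull,
                               trueCategories = ann$truth))
  list(mesh = mesh, connectome = conn$connectome, db = dbout$db,
       corpus = dbout$corpus, annotations = ann$votes, truth = truth)
}
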