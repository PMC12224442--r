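## Accessors and show() methods. Slot access stays inside the package;
## users go through these.

#' @rdname accessors
#' @param object an object from this package.
#' @export
setGeneric("connectivityValues", function(object) standardGeneric("connectivityValues"))
#' @rdname accessors
#' @export
setMethod("connectivityValues", "DenseConnectome", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("vertexIds", function(object) standardGeneric("vertexIds"))
#' @rdname accessors
#' @export
setMethod("vertexIds", "DenseConnectome", function(object) object@vertexIds)

#' @rdname accessors
#' @export
setGeneric("valueKind", function(object) standardGeneric("valueKind"))
#' @rdname accessors
#' @export
setMethod("valueKind", "DenseConnectome", function(object) object@valueKind)

#' Accessors for gradient, segmentation and map objects
#'
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("gradientComponents", function(object) standardGeneric("gradientComponents"))
#' @rdname accessors
#' @export
setMethod("gradientComponents", "GradientSet", function(object) object@components)

#' @rdname accessors
#' @export
setGeneric("gradientEigenvalues", function(object) standardGeneric("gradientEigenvalues"))
#' @rdname accessors
#' @export
setMethod("gradientEigenvalues", "GradientSet", function(object) object@eigenvalues)

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setMethod("explainedVariance", "GradientSet", function(object) object@explainedVariance)

#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))
#' @rdname accessors
#' @export
setMethod("segmentLabels", "Segmentation", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("segmentBoundaries", function(object) standardGeneric("segmentBoundaries"))
#' @rdname accessors
#' @export
setMethod("segmentBoundaries", "Segmentation", function(object) object@boundaries)

#' @rdname accessors
#' @export
setGeneric("segmentAnchors", function(object) standardGeneric("segmentAnchors"))
#' @rdname accessors
#' @export
setMethod("segmentAnchors", "Segmentation", function(object) object@anchors)

#' @rdname accessors
#' @export
setGeneric("segmentMethod", function(object) standardGeneric("segmentMethod"))
#' @rdname accessors
#' @export
setMethod("segmentMethod", "Segmentation", function(object) object@method)

#' @rdname accessors
#' @export
setGeneric("segmentPoints", function(object) standardGeneric("segmentPoints"))
#' @rdname accessors
#' @export
setMethod("segmentPoints", "Segmentation", function(object) object@points)

#' @rdname accessors
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setMethod("nSegments", "Segmentation", function(object) object@k)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "PseudoActivationMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("mapValues", "MetaAnalyticMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("mapLabels", function(object) standardGeneric("mapLabels"))
#' @rdname accessors
#' @export
setMethod("mapLabels", "MetaAnalyticMap", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("mapSigma", function(object) standardGeneric("mapSigma"))
#' @rdname accessors
#' @export
setMethod("mapSigma", "PseudoActivationMap", function(object) object@sigma)

#' @rdname accessors
#' @export
setGeneric("mapPeak", function(object) standardGeneric("mapPeak"))
#' @rdname accessors
#' @export
setMethod("mapPeak", "PseudoActivationMap", function(object) object@peak)

#' @rdname accessors
#' @export
setGeneric("meshCoordinates", function(object) standardGeneric("meshCoordinates"))
#' @rdname accessors
#' @export
setMethod("meshCoordinates", "SphereMesh", function(object) object@coordinates)

#' @rdname accessors
#' @export
setGeneric("cortexMask", function(object) standardGeneric("cortexMask"))
#' @rdname accessors
#' @export
setMethod("cortexMask", "SphereMesh", function(object) object@cortex)

#' @rdname accessors
#' @export
setGeneric("hemisphere", function(object) standardGeneric("hemisphere"))
#' @rdname accessors
#' @export
setMethod("hemisphere", "SphereMesh", function(object) object@hemisphere)

#' @rdname accessors
#' @export
setGeneric("studyIds", function(object) standardGeneric("studyIds"))
#' @rdname accessors
#' @export
setMethod("studyIds", "StudyDatabase", function(object) object@studyIds)

#' @rdname accessors
#' @export
setGeneric("studyCoordinates", function(object) standardGeneric("studyCoordinates"))
#' @rdname accessors
#' @export
setMethod("studyCoordinates", "StudyDatabase", function(object) object@coordinates)

#' @rdname accessors
#' @export
setGeneric("studyFeatures", function(object) standardGeneric("studyFeatures"))
#' @rdname accessors
#' @export
setMethod("studyFeatures", "StudyDatabase", function(object) object@features)

#' @rdname accessors
#' @export
setGeneric("tokenCounts", function(object) standardGeneric("tokenCounts"))
#' @rdname accessors
#' @export
setMethod("tokenCounts", "Corpus", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("wordTopic", function(object) standardGeneric("wordTopic"))
#' @rdname accessors
#' @export
setMethod("wordTopic", "TopicModel", function(object) object@wordTopic)

#' @rdname accessors
#' @export
setGeneric("docTopic", function(object) standardGeneric("docTopic"))
#' @rdname accessors
#' @export
setMethod("docTopic", "TopicModel", function(object) object@docTopic)

setMethod("show", "DenseConnectome", function(object) {
  cat(sprintf("DenseConnectome: %d x %d vertices, %s-valued\n",
              nrow(object@values), ncol(object@values), object@valueKind))
})

setMethod("show", "GradientSet", function(object) {
  cat(sprintf("GradientSet: %d vertices, %d components\n",
              nrow(object@components), ncol(object@components)))
  cat("  explained variance:",
      paste(sprintf("%.3f", object@explainedVariance), collapse = " "), "\n")
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: method=%s k=%d over %d vertices (%d-D)\n",
              object@method, object@k, nrow(object@points), ncol(object@points)))
  if (length(object@boundaries))
    cat("  boundaries:", paste(sprintf("%.4g", object@boundaries), collapse = " "), "\n")
})

setMethod("show", "PseudoActivationMap", function(object) {
  cat(sprintf("PseudoActivationMap: segment %d, sigma=%.4g, %d vertices (%d in segment)\n",
              object@segmentId, object@sigma, length(object@values),
              sum(object@values > 0)))
})

setMethod("show", "MetaAnalyticMap", function(object) {
  cat(sprintf("MetaAnalyticMap [%s]: %d cells, %d/%d studies selected/unselected\n",
              paste(object@labels, collapse = ", "), length(object@values),
              object@nSelected, object@nUnselected))
})

setMethod("show", "SphereMesh", function(object) {
  cat(sprintf("SphereMesh: %d vertices (radius %.4g mm), %d cortex / %d medial wall\n",
              nrow(object@coordinates), object@radius, sum(object@cortex),
              sum(!object@cortex)))
})

setMethod("show", "StudyDatabase", function(object) {
  cat(sprintf("StudyDatabase: %d studies, %d peak coordinates, %d terms\n",
              length(object@studyIds), nrow(object@coordinates),
              ncol(object@features)))
})

setMethod("show", "Corpus", function(object) {
  cat(sprintf("Corpus: %d documents, vocabulary of %d words, %d tokens\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
})

setMethod("show", "TopicModel", function(object) {
  cat(sprintf("TopicModel: %d topics, %d words, %d documents\n",
              object@nTopics, ncol(object@wordTopic), nrow(object@docTopic)))
})
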