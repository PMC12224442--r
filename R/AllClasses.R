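#' @import methods
NULL

## Central S4 containers. All vertex-wise data are plain numeric matrices with
## vertices in rows; validity methods enforce the structural contracts that the
## numerical code relies on.

#' Dense vertex-by-vertex connectivity matrix
#'
#' Square symmetric matrix of functional connectivity values, either Fisher
#' z-scores (\code{valueKind = "z"}) or correlation coefficients
#' (\code{valueKind = "r"}, bounded in [-1, 1]).
#'
#' @slot values square symmetric numeric matrix.
#' @slot vertexIds character vector of vertex identifiers, one per row.
#' @slot valueKind either \code{"z"} or \code{"r"}.
#' @exportClass DenseConnectome
setClass("DenseConnectome",
  representation(values = "matrix", vertexIds = "character",
                 valueKind = "character"))

setValidity("DenseConnectome", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("connectivity matrix must be square")
  if (length(object@vertexIds) != nrow(v))
    return("vertexIds length must equal matrix dimension")
  if (!object@valueKind %in% c("z", "r"))
    return("valueKind must be 'z' or 'r'")
  if (max(abs(v - t(v))) > 1e-8) return("matrix is not symmetric (tol 1e-8)")
  if (object@valueKind == "r" && (min(v) < -1 - 1e-12 || max(v) > 1 + 1e-12))
    return("r-valued connectome must lie in [-1, 1]")
  TRUE
})

#' Construct a DenseConnectome
#'
#' @param values square symmetric numeric matrix.
#' @param vertexIds optional vertex identifiers (default \code{v1..vn}).
#' @param valueKind \code{"z"} for Fisher z-scores, \code{"r"} for correlations.
#' @return A \linkS4class{DenseConnectome}.
#' @export
DenseConnectome <- function(values, vertexIds = NULL, valueKind = c("z", "r")) {
  valueKind <- match.arg(valueKind)
  if (is.null(vertexIds)) vertexIds <- paste0("v", seq_len(nrow(values)))
  new("DenseConnectome", values = values, vertexIds = as.character(vertexIds),
      valueKind = valueKind)
}

#' Gradient embedding of a connectome
#'
#' Ordered set of gradient components (eigenvectors of the diffusion operator,
#' scaled), their eigenvalues and the explained-variance ratios.
#'
#' @slot components vertex-by-component numeric matrix.
#' @slot eigenvalues nonnegative eigenvalue per retained component.
#' @slot explainedVariance per-component variance ratio, sums to 1.
#' @exportClass GradientSet
setClass("GradientSet",
  representation(components = "matrix", eigenvalues = "numeric",
                 explainedVariance = "numeric"))

setValidity("GradientSet", function(object) {
  m <- ncol(object@components)
  if (length(object@eigenvalues) != m || length(object@explainedVariance) != m)
    return("eigenvalues/explainedVariance must match number of components")
  if (any(object@eigenvalues < -1e-12)) return("eigenvalues must be >= 0")
  if (m > 0 && abs(sum(object@explainedVariance) - 1) > 1e-8)
    return("explainedVariance must sum to 1")
  if (is.unsorted(rev(object@explainedVariance), strictly = FALSE))
    return("components must be ordered by descending explained variance")
  TRUE
})

#' Segmentation of the gradient axis or joint gradient space
#'
#' @slot method one of \code{"PCT"}, \code{"KMeans"}, \code{"KDE"}.
#' @slot k number of segments.
#' @slot labels integer vector in 1..k, one per vertex, ordered along the axis.
#' @slot boundaries k-1 interior cut values (1-D methods; empty for n-D).
#' @slot points the n-by-d matrix of gradient coordinates that was segmented.
#' @slot anchors k-by-d matrix of per-segment auxiliary points (median,
#'   centroid, or KDE local maximum depending on method).
#' @slot extras method-specific details (e.g. KDE bandwidth and curve).
#' @exportClass Segmentation
setClass("Segmentation",
  representation(method = "character", k = "integer", labels = "integer",
                 boundaries = "numeric", points = "matrix", anchors = "matrix",
                 extras = "list"))

setValidity("Segmentation", function(object) {
  k <- object@k
  if (!object@method %in% c("PCT", "KMeans", "KDE"))
    return("method must be PCT, KMeans or KDE")
  if (length(object@labels) != nrow(object@points))
    return("labels must match number of points")
  if (!all(sort(unique(object@labels)) == seq_len(k)))
    return("labels must partition vertices into segments 1..k")
  if (length(object@boundaries) > 0) {
    if (length(object@boundaries) != k - 1L)
      return("1-D segmentation must carry k-1 boundaries")
    if (is.unsorted(object@boundaries, strictly = TRUE))
      return("boundaries must be strictly increasing")
  }
  if (nrow(object@anchors) != k) return("one anchor per segment required")
  TRUE
})

#' Pseudo-activation map for one segment
#'
#' Per-vertex affinity to the segment's peak point under a Gaussian
#' radial-basis kernel; zero outside the segment, in [0, 1] inside.
#'
#' @slot segmentId segment index.
#' @slot values per-vertex affinity in [0, 1].
#' @slot sigma kernel width (gradient units).
#' @slot peak peak-point coordinates in gradient space.
#' @exportClass PseudoActivationMap
setClass("PseudoActivationMap",
  representation(segmentId = "integer", values = "numeric", sigma = "numeric",
                 peak = "numeric"))

setValidity("PseudoActivationMap", function(object) {
  if (min(object@values) < 0 || max(object@values) > 1 + 1e-12)
    return("pseudo-activation values must lie in [0, 1]")
  if (object@sigma <= 0) return("sigma must be positive")
  TRUE
})

#' Labeled meta-analytic map
#'
#' Signed association statistic per grid cell or vertex from a two-by-two
#' chi-square meta-analysis, with the study counts that produced it.
#'
#' @slot labels term or top topic words labelling the map.
#' @slot values signed z-like statistic per cell.
#' @slot chi2 raw chi-square statistic per cell.
#' @slot nSelected,nUnselected study counts in the two groups.
#' @exportClass MetaAnalyticMap
setClass("MetaAnalyticMap",
  representation(labels = "character", values = "numeric", chi2 = "numeric",
                 nSelected = "integer", nUnselected = "integer"))

setValidity("MetaAnalyticMap", function(object) {
  if (length(object@labels) == 0) return("labels must be nonempty")
  if (!all(is.finite(object@values))) return("map values must be finite")
  TRUE
})

#' Spherical surface mesh
#'
#' Unit-sphere vertex coordinates (optionally scaled to a physical radius),
#' hemisphere assignment and a cortex mask excluding the medial wall.
#'
#' @slot coordinates n-by-3 matrix of sphere coordinates.
#' @slot hemisphere character vector, \code{"L"} or \code{"R"} per vertex.
#' @slot cortex logical mask; \code{FALSE} marks the medial wall.
#' @slot radius sphere radius in the coordinate units (mm).
#' @exportClass SphereMesh
setClass("SphereMesh",
  representation(coordinates = "matrix", hemisphere = "character",
                 cortex = "logical", radius = "numeric"))

setValidity("SphereMesh", function(object) {
  n <- nrow(object@coordinates)
  if (ncol(object@coordinates) != 3) return("coordinates must be n-by-3")
  if (length(object@hemisphere) != n || length(object@cortex) != n)
    return("hemisphere and cortex must have one entry per vertex")
  nrm <- sqrt(rowSums(object@coordinates^2))
  if (max(abs(nrm - object@radius)) > 1e-6 * max(1, object@radius))
    return("coordinates must lie on the sphere (radius tol 1e-6)")
  if (!any(object@cortex)) return("cortex mask must be nonempty")
  TRUE
})

#' Coordinate-based study database
#'
#' Per-study activation peak coordinates plus a study-by-term feature matrix
#' of TFIDF weights sharing one vocabulary.
#'
#' @slot studyIds unique study identifiers.
#' @slot coordinates data.frame with columns study, x, y, z (mm).
#' @slot features studies-by-terms numeric matrix of TFIDF weights.
#' @exportClass StudyDatabase
setClass("StudyDatabase",
  representation(studyIds = "character", coordinates = "data.frame",
                 features = "matrix"))

setValidity("StudyDatabase", function(object) {
  if (anyDuplicated(object@studyIds)) return("study ids must be unique")
  if (!all(c("study", "x", "y", "z") %in% names(object@coordinates)))
    return("coordinates must have columns study, x, y, z")
  if (!all(object@coordinates$study %in% object@studyIds))
    return("coordinate rows must reference known studies")
  if (!all(is.finite(as.matrix(object@coordinates[, c("x", "y", "z")]))))
    return("coordinates must be finite")
  if (nrow(object@features) != length(object@studyIds))
    return("feature matrix must have one row per study")
  if (min(object@features) < 0) return("TFIDF features must be >= 0")
  TRUE
})

#' Document corpus of token counts
#'
#' @slot counts docs-by-vocabulary matrix of nonnegative integer token counts.
#' @exportClass Corpus
setClass("Corpus", representation(counts = "matrix"))

setValidity("Corpus", function(object) {
  if (is.null(colnames(object@counts))) return("corpus needs a named vocabulary")
  if (min(object@counts) < 0 || any(object@counts != round(object@counts)))
    return("token counts must be nonnegative integers")
  TRUE
})

#' Fitted topic model
#'
#' The two distributions of a latent Dirichlet topic decomposition:
#' p(word | topic) and p(topic | document).
#'
#' @slot wordTopic topics-by-words matrix; each row sums to 1.
#' @slot docTopic docs-by-topics matrix; each row sums to 1.
#' @slot nTopics number of topics.
#' @exportClass TopicModel
setClass("TopicModel",
  representation(wordTopic = "matrix", docTopic = "matrix",
                 nTopics = "integer"))

setValidity("TopicModel", function(object) {
  if (nrow(object@wordTopic) != object@nTopics ||
      ncol(object@docTopic) != object@nTopics)
    return("matrix dimensions must match nTopics")
  if (max(abs(rowSums(object@wordTopic) - 1)) > 1e-6)
    return("each topic's word distribution must sum to 1")
  if (max(abs(rowSums(object@docTopic) - 1)) > 1e-6)
    return("each document's topic distribution must sum to 1")
  TRUE
})
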