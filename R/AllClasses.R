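#' @import methods
NULL

# ---- error helpers -----------------------------------------------------

.satStop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "scAtlasTreeError")))
}

.emptyAliases <- function() {
  data.frame(dataset = character(), label = character(),
             stringsAsFactors = FALSE)
}

.emptyMissing <- .emptyAliases

.aliasKey <- function(dataset, label) paste(dataset, label, sep = "\r")

# ---- LabeledEmbedding --------------------------------------------------

#' Labeled latent embedding of one dataset
#'
#' Container for one dataset's cells in the shared integrated latent space:
#' a cells x d coordinate matrix, unique cell identifiers, and (optionally)
#' one cell-type label per cell. Unlabeled embeddings (empty \code{labels})
#' can only be used as queries for hierarchical label transfer.
#'
#' @slot datasetId single string identifying the dataset.
#' @slot coords numeric matrix, cells x d, finite latent coordinates.
#' @slot cellIds character vector of unique cell identifiers.
#' @slot labels character vector of per-cell labels (length 0 when the
#'   dataset is unlabeled).
#'
#' @export
setClass("LabeledEmbedding",
         representation(datasetId = "character",
                        coords    = "matrix",
                        cellIds   = "character",
                        labels    = "character"))

setValidity("LabeledEmbedding", function(object) {
  msgs <- character()
  if (length(object@datasetId) != 1L || !nzchar(object@datasetId))
    msgs <- c(msgs, "datasetId must be a single non-empty string")
  if (!is.numeric(object@coords))
    msgs <- c(msgs, "coords must be a numeric matrix")
  else if (any(!is.finite(object@coords)))
    msgs <- c(msgs, "coords contains missing or non-finite values")
  if (length(object@cellIds) != nrow(object@coords))
    msgs <- c(msgs, "cellIds length must equal nrow(coords)")
  if (anyDuplicated(object@cellIds))
    msgs <- c(msgs, "cellIds must be unique within a dataset")
  if (length(object@labels) &&
      length(object@labels) != nrow(object@coords))
    msgs <- c(msgs, "labels must be empty or one per cell")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabeledEmbedding
#'
#' @param coords cells x d numeric matrix of latent coordinates.
#' @param datasetId dataset identifier.
#' @param cellIds cell identifiers; defaults to the rownames of
#'   \code{coords} or \code{"<datasetId>_<i>"}.
#' @param labels optional character vector of per-cell labels; leading and
#'   trailing whitespace is stripped at ingest.
#'
#' @return A \linkS4class{LabeledEmbedding}.
#' @examples
#' emb <- LabeledEmbedding(matrix(rnorm(20), 5, 4), "study1",
#'                         labels = rep(c("T cells", "B cells"), c(3, 2)))
#' nCells(emb)
#' @export
LabeledEmbedding <- function(coords, datasetId, cellIds = NULL,
                             labels = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(cellIds)) {
    cellIds <- rownames(coords)
    if (is.null(cellIds))
      cellIds <- paste0(datasetId, "_", seq_len(nrow(coords)))
  }
  rownames(coords) <- NULL
  if (is.null(labels)) labels <- character()
  else labels <- trimws(as.character(labels))
  new("LabeledEmbedding", datasetId = as.character(datasetId),
      coords = coords, cellIds = as.character(cellIds), labels = labels)
}

# ---- CellHierarchy -----------------------------------------------------

#' Cell-type hierarchy learned across datasets
#'
#' The evolving cell-type tree. Every non-root node houses a non-empty set
#' of \code{(dataset, label)} aliases; within one tree each alias pair
#' appears in exactly one node. Labels whose cross-prediction pattern
#' admitted no consistent placement are recorded in \code{missing}. The
#' tree also carries the training embeddings of the datasets incorporated
#' so far and one fitted \linkS4class{NodeClassifier} per internal node
#' with two or more children, making it a hierarchical classifier.
#'
#' Nodes are stored as a named list of records with fields \code{name},
#' \code{parent}, \code{children} (ordered) and \code{aliases}; use the
#' accessors (\code{\link{nodeNames}}, \code{\link{aliasTable}},
#' \code{\link{childrenOf}}, \code{\link{parentOf}}) rather than the slot.
#'
#' @slot rootName display name of the root node.
#' @slot nodes named list of node records.
#' @slot datasetIds datasets incorporated so far, in order.
#' @slot missing data.frame (dataset, label) of unplaceable labels.
#' @slot embeddings named list of \linkS4class{LabeledEmbedding}, one per
#'   incorporated dataset.
#' @slot classifiers named list of fitted \linkS4class{NodeClassifier},
#'   keyed by internal node name.
#' @slot control list of fitting parameters (see
#'   \code{\link{hierarchyControl}}).
#' @slot updateLog list of per-update report data.frames.
#'
#' @export
setClass("CellHierarchy",
         representation(rootName    = "character",
                        nodes       = "list",
                        datasetIds  = "character",
                        missing     = "data.frame",
                        embeddings  = "list",
                        classifiers = "list",
                        control     = "list",
                        updateLog   = "list"))

setValidity("CellHierarchy", function(object) {
  msgs <- character()
  nodes <- object@nodes
  if (!length(nodes) || is.null(nodes[[object@rootName]]))
    return("root node missing from node list")
  seen <- character()
  for (nd in nodes) {
    if (!identical(nd$name, object@rootName) && !nrow(nd$aliases))
      msgs <- c(msgs, sprintf("node '%s' has no aliases", nd$name))
    if (nrow(nd$aliases))
      seen <- c(seen, .aliasKey(nd$aliases$dataset, nd$aliases$label))
    bad <- setdiff(nd$children, names(nodes))
    if (length(bad))
      msgs <- c(msgs, sprintf("node '%s' has unknown children", nd$name))
  }
  if (anyDuplicated(seen))
    msgs <- c(msgs, "a (dataset, label) alias is housed in multiple nodes")
  if (nrow(object@missing)) {
    mk <- .aliasKey(object@missing$dataset, object@missing$label)
    if (length(intersect(mk, seen)))
      msgs <- c(msgs, "missing list overlaps housed aliases")
  }
  # single-parent / acyclicity: every non-root node is the child of
  # exactly one node
  childCount <- table(unlist(lapply(nodes, `[[`, "children")))
  nonRoot <- setdiff(names(nodes), object@rootName)
  if (!all(nonRoot %in% names(childCount)) ||
      any(childCount[nonRoot] != 1L))
    msgs <- c(msgs, "every non-root node must have exactly one parent")
  if (length(msgs)) msgs else TRUE
})

# ---- NodeClassifier ----------------------------------------------------

#' Per-node multiclass kNN classifier with rejection thresholds
#'
#' A k-nearest-neighbour classifier over latent coordinates trained for one
#' parent node of the hierarchy, discriminating its direct children. It
#' carries the three fitted rejection thresholds: \code{tauPosterior}
#' (ambiguity), \code{tauDistance} (99th percentile of mean training
#' neighbour distances) and \code{tauReconstruction} (cross-validated
#' PCA reconstruction-error threshold) together with the PCA basis.
#'
#' @slot parentNode name of the parent node this classifier belongs to.
#' @slot classNames child class names, sorted.
#' @slot kEffective number of neighbours actually used.
#' @slot trainX training coordinates (n x d).
#' @slot trainY integer class index per training cell.
#' @slot tauPosterior posterior-probability threshold in [0, 1].
#' @slot tauDistance fitted mean-neighbour-distance threshold (>= 0).
#' @slot tauReconstruction fitted squared reconstruction-error threshold.
#' @slot pcaRotation PCA component matrix (d x rank).
#' @slot pcaCenter PCA mean (length d).
#' @slot pcaRank number of PCA components retained.
#' @slot metric distance metric name ("euclidean").
#'
#' @export
setClass("NodeClassifier",
         representation(parentNode        = "character",
                        classNames        = "character",
                        kEffective        = "integer",
                        trainX            = "matrix",
                        trainY            = "integer",
                        tauPosterior      = "numeric",
                        tauDistance       = "numeric",
                        tauReconstruction = "numeric",
                        pcaRotation       = "matrix",
                        pcaCenter         = "numeric",
                        pcaRank           = "integer",
                        metric            = "character"))

setValidity("NodeClassifier", function(object) {
  msgs <- character()
  if (object@kEffective < 1L)
    msgs <- c(msgs, "kEffective must be >= 1")
  if (object@tauPosterior < 0 || object@tauPosterior > 1)
    msgs <- c(msgs, "tauPosterior must lie in [0, 1]")
  if (object@tauDistance < 0 || object@tauReconstruction < 0)
    msgs <- c(msgs, "distance/reconstruction thresholds must be >= 0")
  if (length(object@trainY) != nrow(object@trainX))
    msgs <- c(msgs, "trainY length must equal nrow(trainX)")
  if (length(object@trainY) &&
      (min(object@trainY) < 1L ||
       max(object@trainY) > length(object@classNames)))
    msgs <- c(msgs, "trainY indexes outside classNames")
  if (length(msgs)) msgs else TRUE
})

# ---- EdgeGraph ---------------------------------------------------------

#' Ancestor-descendant edge graph of a hierarchy
#'
#' The transitively closed set of directed (ancestor, descendant) pairs
#' obtained from a tree by adding an edge from every node to each of its
#' descendants. Used for quantitative comparison of learned and
#' ground-truth hierarchies.
#'
#' @slot edges data.frame with character columns \code{ancestor} and
#'   \code{descendant}; no self-edges.
#' @slot nodeNames all node names in the graph's universe.
#'
#' @export
setClass("EdgeGraph",
         representation(edges = "data.frame", nodeNames = "character"))

setValidity("EdgeGraph", function(object) {
  msgs <- character()
  if (!all(c("ancestor", "descendant") %in% colnames(object@edges)))
    return("edges must have columns ancestor, descendant")
  if (nrow(object@edges) &&
      any(object@edges$ancestor == object@edges$descendant))
    msgs <- c(msgs, "self-edges are not allowed")
  if (anyDuplicated(paste(object@edges$ancestor, object@edges$descendant,
                          sep = "\r")))
    msgs <- c(msgs, "duplicate edges")
  if (length(msgs)) msgs else TRUE
})

.EdgeGraph <- function(ancestor, descendant, nodeNames) {
  ed <- data.frame(ancestor = as.character(ancestor),
                   descendant = as.character(descendant),
                   stringsAsFactors = FALSE)
  ed <- unique(ed)
  ed <- ed[order(ed$ancestor, ed$descendant), , drop = FALSE]
  rownames(ed) <- NULL
  new("EdgeGraph", edges = ed, nodeNames = sort(unique(nodeNames)))
}

# ---- PredictionResult --------------------------------------------------

#' Hierarchical prediction result
#'
#' Per-cell outcome of top-down label transfer through the hierarchy: the
#' root-to-node path of accepted classifications, the final label (the
#' deepest accepted node, or \code{"REJECTED"}), the rejection flag and
#' reason, and the per-level posterior vectors retained for audit.
#'
#' @slot cellIds query cell identifiers.
#' @slot finalLabel final label per cell (node name or "REJECTED").
#' @slot rejected logical flag per cell.
#' @slot reason rejection reason per cell: "posterior", "reconstruction",
#'   "distance" or "".
#' @slot paths list of root-to-node name chains (accepted nodes only).
#' @slot posteriors list (one per cell) of per-level named posterior
#'   vectors.
#'
#' @export
setClass("PredictionResult",
         representation(cellIds    = "character",
                        finalLabel = "character",
                        rejected   = "logical",
                        reason     = "character",
                        paths      = "list",
                        posteriors = "list"))

setValidity("PredictionResult", function(object) {
  n <- length(object@cellIds)
  if (length(object@finalLabel) != n || length(object@rejected) != n ||
      length(object@reason) != n || length(object@paths) != n)
    return("all per-cell slots must have equal length")
  if (any(object@rejected & !nzchar(object@reason)))
    return("rejected cells must carry a rejection reason")
  TRUE
})

# ---- GraphComparison ---------------------------------------------------

#' Edge-level comparison of two hierarchies
#'
#' Set differences between a learned and a ground-truth
#' \linkS4class{EdgeGraph}: edges present in both (correct), edges only in
#' the learned graph (wrong) and edges only in the truth (missing), with
#' per-edge listings.
#'
#' @slot correct data.frame of shared edges.
#' @slot wrong data.frame of learned-only edges (with a \code{reason}).
#' @slot missing data.frame of truth-only edges.
#'
#' @export
setClass("GraphComparison",
         representation(correct = "data.frame",
                        wrong   = "data.frame",
                        missing = "data.frame"))
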