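# ---- LabeledEmbedding accessors ---------------------------------------

#' @rdname LabeledEmbedding-class
#' @export
setMethod("datasetId", "LabeledEmbedding", function(object) object@datasetId)

#' @rdname LabeledEmbedding-class
#' @export
setMethod("cellIds", "LabeledEmbedding", function(object) object@cellIds)

#' @rdname LabeledEmbedding-class
#' @export
setMethod("cellLabels", "LabeledEmbedding", function(object) object@labels)

#' @rdname LabeledEmbedding-class
#' @export
setMethod("latentCoords", "LabeledEmbedding",
          function(object) object@coords)

#' @rdname LabeledEmbedding-class
#' @export
setMethod("nCells", "LabeledEmbedding",
          function(object) nrow(object@coords))

#' @rdname LabeledEmbedding-class
#' @export
setMethod("latentDim", "LabeledEmbedding",
          function(object) ncol(object@coords))

#' @describeIn LabeledEmbedding-class whether the dataset carries labels.
#' @export
isLabeled <- function(object) length(object@labels) > 0L

setMethod("show", "LabeledEmbedding", function(object) {
  cat(sprintf("LabeledEmbedding '%s': %d cells x %d latent dims; %s\n",
              object@datasetId, nrow(object@coords), ncol(object@coords),
              if (isLabeled(object))
                sprintf("%d labels", length(unique(object@labels)))
              else "unlabeled"))
})

# ---- CellHierarchy accessors ------------------------------------------

#' @rdname CellHierarchy-class
#' @export
setMethod("nodeNames", "CellHierarchy",
          function(object) names(object@nodes))

#' @rdname CellHierarchy-class
#' @export
setMethod("rootName", "CellHierarchy", function(object) object@rootName)

#' @rdname CellHierarchy-class
#' @export
setMethod("aliasTable", "CellHierarchy", function(object) {
  rows <- lapply(object@nodes, function(nd) {
    if (!nrow(nd$aliases)) return(NULL)
    cbind(nd$aliases, node = nd$name, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(dataset = character(), label = character(),
                      node = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
})

#' @rdname CellHierarchy-class
#' @export
setMethod("missingLabels", "CellHierarchy",
          function(object) object@missing)

#' @rdname CellHierarchy-class
#' @export
setMethod("datasetIds", "CellHierarchy",
          function(object) object@datasetIds)

#' @rdname CellHierarchy-class
#' @export
setMethod("updateLog", "CellHierarchy", function(object) object@updateLog)

#' @rdname CellHierarchy-class
#' @export
setMethod("nodeClassifiers", "CellHierarchy",
          function(object) object@classifiers)

#' Children / parent of a node
#'
#' @param tree a \linkS4class{CellHierarchy}.
#' @param name node display name.
#' @return \code{childrenOf}: character vector of child names (ordered);
#'   \code{parentOf}: the parent's name, or \code{NA} for the root.
#' @export
childrenOf <- function(tree, name) {
  nd <- tree@nodes[[name]]
  if (is.null(nd)) .satStop("notFoundError", sprintf("unknown node '%s'", name))
  nd$children
}

#' @rdname childrenOf
#' @export
parentOf <- function(tree, name) {
  nd <- tree@nodes[[name]]
  if (is.null(nd)) .satStop("notFoundError", sprintf("unknown node '%s'", name))
  nd$parent
}

setMethod("show", "CellHierarchy", function(object) {
  cat(sprintf("CellHierarchy: %d nodes, %d dataset(s) [%s]\n",
              length(object@nodes), length(object@datasetIds),
              paste(object@datasetIds, collapse = ", ")))
  if (nrow(object@missing))
    cat(sprintf("  %d unplaceable label(s)\n", nrow(object@missing)))
  cat(formatHierarchy(object), sep = "\n")
})

#' Text rendering of a hierarchy
#'
#' @param tree a \linkS4class{CellHierarchy}.
#' @return character vector, one line per node, indented by depth; each
#'   node shows its display name and aliases.
#' @export
formatHierarchy <- function(tree) {
  out <- character()
  rec <- function(name, depth) {
    nd <- tree@nodes[[name]]
    al <- if (nrow(nd$aliases))
      paste0("  {", paste(sprintf("%s:%s", nd$aliases$dataset,
                                  nd$aliases$label), collapse = ", "), "}")
    else ""
    out <<- c(out, paste0(strrep("  ", depth), "- ", nd$name, al))
    for (ch in nd$children) rec(ch, depth + 1L)
  }
  rec(tree@rootName, 0L)
  out
}

# ---- NodeClassifier / EdgeGraph / PredictionResult --------------------

setMethod("show", "NodeClassifier", function(object) {
  cat(sprintf(paste0("NodeClassifier for '%s': %d classes, k = %d, ",
                     "n = %d\n  tauPosterior = %g, tauDistance = %g, ",
                     "tauReconstruction = %g (PCA rank %d)\n"),
              object@parentNode, length(object@classNames),
              object@kEffective, nrow(object@trainX),
              object@tauPosterior, object@tauDistance,
              object@tauReconstruction, object@pcaRank))
})

#' @rdname EdgeGraph-class
#' @export
setMethod("edges", "EdgeGraph", function(object) object@edges)

setMethod("show", "EdgeGraph", function(object) {
  cat(sprintf("EdgeGraph: %d ancestor-descendant edges over %d nodes\n",
              nrow(object@edges), length(object@nodeNames)))
})

#' @rdname PredictionResult-class
#' @export
setMethod("finalLabels", "PredictionResult",
          function(object) object@finalLabel)

#' @rdname PredictionResult-class
#' @export
setMethod("rejectedCells", "PredictionResult",
          function(object) object@rejected)

#' @rdname PredictionResult-class
#' @export
setMethod("rejectionReasons", "PredictionResult",
          function(object) object@reason)

#' @rdname PredictionResult-class
#' @export
setMethod("predictionPaths", "PredictionResult",
          function(object) object@paths)

setMethod("show", "PredictionResult", function(object) {
  n <- length(object@cellIds)
  cat(sprintf("PredictionResult: %d cells, %d rejected (%.1f%%)\n",
              n, sum(object@rejected),
              if (n) 100 * mean(object@rejected) else 0))
})

#' @rdname GraphComparison-class
#' @export
setMethod("correctEdges", "GraphComparison",
          function(object) nrow(object@correct))

#' @rdname GraphComparison-class
#' @export
setMethod("wrongEdges", "GraphComparison",
          function(object) nrow(object@wrong))

#' @rdname GraphComparison-class
#' @export
setMethod("missingEdges", "GraphComparison",
          function(object) nrow(object@missing))

setMethod("show", "GraphComparison", function(object) {
  cat(sprintf("GraphComparison: %d correct, %d wrong, %d missing edges\n",
              nrow(object@correct), nrow(object@wrong),
              nrow(object@missing)))
})
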