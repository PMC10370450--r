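# Accessor generics. Bioconductor-style: users never touch slots.

#' @rdname LabeledEmbedding-class
#' @param object,x an object.
#' @export
setGeneric("datasetId", function(object) standardGeneric("datasetId"))

#' @rdname LabeledEmbedding-class
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname LabeledEmbedding-class
#' @export
setGeneric("cellLabels", function(object) standardGeneric("cellLabels"))

#' @rdname LabeledEmbedding-class
#' @export
setGeneric("latentCoords", function(object) standardGeneric("latentCoords"))

#' @rdname LabeledEmbedding-class
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname LabeledEmbedding-class
#' @export
setGeneric("latentDim", function(object) standardGeneric("latentDim"))

#' @rdname CellHierarchy-class
#' @param object a \code{CellHierarchy}.
#' @export
setGeneric("nodeNames", function(object) standardGeneric("nodeNames"))

#' @rdname CellHierarchy-class
#' @export
setGeneric("rootName", function(object) standardGeneric("rootName"))

#' @rdname CellHierarchy-class
#' @export
setGeneric("aliasTable", function(object) standardGeneric("aliasTable"))

#' @rdname CellHierarchy-class
#' @export
setGeneric("missingLabels", function(object) standardGeneric("missingLabels"))

#' @rdname CellHierarchy-class
#' @export
setGeneric("datasetIds", function(object) standardGeneric("datasetIds"))

#' @rdname CellHierarchy-class
#' @export
setGeneric("updateLog", function(object) standardGeneric("updateLog"))

#' @rdname CellHierarchy-class
#' @export
setGeneric("nodeClassifiers",
           function(object) standardGeneric("nodeClassifiers"))

#' @rdname EdgeGraph-class
#' @param object an \code{EdgeGraph} or \code{GraphComparison}.
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @rdname GraphComparison-class
#' @param object a \code{GraphComparison}.
#' @export
setGeneric("correctEdges", function(object) standardGeneric("correctEdges"))

#' @rdname GraphComparison-class
#' @export
setGeneric("wrongEdges", function(object) standardGeneric("wrongEdges"))

#' @rdname GraphComparison-class
#' @export
setGeneric("missingEdges", function(object) standardGeneric("missingEdges"))

#' @rdname PredictionResult-class
#' @param object a \code{PredictionResult}.
#' @export
setGeneric("finalLabels", function(object) standardGeneric("finalLabels"))

#' @rdname PredictionResult-class
#' @export
setGeneric("rejectedCells", function(object) standardGeneric("rejectedCells"))

#' @rdname PredictionResult-class
#' @export
setGeneric("rejectionReasons",
           function(object) standardGeneric("rejectionReasons"))

#' @rdname PredictionResult-class
#' @export
setGeneric("predictionPaths",
           function(object) standardGeneric("predictionPaths"))
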