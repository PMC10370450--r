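# Hierarchy serialization. JSON is the lossless round-trip format
# ({"name", "aliases": [["dataset","label"], ...], "children": [...]},
# with dataset_ids and missing carried on the top-level object); Newick is
# a lossy export (node names only) for use with standard tree viewers.

.nodeToList <- function(tree, name) {
  nd <- tree@nodes[[name]]
  al <- lapply(seq_len(nrow(nd$aliases)), function(i)
    c(nd$aliases$dataset[i], nd$aliases$label[i]))
  list(name = nd$name, aliases = al,
       children = lapply(nd$children, function(ch) .nodeToList(tree, ch)))
}

#' Serialize a hierarchy
#'
#' @param tree a \linkS4class{CellHierarchy}.
#' @param path output file path.
#' @param format \code{"json"} (lossless structure round-trip) or
#'   \code{"newick"} (export-only; aliases flattened into node names).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readHierarchy}}
#' @export
writeHierarchy <- function(tree, path, format = c("json", "newick")) {
  stopifnot(is(tree, "CellHierarchy"))
  format <- match.arg(format)
  if (format == "json") {
    obj <- .nodeToList(tree, tree@rootName)
    obj$dataset_ids <- as.list(tree@datasetIds)
    obj$missing <- lapply(seq_len(nrow(tree@missing)), function(i)
      c(tree@missing$dataset[i], tree@missing$label[i]))
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "list")
    writeLines(json, path, useBytes = TRUE)
  } else {
    writeLines(paste0(.newickString(tree, tree@rootName), ";"), path)
  }
  invisible(path)
}

.newickQuote <- function(x) {
  if (grepl("[][ ():;,']", x))
    paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  else x
}

.newickString <- function(tree, name) {
  nd <- tree@nodes[[name]]
  nm <- .newickQuote(nd$name)
  if (!length(nd$children)) return(nm)
  inner <- vapply(nd$children, function(ch) .newickString(tree, ch), "")
  paste0("(", paste(inner, collapse = ","), ")", nm)
}

#' Deserialize a hierarchy from JSON
#'
#' Reconstructs the tree written by \code{\link{writeHierarchy}}.
#' Embeddings and classifiers are not serialized; use
#' \code{\link{restoreHierarchy}} to re-attach training data and refit.
#'
#' @param path JSON file.
#' @return A \linkS4class{CellHierarchy} (structure only).
#' @export
readHierarchy <- function(path) {
  if (!file.exists(path))
    .satStop("notFoundError", sprintf("no such file: %s", path))
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e)
      .satStop("parseError",
               sprintf("malformed hierarchy JSON in '%s': %s", path,
                       conditionMessage(e))))
  if (is.null(obj$name))
    .satStop("parseError", "hierarchy JSON lacks a root 'name' field")
  tree <- createHierarchy(obj$name)
  addRec <- function(nodeObj, parentName) {
    for (ch in nodeObj$children) {
      al <- do.call(rbind, lapply(ch$aliases, function(a)
        data.frame(dataset = a[[1L]], label = a[[2L]],
                   stringsAsFactors = FALSE)))
      if (is.null(al))
        .satStop("parseError",
                 sprintf("non-root node '%s' has no aliases", ch$name))
      tree <<- addNode(tree, parentName, al, name = ch$name)
      addRec(ch, ch$name)
    }
  }
  addRec(obj, obj$name)
  tree@datasetIds <- as.character(unlist(obj$dataset_ids))
  if (length(obj$missing)) {
    tree@missing <- do.call(rbind, lapply(obj$missing, function(m)
      data.frame(dataset = m[[1L]], label = m[[2L]],
                 stringsAsFactors = FALSE)))
  }
  validObject(tree)
  tree
}

#' Re-attach training data to a deserialized hierarchy
#'
#' A hierarchy read back from JSON carries structure only. Given the same
#' labeled embeddings it was built from, this re-attaches them (every
#' housed alias must be covered) and refits all node classifiers, making
#' the tree usable for prediction and updating again.
#'
#' @param tree a structure-only \linkS4class{CellHierarchy}.
#' @param datasets list of \linkS4class{LabeledEmbedding} covering the
#'   tree's housed datasets.
#' @param control fitting parameters, see \code{\link{hierarchyControl}}.
#' @return The hierarchy with embeddings attached and classifiers fitted.
#' @export
restoreHierarchy <- function(tree, datasets,
                             control = hierarchyControl()) {
  stopifnot(is(tree, "CellHierarchy"))
  ids <- vapply(datasets, datasetId, "")
  need <- unique(aliasTable(tree)$dataset)
  lack <- setdiff(need, ids)
  if (length(lack))
    .satStop("invalidArgumentError",
             sprintf("no embedding supplied for dataset(s): %s",
                     paste(lack, collapse = ", ")))
  tree@embeddings <- stats::setNames(datasets, ids)[need]
  if (!length(tree@datasetIds)) tree@datasetIds <- need
  tree@control <- control
  fitClassifiers(tree, control)
}

#' Structural equality of two hierarchies
#'
#' Compares node names, parent/child structure (sibling order included)
#' and housed aliases; embeddings and classifiers are ignored.
#'
#' @param a,b \linkS4class{CellHierarchy} objects.
#' @return logical.
#' @export
sameHierarchyStructure <- function(a, b) {
  if (!identical(sort(names(a@nodes)), sort(names(b@nodes))))
    return(FALSE)
  for (nm in names(a@nodes)) {
    na <- a@nodes[[nm]]; nb <- b@nodes[[nm]]
    if (!identical(na$parent, nb$parent)) return(FALSE)
    if (!identical(na$children, nb$children)) return(FALSE)
    ka <- sort(.aliasKey(na$aliases$dataset, na$aliases$label))
    kb <- sort(.aliasKey(nb$aliases$dataset, nb$aliases$label))
    if (!identical(ka, kb)) return(FALSE)
  }
  TRUE
}
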