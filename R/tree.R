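# Tree construction primitives. The hierarchy is a rooted tree whose
# non-root nodes each house >= 1 (dataset, label) alias; an edge means the
# child is a subpopulation of the parent.

.newNodeRec <- function(name, parent, aliases) {
  list(name = name, parent = parent, children = character(),
       aliases = aliases)
}

.asAliases <- function(aliases) {
  if (is.data.frame(aliases)) {
    stopifnot(all(c("dataset", "label") %in% colnames(aliases)))
    out <- data.frame(dataset = trimws(as.character(aliases$dataset)),
                      label = trimws(as.character(aliases$label)),
                      stringsAsFactors = FALSE)
  } else if (is.character(aliases) && length(aliases) == 2L) {
    out <- data.frame(dataset = trimws(aliases[[1L]]),
                      label = trimws(aliases[[2L]]),
                      stringsAsFactors = FALSE)
  } else {
    .satStop("invalidArgumentError",
             "aliases must be a (dataset, label) pair or a data.frame")
  }
  if (!nrow(out) || any(!nzchar(out$dataset)) || any(!nzchar(out$label)))
    .satStop("invalidArgumentError",
             "aliases must have non-empty dataset and label fields")
  out
}

#' Create an empty cell-type hierarchy
#'
#' @param rootName display name of the root node (reserved; the root
#'   carries no aliases).
#' @return A \linkS4class{CellHierarchy} with a single childless root,
#'   no datasets and no missing labels.
#' @examples
#' createHierarchy("root")
#' @export
createHierarchy <- function(rootName = "root") {
  if (!is.character(rootName) || length(rootName) != 1L ||
      !nzchar(rootName))
    .satStop("invalidArgumentError", "rootName must be a non-empty string")
  nodes <- list()
  nodes[[rootName]] <- .newNodeRec(rootName, NA_character_,
                                   .emptyAliases())
  new("CellHierarchy", rootName = rootName, nodes = nodes,
      datasetIds = character(), missing = .emptyMissing(),
      embeddings = list(), classifiers = list(),
      control = hierarchyControl(), updateLog = list())
}

.housedKeys <- function(tree) {
  at <- aliasTable(tree)
  .aliasKey(at$dataset, at$label)
}

.checkUnhoused <- function(tree, aliases) {
  clash <- .aliasKey(aliases$dataset, aliases$label) %in% .housedKeys(tree)
  if (any(clash))
    .satStop("conflictError",
             sprintf("alias (%s, %s) is already housed in the tree",
                     aliases$dataset[clash][1L], aliases$label[clash][1L]))
}

# Display-name policy: default is the first alias's bare label; qualified
# with " - <dataset>" only when the bare label collides with an existing
# node name (or the root name). Deterministic by insertion order.
.displayName <- function(tree, aliases, name = NULL) {
  if (!is.null(name)) {
    if (name %in% names(tree@nodes))
      .satStop("conflictError",
               sprintf("node name '%s' already exists", name))
    return(name)
  }
  cand <- aliases$label[1L]
  if (cand %in% names(tree@nodes))
    cand <- sprintf("%s - %s", aliases$label[1L], aliases$dataset[1L])
  if (cand %in% names(tree@nodes))
    .satStop("conflictError",
             sprintf("cannot derive a unique display name for '%s'",
                     aliases$label[1L]))
  cand
}

#' Add a node to the hierarchy
#'
#' Appends a new child housing the given aliases under an existing parent.
#'
#' @param tree a \linkS4class{CellHierarchy}.
#' @param parent display name of the parent node.
#' @param aliases a \code{c(dataset, label)} pair or a data.frame with
#'   columns \code{dataset} and \code{label}.
#' @param name optional explicit display name; by default the first
#'   alias's label, dataset-qualified on collision.
#' @return The updated tree (functional update; the input is not
#'   modified).
#' @examples
#' tr <- createHierarchy()
#' tr <- addNode(tr, "root", c("sun", "T cells"))
#' tr <- addNode(tr, "T cells", c("freytag", "CD4+ T cells"))
#' @export
addNode <- function(tree, parent, aliases, name = NULL) {
  stopifnot(is(tree, "CellHierarchy"))
  if (is.null(tree@nodes[[parent]]))
    .satStop("notFoundError", sprintf("unknown parent node '%s'", parent))
  aliases <- .asAliases(aliases)
  .checkUnhoused(tree, aliases)
  nm <- .displayName(tree, aliases, name)
  tree@nodes[[nm]] <- .newNodeRec(nm, parent, aliases)
  tree@nodes[[parent]]$children <- c(tree@nodes[[parent]]$children, nm)
  validObject(tree)
  tree
}

#' Merge an alias into an existing node
#'
#' Records that a dataset's label denotes the same population as an
#' existing node (a perfect match); the tree shape is unchanged.
#'
#' @param tree a \linkS4class{CellHierarchy}.
#' @param node display name of the receiving node (not the root).
#' @param dataset,label the alias to merge.
#' @return The updated tree.
#' @export
mergeAlias <- function(tree, node, dataset, label) {
  stopifnot(is(tree, "CellHierarchy"))
  if (is.null(tree@nodes[[node]]))
    .satStop("notFoundError", sprintf("unknown node '%s'", node))
  if (identical(node, tree@rootName))
    .satStop("invalidArgumentError", "the root carries no aliases")
  al <- .asAliases(c(dataset, label))
  .checkUnhoused(tree, al)
  tree@nodes[[node]]$aliases <- rbind(tree@nodes[[node]]$aliases, al)
  validObject(tree)
  tree
}

#' Delete a subtree
#'
#' Removes a node and all its descendants (their aliases leave the tree;
#' classifiers touching them are dropped). Together with
#' \code{\link{addNode}} this supports manual post-hoc editing; classifier
#' retraining (\code{\link{fitClassifiers}}) is the caller's duty.
#'
#' @inheritParams mergeAlias
#' @return The updated tree.
#' @export
deleteSubtree <- function(tree, node) {
  stopifnot(is(tree, "CellHierarchy"))
  if (is.null(tree@nodes[[node]]))
    .satStop("notFoundError", sprintf("unknown node '%s'", node))
  if (identical(node, tree@rootName))
    .satStop("invalidArgumentError", "cannot delete the root")
  doomed <- .subtreeNames(tree, node)
  par <- tree@nodes[[node]]$parent
  tree@nodes[[par]]$children <- setdiff(tree@nodes[[par]]$children, node)
  tree@nodes[doomed] <- NULL
  tree@classifiers[intersect(names(tree@classifiers), doomed)] <- NULL
  validObject(tree)
  tree
}

.subtreeNames <- function(tree, name) {
  out <- character()
  stack <- name
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, cur)
    stack <- c(tree@nodes[[cur]]$children, stack)
  }
  out
}

.isStrictDescendant <- function(tree, node, ancestor) {
  if (is.null(tree@nodes[[node]]) || is.null(tree@nodes[[ancestor]]))
    return(FALSE)
  cur <- tree@nodes[[node]]$parent
  while (!is.na(cur)) {
    if (identical(cur, ancestor)) return(TRUE)
    cur <- tree@nodes[[cur]]$parent
  }
  FALSE
}

# ---- tree -> ancestor-descendant graph --------------------------------

.nodeGraphNames <- function(tree, name, nameMap) {
  if (is.null(nameMap)) return(name)
  al <- tree@nodes[[name]]$aliases
  if (!nrow(al)) return(name)          # root (only if includeRoot)
  key <- .aliasKey(al$dataset, al$label)
  mk <- .aliasKey(nameMap$dataset, nameMap$label)
  hit <- match(key, mk)
  nms <- ifelse(is.na(hit),
                sprintf("UNMAPPED:%s:%s", al$dataset, al$label),
                nameMap$node[hit])
  unique(nms)
}

#' Convert a hierarchy to its ancestor-descendant edge graph
#'
#' Adds a directed edge from every node to each of its descendants; the
#' result is transitively closed by construction. The root is excluded by
#' default because root-to-X edges carry no cell-type relation.
#'
#' With \code{nameMap} (a data.frame with columns \code{dataset},
#' \code{label}, \code{node}) every tree node is renamed to the
#' ground-truth node name(s) its aliases map to; a node whose aliases span
#' several truth names expands to all of them, pairs collapsing onto the
#' same truth name are dropped (no self-edges), and unmappable aliases are
#' kept under an \code{"UNMAPPED:"} name so that they surface as wrong
#' edges during comparison rather than disappearing.
#'
#' @param tree a \linkS4class{CellHierarchy}.
#' @param includeRoot include edges from the root.
#' @param nameMap optional alias-to-truth-name mapping (see Details).
#' @return An \linkS4class{EdgeGraph}.
#' @examples
#' tr <- createHierarchy()
#' tr <- addNode(tr, "root", c("s1", "A"))
#' tr <- addNode(tr, "A", c("s1", "B"))
#' tr <- addNode(tr, "B", c("s1", "C"))
#' edges(treeToGraph(tr))   # (A,B), (A,C), (B,C)
#' @export
treeToGraph <- function(tree, includeRoot = FALSE, nameMap = NULL) {
  stopifnot(is(tree, "CellHierarchy"))
  anc <- character(); des <- character(); universe <- character()
  nms <- names(tree@nodes)
  if (!includeRoot) nms <- setdiff(nms, tree@rootName)
  mapped <- lapply(names(tree@nodes), function(n)
    .nodeGraphNames(tree, n, nameMap))
  names(mapped) <- names(tree@nodes)
  for (n in nms) {
    universe <- c(universe, mapped[[n]])
    descendants <- setdiff(.subtreeNames(tree, n), n)
    for (m in descendants) {
      pairs <- expand.grid(a = mapped[[n]], d = mapped[[m]],
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$a != pairs$d, , drop = FALSE]
      anc <- c(anc, pairs$a); des <- c(des, pairs$d)
    }
  }
  .EdgeGraph(anc, des, universe)
}

#' Export an edge graph as a two-column TSV
#'
#' @param graph an \linkS4class{EdgeGraph}.
#' @param path output file; two tab-separated columns (ancestor,
#'   descendant), no header.
#' @return \code{path}, invisibly.
#' @export
writeEdgeGraph <- function(graph, path) {
  stopifnot(is(graph, "EdgeGraph"))
  utils::write.table(graph@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an edge graph from a two-column TSV
#'
#' @param path file written by \code{\link{writeEdgeGraph}}.
#' @return An \linkS4class{EdgeGraph}.
#' @export
readEdgeGraph <- function(path) {
  if (!file.exists(path))
    .satStop("notFoundError", sprintf("no such file: %s", path))
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = ""),
    error = function(e) .satStop("parseError", conditionMessage(e)))
  if (ncol(df) < 2L && nrow(df))
    .satStop("parseError", "edge TSV must have two columns")
  if (!nrow(df)) return(.EdgeGraph(character(), character(), character()))
  .EdgeGraph(df[[1L]], df[[2L]], unique(c(df[[1L]], df[[2L]])))
}
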