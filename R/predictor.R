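# Fitting the per-node classifiers of a hierarchy and hierarchical
# top-down label transfer with rejection.

# Pool every housed training cell: coordinates, the node housing its
# (dataset, label) alias, dataset and cell ids. Cells whose label is
# unplaceable (in `missing`) are excluded so they never contaminate
# neighbourhoods.
.pooledCells <- function(tree) {
  at <- aliasTable(tree)
  atKey <- .aliasKey(at$dataset, at$label)
  Xs <- list(); nodes <- list(); ds <- list(); ids <- list()
  for (emb in tree@embeddings) {
    if (!isLabeled(emb)) next
    key <- .aliasKey(datasetId(emb), cellLabels(emb))
    hit <- match(key, atKey)
    keep <- !is.na(hit)
    if (!any(keep)) next
    Xs[[length(Xs) + 1L]] <- latentCoords(emb)[keep, , drop = FALSE]
    nodes[[length(nodes) + 1L]] <- at$node[hit[keep]]
    ds[[length(ds) + 1L]] <- rep(datasetId(emb), sum(keep))
    ids[[length(ids) + 1L]] <- cellIds(emb)[keep]
  }
  list(X = do.call(rbind, Xs), node = unlist(nodes),
       dataset = unlist(ds), cellIds = unlist(ids))
}

#' Fit all node classifiers of a hierarchy
#'
#' Trains one multiclass kNN classifier (with fitted rejection
#' thresholds) for every internal node with at least two children. The
#' training pool of a child class is every cell whose alias is housed at
#' or below that child; single-child nodes act as pass-throughs and carry
#' no classifier.
#'
#' @param tree a \linkS4class{CellHierarchy} with embeddings attached.
#' @param control see \code{\link{hierarchyControl}}.
#' @return The tree with the \code{classifiers} slot refit.
#' @export
fitClassifiers <- function(tree, control = tree@control) {
  stopifnot(is(tree, "CellHierarchy"))
  if (!length(tree@embeddings))
    .satStop("stateError", "hierarchy has no training embeddings")
  pool <- .pooledCells(tree)
  if (is.null(pool$X))
    .satStop("stateError", "no labeled training cells are housed")
  tree@classifiers <- list()
  for (nm in names(tree@nodes)) {
    kids <- tree@nodes[[nm]]$children
    if (length(kids) < 2L) next
    yy <- rep(NA_character_, length(pool$node))
    for (ch in kids) {
      members <- .subtreeNames(tree, ch)
      yy[pool$node %in% members] <- ch
    }
    keep <- !is.na(yy)
    empty <- setdiff(kids, unique(yy[keep]))
    if (length(empty))
      .satStop("validationError",
               sprintf("node '%s': child class '%s' has no training cells",
                       nm, empty[1L]))
    tree@classifiers[[nm]] <-
      fitNodeClassifier(pool$X[keep, , drop = FALSE], yy[keep],
                        control = control, parentNode = nm)
  }
  tree@control <- control
  tree
}

#' Hierarchical top-down label transfer
#'
#' Each query cell starts at the root and is passed down the tree. At a
#' node with a classifier the cell is classified among the direct
#' children: a distance or reconstruction rejection is terminal (the cell
#' is flagged as potentially novel, with that reason); a posterior
#' rejection stops the descent and labels the cell with the current node
#' (a partial, coarse annotation) unless the current node is the root, in
#' which case the cell is rejected with reason \code{"posterior"}; an
#' accepted class sends the cell down. Single-child nodes are descended
#' unconditionally; a leaf yields the final label.
#'
#' @param tree a fitted \linkS4class{CellHierarchy}.
#' @param query a \linkS4class{LabeledEmbedding} (labels, if any, are
#'   ignored) or a coordinate matrix.
#' @param control rejection toggles; defaults to the tree's control.
#' @return A \linkS4class{PredictionResult}.
#' @export
predictCells <- function(tree, query, control = tree@control) {
  stopifnot(is(tree, "CellHierarchy"))
  if (is(query, "LabeledEmbedding")) {
    Q <- latentCoords(query)
    ids <- cellIds(query)
  } else {
    Q <- as.matrix(query)
    ids <- rownames(Q)
    if (is.null(ids)) ids <- paste0("cell_", seq_len(nrow(Q)))
  }
  n <- nrow(Q)
  finalLabel <- character(n)
  rejected <- logical(n)
  reason <- character(n)
  paths <- rep(list(character()), n)
  posts <- rep(list(list()), n)

  # breadth-first over (node, cell-index-group)
  queue <- list(list(node = tree@rootName, cells = seq_len(n)))
  while (length(queue)) {
    item <- queue[[1L]]; queue <- queue[-1L]
    nd <- item$node; cells <- item$cells
    if (!length(cells)) next
    for (i in cells) paths[[i]] <- c(paths[[i]], nd)
    kids <- tree@nodes[[nd]]$children
    if (!length(kids)) {                       # leaf
      for (i in cells) finalLabel[i] <- nd
      next
    }
    if (length(kids) == 1L) {                  # pass-through
      queue <- c(queue, list(list(node = kids, cells = cells)))
      next
    }
    clf <- tree@classifiers[[nd]]
    if (is.null(clf))
      .satStop("stateError",
               sprintf("node '%s' has no fitted classifier; run fitClassifiers()",
                       nd))
    res <- classifyCells(clf, Q[cells, , drop = FALSE], control)
    pm <- attr(res, "posteriors")
    for (j in seq_along(cells)) {
      i <- cells[j]
      posts[[i]][[nd]] <- pm[j, ]
    }
    isRoot <- identical(nd, tree@rootName)
    hard <- res$rejected & res$reason %in% c("distance", "reconstruction")
    soft <- res$rejected & res$reason == "posterior"
    for (j in which(hard)) {
      i <- cells[j]
      finalLabel[i] <- "REJECTED"; rejected[i] <- TRUE
      reason[i] <- res$reason[j]
    }
    for (j in which(soft)) {
      i <- cells[j]
      if (isRoot) {
        finalLabel[i] <- "REJECTED"; rejected[i] <- TRUE
        reason[i] <- "posterior"
      } else {
        finalLabel[i] <- nd                     # partial annotation
      }
    }
    ok <- which(!res$rejected)
    for (ch in kids) {
      sub <- ok[res$predicted[ok] == ch]
      if (length(sub))
        queue <- c(queue,
                   list(list(node = ch, cells = cells[sub])))
    }
  }
  new("PredictionResult", cellIds = ids, finalLabel = finalLabel,
      rejected = rejected, reason = reason, paths = paths,
      posteriors = posts)
}

#' Agreement between two prediction vectors under a hierarchy
#'
#' Classifies each cell's pair of labels as unchanged (identical),
#' refined (the new label is a strict descendant of the old one in the
#' tree, i.e. the cell moved to a subpopulation of its original
#' annotation) or changed (anything else). Fractions are computed on
#' counts, so they sum to exactly 1.
#'
#' @param predOld,predNew equal-length character vectors of labels; every
#'   label must be a node of \code{tree} or \code{"REJECTED"}.
#' @param tree the \linkS4class{CellHierarchy} the new labels live in.
#' @return named numeric vector \code{c(unchanged, refined, changed)};
#'   integer counts are attached as attribute \code{"counts"}.
#' @export
predictionAgreement <- function(predOld, predNew, tree) {
  if (length(predOld) != length(predNew))
    .satStop("invalidArgumentError",
             "prediction vectors must have equal length")
  known <- c(nodeNames(tree), "REJECTED")
  bad <- setdiff(unique(c(predOld, predNew)), known)
  if (length(bad))
    .satStop("validationError",
             sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  n <- length(predOld)
  unchanged <- sum(predOld == predNew)
  refined <- sum(vapply(seq_len(n), function(i) {
    predOld[i] != predNew[i] &&
      predNew[i] != "REJECTED" && predOld[i] != "REJECTED" &&
      .isStrictDescendant(tree, predNew[i], predOld[i])
  }, logical(1)))
  changed <- n - unchanged - refined
  out <- c(unchanged = unchanged / n, refined = refined / n,
           changed = changed / n)
  attr(out, "counts") <- c(unchanged = unchanged, refined = refined,
                           changed = changed, n = n)
  out
}

#' Write an agreement report
#'
#' @param agreement result of \code{\link{predictionAgreement}}.
#' @param path output path; with \code{format = "txt"} a 3-line
#'   \code{key: value} block, with \code{"json"} a machine-readable
#'   object.
#' @param format \code{"txt"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writeAgreement <- function(agreement, path, format = c("txt", "json")) {
  format <- match.arg(format)
  if (format == "txt") {
    writeLines(sprintf("%s: %.6f", names(agreement), agreement), path)
  } else {
    jsonlite::write_json(as.list(agreement), path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
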