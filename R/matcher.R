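# Cross-prediction between the current tree and an incoming labeled
# dataset, confusion binarization, relation resolution and progressive
# tree updating.

.fitFlatClassifier <- function(ds, control) {
  fitNodeClassifier(latentCoords(ds), cellLabels(ds), control = control,
                    parentNode = sprintf("flat:%s", datasetId(ds)))
}

#' Cross-predict labels between a hierarchy and a new dataset
#'
#' Two directions: the tree's hierarchical classifier (with rejection)
#' predicts the incoming cells (\code{treeToDs}: rows are the incoming
#' dataset's labels, columns are tree node names plus the reserved
#' \code{REJECTED} column), and a flat multiclass kNN trained on the
#' incoming dataset's labels, with the same three rejection options,
#' predicts the tree's pooled training cells (\code{dsToTree}: rows are
#' the tree nodes that directly house cells, columns the incoming labels
#' plus \code{REJECTED}). Both matrices are row-normalized fractions.
#'
#' @param tree a fitted \linkS4class{CellHierarchy}.
#' @param ds a labeled \linkS4class{LabeledEmbedding}.
#' @param control see \code{\link{hierarchyControl}}.
#' @return list with matrices \code{treeToDs} and \code{dsToTree}.
#' @export
crossPredict <- function(tree, ds, control = tree@control) {
  stopifnot(is(tree, "CellHierarchy"), is(ds, "LabeledEmbedding"))
  if (!isLabeled(ds))
    .satStop("invalidArgumentError",
             "cross-prediction needs a labeled dataset")
  d0 <- ncol(tree@embeddings[[1L]]@coords)
  if (latentDim(ds) != d0)
    .satStop("dimensionError",
             sprintf("dataset has %d latent dims, tree was built with %d",
                     latentDim(ds), d0))

  labels <- sort(unique(cellLabels(ds)))
  nodeCols <- c(setdiff(nodeNames(tree), tree@rootName), "REJECTED")

  pr <- predictCells(tree, ds, control)
  treeToDs <- matrix(0, length(labels), length(nodeCols),
                     dimnames = list(labels, nodeCols))
  for (lb in labels) {
    idx <- cellLabels(ds) == lb
    tab <- table(factor(finalLabels(pr)[idx], levels = nodeCols))
    treeToDs[lb, ] <- as.numeric(tab) / sum(idx)
  }

  flat <- .fitFlatClassifier(ds, control)
  pool <- .pooledCells(tree)
  res <- classifyCells(flat, pool$X, control)
  pred <- ifelse(res$rejected, "REJECTED", res$predicted)
  rows <- sort(unique(pool$node))
  labCols <- c(labels, "REJECTED")
  dsToTree <- matrix(0, length(rows), length(labCols),
                     dimnames = list(rows, labCols))
  for (nd in rows) {
    idx <- pool$node == nd
    tab <- table(factor(pred[idx], levels = labCols))
    dsToTree[nd, ] <- as.numeric(tab) / sum(idx)
  }
  list(treeToDs = treeToDs, dsToTree = dsToTree)
}

#' Binarize a confusion matrix
#'
#' @param conf row-normalized confusion matrix.
#' @param matchThreshold fraction strictly in (0, 1); an entry at or
#'   above it counts as a match (default 0.25). The \code{REJECTED}
#'   column is binarized identically.
#' @return logical matrix of the same shape.
#' @export
binarizeConfusion <- function(conf, matchThreshold = 0.25) {
  if (matchThreshold <= 0 || matchThreshold >= 1)
    .satStop("invalidArgumentError",
             "matchThreshold must lie strictly in (0, 1)")
  conf >= matchThreshold
}

# ---- relation resolution ----------------------------------------------

#' Resolve pairwise relations between incoming labels and tree nodes
#'
#' Interprets the two binarized match matrices. Writing \code{to(L)} for
#' the tree nodes label L matches (\code{REJECTED} set aside) and
#' \code{to(N)} for the labels node N matches:
#' \itemize{
#' \item \code{to(L) = \{N\}} and \code{to(N) = \{L\}}: reciprocal
#'   exclusive match. If only N's row carries an above-threshold
#'   \code{REJECTED} fraction (the dataset classifier rejects part of N),
#'   N is the broader population and L becomes its subpopulation; if only
#'   L's row does, L is broader and is inserted above N; otherwise the two
#'   are a perfect match and L merges into N as an alias.
#' \item \code{to(L) = \{N\}} and every label N points to is itself
#'   exclusive to N: L (together with those labels) becomes a child of N
#'   (N is split into subpopulations; L need not be matched back by N).
#' \item \code{to(L)} is a set of sibling nodes, each exclusive to L:
#'   L merges them, becoming their new parent under their former parent.
#' \item L matches only \code{REJECTED} and no node matches L: a new
#'   population, attached to the root.
#' \item anything else (crossing many-to-many patterns, matches spanning
#'   non-sibling nodes): unresolved; the label is reported as missing.
#' }
#'
#' @param matchTreeToDs,matchDsToTree binarized matrices from
#'   \code{\link{binarizeConfusion}} over the same label/node universes.
#' @param tree the current \linkS4class{CellHierarchy}.
#' @return list with \code{verdicts} (data.frame: label, verdict in
#'   matched/new_root_child/unresolved, action in
#'   perfect/subpopulation/merge/new/none, target) and \code{pairs}
#'   (data.frame: label, node, relation).
#' @export
resolveRelations <- function(matchTreeToDs, matchDsToTree, tree) {
  labels <- rownames(matchTreeToDs)
  nodes <- rownames(matchDsToTree)
  toNodes <- lapply(labels, function(L)
    colnames(matchTreeToDs)[matchTreeToDs[L, ]])
  names(toNodes) <- labels
  toLabels <- lapply(nodes, function(N)
    colnames(matchDsToTree)[matchDsToTree[N, ]])
  names(toLabels) <- nodes

  cleanL <- lapply(toNodes, setdiff, "REJECTED")
  rejL <- vapply(toNodes, function(x) "REJECTED" %in% x, logical(1))
  cleanN <- lapply(toLabels, setdiff, "REJECTED")
  rejN <- vapply(toLabels, function(x) "REJECTED" %in% x, logical(1))

  # S(N): labels exclusively matching N
  exclTo <- function(N) labels[vapply(cleanL, function(x)
    identical(x, N), logical(1))]
  matchedBySomeNode <- function(L)
    any(vapply(cleanN, function(x) L %in% x, logical(1)))

  verdictRows <- list()
  pairRows <- list()
  addPair <- function(L, N, rel)
    pairRows[[length(pairRows) + 1L]] <<-
      data.frame(label = L, node = N, relation = rel,
                 stringsAsFactors = FALSE)
  addVerdict <- function(L, verdict, action, target)
    verdictRows[[length(verdictRows) + 1L]] <<-
      data.frame(label = L, verdict = verdict, action = action,
                 target = paste(target, collapse = ","),
                 stringsAsFactors = FALSE)

  for (L in labels) {
    tn <- cleanL[[L]]
    if (!length(tn)) {
      if (rejL[[L]] && !matchedBySomeNode(L)) {
        addVerdict(L, "new_root_child", "new", tree@rootName)
      } else {
        addVerdict(L, "unresolved", "none", "")
      }
      next
    }
    if (length(tn) == 1L) {
      N <- tn
      rn <- if (N %in% nodes) cleanN[[N]] else NULL
      if (is.null(rn)) { addVerdict(L, "unresolved", "none", ""); next }
      if (identical(rn, L)) {
        # reciprocal exclusive pair; rejection asymmetry decides
        if (rejN[[N]] && !rejL[[L]]) {
          addVerdict(L, "matched", "subpopulation", N)
          addPair(L, N, "new_is_subpopulation")
        } else if (rejL[[L]] && !rejN[[N]]) {
          addVerdict(L, "matched", "merge", N)
          addPair(L, N, "tree_is_subpopulation")
        } else {
          addVerdict(L, "matched", "perfect", N)
          addPair(L, N, "perfect")
        }
      } else if (L %in% rn || length(rn)) {
        # N points to several labels; L joins the split when every label
        # N points to is itself exclusive to N
        if (all(rn %in% exclTo(N))) {
          addVerdict(L, "matched", "subpopulation", N)
          addPair(L, N, "new_is_subpopulation")
        } else {
          addVerdict(L, "unresolved", "none", "")
        }
      } else {
        addVerdict(L, "unresolved", "none", "")
      }
      next
    }
    # L matches several nodes: merge when they are siblings, each
    # exclusive to L
    if (!all(tn %in% nodes)) { addVerdict(L, "unresolved", "none", ""); next }
    parents <- vapply(tn, function(N) {
      if (is.null(tree@nodes[[N]])) NA_character_
      else tree@nodes[[N]]$parent
    }, "")
    siblings <- !anyNA(parents) && length(unique(parents)) == 1L
    exclusive <- all(vapply(tn, function(N)
      identical(cleanN[[N]], L), logical(1)))
    if (siblings && exclusive) {
      addVerdict(L, "matched", "merge", tn)
      for (N in tn) addPair(L, N, "merge")
    } else {
      addVerdict(L, "unresolved", "none", "")
    }
  }
  verdicts <- do.call(rbind, verdictRows)
  pairs <- if (length(pairRows)) do.call(rbind, pairRows)
  else data.frame(label = character(), node = character(),
                  relation = character(), stringsAsFactors = FALSE)
  list(verdicts = verdicts, pairs = pairs)
}

# ---- tree updating -----------------------------------------------------

#' Update a hierarchy with a new labeled dataset
#'
#' Cross-predicts between the tree and the dataset, resolves the label
#' relations, and applies them: perfect matches merge as aliases,
#' subpopulations are added as children, merging labels are inserted as
#' intermediate parents, new populations are attached to the root, and
#' unresolved labels are recorded as missing (their cells never enter
#' classifier training pools). All node classifiers are then refit on the
#' enlarged pools. The per-label report is appended to the tree's update
#' log.
#'
#' @param tree a fitted \linkS4class{CellHierarchy}.
#' @param ds a labeled \linkS4class{LabeledEmbedding} in the same latent
#'   space.
#' @param control see \code{\link{hierarchyControl}}.
#' @return The updated \linkS4class{CellHierarchy}.
#' @export
updateHierarchy <- function(tree, ds, control = tree@control) {
  stopifnot(is(tree, "CellHierarchy"), is(ds, "LabeledEmbedding"))
  if (!isLabeled(ds))
    .satStop("invalidArgumentError",
             "updating requires a labeled dataset")
  if (datasetId(ds) %in% tree@datasetIds)
    .satStop("conflictError",
             sprintf("dataset '%s' is already incorporated",
                     datasetId(ds)))
  cp <- crossPredict(tree, ds, control)
  thr <- control$matchThreshold
  rel <- resolveRelations(binarizeConfusion(cp$treeToDs, thr),
                          binarizeConfusion(cp$dsToTree, thr), tree)
  v <- rel$verdicts
  dsId <- datasetId(ds)
  placed <- character(nrow(v)); names(placed) <- v$label

  apply_order <- c("perfect", "merge", "subpopulation", "new", "none")
  for (act in apply_order) {
    rows <- which(v$action == act)
    rows <- rows[order(v$label[rows])]
    for (r in rows) {
      L <- v$label[r]
      tgt <- strsplit(v$target[r], ",", fixed = TRUE)[[1L]]
      if (act == "perfect") {
        tree <- mergeAlias(tree, tgt, dsId, L)
        placed[L] <- tgt
      } else if (act == "merge") {
        tree <- .insertParent(tree, tgt, c(dsId, L))
        placed[L] <- tree@nodes[[tree@nodes[[tgt[1L]]]$parent]]$name
      } else if (act == "subpopulation") {
        tree <- addNode(tree, tgt, c(dsId, L))
        placed[L] <- tgt
      } else if (act == "new") {
        tree <- addNode(tree, tree@rootName, c(dsId, L))
        placed[L] <- tree@rootName
      } else {
        tree@missing <- rbind(tree@missing,
                              data.frame(dataset = dsId, label = L,
                                         stringsAsFactors = FALSE))
        placed[L] <- ""
      }
    }
  }
  tree@embeddings[[dsId]] <- ds
  tree@datasetIds <- c(tree@datasetIds, dsId)
  tree <- fitClassifiers(tree, control)
  report <- data.frame(label = v$label, verdict = v$verdict,
                       action = v$action,
                       placed_under = unname(placed[v$label]),
                       notes = v$target, stringsAsFactors = FALSE)
  tree@updateLog <- c(tree@updateLog,
                      stats::setNames(list(report), dsId))
  validObject(tree)
  tree
}

# Insert a new node housing `alias` between sibling nodes `siblings` and
# their common parent; the siblings become its children.
.insertParent <- function(tree, siblings, alias) {
  par <- unique(vapply(siblings, function(N) tree@nodes[[N]]$parent, ""))
  stopifnot(length(par) == 1L)
  al <- .asAliases(alias)
  .checkUnhoused(tree, al)
  nm <- .displayName(tree, al)
  tree@nodes[[nm]] <- .newNodeRec(nm, par, al)
  tree@nodes[[nm]]$children <- siblings
  tree@nodes[[par]]$children <-
    c(setdiff(tree@nodes[[par]]$children, siblings), nm)
  for (N in siblings) tree@nodes[[N]]$parent <- nm
  tree
}

#' Build a hierarchy progressively from labeled datasets
#'
#' The tree is initialized from the first dataset (root plus one child
#' per label), then \code{\link{updateHierarchy}} incorporates the
#' remaining datasets in the given order. Datasets annotated at different
#' resolutions should be supplied from low to high resolution.
#'
#' @param datasets list of labeled \linkS4class{LabeledEmbedding} objects
#'   sharing one latent space.
#' @param control see \code{\link{hierarchyControl}}.
#' @param rootName display name for the root.
#' @return A fitted \linkS4class{CellHierarchy}.
#' @examples
#' sim <- simulateDatasets(presetScenario("equal-resolution-permutation"))
#' tr <- buildHierarchy(sim$datasets, hierarchyControl(k = 15))
#' tr
#' @export
buildHierarchy <- function(datasets, control = hierarchyControl(),
                           rootName = "root") {
  if (!length(datasets))
    .satStop("invalidArgumentError", "need at least one dataset")
  if (!all(vapply(datasets, function(d)
    is(d, "LabeledEmbedding") && isLabeled(d), logical(1))))
    .satStop("invalidArgumentError",
             "all datasets must be labeled LabeledEmbedding objects")
  dims <- vapply(datasets, latentDim, integer(1))
  if (length(unique(dims)) != 1L)
    .satStop("dimensionError",
             "all datasets must share one latent dimensionality")
  ids <- vapply(datasets, datasetId, "")
  if (anyDuplicated(ids))
    .satStop("invalidArgumentError", "dataset ids must be unique")

  tree <- createHierarchy(rootName)
  tree@control <- control
  first <- datasets[[1L]]
  for (lb in sort(unique(cellLabels(first))))
    tree <- addNode(tree, rootName, c(datasetId(first), lb))
  tree@embeddings[[datasetId(first)]] <- first
  tree@datasetIds <- datasetId(first)
  tree <- fitClassifiers(tree, control)
  for (ds in datasets[-1L])
    tree <- updateHierarchy(tree, ds, control)
  tree
}

#' Write the latest update report as TSV
#'
#' @param tree a \linkS4class{CellHierarchy} with at least one update.
#' @param path output path; columns label, verdict, action,
#'   placed_under, notes.
#' @return \code{path}, invisibly.
#' @export
writeUpdateReport <- function(tree, path) {
  if (!length(tree@updateLog))
    .satStop("stateError", "the tree has no update log")
  rep <- tree@updateLog[[length(tree@updateLog)]]
  utils::write.table(rep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
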