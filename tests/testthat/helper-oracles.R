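# Shared fixtures and independent oracles used across the test files.

# Gaussian clusters at given means (rows), unit isotropic sigma.
makeClusters <- function(means, n, d = ncol(means), seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(means)), function(i)
      matrix(rnorm(n * d), n, d) +
        matrix(means[i, ], n, d, byrow = TRUE)))
  })
  list(X = X, y = rep(rownames(means), each = n))
}

# Exhaustive kNN oracle, written independently of the implementation:
# per-pair distances, full sort, ties by training index, majority vote
# with the summed-distance then lexicographic tie-break.
oracleKnn <- function(trainX, trainY, Q, k) {
  classes <- sort(unique(trainY))
  n <- nrow(trainX)
  out <- lapply(seq_len(nrow(Q)), function(i) {
    dv <- vapply(seq_len(n), function(j)
      sqrt(sum((trainX[j, ] - Q[i, ])^2)), numeric(1))
    o <- order(dv, seq_len(n))[seq_len(k)]
    lab <- trainY[o]
    cnt <- vapply(classes, function(cl) sum(lab == cl), numeric(1))
    post <- cnt / k
    best <- classes[cnt == max(cnt)]
    if (length(best) > 1L) {
      sums <- vapply(best, function(cl) sum(dv[o][lab == cl]),
                     numeric(1))
      best <- best[sums == min(sums)]
      best <- sort(best)[1L]
    }
    list(pred = best[1L], post = post, meanDist = mean(dv[o]))
  })
  list(pred = vapply(out, `[[`, "", "pred"),
       post = t(vapply(out, `[[`, numeric(length(classes)), "post")),
       meanDist = vapply(out, `[[`, numeric(1), "meanDist"))
}

# Independent transitive-closure oracle via igraph reachability.
oracleClosure <- function(parentChildEdges, includeNodes) {
  if (!nrow(parentChildEdges))
    return(data.frame(ancestor = character(), descendant = character()))
  g <- igraph::graph_from_data_frame(parentChildEdges,
                                     vertices = includeNodes)
  dm <- igraph::distances(g, mode = "out")
  idx <- which(is.finite(dm) & dm > 0, arr.ind = TRUE)
  out <- data.frame(ancestor = rownames(dm)[idx[, 1]],
                    descendant = colnames(dm)[idx[, 2]],
                    stringsAsFactors = FALSE)
  out[order(out$ancestor, out$descendant), , drop = FALSE]
}

# Random hierarchy built through the public API; aliases are unique.
randomTree <- function(nNodes, seed) {
  withr::with_seed(seed, {
    tr <- createHierarchy("root")
    for (i in seq_len(nNodes - 1L)) {
      parent <- sample(nodeNames(tr), 1L)
      tr <- addNode(tr, parent,
                    c(paste0("ds", sample(3L, 1L)), paste0("lab", i)))
    }
    tr
  })
}

edgeSignature <- function(graph) {
  e <- edges(graph)
  paste(sort(paste(e$ancestor, e$descendant, sep = ">")),
        collapse = ";")
}

# Memoized ladder-scenario fixture shared by the acceptance tests.
.fixtureEnv <- new.env(parent = emptyenv())
ladderFixture <- function() {
  if (is.null(.fixtureEnv$ladder)) {
    sim <- simulateDatasets(presetScenario("pbmc-like-ladder", seed = 0))
    refs <- sim$datasets[names(sim$roles)[sim$roles == "reference"]]
    t0 <- Sys.time()
    tree <- buildHierarchy(refs, hierarchyControl())
    buildSecs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    treeUpdated <- updateHierarchy(tree, sim$datasets[["tenx"]])
    .fixtureEnv$ladder <- list(sim = sim, refs = refs, tree = tree,
                               treeUpdated = treeUpdated,
                               buildSecs = buildSecs)
  }
  .fixtureEnv$ladder
}

# A node is a clean root-attached novel population: single alias, leaf,
# child of the root.
isRootNovel <- function(tree, label, dataset) {
  at <- aliasTable(tree)
  hit <- at$node[at$label == label & at$dataset == dataset]
  length(hit) == 1L &&
    identical(parentOf(tree, hit), rootName(tree)) &&
    length(childrenOf(tree, hit)) == 0L &&
    sum(at$node == hit) == 1L
}
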