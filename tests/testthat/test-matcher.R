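# Cross-prediction, confusion binarization, relation resolution, tree
# updating.

# Two well-separated clusters A, B plus a distant one, reused across
# tests.
.sepMeans <- function(labels, dist = 12, d = 6) {
  m <- matrix(0, length(labels), d, dimnames = list(labels, NULL))
  for (i in seq_along(labels)[-1]) m[i, i - 1] <- dist
  m
}

flatTree <- function(ds, control = hierarchyControl(k = 15)) {
  buildHierarchy(list(ds), control)
}

test_that("cross-prediction of a dataset against itself is the identity", {
  cl <- makeClusters(.sepMeans(c("A", "B", "C")), 120, seed = 1)
  ds <- LabeledEmbedding(cl$X, "ref", labels = cl$y)
  tr <- flatTree(ds)
  twin <- LabeledEmbedding(cl$X, "twin",
                           cellIds = paste0("t", seq_len(nrow(cl$X))),
                           labels = cl$y)
  cp <- crossPredict(tr, twin)
  # near-identity: the fitted 99th-percentile distance threshold flags
  # about 1% of same-distribution cells, everything else is exact
  expect_true(all(diag(cp$treeToDs[c("A", "B", "C"),
                                   c("A", "B", "C")]) >= 0.97))
  expect_true(all(cp$treeToDs[, "REJECTED"] <= 0.03))
  offDiag <- cp$treeToDs[c("A", "B", "C"), c("A", "B", "C")]
  diag(offDiag) <- 0
  expect_equal(unname(offDiag), matrix(0, 3, 3))
  expect_true(all(diag(cp$dsToTree[c("A", "B", "C"),
                                   c("A", "B", "C")]) >= 0.97))
  # rows are normalized fractions
  expect_equal(unname(rowSums(cp$treeToDs)), rep(1, 3))
  expect_equal(unname(rowSums(cp$dsToTree)), rep(1, 3))
})

test_that("a pooling label splits its row across the pooled leaves", {
  cl <- makeClusters(.sepMeans(c("A", "B", "C")), 120, seed = 2)
  ds <- LabeledEmbedding(cl$X, "ref", labels = cl$y)
  tr <- flatTree(ds)
  pooled <- ifelse(cl$y == "C", "C", "AB")   # one label pools A and B
  ds2 <- LabeledEmbedding(cl$X, "new",
                          cellIds = paste0("n", seq_len(nrow(cl$X))),
                          labels = pooled)
  cp <- crossPredict(tr, ds2)
  expect_equal(unname(cp$treeToDs["AB", "A"]), 0.5, tolerance = 0.05)
  expect_equal(unname(cp$treeToDs["AB", "B"]), 0.5, tolerance = 0.05)
  expect_lt(cp$treeToDs["AB", "C"], 0.05)
})

test_that("a far-away cluster is fully rejected in cross-prediction", {
  cl <- makeClusters(.sepMeans(c("A", "B")), 150, seed = 3)
  ds <- LabeledEmbedding(cl$X, "ref", labels = cl$y)
  tr <- flatTree(ds)
  withr::with_seed(4, far <- matrix(rnorm(50 * 6), 50, 6) + 100)
  ds2 <- LabeledEmbedding(rbind(cl$X, far), "new",
                          labels = c(cl$y, rep("weird", 50)))
  cp <- crossPredict(tr, ds2)
  expect_gte(cp$treeToDs["weird", "REJECTED"], 0.99)
})

test_that("binarization applies the threshold inclusively to all columns", {
  conf <- matrix(c(0.6, 0.1, 0.3,
                   0.5, 0.5, 0.0), 2, 3, byrow = TRUE,
                 dimnames = list(c("r1", "r2"),
                                 c("A1", "A2", "REJECTED")))
  b <- binarizeConfusion(conf, 0.25)
  expect_identical(unname(b["r1", ]), c(TRUE, FALSE, TRUE))
  expect_identical(unname(b["r2", ]), c(TRUE, TRUE, FALSE))
  expect_identical(unname(diag(binarizeConfusion(diag(3) + 0, 0.25))),
                   rep(TRUE, 3))
  expect_error(binarizeConfusion(conf, 1.2),
               class = "invalidArgumentError")
})

# helper: binary matrices from named TRUE entries
binMat <- function(rows, cols, hits) {
  m <- matrix(FALSE, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (h in hits) m[h[1], h[2]] <- TRUE
  m
}

test_that("relation resolution recovers the canonical patterns", {
  tr <- createHierarchy()
  tr <- addNode(tr, "root", c("s", "X"))
  tr <- addNode(tr, "root", c("s", "Y"))
  tr <- addNode(tr, "root", c("s", "Z"))

  # identity: three perfect matches
  L <- c("X", "Y", "Z"); N <- c("X", "Y", "Z")
  mTD <- binMat(L, c(N, "REJECTED"),
                list(c("X", "X"), c("Y", "Y"), c("Z", "Z")))
  mDT <- binMat(N, c(L, "REJECTED"),
                list(c("X", "X"), c("Y", "Y"), c("Z", "Z")))
  rel <- resolveRelations(mTD, mDT, tr)
  expect_identical(rel$verdicts$action, rep("perfect", 3))
  expect_identical(rel$pairs$relation, rep("perfect", 3))

  # CD4/CD8 both exclusive to X, X pointing to both: subpopulations
  L2 <- c("CD4", "CD8")
  mTD <- binMat(L2, c(N, "REJECTED"), list(c("CD4", "X"), c("CD8", "X")))
  mDT <- binMat(N, c(L2, "REJECTED"),
                list(c("X", "CD4"), c("X", "CD8")))
  rel <- resolveRelations(mTD, mDT, tr)
  v <- rel$verdicts
  expect_identical(v$action[v$label %in% L2],
                   rep("subpopulation", 2))
  expect_identical(v$target[v$label %in% L2], rep("X", 2))

  # one label matched by two sibling nodes, each exclusive: merge
  mTD <- binMat("T", c(N, "REJECTED"), list(c("T", "X"), c("T", "Y")))
  mDT <- binMat(N, c("T", "REJECTED"), list(c("X", "T"), c("Y", "T")))
  rel <- resolveRelations(mTD, mDT, tr)
  expect_identical(rel$verdicts$action, "merge")
  expect_setequal(strsplit(rel$verdicts$target, ",")[[1]], c("X", "Y"))

  # rejected in both directions: new root child
  mTD <- binMat("P", c(N, "REJECTED"), list(c("P", "REJECTED")))
  mDT <- binMat(N, c("P", "REJECTED"),
                list(c("X", "REJECTED"), c("Y", "REJECTED"),
                     c("Z", "REJECTED")))
  rel <- resolveRelations(mTD, mDT, tr)
  expect_identical(rel$verdicts$verdict, "new_root_child")

  # non-sibling span is unresolved
  tr2 <- addNode(tr, "X", c("s", "X1"))
  N2 <- c("X", "X1", "Y")
  mTD <- binMat("L", c(N2, "REJECTED"),
                list(c("L", "X1"), c("L", "Y")))
  mDT <- binMat(N2, c("L", "REJECTED"),
                list(c("X1", "L"), c("Y", "L")))
  rel <- resolveRelations(mTD, mDT, tr2)
  expect_identical(rel$verdicts$verdict, "unresolved")
})

test_that("rejection asymmetry separates perfect from subpopulation", {
  tr <- createHierarchy()
  tr <- addNode(tr, "root", c("s", "X"))
  # ds classifier rejects part of X: X is broader, L is its subpopulation
  mTD <- binMat("L", c("X", "REJECTED"), list(c("L", "X")))
  mDT <- binMat("X", c("L", "REJECTED"),
                list(c("X", "L"), c("X", "REJECTED")))
  rel <- resolveRelations(mTD, mDT, tr)
  expect_identical(rel$verdicts$action, "subpopulation")
  # tree classifier rejects part of L: L is broader, inserted above X
  mTD <- binMat("L", c("X", "REJECTED"),
                list(c("L", "X"), c("L", "REJECTED")))
  mDT <- binMat("X", c("L", "REJECTED"), list(c("X", "L")))
  rel <- resolveRelations(mTD, mDT, tr)
  expect_identical(rel$verdicts$action, "merge")
  expect_identical(rel$verdicts$target, "X")
})

test_that("every binary pattern maps to exactly one verdict", {
  tr <- createHierarchy()
  tr <- addNode(tr, "root", c("s", "N1"))
  tr <- addNode(tr, "root", c("s", "N2"))
  L <- c("L1", "L2"); N <- c("N1", "N2")
  # enumerate all 2x3 + 2x3 binary matrix pairs (4096 patterns)
  cells1 <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  withr::with_seed(13, pick <- sample(nrow(cells1)^2, 400))
  for (p in pick) {
    i <- (p - 1) %% nrow(cells1) + 1
    j <- (p - 1) %/% nrow(cells1) + 1
    mTD <- matrix(unlist(cells1[i, ]), 2, 3,
                  dimnames = list(L, c(N, "REJECTED")))
    mDT <- matrix(unlist(cells1[j, ]), 2, 3,
                  dimnames = list(N, c(L, "REJECTED")))
    rel <- resolveRelations(mTD, mDT, tr)
    expect_identical(sort(rel$verdicts$label), sort(L))
    expect_true(all(rel$verdicts$verdict %in%
                      c("matched", "new_root_child", "unresolved")))
    expect_true(all(rel$verdicts$action %in%
                      c("perfect", "subpopulation", "merge", "new",
                        "none")))
  }
})

test_that("updating with an identically labeled dataset merges aliases only", {
  cl <- makeClusters(.sepMeans(c("A", "B", "C")), 120, seed = 5)
  ds1 <- LabeledEmbedding(cl$X, "d1", labels = cl$y)
  cl2 <- makeClusters(.sepMeans(c("A", "B", "C")), 120, seed = 6)
  ds2 <- LabeledEmbedding(cl2$X, "d2", labels = cl2$y)
  tr <- flatTree(ds1)
  tr2 <- updateHierarchy(tr, ds2)
  expect_identical(sort(nodeNames(tr2)), sort(nodeNames(tr)))
  at <- aliasTable(tr2)
  expect_equal(sum(at$dataset == "d2"), 3L)
  rep <- updateLog(tr2)[["d2"]]
  expect_identical(rep$action, rep("perfect", 3))
  expect_error(updateHierarchy(tr2, ds2), class = "conflictError")
})

test_that("a coarser relabeling perfectly matches existing structure", {
  cl <- makeClusters(.sepMeans(c("A", "B", "C")), 150, seed = 7)
  fine <- LabeledEmbedding(cl$X, "fine", labels = cl$y)
  cl2 <- makeClusters(.sepMeans(c("A", "B", "C")), 150, seed = 8)
  coarseLabels <- ifelse(cl2$y == "C", "C", "AB")
  coarse <- LabeledEmbedding(cl2$X, "coarse", labels = coarseLabels)
  # low to high resolution: coarse first, fine second
  tr <- buildHierarchy(list(coarse, fine), hierarchyControl(k = 15))
  expect_identical(sort(childrenOf(tr, "AB")), c("A", "B"))
  expect_identical(parentOf(tr, "C"), "root")
  at <- aliasTable(tr)
  expect_identical(at$node[at$dataset == "coarse" & at$label == "C"],
                   "C")
  expect_equal(nrow(missingLabels(tr)), 0L)
})

test_that("a distant novel cluster is attached to the root", {
  cl <- makeClusters(.sepMeans(c("A", "B")), 150, seed = 9)
  ds1 <- LabeledEmbedding(cl$X, "d1", labels = cl$y)
  cl2 <- makeClusters(.sepMeans(c("A", "B")), 150, seed = 10)
  withr::with_seed(11, nov <- matrix(rnorm(80 * 6), 80, 6) + 60)
  ds2 <- LabeledEmbedding(rbind(cl2$X, nov), "d2",
                          labels = c(cl2$y, rep("newpop", 80)))
  tr <- buildHierarchy(list(ds1, ds2), hierarchyControl(k = 15))
  expect_true(isRootNovel(tr, "newpop", "d2"))
  rep <- updateLog(tr)[["d2"]]
  expect_identical(rep$verdict[rep$label == "newpop"],
                   "new_root_child")
  expect_identical(rep$action[rep$label != "newpop"],
                   rep("perfect", 2))
})

test_that("every incorporated label ends housed or missing", {
  cl <- makeClusters(.sepMeans(c("A", "B", "C")), 100, seed = 12)
  ds1 <- LabeledEmbedding(cl$X, "d1", labels = cl$y)
  cl2 <- makeClusters(.sepMeans(c("A", "B", "C")), 100, seed = 13)
  ds2 <- LabeledEmbedding(cl2$X, "d2",
                          labels = ifelse(cl2$y == "A", "A", "BC"))
  tr <- buildHierarchy(list(ds1, ds2), hierarchyControl(k = 15))
  at <- aliasTable(tr)
  for (id in c("d1", "d2")) {
    labs <- unique(cellLabels(tr@embeddings[[id]]))
    housed <- at$label[at$dataset == id]
    miss <- missingLabels(tr)
    missing <- miss$label[miss$dataset == id]
    expect_setequal(labs, c(housed, missing))
    expect_length(intersect(housed, missing), 0)
  }
})

test_that("building requires labeled, dimension-consistent input", {
  expect_error(buildHierarchy(list()), class = "invalidArgumentError")
  a <- LabeledEmbedding(matrix(rnorm(40), 20, 2), "a",
                        labels = rep(c("x", "y"), 10))
  b3 <- LabeledEmbedding(matrix(rnorm(60), 20, 3), "b",
                         labels = rep(c("x", "y"), 10))
  expect_error(buildHierarchy(list(a, b3)), class = "dimensionError")
  q <- LabeledEmbedding(matrix(rnorm(40), 20, 2), "q")
  expect_error(buildHierarchy(list(q)), class = "invalidArgumentError")
})
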