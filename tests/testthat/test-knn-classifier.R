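# Per-node kNN classifier: dynamic k, thresholds, rejection, oracle
# equivalence.

mkClf <- function(trainX, trainY, k, tauPosterior = 0.5,
                  tauDistance = 1e9, tauReconstruction = 1e9) {
  d <- ncol(trainX)
  classes <- sort(unique(trainY))
  new("NodeClassifier", parentNode = "p", classNames = classes,
      kEffective = as.integer(k), trainX = trainX,
      trainY = match(trainY, classes), tauPosterior = tauPosterior,
      tauDistance = tauDistance, tauReconstruction = tauReconstruction,
      pcaRotation = diag(d), pcaCenter = rep(0, d),
      pcaRank = as.integer(d), metric = "euclidean")
}

test_that("dynamic neighbour sizing shrinks k to the smallest child", {
  expect_identical(effectiveK(50, c(1000, 800, 300), TRUE), 50L)
  expect_identical(effectiveK(50, c(1000, 18), TRUE), 18L)
  expect_identical(effectiveK(50, c(1000, 18), FALSE), 50L)
  expect_error(effectiveK(50, integer(), TRUE),
               class = "invalidArgumentError")
})

test_that("well-separated classes are resubstituted perfectly", {
  means <- matrix(0, 3, 10, dimnames = list(c("A", "B", "C"), NULL))
  means[2, 1] <- 12; means[3, 2] <- 12
  cl <- makeClusters(means, 200, seed = 42)
  clf <- fitNodeClassifier(cl$X, cl$y, hierarchyControl())
  expect_identical(clf@kEffective, 50L)
  res <- classifyCells(clf, cl$X)
  # resubstitution accuracy is exact; the fitted 99th-percentile
  # distance threshold by construction flags about 1% of inliers
  expect_identical(res$predicted, cl$y)
  expect_lte(mean(res$rejected), 0.02)
  orc <- oracleKnn(cl$X, cl$y, cl$X, 50L)
  expect_identical(res$predicted, orc$pred)

  expect_error(fitNodeClassifier(cl$X, rep("A", nrow(cl$X)),
                                 hierarchyControl()),
               class = "degenerateNodeError")
  small <- fitNodeClassifier(cl$X[1:81, ], rep(c("A", "B"), c(60, 21)),
                             hierarchyControl())
  expect_identical(small@kEffective, 21L)
})

test_that("distance threshold equals the brute-force percentile oracle", {
  # identical points: all neighbour distances zero
  X0 <- matrix(1, 30, 4)
  expect_identical(fitDistanceThreshold(X0, 5), 0)

  # points on a line, exact enumeration
  X <- cbind(as.numeric(1:200), 0)
  tau <- fitDistanceThreshold(X, 2)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  meansD <- apply(D, 1, function(r) mean(sort(r)[1:2]))
  expect_equal(tau, unname(quantile(meansD, 0.99, type = 7)),
               tolerance = 1e-12)

  # duplicated dataset: nearest neighbour is the duplicate, distance 0
  withr::with_seed(1, Xr <- matrix(rnorm(40), 20, 2))
  expect_identical(fitDistanceThreshold(rbind(Xr, Xr), 1), 0)

  expect_error(fitDistanceThreshold(X0, 30),
               class = "invalidArgumentError")
})

test_that("full-rank reconstruction never rejects", {
  withr::with_seed(3, X <- matrix(rnorm(500), 100, 5))
  fit <- fitReconstructionThreshold(X, varianceKept = 1)
  expect_identical(fit$tau, 0)
  expect_identical(fit$rank, 5L)
  clf <- fitNodeClassifier(X, rep(c("A", "B"), 50),
                           hierarchyControl(varianceKept = 1, k = 10))
  res <- classifyCells(clf, X + 100)  # far away: recon still exact
  expect_false(any(res$reason == "reconstruction"))
  expect_identical(res$reconError, rep(0, 100))
})

test_that("off-manifold queries are rejected by reconstruction error", {
  # 300 cells exactly in the first-2-coordinate plane of d = 5
  withr::with_seed(9, Z <- matrix(rnorm(600), 300, 2))
  X <- cbind(Z, 0, 0, 0)
  fit <- fitReconstructionThreshold(X, varianceKept = 0.9)
  expect_identical(fit$rank, 2L)
  off <- c(colMeans(X)[1:2], 3, 0, 0)  # distance 3 off the plane
  err <- scAtlasTree:::.reconErrors(
    list(rotation = fit$rotation, center = fit$center,
         rank = fit$rank, d = 5L), rbind(off))
  expect_equal(unname(err), 9, tolerance = 1e-8)
  expect_gt(err, fit$tau)
  expect_error(fitReconstructionThreshold(X, fnRate = 0),
               class = "invalidArgumentError")
})

test_that("posteriors are neighbour fractions with documented rejection", {
  # 7 A's closer than 3 B's, plus padding so k = 10 is legal
  trainX <- rbind(matrix(seq(0.1, 0.7, by = 0.1), 7, 1),
                  matrix(seq(0.8, 1.0, by = 0.1), 3, 1),
                  matrix(50 + 1:20, 20, 1))
  trainY <- c(rep("A", 7), rep("B", 3), rep(c("A", "B"), 10))
  clf <- mkClf(trainX, trainY, k = 10)
  res <- classifyCells(clf, matrix(0, 1, 1))
  expect_identical(res$predicted, "A")
  expect_equal(res$posterior, 0.7)
  expect_false(res$rejected)

  # 4/3/3 split: maximal posterior 0.4 < 0.5 rejects as ambiguous
  tr3 <- rbind(matrix(seq(0.1, 1.0, by = 0.1), 10, 1),
               matrix(50 + 1:30, 30, 1))
  y3 <- c(rep(c("A", "B", "C"), c(4, 3, 3)), rep(c("A", "B", "C"), 10))
  clf3 <- mkClf(tr3, y3, k = 10)
  res3 <- classifyCells(clf3, matrix(0, 1, 1))
  expect_true(res3$rejected)
  expect_identical(res3$reason, "posterior")
  expect_equal(res3$posterior, 0.4)
})

test_that("far-away queries are rejected by distance first", {
  means <- matrix(0, 2, 5, dimnames = list(c("A", "B"), NULL))
  means[2, 1] <- 10
  cl <- makeClusters(means, 100, seed = 5)
  clf <- fitNodeClassifier(cl$X, cl$y, hierarchyControl(k = 20))
  far <- matrix(100, 1, 5)
  res <- classifyCells(clf, far)
  expect_true(res$rejected)
  expect_identical(res$reason, "distance")
})

test_that("accepted labels match the exhaustive oracle exactly", {
  withr::with_seed(11, {
    for (rep in 1:3) {
      n <- sample(100:300, 1)
      d <- sample(3:8, 1)
      ncl <- sample(2:4, 1)
      means <- matrix(rnorm(ncl * d, sd = 4), ncl, d,
                      dimnames = list(LETTERS[1:ncl], NULL))
      sizes <- sample(20:60, ncl, replace = TRUE)
      X <- do.call(rbind, lapply(seq_len(ncl), function(i)
        matrix(rnorm(sizes[i] * d), sizes[i], d) +
          matrix(means[i, ], sizes[i], d, byrow = TRUE)))
      y <- rep(LETTERS[1:ncl], sizes)
      Q <- matrix(rnorm(50 * d, sd = 4), 50, d)
      k <- sample(3:15, 1)
      clf <- mkClf(X, y, k)
      res <- classifyCells(clf, Q)
      orc <- oracleKnn(X, y, Q, k)
      expect_identical(res$predicted, orc$pred)
      expect_identical(res$meanDist, orc$meanDist)
      expect_identical(unname(attr(res, "posteriors")),
                       unname(orc$post))
    }
  })
})

test_that("posterior rows sum to one and ordering is immaterial", {
  means <- matrix(c(0, 6), 2, 1, dimnames = list(c("A", "B"), NULL))
  cl <- makeClusters(means, 60, d = 1, seed = 2)
  clf <- fitNodeClassifier(cl$X, cl$y, hierarchyControl(k = 9))
  withr::with_seed(4, Q <- matrix(runif(40, -2, 8), 40, 1))
  res <- classifyCells(clf, Q)
  expect_equal(rowSums(attr(res, "posteriors")), rep(1, 40))

  # permutation equivariance in query order
  perm <- sample(40)
  res2 <- classifyCells(clf, Q[perm, , drop = FALSE])
  expect_identical(res2$predicted, res$predicted[perm])

  # invariance to training-row order (distinct points, no k-th ties)
  ord <- sample(nrow(cl$X))
  clf2 <- fitNodeClassifier(cl$X[ord, , drop = FALSE], cl$y[ord],
                            hierarchyControl(k = 9))
  res3 <- classifyCells(clf2, Q)
  expect_identical(res3$predicted, res$predicted)
})

test_that("disabling all rejections accepts every cell", {
  means <- matrix(c(0, 8), 2, 3)
  rownames(means) <- c("A", "B")
  cl <- makeClusters(means, 80, seed = 6)
  ctl <- hierarchyControl(k = 15, rejectDistance = FALSE,
                          rejectReconstruction = FALSE,
                          rejectPosterior = FALSE)
  clf <- fitNodeClassifier(cl$X, cl$y, ctl)
  Q <- rbind(matrix(100, 5, 3), matrix(0.5, 5, 3))
  res <- classifyCells(clf, Q, ctl)
  expect_false(any(res$rejected))
})

test_that("thresholds act monotonically on acceptance", {
  means <- matrix(c(0, 4), 2, 2)
  rownames(means) <- c("A", "B")
  cl <- makeClusters(means, 70, seed = 8)
  clf <- fitNodeClassifier(cl$X, cl$y, hierarchyControl(k = 10))
  withr::with_seed(5, Q <- matrix(runif(60, -3, 7), 30, 2))
  base <- classifyCells(clf, Q)
  # raising tauPosterior never converts rejected -> accepted
  for (tp in c(0.6, 0.8, 1)) {
    ctl <- hierarchyControl(k = 10, tauPosterior = tp)
    res <- classifyCells(clf, Q, ctl)
    expect_true(all(res$rejected[base$rejected]))
  }
  # raising tauDistance never converts accepted -> rejected
  clfHi <- clf
  clfHi@tauDistance <- clf@tauDistance * 3
  resHi <- classifyCells(clfHi, Q)
  expect_false(any(resHi$rejected[!base$rejected] &
                     resHi$reason[!base$rejected] == "distance"))
})
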