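# Per-node multiclass kNN classifier and its three rejection thresholds.

#' Effective number of neighbours
#'
#' With dynamic neighbour sizing on, the requested k is decreased to the
#' size of the smallest cell type across the direct child classes, so that
#' small populations can still dominate their own neighbourhoods.
#'
#' @param requestedK requested k (>= 1).
#' @param childClassSizes integer vector of per-class training sizes.
#' @param dynamic logical; apply the dynamic rule.
#' @return integer, the k actually used.
#' @examples
#' effectiveK(50, c(1000, 18), dynamic = TRUE)   # 18
#' effectiveK(50, c(1000, 18), dynamic = FALSE)  # 50
#' @export
effectiveK <- function(requestedK, childClassSizes, dynamic = TRUE) {
  if (!length(childClassSizes))
    .satStop("invalidArgumentError", "childClassSizes must be non-empty")
  if (requestedK < 1L || any(childClassSizes < 1L))
    .satStop("invalidArgumentError",
             "requestedK and all class sizes must be >= 1")
  if (isTRUE(dynamic))
    as.integer(min(requestedK, min(childClassSizes)))
  else
    as.integer(requestedK)
}

#' Distance rejection threshold
#'
#' For every training cell, the distance to its \code{kEffective} nearest
#' training neighbours (self excluded) is averaged; the threshold is the
#' 99th percentile of those means (linear interpolation between order
#' statistics, \code{stats::quantile} type 7).
#'
#' @param trainX training coordinate matrix (n x d), n > kEffective.
#' @param kEffective number of neighbours.
#' @param metric distance metric (only \code{"euclidean"}).
#' @return numeric threshold (>= 0).
#' @export
fitDistanceThreshold <- function(trainX, kEffective,
                                 metric = "euclidean") {
  trainX <- as.matrix(trainX)
  n <- nrow(trainX)
  if (n <= kEffective)
    .satStop("invalidArgumentError",
             sprintf("need n > k (n = %d, k = %d)", n, kEffective))
  nn <- .knnSearch(trainX, trainX, kEffective, excludeSelf = TRUE)
  meanD <- rowMeans(nn$dist)
  unname(stats::quantile(meanD, 0.99, type = 7, names = FALSE))
}

.pcaBasis <- function(X, varianceKept) {
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  tot <- sum(v)
  rank <- if (tot <= 0) 0L
  else which(cumsum(v) / tot >= varianceKept - 1e-12)[1L]
  list(rotation = p$rotation[, seq_len(rank), drop = FALSE],
       center = p$center, rank = as.integer(rank), d = ncol(X))
}

# Squared reconstruction error ||x - decode(encode(x))||^2 under the PCA
# basis. With a full-rank basis the projection is the identity, so errors
# are exactly zero by construction.
.reconErrors <- function(basis, Q) {
  Q <- as.matrix(Q)
  if (basis$rank >= basis$d) return(rep(0, nrow(Q)))
  C <- sweep(Q, 2L, basis$center)
  if (basis$rank == 0L) return(rowSums(C^2))
  Z <- C %*% basis$rotation
  rowSums((C - Z %*% t(basis$rotation))^2)
}

.stratifiedFolds <- function(y, nFolds, seed) {
  folds <- integer(length(y))
  .withSeed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  folds
}

#' Reconstruction-error rejection threshold
#'
#' Nested cross-validation: in each outer fold a PCA basis retaining
#' \code{varianceKept} of the variance is fitted on the training part and
#' squared reconstruction errors are computed for the test part; the
#' \code{1 - fnRate} quantile of each fold's errors is recorded and the
#' threshold is the median of those per-fold quantiles (so roughly
#' \code{fnRate} of held-out inliers exceed it). The returned basis is
#' refit on all cells.
#'
#' @param trainX training coordinates (n x d), n >= nFolds.
#' @param trainY optional class labels used to stratify the folds.
#' @param fnRate target false-negative fraction, strictly in (0, 1);
#'   default 0.005.
#' @param nFolds number of outer folds (default 5).
#' @param varianceKept PCA variance fraction retained (default 0.9).
#' @param seed fold-assignment seed.
#' @return list with elements \code{tau}, \code{rotation}, \code{center},
#'   \code{rank}.
#' @export
fitReconstructionThreshold <- function(trainX, trainY = NULL,
                                       fnRate = 0.005, nFolds = 5L,
                                       varianceKept = 0.9, seed = 1L) {
  trainX <- as.matrix(trainX)
  n <- nrow(trainX)
  if (fnRate <= 0 || fnRate >= 1)
    .satStop("invalidArgumentError", "fnRate must lie strictly in (0, 1)")
  if (n < nFolds)
    .satStop("invalidArgumentError",
             sprintf("need n >= nFolds (n = %d, folds = %d)", n, nFolds))
  y <- if (is.null(trainY)) rep("all", n) else as.character(trainY)
  folds <- .stratifiedFolds(y, nFolds, seed)
  qs <- vapply(seq_len(nFolds), function(f) {
    tr <- trainX[folds != f, , drop = FALSE]
    te <- trainX[folds == f, , drop = FALSE]
    if (!nrow(te) || !nrow(tr)) return(NA_real_)
    basis <- .pcaBasis(tr, varianceKept)
    err <- .reconErrors(basis, te)
    stats::quantile(err, 1 - fnRate, type = 7, names = FALSE)
  }, numeric(1))
  tau <- stats::median(qs, na.rm = TRUE)
  basis <- .pcaBasis(trainX, varianceKept)
  list(tau = unname(tau), rotation = basis$rotation,
       center = basis$center, rank = basis$rank)
}

#' Fit a per-node multiclass kNN classifier
#'
#' Fits the neighbour index and the distance and reconstruction rejection
#' thresholds for one parent node, given the pooled training cells of its
#' direct children (a child's pool is every cell housed at or below it).
#'
#' @param trainX pooled training coordinates (n x d).
#' @param trainY character/factor of child class names, one per row.
#' @param control see \code{\link{hierarchyControl}}.
#' @param parentNode name of the parent node (bookkeeping only).
#' @return A fitted \linkS4class{NodeClassifier}.
#' @export
fitNodeClassifier <- function(trainX, trainY,
                              control = hierarchyControl(),
                              parentNode = "node") {
  trainX <- as.matrix(trainX)
  storage.mode(trainX) <- "double"
  trainY <- as.character(trainY)
  if (nrow(trainX) != length(trainY))
    .satStop("invalidArgumentError", "trainX/trainY length mismatch")
  classNames <- sort(unique(trainY))
  if (length(classNames) < 2L)
    .satStop("degenerateNodeError",
             sprintf("node '%s' has < 2 child classes; it acts as a pass-through",
                     parentNode))
  sizes <- as.integer(table(factor(trainY, levels = classNames)))
  if (any(sizes == 0L))
    .satStop("validationError", "a child class has no training cells")
  kEff <- effectiveK(control$k, sizes, control$dynamicNeighbors)
  if (nrow(trainX) <= kEff)
    .satStop("invalidArgumentError",
             "k must be smaller than the pooled training size")
  tauD <- fitDistanceThreshold(trainX, kEff, control$metric)
  rec <- fitReconstructionThreshold(trainX, trainY,
                                    fnRate = control$fnRate,
                                    nFolds = control$nFolds,
                                    varianceKept = control$varianceKept,
                                    seed = control$seed)
  new("NodeClassifier", parentNode = parentNode, classNames = classNames,
      kEffective = kEff, trainX = trainX,
      trainY = match(trainY, classNames),
      tauPosterior = control$tauPosterior, tauDistance = tauD,
      tauReconstruction = rec$tau, pcaRotation = rec$rotation,
      pcaCenter = rec$center, pcaRank = rec$rank,
      metric = control$metric)
}

#' Classify query cells at one node, with rejection
#'
#' For each query cell the \code{kEffective} nearest training cells are
#' found; the posterior for class c is the fraction of those neighbours
#' labeled c and the predicted class is the argmax (ties broken by the
#' smallest summed neighbour distance, then lexicographically). The three
#' rejection criteria are evaluated in the order distance,
#' reconstruction, posterior, and the first that fires is reported;
#' comparisons are strict (equality accepts). Posteriors are always
#' returned, also for rejected cells.
#'
#' @param clf a fitted \linkS4class{NodeClassifier}.
#' @param Q query coordinates (m x d).
#' @param control rejection toggles etc.; defaults to the thresholds
#'   stored in \code{clf} with all three rejections enabled.
#' @return data.frame with columns \code{predicted}, \code{posterior},
#'   \code{meanDist}, \code{reconError}, \code{rejected}, \code{reason};
#'   the full m x classes posterior matrix is attached as attribute
#'   \code{"posteriors"}.
#' @export
classifyCells <- function(clf, Q, control = NULL) {
  stopifnot(is(clf, "NodeClassifier"))
  Q <- as.matrix(Q)
  if (ncol(Q) != ncol(clf@trainX))
    .satStop("dimensionError",
             sprintf("query has %d dims, classifier expects %d",
                     ncol(Q), ncol(clf@trainX)))
  if (any(!is.finite(Q)))
    .satStop("validationError", "query coordinates must be finite")
  rejD <- if (is.null(control)) TRUE else isTRUE(control$rejectDistance)
  rejR <- if (is.null(control)) TRUE
          else isTRUE(control$rejectReconstruction)
  rejP <- if (is.null(control)) TRUE else isTRUE(control$rejectPosterior)
  tauP <- if (is.null(control) || is.null(control$tauPosterior))
    clf@tauPosterior else control$tauPosterior

  m <- nrow(Q)
  nc <- length(clf@classNames)
  nn <- .knnSearch(clf@trainX, Q, clf@kEffective)
  post <- matrix(0, m, nc, dimnames = list(NULL, clf@classNames))
  predicted <- character(m)
  meanDist <- numeric(m)
  reconErr <- .reconErrors(list(rotation = clf@pcaRotation,
                                center = clf@pcaCenter,
                                rank = clf@pcaRank,
                                d = ncol(clf@trainX)), Q)
  for (i in seq_len(m)) {
    lab <- clf@trainY[nn$idx[i, ]]
    cnt <- tabulate(lab, nbins = nc)
    post[i, ] <- cnt / clf@kEffective
    meanDist[i] <- mean(nn$dist[i, ])
    best <- which(cnt == max(cnt))
    if (length(best) > 1L) {
      sums <- vapply(best, function(b)
        sum(nn$dist[i, ][lab == b]), numeric(1))
      best <- best[sums == min(sums)]
      if (length(best) > 1L)
        best <- best[order(clf@classNames[best])][1L]
    }
    predicted[i] <- clf@classNames[best[1L]]
  }
  maxPost <- apply(post, 1L, max)
  reason <- character(m)
  reason[rejD & meanDist > clf@tauDistance] <- "distance"
  idx <- !nzchar(reason) & rejR & reconErr > clf@tauReconstruction
  reason[idx] <- "reconstruction"
  idx <- !nzchar(reason) & rejP & maxPost < tauP
  reason[idx] <- "posterior"
  out <- data.frame(predicted = predicted, posterior = maxPost,
                    meanDist = meanDist, reconError = reconErr,
                    rejected = nzchar(reason), reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "posteriors") <- post
  out
}
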