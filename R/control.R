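#' Fitting and matching parameters
#'
#' Collects every tunable knob of the hierarchy machinery with its
#' default. All classifier fitting, matching and prediction functions take
#' such a list.
#'
#' @param k requested number of neighbours for the kNN classifiers
#'   (default 50).
#' @param dynamicNeighbors when \code{TRUE} (default), \code{k} is
#'   automatically decreased to the size of the smallest cell type across
#'   the direct child classes of a node, so each node classifier may end up
#'   with its own effective k.
#' @param tauPosterior posterior-probability rejection threshold (default
#'   0.5); a cell whose maximal class posterior is strictly below it is
#'   ambiguous.
#' @param fnRate target fraction of held-out inliers rejected by the
#'   reconstruction-error criterion (default 0.005, i.e. 0.5\%).
#' @param varianceKept fraction of variance retained by the PCA basis used
#'   for the reconstruction error (default 0.9).
#' @param nFolds outer folds of the nested cross-validation that fits the
#'   reconstruction threshold (default 5, stratified by class).
#' @param matchThreshold binarization threshold on row-normalized
#'   confusion fractions (default 0.25); an entry at or above it counts as
#'   a match.
#' @param metric distance metric; only \code{"euclidean"} is supported.
#' @param rejectDistance,rejectReconstruction,rejectPosterior independent
#'   toggles for the three rejection criteria (all default \code{TRUE}).
#' @param seed integer seed controlling the stochastic parts of fitting
#'   (cross-validation fold assignment).
#'
#' @return A named list of parameters.
#' @examples
#' ctl <- hierarchyControl(k = 30, tauPosterior = 0.25)
#' @export
hierarchyControl <- function(k = 50L,
                             dynamicNeighbors = TRUE,
                             tauPosterior = 0.5,
                             fnRate = 0.005,
                             varianceKept = 0.9,
                             nFolds = 5L,
                             matchThreshold = 0.25,
                             metric = "euclidean",
                             rejectDistance = TRUE,
                             rejectReconstruction = TRUE,
                             rejectPosterior = TRUE,
                             seed = 1L) {
  if (k < 1L) .satStop("invalidArgumentError", "k must be >= 1")
  if (tauPosterior < 0 || tauPosterior > 1)
    .satStop("invalidArgumentError", "tauPosterior must lie in [0, 1]")
  if (fnRate <= 0 || fnRate >= 1)
    .satStop("invalidArgumentError", "fnRate must lie strictly in (0, 1)")
  if (varianceKept <= 0 || varianceKept > 1)
    .satStop("invalidArgumentError", "varianceKept must lie in (0, 1]")
  if (matchThreshold <= 0 || matchThreshold >= 1)
    .satStop("invalidArgumentError",
             "matchThreshold must lie strictly in (0, 1)")
  if (!identical(metric, "euclidean"))
    .satStop("invalidArgumentError",
             sprintf("unsupported metric '%s'", metric))
  list(k = as.integer(k),
       dynamicNeighbors = isTRUE(dynamicNeighbors),
       tauPosterior = tauPosterior,
       fnRate = fnRate,
       varianceKept = varianceKept,
       nFolds = as.integer(nFolds),
       matchThreshold = matchThreshold,
       metric = metric,
       rejectDistance = isTRUE(rejectDistance),
       rejectReconstruction = isTRUE(rejectReconstruction),
       rejectPosterior = isTRUE(rejectPosterior),
       seed = as.integer(seed))
}

# Run code with a local RNG state so fitting never perturbs the caller's
# random stream.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
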