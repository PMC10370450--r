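# Synthetic latent-space generator with known ground-truth hierarchy.
#
# Emulates the output of a well-integrated reference-building model:
# hierarchically structured, well-mixed Gaussian clusters (isotropic unit
# within-cluster sigma; separations expressed in sigma units so scenario
# difficulty is scale-free), per-dataset annotation-resolution relabeling,
# dataset-specific novel clusters at a stated offset, and an optional
# residual per-dataset batch translation.

.unitDir <- function(d) {
  z <- stats::rnorm(d)
  z / sqrt(sum(z^2))
}

# largest-remainder apportionment of n into parts proportional to w
.apportion <- function(w, n) {
  raw <- w / sum(w) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(-(raw - base), seq_along(w))
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

.walkSpec <- function(spec, parent = NA_character_, acc = NULL) {
  if (is.null(acc)) acc <- list(rows = list())
  acc$rows[[length(acc$rows) + 1L]] <-
    list(name = spec$name, parent = parent,
         weight = if (is.null(spec$weight)) NA_real_ else spec$weight,
         leaf = is.null(spec$children) || !length(spec$children))
  for (ch in spec$children) acc <- .walkSpec(ch, spec$name, acc)
  acc
}

.specIndex <- function(treeSpec) {
  acc <- .walkSpec(treeSpec)
  nm <- vapply(acc$rows, `[[`, "", "name")
  if (anyDuplicated(nm))
    .satStop("invalidArgumentError", "treeSpec node names must be unique")
  list(rows = stats::setNames(acc$rows, nm), names = nm)
}

.specAncestors <- function(idx, name) {
  out <- character()
  cur <- idx$rows[[name]]$parent
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- idx$rows[[cur]]$parent
  }
  out
}

#' Synthetic scenario configuration
#'
#' @param treeSpec nested list describing the ground-truth hierarchy:
#'   each node is \code{list(name = , children = list(...))}, leaves carry
#'   a \code{weight} (relative mixing proportion). The root's name is the
#'   tree's root.
#' @param d latent dimensionality (default 10).
#' @param separation inter-cluster mean offset, in units of the
#'   within-cluster standard deviation (child mean = parent mean + an
#'   isotropic offset of this norm; default 8).
#' @param nCells cells per dataset (apportioned across leaves by weight,
#'   largest-remainder rule).
#' @param datasets list of per-dataset entries:
#'   \code{list(id = , resolutionMap = c(leaf = ancestor, ...),
#'   novel = list(list(name = , offset = , n = ), ...), role = )}.
#'   \code{resolutionMap} relabels a leaf to one of its ancestors
#'   (annotation at coarser resolution); \code{novel} adds
#'   dataset-specific clusters whose mean sits at \code{offset} sigma
#'   from the root mean; \code{role} is \code{"reference"} (default) or
#'   \code{"query"}.
#' @param batchShift per-dataset residual translation magnitude in sigma
#'   units (default 0: perfectly integrated).
#' @param seed integer; the same seed yields bit-identical output.
#' @return validated config list (class \code{"syntheticConfig"}).
#' @export
syntheticConfig <- function(treeSpec, d = 10L, separation = 8,
                            nCells = 1000L, datasets,
                            batchShift = 0, seed = 0L) {
  if (separation <= 0)
    .satStop("invalidArgumentError", "separation must be > 0")
  idx <- .specIndex(treeSpec)
  leaves <- idx$names[vapply(idx$rows, `[[`, TRUE, "leaf")]
  w <- vapply(leaves, function(l) idx$rows[[l]]$weight, numeric(1))
  if (anyNA(w) || any(w <= 0))
    .satStop("invalidArgumentError",
             "every leaf needs a positive mixing weight")
  for (ds in datasets) {
    rm <- ds$resolutionMap
    if (is.null(rm)) next
    for (src in names(rm)) {
      if (!src %in% leaves)
        .satStop("validationError",
                 sprintf("resolutionMap source '%s' is not a leaf", src))
      if (!rm[[src]] %in% .specAncestors(idx, src))
        .satStop("validationError",
                 sprintf("relabel target '%s' is not an ancestor of '%s'",
                         rm[[src]], src))
    }
  }
  structure(list(treeSpec = treeSpec, d = as.integer(d),
                 separation = separation, nCells = as.integer(nCells),
                 datasets = datasets, batchShift = batchShift,
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Generate synthetic latent datasets with ground truth
#'
#' Leaf means are drawn hierarchically (each child mean is its parent's
#' mean plus an isotropic offset of norm \code{separation}), cells are
#' Gaussian with unit isotropic variance around their leaf mean, labels
#' follow each dataset's resolution map, novel clusters are placed at
#' their stated offsets from the root mean, and an optional per-dataset
#' batch translation is applied. Output is deterministic given the seed.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{datasets} (list of
#'   \linkS4class{LabeledEmbedding}), \code{roles} (named character), and
#'   \code{truth}: the ground-truth \linkS4class{CellHierarchy} (aliases
#'   attached per dataset), its \linkS4class{EdgeGraph}, the
#'   \code{nameMap} (dataset, label, node) for
#'   \code{\link{treeToGraph}}/\code{\link{compareGraphs}}, and
#'   \code{leafLabels}, the per-dataset true leaf labels before
#'   relabeling.
#' @examples
#' sim <- simulateDatasets(presetScenario("equal-resolution-permutation"))
#' names(sim$datasets)
#' @export
simulateDatasets <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  idx <- .specIndex(config$treeSpec)
  leaves <- idx$names[vapply(idx$rows, `[[`, TRUE, "leaf")]
  w <- vapply(leaves, function(l) idx$rows[[l]]$weight, numeric(1))
  d <- config$d

  out <- .withSeed(config$seed, {
    means <- list()
    assignMeans <- function(spec, parentMean) {
      means[[spec$name]] <<- if (is.na(parentMean[1L])) rep(0, d)
      else parentMean + config$separation * .unitDir(d)
      for (ch in spec$children) assignMeans(ch, means[[spec$name]])
    }
    assignMeans(config$treeSpec, NA_real_)

    datasets <- list()
    leafLabels <- list()
    for (ds in config$datasets) {
      counts <- .apportion(w, config$nCells)
      Xs <- list(); true <- character(); lab <- character()
      for (j in seq_along(leaves)) {
        nl <- counts[j]
        if (!nl) next
        M <- matrix(stats::rnorm(nl * d), nl, d) +
          matrix(means[[leaves[j]]], nl, d, byrow = TRUE)
        Xs[[length(Xs) + 1L]] <- M
        true <- c(true, rep(leaves[j], nl))
        rl <- unname(ds$resolutionMap[leaves[j]])
        if (is.null(rl) || is.na(rl)) rl <- leaves[j]
        lab <- c(lab, rep(rl, nl))
      }
      for (nv in ds$novel) {
        mu <- nv$offset * .unitDir(d)
        M <- matrix(stats::rnorm(nv$n * d), nv$n, d) +
          matrix(mu, nv$n, d, byrow = TRUE)
        Xs[[length(Xs) + 1L]] <- M
        true <- c(true, rep(nv$name, nv$n))
        lab <- c(lab, rep(nv$name, nv$n))
      }
      X <- do.call(rbind, Xs)
      if (config$batchShift > 0)
        X <- X + matrix(config$batchShift * .unitDir(d),
                        nrow(X), d, byrow = TRUE)
      datasets[[ds$id]] <- LabeledEmbedding(
        X, ds$id, cellIds = paste0(ds$id, "_", seq_len(nrow(X))),
        labels = lab)
      leafLabels[[ds$id]] <- true
    }
    list(datasets = datasets, leafLabels = leafLabels)
  })

  # ground truth: which (dataset, label) alias sits at which spec node
  usedBy <- list()   # spec/novel node name -> character of dataset ids
  novelOf <- list()  # dataset id -> novel names, in order
  for (ds in config$datasets) {
    labs <- unique(out$datasets[[ds$id]]@labels)
    for (lb in labs) usedBy[[lb]] <- c(usedBy[[lb]], ds$id)
    novelOf[[ds$id]] <- vapply(ds$novel, `[[`, "", "name")
  }
  truthTree <- createHierarchy(config$treeSpec$name)
  addTruth <- function(spec, parentName) {
    for (ch in spec$children) {
      dsIds <- usedBy[[ch$name]]
      if (!is.null(dsIds)) {
        al <- data.frame(dataset = dsIds, label = ch$name,
                         stringsAsFactors = FALSE)
        truthTree <<- addNode(truthTree, parentName, al, name = ch$name)
        addTruth(ch, ch$name)
      } else {
        # unused intermediate resolution: promote its children
        addTruth(ch, parentName)
      }
    }
  }
  addTruth(config$treeSpec, config$treeSpec$name)
  for (dsId in names(novelOf)) {
    for (nv in novelOf[[dsId]]) {
      truthTree <- addNode(truthTree, config$treeSpec$name,
                           c(dsId, nv), name = nv)
    }
  }
  truthTree@datasetIds <- vapply(config$datasets, `[[`, "", "id")
  at <- aliasTable(truthTree)
  nameMap <- data.frame(dataset = at$dataset, label = at$label,
                        node = at$node, stringsAsFactors = FALSE)
  roles <- vapply(config$datasets, function(ds)
    if (is.null(ds$role)) "reference" else ds$role, "")
  names(roles) <- vapply(config$datasets, `[[`, "", "id")
  list(datasets = out$datasets, roles = roles,
       truth = list(tree = truthTree,
                    graph = treeToGraph(truthTree),
                    nameMap = nameMap,
                    leafLabels = out$leafLabels))
}

#' Preset synthetic scenarios
#'
#' \describe{
#' \item{"pbmc-like-ladder"}{Three reference datasets annotated at
#'   coarse, mid and fine resolution over a 3-level immune-like hierarchy
#'   (lymphoid "Group 1" splitting into T/NK/B, T into CD4+/CD8+;
#'   monocytes into CD14+/CD16+; HSPCs), plus one fine-resolution query
#'   carrying two small dataset-specific populations of 21 (plasma
#'   cells) and 18 (MK progenitors) cells at 10 sigma.}
#' \item{"novelty-stress"}{Two equal-resolution datasets over three cell
#'   types, each dataset carrying one 10-sigma novel cluster of its own.}
#' \item{"equal-resolution-permutation"}{Three identically labeled
#'   datasets over three cell types; building from any permutation must
#'   give the same edge graph.}
#' }
#'
#' @param name one of the preset names above.
#' @param seed generator seed (default 0).
#' @return a \code{\link{syntheticConfig}}.
#' @export
presetScenario <- function(name = c("pbmc-like-ladder", "novelty-stress",
                                    "equal-resolution-permutation"),
                           seed = 0L) {
  name <- match.arg(name)
  if (name == "pbmc-like-ladder") {
    spec <- list(name = "root", children = list(
      list(name = "Group 1", children = list(
        list(name = "T cells", children = list(
          list(name = "CD4+ T cells", weight = 1),
          list(name = "CD8+ T cells", weight = 1))),
        list(name = "NK cells", weight = 1.5),
        list(name = "B cells", weight = 1.5))),
      list(name = "Monocytes", children = list(
        list(name = "CD14+ Monocytes", weight = 1),
        list(name = "CD16+ Monocytes", weight = 1))),
      list(name = "HSPC", weight = 1)))
    coarse <- c("CD4+ T cells" = "Group 1", "CD8+ T cells" = "Group 1",
                "NK cells" = "Group 1", "B cells" = "Group 1",
                "CD14+ Monocytes" = "Monocytes",
                "CD16+ Monocytes" = "Monocytes")
    mid <- c("CD4+ T cells" = "T cells", "CD8+ T cells" = "T cells",
             "CD14+ Monocytes" = "Monocytes",
             "CD16+ Monocytes" = "Monocytes")
    syntheticConfig(
      spec, d = 10L, separation = 8, nCells = 1200L,
      datasets = list(
        list(id = "sun", resolutionMap = coarse, role = "reference"),
        list(id = "oetjen", resolutionMap = mid, role = "reference"),
        list(id = "freytag", role = "reference"),
        list(id = "tenx", role = "query",
             novel = list(
               list(name = "Plasma cells", offset = 10, n = 21L),
               list(name = "MK progenitors", offset = 10, n = 18L)))),
      seed = seed)
  } else if (name == "novelty-stress") {
    spec <- list(name = "root", children = list(
      list(name = "alpha", weight = 1),
      list(name = "beta", weight = 1),
      list(name = "gamma", weight = 1)))
    syntheticConfig(
      spec, d = 10L, separation = 8, nCells = 450L,
      datasets = list(
        list(id = "study1",
             novel = list(list(name = "novel1", offset = 10, n = 100L))),
        list(id = "study2",
             novel = list(list(name = "novel2", offset = 10, n = 100L)))),
      seed = seed)
  } else {
    spec <- list(name = "root", children = list(
      list(name = "alpha", weight = 1),
      list(name = "beta", weight = 1),
      list(name = "gamma", weight = 1)))
    syntheticConfig(
      spec, d = 10L, separation = 8, nCells = 450L,
      datasets = list(list(id = "study1"), list(id = "study2"),
                      list(id = "study3")),
      seed = seed)
  }
}
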