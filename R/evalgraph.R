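# Edge-level scoring of a learned hierarchy against ground truth.

.edgeKeys <- function(graph) {
  if (!nrow(graph@edges)) return(character())
  paste(graph@edges$ancestor, graph@edges$descendant, sep = "\r")
}

#' Compare two ancestor-descendant edge graphs
#'
#' Directed set differences: edges in both graphs are correct, edges only
#' in the learned graph are wrong, edges only in the truth are missing
#' (an inverted relation therefore counts as one wrong plus one missing).
#' Learned nodes are typically mapped into the truth's name space first
#' via \code{\link{treeToGraph}}'s \code{nameMap}; edges involving an
#' \code{"UNMAPPED:"} node are reported as wrong with that reason rather
#' than silently dropped.
#'
#' @param learned,truth \linkS4class{EdgeGraph} objects over a shared
#'   (reconciled) name universe.
#' @return A \linkS4class{GraphComparison}.
#' @examples
#' tr <- createHierarchy()
#' tr <- addNode(tr, "root", c("s", "A"))
#' tr <- addNode(tr, "A", c("s", "B"))
#' g <- treeToGraph(tr)
#' compareGraphs(g, g)
#' @export
compareGraphs <- function(learned, truth) {
  stopifnot(is(learned, "EdgeGraph"), is(truth, "EdgeGraph"))
  lk <- .edgeKeys(learned)
  tk <- .edgeKeys(truth)
  correct <- learned@edges[lk %in% tk, , drop = FALSE]
  wrong <- learned@edges[!lk %in% tk, , drop = FALSE]
  missing <- truth@edges[!tk %in% lk, , drop = FALSE]
  if (nrow(wrong)) {
    unmapped <- grepl("^UNMAPPED:", wrong$ancestor) |
      grepl("^UNMAPPED:", wrong$descendant)
    wrong$reason <- ifelse(unmapped, "unmappable node", "not in truth")
  } else {
    wrong$reason <- character()
  }
  rownames(correct) <- rownames(wrong) <- rownames(missing) <- NULL
  new("GraphComparison", correct = correct, wrong = wrong,
      missing = missing)
}

#' Write a graph comparison report
#'
#' @param comparison a \linkS4class{GraphComparison}.
#' @param path output path without extension-specific meaning;
#'   \code{format = "json"} writes counts + per-edge listings as JSON,
#'   \code{"tsv"} writes the per-edge listings (columns ancestor,
#'   descendant, status), \code{"txt"} a human-readable summary.
#' @param format one of \code{"json"}, \code{"tsv"}, \code{"txt"}.
#' @return \code{path}, invisibly.
#' @export
writeComparison <- function(comparison, path,
                            format = c("json", "tsv", "txt")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(correct = nrow(comparison@correct),
                wrong = nrow(comparison@wrong),
                missing = nrow(comparison@missing),
                wrong_edges = comparison@wrong,
                missing_edges = comparison@missing)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (format == "tsv") {
    df <- rbind(
      if (nrow(comparison@correct))
        cbind(comparison@correct, status = "correct"),
      if (nrow(comparison@wrong))
        cbind(comparison@wrong[, c("ancestor", "descendant")],
              status = "wrong"),
      if (nrow(comparison@missing))
        cbind(comparison@missing, status = "missing"))
    if (is.null(df))
      df <- data.frame(ancestor = character(), descendant = character(),
                       status = character())
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(c(
      sprintf("correct edges: %d", nrow(comparison@correct)),
      sprintf("wrong edges:   %d", nrow(comparison@wrong)),
      sprintf("missing edges: %d", nrow(comparison@missing))), path)
  }
  invisible(path)
}
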