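# Reading and writing labeled latent embeddings and prediction tables.
#
# TSV dialect: tab-separated with a header row; column `cell_id`, then one
# column per latent dimension, then (optionally) the label column. Floats
# are written with 17 significant digits so a write/read round trip is
# exact for double precision.

#' Read a labeled latent embedding
#'
#' @param path input file.
#' @param format \code{"tsv"} (native dialect, see Details) or
#'   \code{"h5ad"} (HDF5 single-cell container; the embedding is read from
#'   the multidimensional-observation group under \code{latentKey} and the
#'   labels from the per-cell annotation table under \code{labelKey}; the
#'   expression matrix is ignored). Reading h5ad requires the
#'   \code{python} interpreter with \code{h5py} on the PATH.
#' @param latentKey name of the embedding slot for h5ad input (e.g.
#'   \code{"X_scVI"}); ignored for TSV.
#' @param labelKey name of the label column (\code{"label"} for TSV), or
#'   \code{NULL} for an unlabeled query dataset.
#' @param datasetId dataset identifier to assign.
#' @return A validated \linkS4class{LabeledEmbedding}; row order is
#'   preserved from the file.
#' @export
readEmbedding <- function(path, format = c("tsv", "h5ad"),
                          latentKey = "X_latent", labelKey = "label",
                          datasetId) {
  format <- match.arg(format)
  if (!file.exists(path))
    .satStop("notFoundError", sprintf("no such file: %s", path))
  if (format == "h5ad") {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp), add = TRUE)
    helper <- system.file("python", "read_h5ad.py",
                          package = "scAtlasTree", mustWork = TRUE)
    st <- suppressWarnings(
      system2("python",
              c(helper, shQuote(path), shQuote(latentKey),
                shQuote(if (is.null(labelKey)) "" else labelKey),
                shQuote(tmp)),
              stdout = TRUE, stderr = TRUE))
    code <- attr(st, "status")
    if (!is.null(code) && code != 0L)
      .satStop("notFoundError",
               sprintf("h5ad reader failed: %s", paste(st, collapse = " ")))
    path <- tmp
  }
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      check.names = FALSE, quote = "",
                      comment.char = "", stringsAsFactors = FALSE),
    error = function(e) .satStop("parseError", conditionMessage(e)))
  if (!"cell_id" %in% colnames(df))
    .satStop("notFoundError", "embedding TSV lacks a 'cell_id' column")
  labKey <- if (format == "h5ad" && !is.null(labelKey)) "label"
            else labelKey
  labels <- NULL
  if (!is.null(labKey) && labKey %in% colnames(df))
    labels <- as.character(df[[labKey]])
  else if (!is.null(labelKey) && format == "tsv" &&
           !labelKey %in% colnames(df) && labelKey != "label")
    .satStop("notFoundError",
             sprintf("label column '%s' not found", labelKey))
  cand <- setdiff(colnames(df), c("cell_id", labKey))
  num <- cand[vapply(df[cand], is.numeric, logical(1))]
  if (!length(num))
    .satStop("validationError", "no numeric latent columns found")
  X <- as.matrix(df[, num, drop = FALSE])
  if (any(!is.finite(X)))
    .satStop("validationError",
             "embedding contains missing or non-finite values")
  dimnames(X) <- NULL
  LabeledEmbedding(X, datasetId, cellIds = df$cell_id, labels = labels)
}

#' Write a labeled embedding in the native TSV dialect
#'
#' @param emb a \linkS4class{LabeledEmbedding}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEmbedding <- function(emb, path) {
  stopifnot(is(emb, "LabeledEmbedding"))
  X <- latentCoords(emb)
  cols <- c("cell_id", paste0("dim_", seq_len(ncol(X))),
            if (isLabeled(emb)) "label")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  num <- apply(X, 2L, function(col) sprintf("%.17g", col))
  if (nrow(X) == 1L) num <- matrix(num, nrow = 1L)
  body <- cbind(emb@cellIds, num,
                if (isLabeled(emb)) emb@labels)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write hierarchical predictions as TSV
#'
#' Columns: \code{cell_id}, \code{predicted_label}, \code{path} (the
#' root-to-label chain, "/"-joined), \code{rejected} (true/false) and
#' \code{rejection_reason} (\code{posterior}, \code{reconstruction},
#' \code{distance} or empty).
#'
#' @param result a \linkS4class{PredictionResult}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(result, path) {
  stopifnot(is(result, "PredictionResult"))
  df <- data.frame(
    cell_id = result@cellIds,
    predicted_label = result@finalLabel,
    path = vapply(result@paths, paste, "", collapse = "/"),
    rejected = ifelse(result@rejected, "true", "false"),
    rejection_reason = result@reason,
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) .satStop("ioError", conditionMessage(e)))
  invisible(path)
}

#' Read back a prediction TSV
#'
#' @param path file written by \code{\link{writePredictions}}.
#' @return data.frame with the five prediction columns.
#' @export
readPredictions <- function(path) {
  if (!file.exists(path))
    .satStop("notFoundError", sprintf("no such file: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Export a confusion matrix as TSV
#'
#' Row-normalized fractions; the reserved \code{REJECTED} column is kept
#' last.
#'
#' @param conf numeric confusion matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConfusion <- function(conf, path) {
  cols <- colnames(conf)
  if ("REJECTED" %in% cols)
    conf <- conf[, c(setdiff(cols, "REJECTED"), "REJECTED"),
                 drop = FALSE]
  utils::write.table(
    data.frame(label = rownames(conf), conf, check.names = FALSE,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
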