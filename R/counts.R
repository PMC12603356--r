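#' Count matrix container
#'
#' A light S3 container for non-negative integer expression counts with genes
#' in rows. Columns are cells, samples, or pseudo-bulk groups depending on
#' \code{column_kind}.
#'
#' @param values numeric matrix or \code{Matrix::dgCMatrix} of non-negative
#'   integer counts, genes in rows.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   rownames).
#' @param column_ids character vector of unique column identifiers (defaults
#'   to colnames).
#' @param column_kind one of \code{"cell"}, \code{"sample"},
#'   \code{"pseudobulk"}.
#' @return an object of class \code{count_matrix}: a list with elements
#'   \code{values}, \code{gene_ids}, \code{column_ids}, \code{column_kind}.
#' @examples
#' m <- matrix(c(0, 1, 2, 0, 5, 5), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' cm <- count_matrix(m)
#' dim(cm$values)
#' @export
count_matrix <- function(values,
                         gene_ids = rownames(values),
                         column_ids = colnames(values),
                         column_kind = c("cell", "sample", "pseudobulk")) {
  column_kind <- match.arg(column_kind)
  if (is.null(gene_ids) || is.null(column_ids))
    stop("gene_ids and column_ids are required (or provide dimnames)")
  gene_ids <- as.character(gene_ids)
  column_ids <- as.character(column_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)")
  if (length(column_ids) != ncol(values))
    stop("length(column_ids) must equal ncol(values)")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(column_ids)) stop("duplicate column ids")
  vals_num <- if (methods::is(values, "sparseMatrix")) values@x else values
  if (length(vals_num) && (anyNA(vals_num) || min(vals_num) < 0))
    stop("counts must be non-negative and non-missing")
  if (length(vals_num) && any(abs(vals_num - round(vals_num)) > 1e-8))
    stop("counts must be integral")
  dimnames(values) <- list(gene_ids, column_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 column_ids = column_ids, column_kind = column_kind),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d columns (%s)\n",
              length(x$gene_ids), length(x$column_ids), x$column_kind))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

# Subset a count_matrix by gene and/or column index, keeping class and kind.
subset_counts <- function(x, genes = NULL, cols = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cols)) v <- v[, cols, drop = FALSE]
  count_matrix(v, column_kind = x$column_kind)
}

#' Read a count matrix from disk
#'
#' Supports the 10x-style MatrixMarket triplet (\code{matrix.mtx} with
#' \code{features.tsv} and \code{barcodes.tsv} sidecars, genes in rows) and a
#' dense TSV whose first column holds gene ids and whose header row holds
#' column ids.
#'
#' @param path for \code{"mtx_triplet"}, a directory containing
#'   \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv} (or the path
#'   of the \code{.mtx} file itself, with sidecars alongside); for
#'   \code{"dense_tsv"}, the TSV file.
#' @param format \code{"mtx_triplet"} or \code{"dense_tsv"}.
#' @param column_kind column interpretation, default \code{"cell"}.
#' @return a \code{\link{count_matrix}}.
#' @export
read_counts <- function(path, format = c("mtx_triplet", "dense_tsv"),
                        column_kind = "cell") {
  format <- match.arg(format)
  if (format == "dense_tsv") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- gene_ids
    return(count_matrix(m, column_kind = column_kind))
  }
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
  } else {
    mtx <- path
    path <- dirname(path)
  }
  feats <- file.path(path, "features.tsv")
  if (!file.exists(feats)) feats <- file.path(path, "genes.tsv")
  bars <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, feats, bars))
    if (!file.exists(f)) stop("file not found: ", f)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  gene_ids <- utils::read.delim(feats, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  cell_ids <- utils::read.delim(bars, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  if (length(gene_ids) != nrow(m))
    stop("dimension mismatch: ", length(gene_ids), " features for ",
         nrow(m), " matrix rows")
  if (length(cell_ids) != ncol(m))
    stop("dimension mismatch: ", length(cell_ids), " barcodes for ",
         ncol(m), " matrix columns")
  rownames(m) <- gene_ids
  colnames(m) <- cell_ids
  count_matrix(m, column_kind = column_kind)
}

#' Write a count matrix to disk
#'
#' Inverse of \code{\link{read_counts}}; round trips are lossless.
#'
#' @param x a \code{\link{count_matrix}}.
#' @param path output directory (\code{"mtx_triplet"}) or file
#'   (\code{"dense_tsv"}).
#' @param format \code{"mtx_triplet"} or \code{"dense_tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "dense_tsv") {
    df <- data.frame(gene_id = x$gene_ids,
                     as.matrix(x$values), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sp <- methods::as(methods::as(x$values, "dMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(path, "features.tsv"))
  writeLines(x$column_ids, file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Cell annotation table
#'
#' Per-cell grouping keys and numeric covariates. Required columns are
#' \code{cell_id}, \code{individual_id}, \code{cell_type}; an optional
#' \code{condition} column and any further columns are retained, numeric ones
#' being treated as covariates (e.g. RIN, which must lie in [1, 10]).
#'
#' @param df data frame with at least the required columns.
#' @return a \code{cell_annotation} data frame.
#' @export
cell_annotation <- function(df) {
  required <- c("cell_id", "individual_id", "cell_type")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df$cell_id <- as.character(df$cell_id)
  df$individual_id <- as.character(df$individual_id)
  df$cell_type <- as.character(df$cell_type)
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  if ("RIN" %in% names(df)) {
    rin <- df$RIN[!is.na(df$RIN)]
    if (length(rin) && (min(rin) < 1 || max(rin) > 10))
      stop("RIN values must lie in [1, 10]")
  }
  class(df) <- c("cell_annotation", "data.frame")
  df
}

#' Read a cell annotation TSV
#'
#' @param path TSV with a header including \code{cell_id},
#'   \code{individual_id}, \code{cell_type}; extra columns are kept
#'   (numeric ones as covariates).
#' @return a \code{\link{cell_annotation}}.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cell_annotation(utils::read.delim(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
}

#' Covariate columns of an annotation
#'
#' @param ann a \code{\link{cell_annotation}}.
#' @return data frame of the numeric non-key columns (possibly zero columns).
#' @export
annotation_covariates <- function(ann) {
  keys <- c("cell_id", "individual_id", "cell_type", "condition")
  extra <- setdiff(names(ann), keys)
  num <- extra[vapply(ann[extra], is.numeric, logical(1))]
  as.data.frame(ann)[, num, drop = FALSE]
}

# Check that every column of a cell-kind count matrix is annotated; returns
# the annotation reordered to the matrix columns.
align_annotation <- function(counts, ann) {
  idx <- match(counts$column_ids, ann$cell_id)
  if (anyNA(idx))
    stop("unannotated cells: ",
         paste(utils::head(counts$column_ids[is.na(idx)], 5), collapse = ", "))
  ann[idx, , drop = FALSE]
}
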