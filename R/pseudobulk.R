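#' Pseudo-bulk aggregation
#'
#' Sums single-cell counts over every observed (individual, cell type) group,
#' producing one pseudo-bulk column per group.
#'
#' @param counts a cell-level \code{\link{count_matrix}}.
#' @param ann a \code{\link{cell_annotation}} covering every cell.
#' @param by grouping columns of \code{ann}; default
#'   \code{c("individual_id", "cell_type")}.
#' @return a \code{pseudobulk_matrix}: a \code{\link{count_matrix}} of kind
#'   \code{"pseudobulk"} with extra fields \code{group_keys} (data frame, one
#'   row per column) and \code{cell_counts} (cells summed per column).
#' @export
make_pseudobulk <- function(counts, ann,
                            by = c("individual_id", "cell_type")) {
  ann <- align_annotation(counts, ann)
  key <- interaction(ann[by], drop = TRUE, sep = ":", lex.order = TRUE)
  groups <- levels(key)
  ind <- Matrix::sparseMatrix(i = seq_along(key), j = as.integer(key),
                              x = 1, dims = c(length(key), length(groups)))
  pb <- as.matrix(counts$values %*% ind)
  colnames(pb) <- groups
  rownames(pb) <- counts$gene_ids
  keys <- unique(ann[by])
  keys <- keys[match(groups, do.call(paste, c(keys[by], sep = ":"))), ,
               drop = FALSE]
  rownames(keys) <- NULL
  out <- count_matrix(round(pb), column_kind = "pseudobulk")
  out$group_keys <- keys
  out$cell_counts <- as.integer(tabulate(as.integer(key),
                                         nbins = length(groups)))
  class(out) <- c("pseudobulk_matrix", class(out))
  out
}

#' Per-gene missing rate
#'
#' Fraction of units with a zero count for each gene, at the single-cell
#' level (units are cells of the requested cell type) or at the pseudo-bulk
#' level (units are per-individual pseudo-bulks of that cell type).
#'
#' @param counts a cell-level \code{\link{count_matrix}}.
#' @param ann a \code{\link{cell_annotation}}.
#' @param cell_type cell type to evaluate.
#' @param level \code{"cell"} or \code{"pseudobulk"}.
#' @return data frame with \code{gene_id}, \code{rate}, \code{level},
#'   \code{n_units}.
#' @export
missing_rate <- function(counts, ann, cell_type,
                         level = c("cell", "pseudobulk")) {
  level <- match.arg(level)
  ann <- align_annotation(counts, ann)
  if (!cell_type %in% ann$cell_type)
    stop("unknown cell type: ", cell_type)
  sel <- ann$cell_type == cell_type
  if (level == "cell") {
    v <- counts$values[, sel, drop = FALSE]
  } else {
    pb <- make_pseudobulk(subset_counts(counts, cols = which(sel)),
                          ann[sel, , drop = FALSE])
    v <- pb$values
  }
  n <- ncol(v)
  data.frame(gene_id = counts$gene_ids,
             rate = as.numeric(Matrix::rowSums(v == 0)) / n,
             level = level, n_units = n, stringsAsFactors = FALSE)
}

#' Randomized pseudo-bulk technical replicates
#'
#' Randomly partitions the cells of one (individual, cell type) group into
#' \code{g} disjoint groups of \code{cells_per_replicate} cells each (sampled
#' without replacement) and sums counts within each group. Cells left over
#' (n mod g with the default size, or all unsampled cells otherwise) are
#' discarded.
#'
#' @param counts a cell-level \code{\link{count_matrix}}.
#' @param ann a \code{\link{cell_annotation}}.
#' @param individual individual id.
#' @param cell_type cell type.
#' @param g number of replicates (default 3).
#' @param cells_per_replicate cells per replicate; default
#'   \code{floor(n / g)} over the n available cells.
#' @param seed integer seed; identical seeds give identical membership.
#' @return a \code{replicate_set}: list with \code{values} (genes x g dense
#'   matrix), \code{source}, \code{cells_per_replicate}, \code{member_cells}
#'   (list of g disjoint cell-id vectors), \code{seed}.
#' @export
sample_replicates <- function(counts, ann, individual, cell_type, g = 3,
                              cells_per_replicate = NULL, seed = 1) {
  ann <- align_annotation(counts, ann)
  sel <- which(ann$individual_id == individual & ann$cell_type == cell_type)
  n <- length(sel)
  if (n < g)
    stop("insufficient cells: ", n, " available for ", g, " replicates")
  if (is.null(cells_per_replicate)) cells_per_replicate <- n %/% g
  cells_per_replicate <- as.integer(cells_per_replicate)
  if (cells_per_replicate < 1L)
    stop("cells_per_replicate must be at least 1")
  if (g * cells_per_replicate > n)
    stop("insufficient cells: need ", g * cells_per_replicate,
         ", have ", n)
  picked <- with_seed(seed, sel[sample.int(n, g * cells_per_replicate)])
  groups <- split(picked, rep(seq_len(g), each = cells_per_replicate))
  vals <- vapply(groups, function(ix)
    as.numeric(Matrix::rowSums(counts$values[, ix, drop = FALSE])),
    numeric(length(counts$gene_ids)))
  if (is.null(dim(vals)))
    vals <- matrix(vals, nrow = length(counts$gene_ids))
  dimnames(vals) <- list(counts$gene_ids, paste0("rep", seq_len(g)))
  structure(list(values = vals,
                 source = c(individual = individual, cell_type = cell_type),
                 cells_per_replicate = cells_per_replicate,
                 member_cells = lapply(groups, function(ix)
                   counts$column_ids[ix]),
                 seed = as.integer(seed)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf(
    "replicate_set: %d genes x %d replicates of %d cells (%s / %s)\n",
    nrow(x$values), ncol(x$values), x$cells_per_replicate,
    x$source[["individual"]], x$source[["cell_type"]]))
  invisible(x)
}
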