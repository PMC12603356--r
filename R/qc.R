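#' Cell and gene quality-control filter
#'
#' Applies, in a fixed order: (1) remove cells with a mitochondrial read
#' fraction at or above \code{mito_max}; (2) remove cells detecting fewer than
#' \code{min_genes} genes; (3) remove cells whose detected-gene count exceeds
#' mean + \code{sd_mult} x sd, the statistics being computed on cells
#' surviving the first two rules; (4) remove genes detected (count > 0) in
#' fewer than \code{min_cell_fraction} of the retained cells.
#'
#' Mitochondrial genes are recognized by an id prefix. If no gene matches the
#' prefix the mitochondrial rule is skipped with a warning (recorded in the
#' report).
#'
#' @param counts a \code{\link{count_matrix}} of cells.
#' @param ann a \code{\link{cell_annotation}} covering every cell.
#' @param mito_gene_prefix gene-id prefix marking mitochondrial genes
#'   (default \code{"MT-"}).
#' @param mito_max maximal allowed mitochondrial fraction (default 0.10;
#'   cells at or above it are removed).
#' @param min_genes minimal detected genes per cell (default 200).
#' @param sd_mult multiplier for the detected-genes outlier rule (default 3).
#' @param min_cell_fraction minimal fraction of retained cells a gene must be
#'   detected in (default 0.001).
#' @return list with elements \code{counts}, \code{ann} (filtered), and
#'   \code{report} (per-rule removal counts, in application order).
#' @export
qc_filter <- function(counts, ann, mito_gene_prefix = "MT-",
                      mito_max = 0.10, min_genes = 200, sd_mult = 3,
                      min_cell_fraction = 0.001) {
  ann <- align_annotation(counts, ann)
  v <- counts$values
  n_cells0 <- ncol(v)
  n_genes0 <- nrow(v)

  mito <- startsWith(counts$gene_ids, mito_gene_prefix)
  mito_skipped <- !any(mito)
  if (mito_skipped) {
    warning("no gene ids match mitochondrial prefix '", mito_gene_prefix,
            "'; mitochondrial rule skipped")
    keep <- rep(TRUE, n_cells0)
    removed_mito <- 0L
  } else {
    lib <- Matrix::colSums(v)
    mito_frac <- Matrix::colSums(v[mito, , drop = FALSE]) / pmax(lib, 1)
    keep <- mito_frac < mito_max
    removed_mito <- sum(!keep)
  }

  detected <- Matrix::colSums(v > 0)
  low <- keep & detected < min_genes
  removed_min_genes <- sum(low)
  keep <- keep & !low

  det_kept <- detected[keep]
  if (sum(keep) >= 2L) {
    hi_cut <- mean(det_kept) + sd_mult * stats::sd(det_kept)
    hi <- keep & detected > hi_cut
  } else {
    hi <- rep(FALSE, n_cells0)
  }
  removed_outlier <- sum(hi)
  keep <- keep & !hi

  if (!any(keep)) {
    stop("no cells survive QC (mito: ", removed_mito, ", min_genes: ",
         removed_min_genes, ", outlier: ", removed_outlier,
         " removed of ", n_cells0, ")")
  }

  v <- v[, keep, drop = FALSE]
  n_det_cells <- Matrix::rowSums(v > 0)
  gene_keep <- n_det_cells >= min_cell_fraction * ncol(v)
  removed_genes <- sum(!gene_keep)
  v <- v[gene_keep, , drop = FALSE]

  report <- list(
    n_input_cells = n_cells0,
    removed_mito = as.integer(removed_mito),
    removed_min_genes = as.integer(removed_min_genes),
    removed_outlier = as.integer(removed_outlier),
    n_cells_retained = ncol(v),
    n_input_genes = n_genes0,
    removed_genes = as.integer(removed_genes),
    n_genes_retained = nrow(v),
    mito_rule_skipped = mito_skipped,
    parameters = list(mito_gene_prefix = mito_gene_prefix,
                      mito_max = mito_max, min_genes = min_genes,
                      sd_mult = sd_mult,
                      min_cell_fraction = min_cell_fraction)
  )
  list(counts = count_matrix(v, column_kind = counts$column_kind),
       ann = ann[keep, , drop = FALSE],
       report = report)
}

#' Library-size normalization
#'
#' \code{"lognorm10k"}: ln(1 + 1e4 x / libsize), the standard log-normalized
#' scaling to 10,000 counts per column. \code{"log2cpm"}: log2(pseudo_count +
#' 1e6 x / libsize), log2 counts-per-million.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param scheme \code{"lognorm10k"} or \code{"log2cpm"}.
#' @param pseudo_count pseudo-count for \code{"log2cpm"} (default 1, added
#'   after CPM scaling).
#' @return a \code{normalized_matrix}: list with \code{values} (dense),
#'   \code{scheme}, \code{pseudo_count}, \code{gene_ids}, \code{column_ids}.
#' @export
normalize_counts <- function(counts, scheme = c("lognorm10k", "log2cpm"),
                             pseudo_count = 1) {
  scheme <- match.arg(scheme)
  v <- counts$values
  lib <- Matrix::colSums(v)
  if (any(lib <= 0))
    stop("zero library size in column(s): ",
         paste(counts$column_ids[lib <= 0], collapse = ", "))
  m <- as.matrix(v) %*% diag(1 / lib, length(lib))
  out <- if (scheme == "lognorm10k") log1p(1e4 * m)
         else log2(pseudo_count + 1e6 * m)
  dimnames(out) <- list(counts$gene_ids, counts$column_ids)
  structure(list(values = out, scheme = scheme, pseudo_count = pseudo_count,
                 gene_ids = counts$gene_ids, column_ids = counts$column_ids),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (%s): %d genes x %d columns\n",
              x$scheme, nrow(x$values), ncol(x$values)))
  invisible(x)
}
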