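#' Pair single-cell pseudo-bulks with reference bulk and normalize
#'
#' Restricts both matrices to their common genes, aligns columns according to
#' the sample map, and converts both sides to log2 counts-per-million
#' (pseudo-count 1). The bulk side is the reference (independent variable in
#' the accuracy regression); the single-cell pseudo-bulk side is the
#' dependent variable.
#'
#' @param sc_pb \code{\link{count_matrix}} of single-cell pseudo-bulks
#'   (genes x samples).
#' @param bulk \code{\link{count_matrix}} of reference bulk counts.
#' @param sample_map data frame with columns \code{sc_id}, \code{bulk_id};
#'   at least 3 pairs.
#' @return a \code{paired_expression}: list with \code{genes},
#'   \code{x_bulk}, \code{y_sc} (aligned log2-CPM matrices), \code{sample_ids}.
#' @export
pair_and_normalize <- function(sc_pb, bulk, sample_map) {
  if (nrow(sample_map) < 3) stop("fewer than 3 matched samples")
  if (!all(sample_map$sc_id %in% sc_pb$column_ids))
    stop("sample_map sc_id not found in single-cell pseudo-bulks")
  if (!all(sample_map$bulk_id %in% bulk$column_ids))
    stop("sample_map bulk_id not found in bulk matrix")
  genes <- intersect(sc_pb$gene_ids, bulk$gene_ids)
  if (!length(genes)) stop("empty gene intersection")
  sc <- subset_counts(sc_pb, genes = match(genes, sc_pb$gene_ids),
                      cols = match(sample_map$sc_id, sc_pb$column_ids))
  bk <- subset_counts(bulk, genes = match(genes, bulk$gene_ids),
                      cols = match(sample_map$bulk_id, bulk$column_ids))
  y <- normalize_counts(sc, "log2cpm")$values
  x <- normalize_counts(bk, "log2cpm")$values
  ids <- paste(sample_map$bulk_id, sample_map$sc_id, sep = "|")
  colnames(x) <- colnames(y) <- ids
  structure(list(genes = genes, x_bulk = x, y_sc = y, sample_ids = ids),
            class = "paired_expression")
}

#' Per-gene location-scale batch adjustment
#'
#' Removes the systematic shift and scale difference between the two sides of
#' a \code{\link{paired_expression}}: for each gene, each side is centered
#' and rescaled so that its mean and sd equal the pooled targets (the average
#' of the two sides' means and of their sds). A side with zero sd is shifted
#' only. The adjustment is idempotent.
#'
#' @param pe a \code{\link{paired_expression}}.
#' @return the adjusted \code{paired_expression}.
#' @export
batch_adjust <- function(pe) {
  if (ncol(pe$x_bulk) < 2) stop("need at least 2 samples per side")
  adjust <- function(v, m_side, s_side, m_pool, s_pool) {
    scale_ok <- s_side > 0 & s_pool > 0
    f <- ifelse(scale_ok, s_pool / s_side, 1)
    (v - m_side) * f + m_pool
  }
  mx <- rowMeans(pe$x_bulk); my <- rowMeans(pe$y_sc)
  sx <- row_sds(pe$x_bulk); sy <- row_sds(pe$y_sc)
  m_pool <- (mx + my) / 2
  s_pool <- (sx + sy) / 2
  pe$x_bulk <- adjust(pe$x_bulk, mx, sx, m_pool, s_pool)
  pe$y_sc <- adjust(pe$y_sc, my, sy, m_pool, s_pool)
  pe
}

#' Per-gene expression accuracy
#'
#' For each gene, computes the Pearson correlation between the reference bulk
#' (x) and the single-cell pseudo-bulk (y) profiles across samples, and a
#' regression of y on x through the origin. The slope is tested against 1:
#' b = sum(xy)/sum(x^2), se = sqrt(sum((y - bx)^2) / ((n-1) sum(x^2))),
#' t = (b - 1)/se with n-1 degrees of freedom (two-sided). A gene has good
#' accuracy when r > \code{r_min} and the slope test does not reject
#' (p_slope > \code{p_min}).
#'
#' @param pe a \code{\link{paired_expression}} (typically after
#'   \code{\link{batch_adjust}}).
#' @param r_min correlation threshold (default 0.9).
#' @param p_min slope-test p-value threshold (default 0.05).
#' @return an \code{accuracy_table} data frame: \code{gene_id}, \code{r},
#'   \code{slope}, \code{slope_se}, \code{p_slope}, \code{good},
#'   \code{n_samples}.
#' @export
gene_accuracy <- function(pe, r_min = 0.9, p_min = 0.05) {
  x <- pe$x_bulk; y <- pe$y_sc
  n <- ncol(x)
  if (n < 3) stop("need at least 3 samples")
  sxx <- rowSums(x^2)
  b <- rowSums(x * y) / sxx
  rss <- rowSums((y - b * x)^2)
  rss <- pmax(rss, 0)
  se <- sqrt(rss / ((n - 1) * sxx))
  tt <- (b - 1) / se
  p_slope <- 2 * stats::pt(-abs(tt), df = n - 1)
  # exact fits: se = 0 -> p 1 if b = 1, else 0
  exact <- is.finite(b) & se == 0
  p_slope[exact] <- ifelse(abs(b[exact] - 1) < 1e-12, 1, 0)
  # Pearson r, NA when either side has zero variance
  cx <- x - rowMeans(x); cy <- y - rowMeans(y)
  vx <- rowSums(cx^2); vy <- rowSums(cy^2)
  r <- rowSums(cx * cy) / sqrt(vx * vy)
  r[vx == 0 | vy == 0] <- NA_real_
  # genes with all-zero x: slope undefined
  degenerate <- sxx == 0
  b[degenerate] <- NA_real_
  se[degenerate] <- NA_real_
  p_slope[degenerate] <- NA_real_
  good <- !is.na(r) & !is.na(p_slope) & r > r_min & p_slope > p_min
  out <- data.frame(gene_id = pe$genes, r = r, slope = b, slope_se = se,
                    p_slope = p_slope, good = good, n_samples = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("accuracy_table", "data.frame")
  out
}

#' Number of genes with good accuracy
#'
#' @param acc an \code{accuracy_table} from \code{\link{gene_accuracy}}.
#' @return integer count of genes flagged good.
#' @export
count_good <- function(acc) {
  if (!nrow(acc)) return(0L)
  sum(acc$good, na.rm = TRUE)
}

#' Accuracy versus cell number (downsampling curve)
#'
#' For each grid value, subsamples that many cells per sample (without
#' replacement), rebuilds per-sample pseudo-bulks, reruns pairing, batch
#' adjustment, and the per-gene accuracy test against the bulk reference, and
#' records the number of genes with good accuracy.
#'
#' @param sc_counts cell-level \code{\link{count_matrix}}.
#' @param ann a \code{\link{cell_annotation}}; samples are its
#'   \code{individual_id} values.
#' @param bulk reference bulk \code{\link{count_matrix}} (genes x samples).
#' @param sample_map data frame with \code{sc_id} (= individual_id) and
#'   \code{bulk_id}.
#' @param cell_grid cell numbers per sample to evaluate.
#' @param seed integer seed.
#' @param r_min,p_min accuracy thresholds, see \code{\link{gene_accuracy}}.
#' @param adjust apply \code{\link{batch_adjust}} (default TRUE).
#' @return data frame with \code{cells} and \code{n_good}.
#' @export
accuracy_downsampling_curve <- function(sc_counts, ann, bulk, sample_map,
                                        cell_grid, seed = 1, r_min = 0.9,
                                        p_min = 0.05, adjust = TRUE) {
  ann <- align_annotation(sc_counts, ann)
  by_sample <- split(seq_along(ann$cell_id), ann$individual_id)
  avail <- vapply(by_sample, length, integer(1))
  cell_grid <- as.integer(sort(unique(cell_grid)))
  if (max(cell_grid) > min(avail))
    stop("grid value ", max(cell_grid), " exceeds available cells (",
         min(avail), ") in at least one sample")
  n_good <- vapply(seq_along(cell_grid), function(i) {
    m <- cell_grid[i]
    keep <- with_seed(derive_seed(seed, i), {
      unlist(lapply(by_sample, function(ix) ix[sample.int(length(ix), m)]),
             use.names = FALSE)
    })
    sub <- subset_counts(sc_counts, cols = sort(keep))
    pb <- make_pseudobulk(sub, ann[sort(keep), , drop = FALSE],
                          by = "individual_id")
    pe <- pair_and_normalize(pb, bulk, sample_map)
    if (adjust) pe <- batch_adjust(pe)
    count_good(gene_accuracy(pe, r_min = r_min, p_min = p_min))
  }, integer(1))
  data.frame(cells = cell_grid, n_good = n_good)
}
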