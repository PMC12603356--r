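#' Per-gene coefficient of variation across technical replicates
#'
#' CV_i = sample sd / mean of gene i across the g replicate columns (n-1
#' denominator). Genes with zero mean are undefined (NA) and excluded from
#' downstream medians.
#'
#' @param reps a \code{replicate_set} from \code{\link{sample_replicates}},
#'   or a plain genes x g matrix.
#' @param normalize if TRUE, scale each replicate column to counts-per-million
#'   before computing CV (for unequal-depth replicates).
#' @return named numeric vector of CVs (NA where undefined).
#' @export
cv_per_gene <- function(reps, normalize = FALSE) {
  v <- if (is.list(reps)) reps$values else reps
  if (ncol(v) < 2L) stop("need at least 2 replicates for a CV")
  if (normalize) {
    lib <- colSums(v)
    if (any(lib <= 0)) stop("cannot CPM-normalize an all-zero replicate")
    v <- sweep(v, 2L, lib / 1e6, "/")
  }
  mu <- rowMeans(v)
  cv <- row_sds(v) / mu
  cv[mu == 0] <- NA_real_
  cv
}

#' Average CV over repeated random groupings
#'
#' Draws \code{R} independent random replicate partitions of the same
#' (individual, cell type) group (repeat r uses seed \code{seed_base + r}),
#' computes per-gene CV in each, and averages each gene's CV over the repeats
#' where it is defined.
#'
#' @inheritParams sample_replicates
#' @param R number of repeats (default 100).
#' @param seed_base base seed; repeat r uses \code{seed_base + r}.
#' @param normalize passed to \code{\link{cv_per_gene}}.
#' @return data frame (\code{cv_table}) with \code{gene_id}, \code{mean_cv},
#'   \code{n_repeats_defined}, \code{detected}.
#' @export
average_cv <- function(counts, ann, individual, cell_type, g = 3, R = 100,
                       cells_per_replicate = NULL, seed_base = 1,
                       normalize = FALSE) {
  gene_ids <- counts$gene_ids
  sum_cv <- numeric(length(gene_ids))
  n_def <- integer(length(gene_ids))
  for (r in seq_len(R)) {
    reps <- sample_replicates(counts, ann, individual, cell_type, g = g,
                              cells_per_replicate = cells_per_replicate,
                              seed = derive_seed(seed_base, r))
    cv <- cv_per_gene(reps, normalize = normalize)
    ok <- !is.na(cv)
    sum_cv[ok] <- sum_cv[ok] + cv[ok]
    n_def <- n_def + ok
  }
  mean_cv <- ifelse(n_def > 0L, sum_cv / n_def, NA_real_)
  out <- data.frame(gene_id = gene_ids, mean_cv = mean_cv,
                    n_repeats_defined = n_def, detected = n_def > 0L,
                    stringsAsFactors = FALSE)
  class(out) <- c("cv_table", "data.frame")
  out
}

# Median mean_cv over detected genes of a cv_table.
median_cv <- function(cv_table) {
  stats::median(cv_table$mean_cv[cv_table$detected], na.rm = TRUE)
}

#' Precision (CV versus cell number) curve
#'
#' For each grid value m, builds technical replicates of m cells each and
#' records the median (over detected genes) of the repeat-averaged CV.
#'
#' @inheritParams average_cv
#' @param grid increasing cell numbers per replicate; default
#'   \code{c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000, 2000, 5000)}
#'   intersected with \code{[1, floor(n/g)]}.
#' @return a \code{precision_curve}: list with \code{points} (data frame of
#'   \code{cells_per_replicate}, \code{median_cv}), \code{source}, \code{g},
#'   \code{R}, \code{normalize}.
#' @export
precision_curve <- function(counts, ann, individual, cell_type,
                            grid = NULL, g = 3, R = 100, seed_base = 1,
                            normalize = FALSE) {
  ann_al <- align_annotation(counts, ann)
  n <- sum(ann_al$individual_id == individual &
             ann_al$cell_type == cell_type)
  cap <- n %/% g
  if (is.null(grid)) {
    grid <- c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000, 2000, 5000)
    grid <- grid[grid >= 1 & grid <= cap]
  }
  grid <- as.integer(sort(unique(grid)))
  if (!length(grid)) stop("empty downsampling grid")
  if (max(grid) > cap)
    stop("grid value ", max(grid), " exceeds floor(n/g) = ", cap)
  med <- vapply(seq_along(grid), function(i) {
    tab <- average_cv(counts, ann, individual, cell_type, g = g, R = R,
                      cells_per_replicate = grid[i],
                      seed_base = derive_seed(seed_base, i * 1000L),
                      normalize = normalize)
    median_cv(tab)
  }, numeric(1))
  structure(list(points = data.frame(cells_per_replicate = grid,
                                     median_cv = med),
                 source = c(individual = individual, cell_type = cell_type),
                 g = g, R = R, normalize = normalize),
            class = "precision_curve")
}

#' @export
print.precision_curve <- function(x, ...) {
  cat(sprintf("precision_curve (%s / %s), g = %d, R = %d:\n",
              x$source[["individual"]], x$source[["cell_type"]], x$g, x$R))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Minimum cells per replicate reaching a CV threshold
#'
#' Smallest grid value whose median CV is at or below \code{threshold}; the
#' conventional threshold 0.1 matches bulk RNA-seq quality-control practice.
#'
#' @param curve a \code{\link{precision_curve}}.
#' @param threshold CV threshold (default 0.1).
#' @return integer cell number, or \code{NA_integer_} if no grid point
#'   reaches the threshold.
#' @export
min_cells_for_cv <- function(curve, threshold = 0.1) {
  pts <- curve$points
  if (!nrow(pts)) stop("empty precision curve")
  hit <- which(pts$median_cv <= threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(pts$cells_per_replicate[min(hit)])
}

#' Fraction of samples passing a CV threshold
#'
#' @param cv_tables list of \code{cv_table} data frames (one per sample).
#' @param threshold CV threshold (default 0.1).
#' @return fraction of samples whose median CV over detected genes is at or
#'   below the threshold.
#' @export
fraction_passing <- function(cv_tables, threshold = 0.1) {
  if (!length(cv_tables)) stop("empty input")
  meds <- vapply(cv_tables, median_cv, numeric(1))
  mean(meds <= threshold)
}

#' Regression of sample median CV on a covariate
#'
#' Simple linear regression of per-sample median CV on a sample covariate
#' (e.g. RNA integrity number), reporting the Pearson correlation, R^2,
#' slope, and the two-sided slope p-value.
#'
#' @param sample_median_cvs data frame with \code{sample_id},
#'   \code{median_cv}.
#' @param covariate data frame with \code{sample_id}, \code{value}.
#' @return list with \code{r}, \code{r2}, \code{p}, \code{slope}, \code{n}.
#' @export
cv_covariate_correlation <- function(sample_median_cvs, covariate) {
  m <- merge(sample_median_cvs, covariate, by = "sample_id")
  if (nrow(m) < 3) stop("fewer than 3 matched samples")
  if (stats::sd(m$value) == 0) stop("zero variance covariate")
  fit <- stats::lm(median_cv ~ value, data = m)
  sm <- summary(fit)
  list(r = stats::cor(m$value, m$median_cv),
       r2 = sm$r.squared,
       p = sm$coefficients["value", "Pr(>|t|)"],
       slope = sm$coefficients["value", "Estimate"],
       n = nrow(m))
}

#' Slope fit summary
#'
#' Container for a regression slope and its standard error, as used by the
#' two-sample slope-difference Z-test.
#'
#' @param b slope estimate.
#' @param se standard error of the slope (> 0).
#' @param n number of observations.
#' @return a \code{slope_fit} list.
#' @export
slope_fit <- function(b, se, n = NA_integer_) {
  if (!is.finite(se) || se <= 0) stop("standard error must be positive")
  structure(list(b = b, se = se, n = n), class = "slope_fit")
}

#' Slope of a precision curve
#'
#' Fits median CV on cells-per-replicate by ordinary least squares and
#' returns the slope as a \code{\link{slope_fit}}, ready for
#' \code{\link{slope_difference_z}}.
#'
#' @param curve a \code{\link{precision_curve}}.
#' @param log_cells if TRUE (default), regress on log10 cell number.
#' @return a \code{\link{slope_fit}}.
#' @export
fit_precision_slope <- function(curve, log_cells = TRUE) {
  pts <- curve$points
  if (nrow(pts) < 3) stop("need at least 3 curve points to fit a slope")
  x <- if (log_cells) log10(pts$cells_per_replicate)
       else pts$cells_per_replicate
  fit <- summary(stats::lm(pts$median_cv ~ x))
  slope_fit(fit$coefficients[2, 1], fit$coefficients[2, 2], nrow(pts))
}

#' Two-sample slope-difference Z-test
#'
#' Standardized difference (b1 - b2) / sqrt(se1^2 + se2^2) between two
#' regression slopes, with a two-tailed standard-normal p-value.
#'
#' @param fit1,fit2 \code{\link{slope_fit}} objects (or lists with \code{b},
#'   \code{se}).
#' @return list with \code{diff} (the Z statistic) and \code{p}.
#' @export
slope_difference_z <- function(fit1, fit2) {
  if (fit1$se <= 0 || fit2$se <= 0) stop("standard errors must be positive")
  z <- (fit1$b - fit2$b) / sqrt(fit1$se^2 + fit2$se^2)
  list(diff = z, p = 2 * stats::pnorm(-abs(z)))
}
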