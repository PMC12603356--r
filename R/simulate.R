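# Gamma-Poisson two-condition single-cell simulator with known DE ground
# truth. Gene base means are gamma; DE genes receive a lognormal fold factor
# (random direction) in condition 2; each cell's expected total library size
# is lognormal and per-gene Poisson rates are relative expression times
# library size, so marginal counts are gamma-Poisson (NB-like) overdispersed.

#' Simulation parameters
#'
#' @param n_genes number of genes (default 2000).
#' @param n_cells_per_sample cells per sample, in [10, 3000] (default 3000).
#' @param n_samples_per_group samples per condition (default 3).
#' @param de_prob probability a gene is differentially expressed
#'   (default 0.25).
#' @param de_factor_loc,de_factor_scale meanlog / sdlog of the lognormal DE
#'   fold factor (defaults 0.1 and 0.4).
#' @param mean_shape,mean_rate gamma shape / rate of gene base means
#'   (defaults 0.6 and 0.3).
#' @param lib_loc,lib_scale meanlog / sdlog of per-cell expected library
#'   size (defaults ln(10000) and 0.2).
#' @param seed integer seed.
#' @return a \code{sim_params} list.
#' @export
sim_params <- function(n_genes = 2000, n_cells_per_sample = 3000,
                       n_samples_per_group = 3, de_prob = 0.25,
                       de_factor_loc = 0.1, de_factor_scale = 0.4,
                       mean_shape = 0.6, mean_rate = 0.3,
                       lib_loc = log(10000), lib_scale = 0.2, seed = 1) {
  p <- list(n_genes = as.integer(n_genes),
            n_cells_per_sample = as.integer(n_cells_per_sample),
            n_samples_per_group = as.integer(n_samples_per_group),
            de_prob = de_prob, de_factor_loc = de_factor_loc,
            de_factor_scale = de_factor_scale, mean_shape = mean_shape,
            mean_rate = mean_rate, lib_loc = lib_loc,
            lib_scale = lib_scale, seed = as.integer(seed))
  if (p$de_prob < 0 || p$de_prob > 1) stop("de_prob must lie in [0, 1]")
  if (p$n_cells_per_sample < 1) stop("n_cells_per_sample must be positive")
  if (p$n_samples_per_group < 1) stop("need at least 1 sample per group")
  if (p$de_factor_scale <= 0 || p$mean_shape <= 0 || p$mean_rate <= 0 ||
      p$lib_scale <= 0)
    stop("scale/shape/rate parameters must be positive")
  class(p) <- "sim_params"
  p
}

#' Simulate two-condition single-cell counts
#'
#' @param params a \code{\link{sim_params}}.
#' @return a \code{sim_result}: list with \code{counts} (sparse cell-level
#'   \code{\link{count_matrix}}), \code{ann}
#'   (\code{\link{cell_annotation}} with \code{individual_id} = sample and
#'   \code{condition}), \code{truth} (data frame \code{gene_id},
#'   \code{is_de}, \code{true_log2fc}), \code{params}.
#' @export
simulate_sc <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    gene_ids <- sprintf("gene%04d", seq_len(p$n_genes))
    base <- stats::rgamma(p$n_genes, shape = p$mean_shape,
                          rate = p$mean_rate)
    is_de <- stats::runif(p$n_genes) < p$de_prob
    fold <- stats::rlnorm(p$n_genes, meanlog = p$de_factor_loc,
                          sdlog = p$de_factor_scale)
    sign_up <- sample(c(1, -1), p$n_genes, replace = TRUE)
    factor2 <- ifelse(is_de, fold^sign_up, 1)
    true_log2fc <- ifelse(is_de, sign_up * log2(fold), 0)
    mean1 <- base
    mean2 <- base * factor2
    n_samples <- 2L * p$n_samples_per_group
    sample_ids <- sprintf("s%d", seq_len(n_samples))
    condition <- rep(c("cond1", "cond2"), each = p$n_samples_per_group)
    blocks <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      mu <- if (condition[s] == "cond1") mean1 else mean2
      rel <- mu / sum(mu)
      libs <- stats::rlnorm(p$n_cells_per_sample, meanlog = p$lib_loc,
                            sdlog = p$lib_scale)
      rate <- outer(rel, libs)
      cnt <- matrix(stats::rpois(length(rate), rate), nrow = p$n_genes)
      blocks[[s]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                 "CsparseMatrix")
    }
    counts <- do.call(cbind, blocks)
    cell_ids <- sprintf("%s_c%04d", rep(sample_ids,
                                        each = p$n_cells_per_sample),
                        rep(seq_len(p$n_cells_per_sample), n_samples))
    dimnames(counts) <- list(gene_ids, cell_ids)
    ann <- cell_annotation(data.frame(
      cell_id = cell_ids,
      individual_id = rep(sample_ids, each = p$n_cells_per_sample),
      cell_type = "simulated",
      condition = rep(condition, each = p$n_cells_per_sample),
      stringsAsFactors = FALSE))
    structure(list(counts = count_matrix(counts, column_kind = "cell"),
                   ann = ann,
                   truth = data.frame(gene_id = gene_ids, is_de = is_de,
                                      true_log2fc = true_log2fc,
                                      stringsAsFactors = FALSE),
                   params = p),
              class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "sim_result: %d genes x %d cells (%d samples x %d cells), %d DE genes\n",
    length(x$counts$gene_ids), length(x$counts$column_ids),
    2L * x$params$n_samples_per_group, x$params$n_cells_per_sample,
    sum(x$truth$is_de)))
  invisible(x)
}

#' Pooled per-sample ground-truth profiles
#'
#' Sums every sample's cells into one column: the matched "pooled-cell"
#' reference against which downsampled analyses are compared.
#'
#' @param sim a \code{sim_result}.
#' @return a \code{\link{count_matrix}} (genes x samples, kind
#'   \code{"sample"}).
#' @export
pooled_truth <- function(sim) {
  pb <- make_pseudobulk(sim$counts, sim$ann, by = "individual_id")
  count_matrix(pb$values, column_kind = "sample")
}

#' Downsample cells per sample
#'
#' Uniform subsample without replacement of \code{cells} cells from each
#' sample; the ground truth is unchanged.
#'
#' @param sim a \code{sim_result}.
#' @param cells cells to keep per sample.
#' @param seed integer seed.
#' @return a \code{sim_result} on the subsampled cells.
#' @export
downsample_cells <- function(sim, cells, seed = 1) {
  cells <- as.integer(cells)
  if (cells > sim$params$n_cells_per_sample)
    stop("cells exceeds availability (", sim$params$n_cells_per_sample, ")")
  by_sample <- split(seq_along(sim$ann$cell_id), sim$ann$individual_id)
  keep <- sort(with_seed(seed, unlist(
    lapply(by_sample, function(ix) ix[sample.int(length(ix), cells)]),
    use.names = FALSE)))
  out <- sim
  out$counts <- subset_counts(sim$counts, cols = keep)
  out$ann <- sim$ann[keep, , drop = FALSE]
  out
}

#' Condition labels of a simulation's samples
#'
#' @param sim a \code{sim_result}.
#' @return named character vector mapping sample id to condition.
#' @export
sample_conditions <- function(sim) {
  u <- unique(sim$ann[c("individual_id", "condition")])
  stats::setNames(u$condition, u$individual_id)
}
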