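# Design calculator: expected true-positive rate of a pseudo-bulk DE
# analysis from sample size, technical noise (CV at the planned cell
# number), and expected effect size, by Monte-Carlo simulation.

#' Power-calculation specification
#'
#' @param n_per_group samples per group (>= 2).
#' @param effect_log2fc expected absolute log2 fold change of DE genes.
#' @param cv per-replicate technical coefficient of variation at the planned
#'   cell number (> 0); measure it with \code{\link{average_cv}} /
#'   \code{\link{cv_for_cells}}.
#' @param n_genes genes per simulated experiment (default 2000).
#' @param prop_de fraction of DE genes (default 0.25).
#' @param fdr_max BH FDR detection threshold (default 0.05).
#' @param n_sims Monte-Carlo repetitions (default 20).
#' @param seed integer seed.
#' @param base_log2_range range the per-gene baseline log2 expression is
#'   drawn from, uniform (default c(2, 12)).
#' @return a \code{power_spec} list.
#' @export
power_spec <- function(n_per_group = 3, effect_log2fc = 1, cv = 0.2,
                       n_genes = 2000, prop_de = 0.25, fdr_max = 0.05,
                       n_sims = 20, seed = 1,
                       base_log2_range = c(2, 12)) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  if (cv <= 0) stop("cv must be positive")
  if (prop_de <= 0 || prop_de >= 1) stop("prop_de must lie in (0, 1)")
  if (n_sims < 1) stop("n_sims must be at least 1")
  structure(list(n_per_group = as.integer(n_per_group),
                 effect_log2fc = effect_log2fc, cv = cv,
                 n_genes = as.integer(n_genes), prop_de = prop_de,
                 fdr_max = fdr_max, n_sims = as.integer(n_sims),
                 seed = as.integer(seed),
                 base_log2_range = base_log2_range),
            class = "power_spec")
}

#' Estimate the expected true-positive rate of a DE design
#'
#' Monte-Carlo model: per-gene baseline log2 expression uniform over
#' \code{base_log2_range}; replicate technical noise is lognormal with
#' natural-log sd \code{sqrt(log(1 + cv^2))} (the exact lognormal/CV link for
#' multiplicative noise); a fraction \code{prop_de} of genes receives
#' +/- \code{effect_log2fc} in one group. Each gene is tested by Welch's
#' t-test on the log2 values, detection is BH FDR < \code{fdr_max}, and the
#' TPR is the detected fraction of true DE genes, averaged over
#' \code{n_sims} simulations.
#'
#' @param spec a \code{\link{power_spec}}.
#' @return a \code{power_estimate}: list with \code{tpr}, \code{mc_se}
#'   (binomial-style Monte-Carlo standard error over simulated DE genes),
#'   \code{spec}.
#' @export
estimate_tpr <- function(spec = power_spec()) {
  stopifnot(inherits(spec, "power_spec"))
  s <- spec
  sd_log2 <- sqrt(log(1 + s$cv^2)) / log(2)
  n_de <- max(1L, round(s$prop_de * s$n_genes))
  n <- s$n_per_group
  tprs <- with_seed(s$seed, vapply(seq_len(s$n_sims), function(sim) {
    base <- stats::runif(s$n_genes, s$base_log2_range[1],
                         s$base_log2_range[2])
    de <- seq_len(n_de)                 # first n_de genes are DE
    shift <- numeric(s$n_genes)
    shift[de] <- sample(c(1, -1), n_de, replace = TRUE) * s$effect_log2fc
    ya <- matrix(stats::rnorm(s$n_genes * n, mean = base, sd = sd_log2),
                 s$n_genes, n)
    yb <- matrix(stats::rnorm(s$n_genes * n, mean = base + shift,
                              sd = sd_log2), s$n_genes, n)
    ma <- rowMeans(ya); mb <- rowMeans(yb)
    va <- row_sds(ya)^2; vb <- row_sds(yb)^2
    se2 <- va / n + vb / n
    tstat <- (mb - ma) / sqrt(se2)
    df <- se2^2 / ((va / n)^2 / (n - 1) + (vb / n)^2 / (n - 1))
    p <- 2 * stats::pt(-abs(tstat), df = df)
    detected <- bh_fdr(p) < s$fdr_max
    mean(detected[de])
  }, numeric(1)))
  tpr <- mean(tprs)
  mc_se <- sqrt(max(tpr * (1 - tpr), 1e-12) / (s$n_sims * n_de))
  structure(list(tpr = tpr, mc_se = mc_se, per_sim = tprs, spec = s),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "power_estimate: TPR %.3f (MC se %.4f) at n=%d/group, effect %.2f, CV %.2f\n",
    x$tpr, x$mc_se, x$spec$n_per_group, x$spec$effect_log2fc, x$spec$cv))
  invisible(x)
}

#' Interpolate a precision curve at a cell number
#'
#' Log-linear interpolation (straight line in log(cells) vs log(CV)) between
#' the measured grid points; extrapolation outside the grid is refused.
#'
#' @param curve a \code{\link{precision_curve}}.
#' @param cells requested cells per replicate.
#' @return the interpolated median CV.
#' @export
cv_for_cells <- function(curve, cells) {
  pts <- curve$points
  if (!nrow(pts)) stop("empty precision curve")
  if (cells < min(pts$cells_per_replicate) ||
      cells > max(pts$cells_per_replicate))
    stop("extrapolation refused: ", cells, " outside grid [",
         min(pts$cells_per_replicate), ", ",
         max(pts$cells_per_replicate), "]")
  hit <- which(pts$cells_per_replicate == cells)
  if (length(hit)) return(pts$median_cv[hit[1]])
  exp(stats::approx(log(pts$cells_per_replicate), log(pts$median_cv),
                    xout = log(cells))$y)
}
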