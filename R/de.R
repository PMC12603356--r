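# Negative-binomial pseudo-bulk differential expression.
#
# The GLM machinery is deliberately self-contained: a two-group NB GLM with a
# log link and log-library-size offsets, fitted per gene by IRLS with the
# dispersion held fixed (two-stage fitting), compared to its intercept-only
# null by a 1-df likelihood-ratio chi-square. Everything is vectorized across
# genes; for the 2-parameter design the weighted least-squares update has the
# closed form "per-group weighted mean of the working response".

#' Method-of-moments NB dispersion with empirical-Bayes shrinkage
#'
#' Estimates a per-gene negative-binomial dispersion phi (variance =
#' mu + phi mu^2) from library-size-scaled, group-centered counts. Within
#' each design group, phi is estimated by method of moments as
#' (s^2 - m) / (m^2 - s^2/n_g), the denominator correcting the upward bias
#' of the squared sample mean; group estimates are combined with weights
#' proportional to their degrees of freedom and floored at 0. Gene-wise
#' estimates are then shrunk toward the trimmed-mean common dispersion with
#' the moderation weight df / (df + prior_df), df being the residual degrees
#' of freedom: with few replicates almost all weight sits on the common
#' value, which is what keeps the downstream likelihood-ratio test
#' calibrated.
#'
#' @param counts genes x samples counts (a \code{\link{count_matrix}},
#'   \code{pseudobulk_matrix}, or plain matrix).
#' @param group factor-like vector of group labels, one per column; every
#'   group needs at least 2 samples.
#' @param prior_df prior degrees of freedom of the common dispersion
#'   (default 10, the conventional moderation strength).
#' @param trim trim fraction for the common (trimmed-mean) dispersion
#'   (default 0.1).
#' @return named numeric vector of per-gene dispersions (>= 0).
#' @export
estimate_dispersion <- function(counts, group, prior_df = 10, trim = 0.1) {
  v <- dense_values(counts)
  group <- as.factor(group)
  n_per <- table(group)
  if (any(n_per < 2)) stop("every group needs at least 2 samples")
  lib <- colSums(v)
  sf <- lib / mean(lib)
  vs <- sweep(v, 2L, sf, "/")
  num <- matrix(0, nrow(v), nlevels(group))
  wt <- numeric(nlevels(group))
  for (k in seq_len(nlevels(group))) {
    cols <- which(group == levels(group)[k])
    ng <- length(cols)
    m <- rowMeans(vs[, cols, drop = FALSE])
    s2 <- row_sds(vs[, cols, drop = FALSE])^2
    den <- pmax(m^2 - s2 / ng, 0.25 * m^2)
    phi_k <- ifelse(m > 0, (s2 - m) / den, 0)
    num[, k] <- phi_k * (ng - 1L)
    wt[k] <- ng - 1L
  }
  phi_raw <- pmax(rowSums(num) / sum(wt), 0)
  expressed <- rowMeans(vs) > 0
  common <- if (any(expressed)) mean(phi_raw[expressed], trim = trim) else 0
  df_res <- ncol(v) - nlevels(group)
  w <- df_res / (df_res + prior_df)
  phi <- pmax(w * phi_raw + (1 - w) * common, 0)
  names(phi) <- rownames(v)
  phi
}

# Vectorized IRLS fit of a per-gene NB GLM with log link and fixed
# dispersion. y: G x n counts; offset: length-n log library sizes; phi:
# length-G dispersions; group: NULL (intercept-only) or 0/1 per column.
# Returns per-gene coefficients, fitted means, log-likelihood, convergence.
nb_glm_fit <- function(y, offset, phi, group = NULL, max_iter = 100,
                       tol = 1e-8) {
  G <- nrow(y); n <- ncol(y)
  off <- matrix(offset, G, n, byrow = TRUE)
  phi_eff <- pmax(phi, 1e-10)
  mu <- pmax(y, 1 / 6)
  eta <- log(mu)
  b0 <- rep(0, G); b1 <- if (is.null(group)) NULL else rep(0, G)
  i0 <- if (!is.null(group)) which(group == 0) else NULL
  i1 <- if (!is.null(group)) which(group == 1) else NULL
  converged <- rep(FALSE, G)
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi_eff * mu)
    z <- (eta - off) + (y - mu) / mu
    wz <- w * z
    if (is.null(group)) {
      b0_new <- rowSums(wz) / rowSums(w)
      delta <- abs(b0_new - b0)
      b0 <- b0_new
      eta <- off + b0
    } else {
      m0 <- rowSums(wz[, i0, drop = FALSE]) / rowSums(w[, i0, drop = FALSE])
      m1 <- rowSums(wz[, i1, drop = FALSE]) / rowSums(w[, i1, drop = FALSE])
      delta <- pmax(abs(m0 - b0), abs((m1 - m0) - b1))
      b0 <- m0; b1 <- m1 - m0
      eta <- off + b0
      eta[, i1] <- eta[, i1, drop = FALSE] + b1
    }
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    newly <- !converged & (is.na(delta) | delta < tol * (1 + abs(b0)))
    converged <- converged | newly
    if (all(converged)) break
  }
  ll <- rowSums(matrix(
    stats::dnbinom(as.vector(y), size = 1 / phi_eff, mu = as.vector(mu),
                   log = TRUE), G, n))
  list(b0 = b0, b1 = b1, mu = mu, loglik = ll, converged = converged)
}

#' Negative-binomial likelihood-ratio differential expression
#'
#' Two-group pseudo-bulk DE: per gene, a NB GLM with a group effect (log
#' link, log-library-size offsets, fixed per-gene dispersion) is compared to
#' the intercept-only null by a likelihood-ratio chi-square with 1 df. P
#' values are BH-adjusted and DEGs called at the active thresholds.
#'
#' @param counts genes x samples counts (\code{pseudobulk_matrix},
#'   \code{\link{count_matrix}}, or plain matrix).
#' @param group vector of two group labels, one per column, each group with
#'   at least 2 samples; the second factor level is the "treatment" whose
#'   log2 fold change is reported.
#' @param offsets log library sizes per sample; default
#'   \code{log(colSums(counts))}.
#' @param dispersion per-gene NB dispersions; default
#'   \code{\link{estimate_dispersion}}.
#' @param fdr_max,lfc_min DEG thresholds passed to \code{\link{call_degs}}.
#' @return a \code{de_table} data frame: \code{gene_id}, \code{log2fc},
#'   \code{p}, \code{fdr}, \code{is_deg}, \code{dispersion},
#'   \code{converged}.
#' @export
nb_lrt <- function(counts, group, offsets = NULL, dispersion = NULL,
                   fdr_max = 0.05, lfc_min = 0) {
  v <- dense_values(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly 2 groups required")
  if (any(table(group) < 2)) stop("every group needs at least 2 samples")
  g01 <- as.integer(group) - 1L
  if (is.null(offsets)) {
    lib <- colSums(v)
    if (any(lib <= 0)) stop("zero library size column")
    offsets <- log(lib)
  }
  if (is.null(dispersion)) dispersion <- estimate_dispersion(v, group)
  gene_ids <- rownames(v) %||% paste0("g", seq_len(nrow(v)))

  all_zero <- rowSums(v) == 0
  full <- nb_glm_fit(v, offsets, dispersion, group = g01)
  null <- nb_glm_fit(v, offsets, dispersion, group = NULL)
  dev <- pmax(2 * (full$loglik - null$loglik), 0)
  p <- stats::pchisq(dev, df = 1, lower.tail = FALSE)
  log2fc <- full$b1 / log(2)
  converged <- full$converged & null$converged
  p[!converged] <- 1          # conservative fallback for non-converged fits
  p[all_zero] <- 1
  log2fc[all_zero] <- 0
  out <- data.frame(gene_id = gene_ids, log2fc = log2fc, p = p,
                    fdr = bh_fdr(p), is_deg = FALSE,
                    dispersion = as.numeric(dispersion),
                    converged = converged | all_zero,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  call_degs(out, fdr_max = fdr_max, lfc_min = lfc_min)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Flags genes with \code{fdr < fdr_max} and \code{|log2fc| > lfc_min}
#' (strict inequalities).
#'
#' @param table a \code{de_table}.
#' @param fdr_max FDR threshold (default 0.05).
#' @param lfc_min absolute log2-fold-change threshold (default 0).
#' @return the table with \code{is_deg} set.
#' @export
call_degs <- function(table, fdr_max = 0.05, lfc_min = 0) {
  if (is.null(table$fdr)) stop("fdr column not populated")
  table$is_deg <- table$fdr < fdr_max & abs(table$log2fc) > lfc_min
  attr(table, "deg_criteria") <- c(fdr_max = fdr_max, lfc_min = lfc_min)
  table
}

#' True-positive rate of DE calls against a ground-truth set
#'
#' The TPR is the fraction of ground-truth DEGs also called in the test
#' table, overall and stratified by the truth-set effect size: high
#' (|log2FC| >= 2), medium (1 < |log2FC| < 2), low (|log2FC| <= 1).
#'
#' @param test \code{de_table} being evaluated.
#' @param truth ground-truth \code{de_table} (its \code{is_deg} defines the
#'   positives; its \code{log2fc} defines the strata).
#' @param cv optional named per-gene CV vector (e.g. from
#'   \code{\link{average_cv}}) used to attach per-gene SNR.
#' @return a \code{reproducibility_result}: list with \code{tpr_overall},
#'   \code{tpr_by_stratum}, \code{per_gene} (gene_id, snr, replicated,
#'   stratum), \code{n_truth_degs}, \code{undefined} flag.
#' @export
true_positive_rate <- function(test, truth, cv = NULL) {
  genes <- intersect(truth$gene_id, test$gene_id)
  if (!length(genes)) stop("no shared gene universe")
  truth <- truth[match(genes, truth$gene_id), ]
  test <- test[match(genes, test$gene_id), ]
  pos <- which(truth$is_deg)
  if (!length(pos)) {
    return(structure(list(tpr_overall = NA_real_,
                          tpr_by_stratum = c(high = NA_real_,
                                             medium = NA_real_,
                                             low = NA_real_),
                          per_gene = data.frame(), n_truth_degs = 0L,
                          undefined = TRUE),
                     class = "reproducibility_result"))
  }
  lfc <- abs(truth$log2fc[pos])
  stratum <- ifelse(lfc >= 2, "high", ifelse(lfc > 1, "medium", "low"))
  replicated <- test$is_deg[pos]
  snr_vals <- rep(NA_real_, length(pos))
  if (!is.null(cv)) {
    cvv <- cv[match(truth$gene_id[pos], names(cv))]
    ok <- !is.na(cvv) & cvv > 0
    snr_vals[ok] <- lfc[ok] / cvv[ok]
  }
  by_stratum <- vapply(c("high", "medium", "low"), function(s) {
    sel <- stratum == s
    if (!any(sel)) NA_real_ else mean(replicated[sel])
  }, numeric(1))
  structure(list(tpr_overall = mean(replicated),
                 tpr_by_stratum = by_stratum,
                 per_gene = data.frame(gene_id = truth$gene_id[pos],
                                       snr = snr_vals,
                                       replicated = replicated,
                                       stratum = stratum,
                                       stringsAsFactors = FALSE),
                 n_truth_degs = length(pos), undefined = FALSE),
            class = "reproducibility_result")
}

#' @export
print.reproducibility_result <- function(x, ...) {
  if (x$undefined) {
    cat("reproducibility_result: undefined (no ground-truth DEGs)\n")
    return(invisible(x))
  }
  cat(sprintf("reproducibility_result: TPR %.3f over %d truth DEGs\n",
              x$tpr_overall, x$n_truth_degs))
  print(round(x$tpr_by_stratum, 3))
  invisible(x)
}

#' Per-gene signal-to-noise ratio
#'
#' SNR = |log2 fold change| / CV; genes whose CV is undefined or zero are
#' excluded.
#'
#' @param log2fc named per-gene log2 fold changes.
#' @param cv named per-gene CVs (e.g. \code{mean_cv} from
#'   \code{\link{average_cv}}).
#' @return named numeric vector over the genes with a usable CV.
#' @export
snr <- function(log2fc, cv) {
  genes <- intersect(names(log2fc), names(cv))
  cvv <- cv[genes]
  ok <- !is.na(cvv) & cvv > 0
  out <- abs(log2fc[genes[ok]]) / cvv[ok]
  out
}

#' Exact (hypergeometric) test of DEG replication
#'
#' Over-representation tail probability P(X >= n_overlap) with X ~
#' Hypergeometric(n_universe, n_deg_a, n_deg_b): the chance of at least the
#' observed overlap between two DEG sets drawn from a shared gene universe.
#'
#' @param n_universe size of the shared gene universe.
#' @param n_deg_a,n_deg_b DEG counts in the two analyses.
#' @param n_overlap observed overlap.
#' @return the one-sided p-value.
#' @export
replication_exact_test <- function(n_universe, n_deg_a, n_deg_b, n_overlap) {
  if (n_overlap > min(n_deg_a, n_deg_b) || max(n_deg_a, n_deg_b) > n_universe ||
      any(c(n_universe, n_deg_a, n_deg_b, n_overlap) < 0))
    stop("inconsistent counts")
  stats::phyper(n_overlap - 1, n_deg_a, n_universe - n_deg_a, n_deg_b,
                lower.tail = FALSE)
}
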