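# NB dispersion estimation, the likelihood-ratio test, DEG calling, TPR,
# SNR, and the replication exact test.

test_that("dispersion estimates hit the Poisson limit and recover NB truth", {
  pois <- make_nb_pseudobulk(G = 1500, phi = 0, seed = 2)
  d0 <- estimate_dispersion(pois$y, pois$group)
  expect_lte(median(d0), 0.05)

  nb <- make_nb_pseudobulk(G = 2000, phi = 0.4, seed = 3)
  d4 <- estimate_dispersion(nb$y, nb$group)
  expect_gte(median(d4), 0.2)
  expect_lte(median(d4), 0.6)

  # constant counts within groups: dispersion 0
  const <- matrix(rep(c(5, 9), each = 3), 4, 6, byrow = TRUE,
                  dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  expect_equal(unname(estimate_dispersion(const, rep(c("a", "b"), each = 3))),
               rep(0, 4))

  expect_error(estimate_dispersion(const[, 1:3], c("a", "a", "b")),
               "at least 2 samples")
})

test_that("nb_lrt is null on identical groups and calibrated under the null", {
  # identical counts in both groups: no effect, p ~ 1
  y <- matrix(rep(rpois(50, 100), 6), 50, 6)
  rownames(y) <- paste0("g", 1:50)
  de <- nb_lrt(y, rep(c("a", "b"), each = 3))
  expect_equal(de$log2fc, rep(0, 50), tolerance = 1e-6)
  expect_true(all(de$p > 0.99))

  # type-I calibration at phi = 0.1, scaled-down (full run in acceptance)
  null <- make_nb_pseudobulk(G = 1500, phi = 0.1, seed = 5)
  de2 <- nb_lrt(null$y, null$group)
  expect_lt(abs(mean(de2$p < 0.05) - 0.05), 0.025)
})

test_that("nb_lrt detects four-fold shifts with high power", {
  sim <- make_nb_pseudobulk(G = 1500, phi = 0.1, fold = 4, frac_de = 0.1,
                            seed = 6)
  de <- nb_lrt(sim$y, sim$group)
  expect_gt(mean(de$fdr[de$gene_id %in% sim$de_genes] < 0.05), 0.8)
  # direction: first half of the DE block is up in group b
  up <- sim$de_genes[seq_len(length(sim$de_genes) / 2)]
  expect_gt(median(de$log2fc[de$gene_id %in% up]), 1.5)
})

test_that("nb_lrt is invariant to within-group relabeling and antisymmetric", {
  sim <- make_nb_pseudobulk(G = 200, phi = 0.1, fold = 3, frac_de = 0.2,
                            seed = 9)
  base <- nb_lrt(sim$y, sim$group)
  shuffled <- nb_lrt(sim$y[, c(2, 3, 1, 6, 4, 5)], sim$group)
  expect_equal(shuffled$p, base$p, tolerance = 1e-6)
  flipped <- nb_lrt(sim$y, rev(sim$group),
                    dispersion = estimate_dispersion(sim$y, sim$group))
  expect_equal(flipped$log2fc, -base$log2fc, tolerance = 1e-5)
  expect_equal(flipped$p, base$p, tolerance = 1e-6)
})

test_that("nb_lrt agrees with an independent NB GLM implementation", {
  skip_if_not_installed("edgeR")
  sim <- make_nb_pseudobulk(G = 400, phi = 0.15, fold = 2, frac_de = 0.25,
                            seed = 14)
  dge <- edgeR::DGEList(counts = sim$y, group = sim$group)
  design <- model.matrix(~ factor(sim$group))
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmFit(dge, design, prior.count = 0)
  lrt <- edgeR::glmLRT(fit)
  # same model with the same dispersions: statistics must match closely
  ours <- nb_lrt(sim$y, sim$group,
                 offsets = log(colSums(sim$y)),
                 dispersion = dge$tagwise.dispersion)
  expect_gt(cor(-log10(ours$p + 1e-300),
                -log10(lrt$table$PValue + 1e-300)), 0.999)
  expect_lt(median(abs(ours$log2fc - lrt$table$logFC)), 0.01)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # hand-computed staggered case: p_(i) * n / i, cumulative minimum
  p <- c(0.005, 0.1, 0.02, 0.8)
  expect_equal(bh_fdr(p), c(0.02, 4 / 30, 0.04, 0.8))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone and never below raw p
  set.seed(10)
  pr <- runif(100)
  adj <- bh_fdr(pr)
  expect_true(all(adj >= pr))
  ord <- order(pr)
  expect_true(all(diff(adj[ord]) >= -1e-12))
})

test_that("DEG calling uses strict thresholds on FDR and fold change", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    log2fc = c(0.5, 0.05, 1),
                    p = c(0.001, 0.001, 0.05),
                    fdr = c(0.04, 0.04, 0.05))
  out <- call_degs(tab, fdr_max = 0.05, lfc_min = 0)
  expect_equal(out$is_deg, c(TRUE, TRUE, FALSE))   # fdr = 0.05 excluded
  out2 <- call_degs(tab, fdr_max = 0.05, lfc_min = 0.1)
  expect_equal(out2$is_deg, c(TRUE, FALSE, FALSE)) # |lfc| 0.05 excluded
})

test_that("TPR equals brute-force set intersection, stratified by effect", {
  mk <- function(ids, deg, lfc) data.frame(gene_id = ids, log2fc = lfc,
                                           p = 0.5, fdr = 0.5,
                                           is_deg = deg)
  ids <- sprintf("g%02d", 1:20)
  set.seed(20)
  for (trial in 1:20) {
    truth_deg <- runif(20) < 0.5
    test_deg <- runif(20) < 0.5
    lfc <- runif(20, 0, 3)
    res <- true_positive_rate(mk(ids, test_deg, lfc * 0.9),
                              mk(ids, truth_deg, lfc))
    brute <- length(intersect(ids[truth_deg], ids[test_deg])) /
      sum(truth_deg)
    if (sum(truth_deg) == 0) {
      expect_true(res$undefined)
    } else {
      expect_equal(res$tpr_overall, brute)
    }
  }

  # exact strata boundaries: high >= 2, medium (1, 2), low <= 1
  truth <- mk(ids[1:4], rep(TRUE, 4), c(2, 1.99, 1.01, 1))
  test <- mk(ids[1:4], c(TRUE, FALSE, TRUE, TRUE), c(2, 2, 1, 1))
  res <- true_positive_rate(test, truth)
  expect_equal(res$per_gene$stratum, c("high", "medium", "medium", "low"))
  expect_equal(unname(res$tpr_by_stratum),
               c(1, 0.5, 1))

  # test = truth: TPR 1 in every populated stratum
  res2 <- true_positive_rate(truth, truth)
  expect_equal(res2$tpr_overall, 1)
  expect_true(all(res2$tpr_by_stratum[!is.na(res2$tpr_by_stratum)] == 1))

  # zero truth DEGs: undefined, not an error
  res3 <- true_positive_rate(test, mk(ids[1:4], rep(FALSE, 4), 1:4))
  expect_true(res3$undefined)
})

test_that("SNR is |log2fc| / CV over genes with usable CV", {
  lfc <- c(a = 2, b = 0, c = 1)
  cv <- c(a = 0.5, b = 0.2, c = 0, d = 1)
  s <- snr(lfc, cv)
  expect_equal(unname(s["a"]), 4)
  expect_equal(unname(s["b"]), 0)
  expect_false("c" %in% names(s))   # zero CV excluded
  expect_false("d" %in% names(s))   # no fold change available
})

test_that("replication exact test matches brute-force enumeration", {
  # worked case: universe 10, |A| = |B| = 5, overlap 5 -> 1/252
  expect_equal(replication_exact_test(10, 5, 5, 5), 1 / 252)
  expect_equal(replication_exact_test(5, 0, 0, 0), 1)

  # brute force over all subsets B of a small universe, A fixed
  brute <- function(N, a, b, k) {
    A <- seq_len(a)
    combos <- combn(N, b)
    mean(apply(combos, 2, function(B) length(intersect(A, B)) >= k))
  }
  set.seed(30)
  for (trial in 1:15) {
    N <- sample(4:12, 1)
    a <- sample.int(N, 1); b <- sample.int(N, 1)
    k <- sample(0:min(a, b), 1)
    expect_equal(replication_exact_test(N, a, b, k), brute(N, a, b, k),
                 info = sprintf("N=%d a=%d b=%d k=%d", N, a, b, k))
  }
  expect_error(replication_exact_test(10, 5, 5, 6), "inconsistent")
})
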