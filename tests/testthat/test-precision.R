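# CV computation, precision curves, thresholds, covariate regression, and
# the slope-difference Z-test.

test_that("cv_per_gene matches forced arithmetic and handles edge cases", {
  m <- rbind(flat = c(10, 10, 10), ramp = c(1, 2, 3), zero = c(0, 0, 0))
  cv <- cv_per_gene(m)
  expect_equal(unname(cv["flat"]), 0)
  expect_equal(unname(cv["ramp"]), 0.5)          # sd 1 / mean 2
  expect_true(is.na(cv["zero"]))
  expect_error(cv_per_gene(m[, 1, drop = FALSE]), "at least 2")

  # scale invariance: per-gene rescaling leaves CV unchanged
  set.seed(21)
  x <- matrix(rpois(60, 20) + 1, 20, 3)
  expect_equal(cv_per_gene(x * 7), cv_per_gene(x))

  # CPM normalization equalizes depth before CV
  y <- rbind(a = c(10, 20), b = c(90, 180))
  expect_equal(unname(cv_per_gene(y, normalize = TRUE)), c(0, 0))
})

test_that("average_cv reduces to one draw at R = 1 and to 0 for clones", {
  pop <- make_poisson_cells(G = 30, n = 12, seed = 5)
  one <- average_cv(pop$counts, pop$ann, "ind1", "Exc", R = 1,
                    seed_base = 10)
  reps <- sample_replicates(pop$counts, pop$ann, "ind1", "Exc",
                            seed = scprecision:::derive_seed(10, 1))
  cv <- cv_per_gene(reps)
  expect_equal(one$mean_cv[one$detected],
               unname(cv[!is.na(cv)]))

  # identical cells: every expressed gene has CV exactly 0
  m <- matrix(rep(c(2, 0, 7), 9), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), sprintf("c%d", 1:9)))
  ann <- cell_annotation(data.frame(cell_id = colnames(m),
                                    individual_id = "i", cell_type = "t"))
  tab <- average_cv(count_matrix(m), ann, "i", "t", R = 5)
  expect_equal(tab$mean_cv[tab$detected], c(0, 0))
  expect_false(tab$detected[tab$gene_id == "g2"])
})

test_that("Poisson replicates recover the 1/sqrt(m*lambda) closed form", {
  # scaled-down spot check (the acceptance suite runs the full version)
  pop <- make_poisson_cells(G = 800, n = 300, lambda = 10, seed = 33)
  tab <- average_cv(pop$counts, pop$ann, "ind1", "Exc", R = 30,
                    cells_per_replicate = 10, seed_base = 4)
  med <- median(tab$mean_cv[tab$detected])
  expect_lt(abs(med - 0.1) / 0.1, 0.15)
})

test_that("average_cv has lower across-run variance than a single repeat", {
  pop <- make_poisson_cells(G = 60, n = 30, lambda = 3, seed = 12)
  med_multi <- med_single <- numeric(50)
  for (run in 1:50) {
    multi <- average_cv(pop$counts, pop$ann, "ind1", "Exc", R = 10,
                        cells_per_replicate = 5, seed_base = run * 100)
    single <- average_cv(pop$counts, pop$ann, "ind1", "Exc", R = 1,
                         cells_per_replicate = 5, seed_base = run * 100)
    med_multi[run] <- median(multi$mean_cv[multi$detected])
    med_single[run] <- median(single$mean_cv[single$detected])
  }
  expect_lt(var(med_multi), var(med_single))
})

test_that("precision curves decay with cell number and respect the cap", {
  pop <- make_poisson_cells(G = 200, n = 90, lambda = 5, seed = 7)
  curve <- precision_curve(pop$counts, pop$ann, "ind1", "Exc",
                           grid = c(1, 30), R = 30, seed_base = 2)
  expect_equal(nrow(curve$points), 2L)
  expect_lt(curve$points$median_cv[2], curve$points$median_cv[1])

  single <- precision_curve(pop$counts, pop$ann, "ind1", "Exc",
                            grid = 5, R = 5)
  expect_equal(nrow(single$points), 1L)
  expect_error(precision_curve(pop$counts, pop$ann, "ind1", "Exc",
                               grid = c(10, 31), R = 2),
               "exceeds floor")

  # default grid is capped at floor(n/3)
  def <- precision_curve(pop$counts, pop$ann, "ind1", "Exc", R = 2)
  expect_true(all(def$points$cells_per_replicate <= 30))
})

test_that("min_cells_for_cv looks up the threshold and is monotone in it", {
  curve <- structure(list(points = data.frame(
    cells_per_replicate = c(100L, 500L),
    median_cv = c(0.3, 0.09))), class = "precision_curve")
  expect_equal(min_cells_for_cv(curve, 0.1), 500L)
  expect_true(is.na(min_cells_for_cv(curve, 0.05)))
  expect_equal(min_cells_for_cv(curve, 0.5), 100L)

  # monotone: larger threshold, smaller-or-equal answer
  set.seed(2)
  pts <- data.frame(cells_per_replicate = c(10L, 50L, 200L, 1000L),
                    median_cv = sort(runif(4, 0.05, 0.6),
                                     decreasing = TRUE))
  cv2 <- structure(list(points = pts), class = "precision_curve")
  answers <- vapply(seq(0.05, 0.7, by = 0.05), function(th) {
    a <- min_cells_for_cv(cv2, th)
    if (is.na(a)) 1e9 else as.numeric(a)   # not-reached sentinel
  }, numeric(1))
  expect_true(all(diff(answers) <= 0))
})

test_that("fraction_passing counts samples at or below the threshold", {
  mk <- function(med) data.frame(gene_id = "g", mean_cv = med,
                                 n_repeats_defined = 1L, detected = TRUE)
  tables <- c(lapply(rep(0.05, 2), mk), lapply(rep(0.4, 38), mk))
  expect_equal(fraction_passing(tables, 0.1), 0.05)
  expect_equal(fraction_passing(lapply(rep(0.01, 4), mk), 0.1), 1)
  expect_error(fraction_passing(list()), "empty input")
})

test_that("covariate regression recovers exact fits and stays calibrated", {
  med <- data.frame(sample_id = sprintf("s%d", 1:6),
                    median_cv = c(0.5, 0.4, 0.3, 0.25, 0.2, 0.1))
  cov <- data.frame(sample_id = med$sample_id,
                    value = 10 - 12 * med$median_cv)
  # perfect fit triggers R's advisory "may be unreliable" warning
  fit <- suppressWarnings(cv_covariate_correlation(med, cov))
  expect_equal(fit$r, -1)
  expect_equal(fit$r2, 1)
  expect_equal(fit$slope, -1 / 12)

  expect_error(cv_covariate_correlation(med[1:2, ], cov[1:2, ]),
               "fewer than 3")
  cov0 <- data.frame(sample_id = med$sample_id, value = 7)
  expect_error(cv_covariate_correlation(med, cov0), "zero variance")

  # null calibration: independent covariate, p roughly uniform
  set.seed(99)
  pvals <- replicate(200, {
    d <- data.frame(sample_id = sprintf("s%d", 1:100),
                    median_cv = runif(100))
    cc <- data.frame(sample_id = d$sample_id, value = rnorm(100))
    cv_covariate_correlation(d, cc)$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("slope-difference Z-test matches the normal-CDF oracle", {
  f <- function(b, se) slope_fit(b, se, 10)
  same <- slope_difference_z(f(1.2, 0.1), f(1.2, 0.2))
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)

  # b1=1, b2=0, se1=se2=sqrt(0.5): diff 1, p = 2*(1 - Phi(1)) ~ 0.3173
  z <- slope_difference_z(f(1, sqrt(0.5)), f(0, sqrt(0.5)))
  expect_equal(z$diff, 1)
  expect_equal(z$p, 2 * pnorm(-1))
  expect_equal(round(z$p, 4), 0.3173)

  # antisymmetry in the arguments, p unchanged
  fwd <- slope_difference_z(f(2, 0.3), f(1, 0.4))
  rev <- slope_difference_z(f(1, 0.4), f(2, 0.3))
  expect_equal(fwd$diff, -rev$diff)
  expect_equal(fwd$p, rev$p)

  expect_error(slope_fit(1, 0), "positive")
})
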