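test_that("misclassification rate counts reference-set contamination", {
  truth <- list(da_taxa = "d", nonda_taxa = c("a", "b", "c"))
  expect_equal(misclassification_rate(c("a", "b", "c", "d"), truth), 0.25)
  expect_equal(misclassification_rate(c("a", "b"), truth), 0)
  expect_equal(misclassification_rate("d", truth), 1)
  expect_error(misclassification_rate(character(0), truth), "empty")
})

test_that("Welch t-test matches the textbook formula and handles degeneracy", {
  m <- rbind(t1 = c(1, 2, 3, 4, 5, 6), t2 = c(2, 2, 2, 2, 2, 2))
  colnames(m) <- paste0("s", 1:6)
  cov <- tibble::tibble(sample = colnames(m), group = rep(1:2, each = 3))
  res <- per_taxon_tests(m, cov, test = "t_test", log_transform = FALSE)
  # groups [1,2,3] vs [4,5,6]: Welch t = -3.674, df = 4, p = 0.0214
  expect_equal(res$statistic[1], -3.674, tolerance = 1e-3)
  expect_equal(res$p_value[1], 0.02131, tolerance = 1e-3)
  # cross-check against stats::t.test
  tt <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value[1], tt$p.value, tolerance = 1e-12)
  # identical values in both groups: statistic 0, p = 1
  expect_equal(res$statistic[2], 0)
  expect_equal(res$p_value[2], 1)
})

test_that("Pearson route flags a perfectly correlated taxon", {
  set.seed(2)
  m <- rbind(t1 = 1:8, t2 = rpois(8, 10) + 1)
  colnames(m) <- paste0("s", 1:8)
  cov <- tibble::tibble(sample = colnames(m), latent = as.numeric(1:8))
  res <- per_taxon_tests(m, cov, test = "pearson", log_transform = FALSE)
  expect_equal(res$statistic[1], 1, tolerance = 1e-12)
  expect_lt(res$p_value[1], 1e-12)
  ct <- cor.test(m["t2", ], cov$latent)
  expect_equal(res$p_value[2], ct$p.value, tolerance = 1e-12)
  expect_error(per_taxon_tests(m, cov, test = "t_test"), "group")
  cov3 <- tibble::tibble(sample = colnames(m), group = c(1, 1, 2, 2, 3, 3, 3, 3))
  expect_error(per_taxon_tests(m, cov3, test = "t_test"), "binary")
})

test_that("FDP and sensitivity bookkeeping follows the conventions", {
  truth <- list(da_taxa = c("d1", "d2", "d3", "d4"),
                nonda_taxa = c("n1", "n2"))
  expect_equal(fdp_and_sensitivity(c("d1", "d2", "d3", "d4"), truth)$fdp, 0)
  expect_equal(fdp_and_sensitivity(c("d1", "d2", "d3", "d4"), truth)$sensitivity, 1)
  r <- fdp_and_sensitivity(character(0), truth)
  expect_equal(r$fdp, 0)
  expect_equal(r$sensitivity, 0)
  r2 <- fdp_and_sensitivity(c("n1", "d1"), truth)
  expect_equal(r2$fdp, 0.5)
  expect_equal(r2$sensitivity, 0.25)
  # conservation: |rejections| = sensitivity*|J1| + fdp*|rejections|
  expect_equal(r2$n_rejections,
               r2$sensitivity * 4 + r2$fdp * r2$n_rejections)
  # no DA taxa: sensitivity undefined
  expect_true(is.na(fdp_and_sensitivity("n1", list(da_taxa = character(0),
                                                   nonda_taxa = "n1"))$sensitivity))
})

test_that("PERMANOVA enumerates small designs exactly and matches the centroid oracle", {
  # 1-D toy: {0, 0.1} vs {10, 10.1}; all 6 assignments enumerable
  y <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
              dimnames = list(paste0("s", 1:4), "t1"))
  res <- permanova(t(y), rep(1:2, each = 2), n_permutations = 99,
                   log_transform = FALSE)
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(res$pseudo_f, oracle_pseudo_f(y, rep(1:2, each = 2)),
               tolerance = 1e-10)

  # random data: distance-based pseudo-F equals the coordinate-space oracle
  set.seed(19)
  for (rep in 1:3) {
    y <- matrix(rnorm(15 * 4), nrow = 15,
                dimnames = list(paste0("s", 1:15), paste0("t", 1:4)))
    g <- c(rep(1, 7), rep(2, 8))
    res <- permanova(t(y), g, n_permutations = 5, log_transform = FALSE, seed = rep)
    expect_equal(res$pseudo_f, oracle_pseudo_f(y, g), tolerance = 1e-10)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 on the pseudo-F statistic", {
  skip_if_not_installed("vegan")
  set.seed(23)
  y <- matrix(rnorm(20 * 6), nrow = 20,
              dimnames = list(paste0("s", 1:20), paste0("t", 1:6)))
  g <- factor(rep(1:2, each = 10))
  res <- permanova(t(y), as.integer(g), n_permutations = 199,
                   log_transform = FALSE, seed = 1)
  ad <- vegan::adonis2(dist(y) ~ g, permutations = 199)
  expect_equal(res$pseudo_f, ad$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA p-values are calibrated under label exchangeability", {
  # fixed data, random labels: p is uniform by exchangeability alone
  set.seed(7)
  y <- matrix(rnorm(12 * 5), nrow = 12,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:5)))
  ps <- vapply(1:150, function(r) {
    permanova(t(y), sample(rep(1:2, each = 6)), n_permutations = 99,
              log_transform = FALSE, seed = r)$p_value
  }, numeric(1))
  # super-uniformity at common levels, within 3 binomial SEs of nominal
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
  expect_lte(mean(ps <= 0.2), 0.2 + 3 * sqrt(0.2 * 0.8 / 150))
  one_group <- matrix(rnorm(12), 2, 6,
                      dimnames = list(c("t1", "t2"), paste0("s", 1:6)))
  expect_error(permanova(one_group, rep(1, 6), log_transform = FALSE),
               "two groups")
})

test_that("PCoA recovers Euclidean configurations and degenerate geometries", {
  set.seed(31)
  pts <- matrix(rnorm(10 * 2), ncol = 2,
                dimnames = list(paste0("s", 1:10), c("x", "y")))
  res <- pcoa_coordinates(t(pts), k = 2, log_transform = FALSE)
  rec <- as.matrix(res$coordinates[, -1])
  # Procrustes check: distances are reproduced exactly up to rotation/reflection
  expect_equal(as.matrix(dist(rec)), as.matrix(dist(pts)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigenvalue sum equals total centred inertia
  expect_equal(sum(res$eigenvalues),
               sum(sweep(pts, 2, colMeans(pts))^2), tolerance = 1e-8)

  # identical samples -> no positive axes survive
  same <- matrix(5, nrow = 3, ncol = 4,
                 dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
  res0 <- pcoa_coordinates(same, k = 2, log_transform = FALSE)
  expect_equal(ncol(res0$coordinates) - 1, 0)

  # collinear points: first axis carries essentially all positive inertia
  line <- matrix(c(0, 1, 2, 3), ncol = 1,
                 dimnames = list(paste0("s", 1:4), "t1"))
  res1 <- pcoa_coordinates(t(cbind(line, 2 * line)), k = 3, log_transform = FALSE)
  ev <- res1$eigenvalues[res1$eigenvalues > 1e-10]
  expect_gt(ev[1] / sum(ev), 0.999)
  expect_error(pcoa_coordinates(t(pts), k = 10, log_transform = FALSE), "n - 1")
})
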