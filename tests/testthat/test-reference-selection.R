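test_that("empirical_cdf counts correctly and meets the DKW band on uniforms", {
  f <- empirical_cdf(c(0.2, 0.4, 0.6))
  expect_equal(f(0.4), 2 / 3)
  expect_equal(f(0.1), 0)
  expect_equal(f(0.6), 1)
  expect_equal(f(2), 1)
  expect_error(empirical_cdf(numeric(0)), "empty")

  # DKW: sup |F_n - F| <= sqrt(log(2/alpha)/(2n)), alpha = 0.01, n = 1000 -> 0.0515
  set.seed(5)
  u <- runif(1000)
  f <- empirical_cdf(u)
  grid <- seq(0, 1, by = 1e-3)
  expect_lt(max(abs(f(grid) - grid)), 0.08)
})

test_that("null resampling is degenerate on noiseless data and deterministic under a seed", {
  cm <- proportional_counts(d = 15, n = 8)
  st <- median_rank_statistics(cm)
  f0 <- estimate_f0(cm, st, gamma = 0.8, n_resamples = 20, seed = 3)
  meds <- attr(f0, "medians")
  expect_true(all(meds == 1))
  expect_equal(f0(1 - 1e-9), 0)

  cm2 <- random_counts(d = 20, n = 12, seed = 9, lambda = 30)
  st2 <- median_rank_statistics(cm2)
  g <- sort(st2$m)[10]  # ensure >= 10 candidates
  a <- estimate_f0(cm2, st2, gamma = g - 1e-9, n_resamples = 10, seed = 7)
  b <- estimate_f0(cm2, st2, gamma = g - 1e-9, n_resamples = 10, seed = 7)
  expect_identical(attr(a, "medians"), attr(b, "medians"))
  expect_error(estimate_f0(cm2, st2, gamma = 1, n_resamples = 10, seed = 1),
               "lower gamma")
})

test_that("resampled null medians track the true statistic distribution with no DA taxa", {
  # wide, high depth range: the low-noise regime where rank similarity is
  # strong for every null taxon and the candidate set is the full panel
  cfg <- sim_config(d = 100, n = 50, prop_da = 0, depth_range = c(1e4, 1e6),
                    seed = 21)
  sim <- simulate_counts(cfg)
  cm <- filter_quietly(sim$counts)
  st <- median_rank_statistics(cm)
  f0 <- estimate_f0(cm, st, gamma = 0.8, n_resamples = 50, seed = 21)
  meds <- attr(f0, "medians")
  # two-sample KS distance between pooled null medians and the observed M
  grid <- sort(unique(c(meds, st$m)))
  ks <- max(abs(f0(grid) - empirical_cdf(st$m)(grid)))
  expect_lt(ks, 0.1)
})

test_that("pi0 closed form matches the grid-search oracle and clips correctly", {
  # two qualifying taxa with survival pairs (0.3, 0.4) and (0.1, 0.15)
  st <- tibble::tibble(taxon = c("a", "b"), m = c(0.85, 0.95))
  f_hat <- function(t) ifelse(t < 0.85, 0, ifelse(t < 0.95, 0.7, 0.9))
  f0_hat <- function(t) ifelse(t < 0.85, 0, ifelse(t < 0.95, 0.6, 0.85))
  p <- estimate_pi0(st, f_hat, f0_hat, gamma = 0.8)
  expect_equal(p, 0.135 / 0.1825, tolerance = 1e-12)
  expect_equal(oracle_pi0(st$m, f_hat, f0_hat, 0.8), 0.740, tolerance = 1e-3)

  # random step functions: closed form equals fine grid search
  set.seed(8)
  for (rep in 1:3) {
    m <- runif(30, 0.5, 1)
    f_hat <- empirical_cdf(runif(200, 0.4, 1))
    f0_hat <- empirical_cdf(runif(200, 0.6, 1))
    st2 <- tibble::tibble(taxon = as.character(seq_along(m)), m = m)
    expect_equal(estimate_pi0(st2, f_hat, f0_hat, 0.6),
                 oracle_pi0(m, f_hat, f0_hat, 0.6, grid = seq(0, 1, 1e-4)),
                 tolerance = 1e-3)
  }

  # all null mass at the right edge -> pi0 = 1 with a warning
  st3 <- tibble::tibble(taxon = "a", m = 0.9)
  expect_warning(
    p3 <- estimate_pi0(st3, function(t) 0.5, function(t) 1, gamma = 0.8), "pi0 = 1")
  expect_equal(p3, 1)

  # a_j = 0 everywhere -> clipped to the 1e-6 floor
  p4 <- estimate_pi0(st3, function(t) 1, function(t) 0.5, gamma = 0.8)
  expect_equal(p4, 1e-6)
})

test_that("threshold selection follows the misclassification ratio on the grid", {
  # grid {0.7, 0.8, 0.9}; survival of F: 0.8, 0.42, 0.165; of F0: 0.9, 0.5, 0.2
  st <- tibble::tibble(taxon = c("a", "b", "c"), m = c(0.7, 0.8, 0.9))
  f_hat <- stats::stepfun(c(0.7, 0.8, 0.9), c(0.2, 0.58, 0.835, 1))
  f0_hat <- stats::stepfun(c(0.7, 0.8, 0.9), c(0.1, 0.5, 0.8, 1))
  # e(T) = 0.1, 0.0476, 0.0303 at the three grid points
  t_hat <- choose_threshold(st, f_hat, f0_hat, pi0_hat = 0.8, eta = 0.05)
  expect_equal(t_hat, 0.8 - 1e-12)
  expect_equal(oracle_threshold(st$m, f_hat, f0_hat, 0.8, 0.05), 0.8 - 1e-12)

  # eta large -> most permissive grid point
  expect_equal(choose_threshold(st, f_hat, f0_hat, 0.8, eta = 0.999), 0.7 - 1e-12)

  # random empirical CDFs: implementation equals the direct-evaluation oracle
  set.seed(13)
  for (rep in 1:5) {
    m <- round(runif(40, 0, 1), 2)
    st2 <- tibble::tibble(taxon = as.character(seq_along(m)), m = m)
    f_hat <- empirical_cdf(m)
    f0_hat <- empirical_cdf(runif(300, 0.3, 1))
    pi0 <- runif(1, 0.4, 1)
    eta <- runif(1, 0.02, 0.3)
    expected <- oracle_threshold(m, f_hat, f0_hat, pi0, eta)
    if (is.na(expected)) {
      expect_error(choose_threshold(st2, f_hat, f0_hat, pi0, eta), "unattainable")
    } else {
      expect_equal(choose_threshold(st2, f_hat, f0_hat, pi0, eta), expected)
    }
  }
})

test_that("noiseless proportional data selects every taxon at any eta", {
  cm <- proportional_counts(d = 50, n = 20, seed = 2)
  for (eta in c(0.01, 0.2)) {
    fit <- fit_quietly(cm, eta = eta, seed = 1)
    expect_setequal(fit$reference_set, rownames(cm))
    expect_equal(fit$pi0_hat, 1)
  }
})

test_that("the fit is reproducible, eta-monotone, and controls the plug-in estimate", {
  cfg <- sim_config(d = 80, n = 40, prop_da = 0.1, signal = 4,
                    depth_range = c(5e3, 5e4), seed = 31)
  cm <- filter_quietly(simulate_counts(cfg)$counts)

  f1 <- fit_quietly(cm, eta = 0.05, seed = 5)
  f2 <- fit_quietly(cm, eta = 0.05, seed = 5)
  expect_identical(f1$reference_set, f2$reference_set)
  expect_identical(f1$t_hat, f2$t_hat)

  # J0-hat non-decreasing and T-hat non-increasing in eta (same seed)
  fits <- lapply(c(0.01, 0.05, 0.2), function(e) fit_quietly(cm, eta = e, seed = 5))
  expect_true(all(fits[[1]]$reference_set %in% fits[[2]]$reference_set))
  expect_true(all(fits[[2]]$reference_set %in% fits[[3]]$reference_set))
  expect_true(fits[[1]]$t_hat >= fits[[2]]$t_hat)
  expect_true(fits[[2]]$t_hat >= fits[[3]]$t_hat)

  # plug-in misclassification estimate at T-hat is within target
  for (f in fits) {
    e_hat <- 1 - f$pi0_hat * (1 - f$f0_hat(f$t_hat)) / (1 - f$f_hat(f$t_hat))
    expect_lte(max(min(e_hat, 1), 0), f$eta)
  }
})

test_that("tidy/glance/autoplot expose the fitted model", {
  cm <- proportional_counts(d = 20, n = 10)
  fit <- fit_quietly(cm, seed = 1)
  td <- tidy(fit)
  expect_named(td, c("taxon", "m", "in_candidate", "in_reference"))
  expect_equal(nrow(td), 20)
  gl <- glance(fit)
  expect_equal(gl$n_reference, 20)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")

  dir <- withr::local_tempdir()
  p <- file.path(dir, "model.json")
  write_reference_model(fit, p)
  model <- jsonlite::read_json(p)
  expect_equal(model$t_hat, fit$t_hat)
  expect_setequal(unlist(model$reference_set), fit$reference_set)
})
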