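# Independent brute-force oracles and small fixture builders used across the
# suite.  These deliberately avoid the code paths they check.

# Mid-rank Pearson correlation from first principles.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Double loop over the full d x d pairwise Spearman matrix.
oracle_median_stats <- function(counts) {
  d <- nrow(counts)
  m <- numeric(d)
  for (j in seq_len(d)) {
    r <- vapply(seq_len(d), function(k) {
      oracle_spearman(counts[j, ], counts[k, ])
    }, numeric(1))
    m[j] <- median(r)
  }
  m
}

# Grid search for the least-squares pi0 over candidate taxa.
oracle_pi0 <- function(m, f_hat, f0_hat, gamma, grid = seq(0, 1, by = 0.001)) {
  mm <- m[m > gamma]
  loss <- vapply(grid, function(p) {
    sum((1 - f_hat(mm) - p * (1 - f0_hat(mm)))^2)
  }, numeric(1))
  grid[which.min(loss)]
}

# Direct evaluation of the misclassification ratio on every grid point.
oracle_threshold <- function(m, f_hat, f0_hat, pi0, eta) {
  grid <- sort(unique(m)) - 1e-12
  for (t in grid) {
    surv <- 1 - f_hat(t)
    if (surv <= 0) break
    e <- min(max(1 - pi0 * (1 - f0_hat(t)) / surv, 0), 1)
    if (e <= eta) return(t)
  }
  NA_real_
}

# Pseudo-F recomputed from group centroids in coordinate space (valid for
# Euclidean distances), not from the distance matrix.
oracle_pseudo_f <- function(y, labels) {
  n <- nrow(y)
  g <- unique(labels)
  grand <- colMeans(y)
  ss_total <- sum(sweep(y, 2, grand)^2)
  ss_within <- 0
  for (lev in g) {
    sub <- y[labels == lev, , drop = FALSE]
    ss_within <- ss_within + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  ((ss_total - ss_within) / (length(g) - 1)) / (ss_within / (n - length(g)))
}

# Noiseless proportional world: counts = outer(A_j, c_i), scaled up to stay
# integral.  Every taxon is a positive multiple of every other across samples.
proportional_counts <- function(d = 10, n = 8, seed = 1) {
  set.seed(seed)
  a <- sample(1:20, d, replace = TRUE)
  c_i <- sample(1:30, n)
  m <- outer(a, c_i)
  dimnames(m) <- list(paste0("t", seq_len(d)), paste0("s", seq_len(n)))
  m
}

# Small random integer count matrix with no constant taxa.
random_counts <- function(d = 6, n = 10, seed = 42, lambda = 8) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(d * n, lambda), d, n,
                dimnames = list(paste0("t", seq_len(d)), paste0("s", seq_len(n))))
    if (!any(apply(m, 1, function(x) max(x) == min(x)))) return(m)
  }
}

fit_quietly <- function(...) suppressWarnings(fit_reference_model(...))
rsim_quietly <- function(...) suppressWarnings(rsim_normalize(...))
filter_quietly <- function(...) suppressMessages(filter_taxa(...))
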