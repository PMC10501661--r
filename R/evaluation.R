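# Samples-by-taxa log-transformed view of a rsim_norm (or plain matrix).
# The pseudo-count is added on the values' own scale; the default of 1 is
# near-linear on proportion-like normalized values, so distances stay driven
# by the (composition-unbiased) abundant taxa rather than by depth-linked
# zero patterns, while raw counts are still strongly compressed.  A tiny
# pseudo-count (e.g. half the minimum non-zero value) makes log distances
# measure sequencing depth instead of composition; see the methods vignette.
log_view <- function(nm, log_transform = TRUE, pseudo = 1) {
  values <- if (inherits(nm, "rsim_norm")) nm$values else nm
  if (log_transform) {
    stopifnot(pseudo > 0)
    values <- log(values + pseudo)
  }
  t(values)
}

#' Empirical misclassification rate of an estimated reference set
#'
#' Fraction of the estimated reference set that is truly differentially
#' abundant: |J0-hat intersect J1| / |J0-hat|.
#'
#' @param fit A `rsim_fit` object, or a character vector of reference taxon ids.
#' @param truth A simulation `truth` list (see [simulate_counts()]).
#' @return A scalar in \[0, 1\].
#' @export
misclassification_rate <- function(fit, truth) {
  ref <- if (inherits(fit, "rsim_fit")) fit$reference_set else fit
  if (!length(ref)) stop("empty reference set", call. = FALSE)
  length(intersect(ref, truth$da_taxa)) / length(ref)
}

# Welch two-sample t-test, implemented directly so degenerate (zero-variance)
# taxa get the conventional statistic instead of an error.
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  diff <- mean(x) - mean(y)
  if (se2 == 0) {
    if (diff == 0) return(c(statistic = 0, p_value = 1))
    return(c(statistic = sign(diff) * Inf, p_value = 0))
  }
  tstat <- diff / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  c(statistic = tstat, p_value = 2 * stats::pt(-abs(tstat), df))
}

pearson_test <- function(x, y) {
  if (stats::sd(x) == 0) return(c(statistic = 0, p_value = 1))
  ct <- stats::cor.test(x, y)
  c(statistic = unname(ct$estimate), p_value = ct$p.value)
}

#' Per-taxon differential abundance tests
#'
#' Welch two-sample t-tests (binary covariate) or Pearson correlation tests
#' (continuous covariate), taxon by taxon, on log-transformed normalized
#' values by default.  Rejections at the raw p-value threshold `alpha` are the
#' primary output; Benjamini-Hochberg-adjusted rejections are reported as a
#' secondary column.
#'
#' @param nm A `rsim_norm` object (or plain taxa-by-samples matrix).
#' @param covariate A data frame with columns `sample` and either `group`
#'   (binary, for `t_test`) or `latent` (continuous, for `pearson`); or a
#'   plain vector aligned to the samples.
#' @param test `"t_test"` or `"pearson"`.
#' @param alpha Raw rejection threshold.
#' @param log_transform Test on `log(value + pseudo)`? Default `TRUE`.
#' @param pseudo Pseudo-count added before the log, on the values' own scale.
#'   Default 1 (near-linear for proportion-like normalized values).
#' @return A tibble: `taxon`, `statistic`, `p_value`, `rejected`, `p_bh`,
#'   `rejected_bh`.
#' @export
per_taxon_tests <- function(nm, covariate, test = c("t_test", "pearson"),
                            alpha = 0.05, log_transform = TRUE, pseudo = 1) {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1)
  y <- log_view(nm, log_transform, pseudo)
  v <- extract_covariate(covariate, rownames(y),
                         if (test == "t_test") "group" else "latent")
  if (test == "t_test") {
    lev <- unique(v)
    if (length(lev) != 2) stop("t_test needs a binary covariate", call. = FALSE)
    if (min(table(v)) < 2) stop("each group needs at least 2 samples", call. = FALSE)
    res <- apply(y, 2L, function(col) welch_t(col[v == lev[1]], col[v == lev[2]]))
  } else {
    if (!is.numeric(v) || length(unique(v)) < 3) {
      stop("pearson needs a continuous covariate", call. = FALSE)
    }
    res <- apply(y, 2L, function(col) pearson_test(col, v))
  }
  p <- res["p_value", ]
  tibble::tibble(
    taxon = colnames(y),
    statistic = unname(res["statistic", ]),
    p_value = unname(p),
    rejected = unname(p <= alpha),
    p_bh = unname(stats::p.adjust(p, "BH")),
    rejected_bh = unname(stats::p.adjust(p, "BH") <= alpha)
  )
}

# Pull an aligned covariate vector out of a data frame or plain vector.
extract_covariate <- function(covariate, sample_ids, column) {
  if (is.data.frame(covariate)) {
    if (!"sample" %in% names(covariate)) {
      stop("covariate table needs a 'sample' column", call. = FALSE)
    }
    if (!column %in% names(covariate)) {
      stop("covariate table needs a '", column, "' column", call. = FALSE)
    }
    idx <- match(sample_ids, covariate$sample)
    if (anyNA(idx)) stop("covariate table does not cover all samples", call. = FALSE)
    covariate[[column]][idx]
  } else {
    if (length(covariate) != length(sample_ids)) {
      stop("covariate length does not match sample count", call. = FALSE)
    }
    covariate
  }
}

#' Realized false-discovery proportion and sensitivity
#'
#' @param rejections Character vector of rejected taxon ids.
#' @param truth A simulation `truth` list.
#' @return A tibble with `fdp` (= |rejections in J0| / max(|rejections|, 1))
#'   and `sensitivity` (= |rejections in J1| / |J1|; `NA` when no taxa are
#'   differentially abundant).
#' @export
fdp_and_sensitivity <- function(rejections, truth) {
  fdp <- length(intersect(rejections, truth$nonda_taxa)) /
    max(length(rejections), 1)
  sens <- if (length(truth$da_taxa)) {
    length(intersect(rejections, truth$da_taxa)) / length(truth$da_taxa)
  } else NA_real_
  tibble::tibble(fdp = fdp, sensitivity = sens,
                 n_rejections = length(rejections))
}

# Pseudo-F for a two-or-more-group partition from a squared distance matrix.
pseudo_f_stat <- function(d2, labels) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  g <- length(unique(labels))
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

#' PERMANOVA on log-Euclidean distances
#'
#' Permutational multivariate analysis of variance with the pseudo-F statistic
#' computed directly from the distance matrix (Euclidean distance on
#' log-transformed normalized values).  The p-value is
#' (1 + number of permuted F >= observed F) / (1 + permutations); when the
#' number of distinct group assignments is at most `n_permutations` the
#' assignments are enumerated exhaustively and the p-value is the exact
#' fraction of assignments with F >= observed.
#'
#' @param nm A `rsim_norm` object or plain taxa-by-samples matrix.
#' @param covariate Binary group labels (data frame with `sample` + `group`,
#'   or plain vector); each group needs >= 2 samples.
#' @param n_permutations Number of label permutations (default 999).
#' @param log_transform,pseudo As in [per_taxon_tests()].
#' @param seed Integer seed for the permutation stream.
#' @return A one-row tibble: `pseudo_f`, `p_value`, `n_permutations`, `exact`.
#' @export
permanova <- function(nm, covariate, n_permutations = 999,
                      log_transform = TRUE, pseudo = 1, seed = 0) {
  stopifnot(n_permutations >= 1)
  y <- log_view(nm, log_transform, pseudo)
  labels <- extract_covariate(covariate, rownames(y), "group")
  lev <- unique(labels)
  if (length(lev) != 2) stop("need exactly two groups", call. = FALSE)
  if (min(table(labels)) < 2) stop("each group needs at least 2 samples",
                                   call. = FALSE)
  d2 <- as.matrix(stats::dist(y))^2
  f_obs <- pseudo_f_stat(d2, labels)
  n <- length(labels)
  n1 <- sum(labels == lev[1])
  n_assign <- choose(n, n1)
  if (n_assign <= n_permutations) {
    combos <- utils::combn(n, n1)
    f_all <- apply(combos, 2L, function(idx) {
      lab <- rep(lev[2], n)
      lab[idx] <- lev[1]
      pseudo_f_stat(d2, lab)
    })
    p <- mean(f_all >= f_obs - 1e-12)
    exact <- TRUE
    n_used <- n_assign
  } else {
    f_perm <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        pseudo_f_stat(d2, sample(labels))
      }, numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    exact <- FALSE
    n_used <- n_permutations
  }
  tibble::tibble(pseudo_f = f_obs, p_value = p,
                 n_permutations = n_used, exact = exact)
}

#' Principal-coordinates analysis (classical scaling)
#'
#' Classical multidimensional scaling of Euclidean distances on
#' log-transformed normalized values: Gower-centred squared distances are
#' eigendecomposed and coordinates are eigenvectors scaled by root
#' eigenvalues.  Axes with non-positive eigenvalues are dropped (and the
#' negative eigenvalues reported).
#'
#' @param nm A `rsim_norm` object or plain taxa-by-samples matrix.
#' @param k Number of coordinate axes (k <= n - 1).
#' @param log_transform,pseudo As in [per_taxon_tests()].
#' @return A list with `coordinates` (tibble: `sample`, `axis_1`, ...) and
#'   `eigenvalues` (all n of them, sorted decreasing).
#' @export
pcoa_coordinates <- function(nm, k = 2, log_transform = TRUE, pseudo = 1) {
  y <- log_view(nm, log_transform, pseudo)
  n <- nrow(y)
  if (k > n - 1) stop("k must be at most n - 1", call. = FALSE)
  d2 <- as.matrix(stats::dist(y))^2
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% d2 %*% j
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  scale <- max(abs(eig$values), .Machine$double.eps)
  keep <- which(eig$values[seq_len(k)] > 1e-10 * scale)
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), nrow = length(keep))
  colnames(coords) <- if (length(keep)) paste0("axis_", seq_along(keep))
                      else character(0)
  tab <- tibble::as_tibble(coords)
  list(coordinates = dplyr::bind_cols(tibble::tibble(sample = rownames(y)), tab),
       eigenvalues = eig$values)
}
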