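#' Empirical cumulative distribution function
#'
#' Thin wrapper over [stats::ecdf()] with an explicit empty-input error; the
#' returned function satisfies F(t) = (number of values <= t) / length(values).
#'
#' @param values Non-empty numeric vector.
#' @return A right-continuous step function of class `ecdf`.
#' @export
empirical_cdf <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input", call. = FALSE)
  stats::ecdf(values)
}

# Pooled null medians from repeated taxon subsampling of the candidate set.
resample_null_medians <- function(counts, m_values, gamma, n_resamples,
                                  subsample_fraction, seed) {
  cand <- which(m_values > gamma)
  if (length(cand) < 10) {
    stop("only ", length(cand), " taxa have M > gamma = ", gamma,
         "; lower gamma or inspect the data", call. = FALSE)
  }
  size <- ceiling(subsample_fraction * length(cand))
  if (size < 5) stop("subsample size below 5; raise subsample_fraction", call. = FALSE)
  withr::with_seed(seed, {
    unlist(lapply(seq_len(n_resamples), function(b) {
      idx <- sample(cand, size)
      sub <- counts[idx, , drop = FALSE]
      r <- stats::cor(t(sub), method = "spearman")
      apply(r, 1L, stats::median)
    }), use.names = FALSE)
  })
}

#' Estimate the null distribution of the rank-similarity statistic
#'
#' Resamples taxa (without replacement) from the candidate set
#' J~0 = \{j : M_j > gamma\} -- taxa that are non-differentially abundant with
#' high probability -- recomputes the per-taxon median pairwise Spearman
#' statistic inside each subsampled count sub-matrix, and pools all resampled
#' medians into one empirical CDF, the estimate of F0 (the distribution of M_j
#' for a non-differentially-abundant taxon).
#'
#' @param counts Taxa-by-samples count matrix.
#' @param stats A tibble from [median_rank_statistics()] aligned to `counts`.
#' @param gamma Candidate-set threshold in (0, 1); default 0.8.
#' @param n_resamples Number of subsamples B.
#' @param subsample_fraction Fraction of the candidate set drawn each time.
#' @param seed Integer seed; fixes the resampling stream.
#' @return An `ecdf` function with the pooled medians in attribute `"medians"`.
#' @export
estimate_f0 <- function(counts, stats, gamma = 0.8, n_resamples = 100,
                        subsample_fraction = 0.5, seed = 0) {
  validate_counts(counts)
  stopifnot(identical(stats$taxon, rownames(counts)))
  meds <- resample_null_medians(counts, stats$m, gamma, n_resamples,
                                subsample_fraction, seed)
  out <- empirical_cdf(meds)
  attr(out, "medians") <- meds
  out
}

#' Estimate the non-differentially-abundant proportion pi0
#'
#' Uses the tail identity 1 - F(t) ~= pi0 (1 - F0(t)) for t above `gamma`:
#' pi0 is the least-squares fit of a_j = 1 - F(M_j) on b_j = 1 - F0(M_j) over
#' candidate taxa, solved in closed form as sum(a b) / sum(b^2) and clipped to
#' \[1e-6, 1\].
#'
#' @param stats Tibble with per-taxon `m` values.
#' @param f_hat,f0_hat CDF functions for all statistics and for the null.
#' @param gamma Candidate-set threshold.
#' @return Scalar pi0 estimate in (0, 1\].
#' @export
estimate_pi0 <- function(stats, f_hat, f0_hat, gamma = 0.8) {
  m <- stats$m[stats$m > gamma]
  if (!length(m)) stop("no taxa with M > gamma", call. = FALSE)
  a <- 1 - f_hat(m)
  b <- 1 - f0_hat(m)
  if (sum(b^2) == 0) {
    warning("all null mass at the right edge; returning pi0 = 1")
    return(1)
  }
  min(max(sum(a * b) / sum(b^2), 1e-6), 1)
}

#' Choose the misclassification-controlled threshold
#'
#' Scans the estimated misclassification rate
#' e(T) = 1 - pi0 (1 - F0(T)) / (1 - F(T)), clamped to \[0, 1\], over the grid
#' of sorted unique statistic values shifted down by 1e-12 (so the strict rule
#' M_j > T keeps each grid point's own taxa), and returns the smallest grid
#' value with e(T) <= eta.  The scan stops once 1 - F(T) reaches 0.
#'
#' @param stats Tibble with per-taxon `m` values.
#' @param f_hat,f0_hat CDF functions.
#' @param pi0_hat Estimated non-differential proportion.
#' @param eta Target misclassification rate in (0, 1).
#' @return The threshold T-hat (a scalar).
#' @export
choose_threshold <- function(stats, f_hat, f0_hat, pi0_hat, eta) {
  stopifnot(eta > 0, eta < 1)
  grid <- sort(unique(stats$m)) - 1e-12
  for (t in grid) {
    surv <- 1 - f_hat(t)
    if (surv <= 0) break
    e <- 1 - pi0_hat * (1 - f0_hat(t)) / surv
    e <- min(max(e, 0), 1)
    if (e <= eta) return(t)
  }
  stop("misclassification target unattainable; raise eta or gamma", call. = FALSE)
}

#' Fit the rank-similarity reference model
#'
#' Full reference-set selection: per-taxon median pairwise Spearman statistics,
#' empirical CDF of all statistics, a resampled null CDF from the candidate set
#' \{M_j > gamma\}, a closed-form pi0 estimate, and the smallest threshold
#' T-hat whose estimated misclassification rate is at most `eta`.  The
#' reference set is \{j : M_j > T-hat\}.
#'
#' Guidance: smaller `eta` (e.g. 0.01) for bias-sensitive downstream work such
#' as differential abundance analysis; larger `eta` for low-variance size
#' factors in ordination.  `gamma = 0.8` works well at ASV/OTU resolution.
#'
#' @param counts Taxa-by-samples count matrix; constant taxa must be removed
#'   first (see [filter_taxa()]).
#' @param eta Target misclassification rate (default 0.05).
#' @param gamma Candidate-set threshold (default 0.8).
#' @param n_resamples,subsample_fraction Null-resampling controls.
#' @param seed Integer seed; the fit is fully reproducible given it.
#' @return An object of class `rsim_fit`: per-taxon statistics, both CDFs, the
#'   pooled null medians, `pi0_hat`, `t_hat`, the candidate and reference sets,
#'   and all tuning parameters.
#' @export
fit_reference_model <- function(counts, eta = 0.05, gamma = 0.8,
                                n_resamples = 100, subsample_fraction = 0.5,
                                seed = 0) {
  validate_counts(counts)
  stopifnot(eta > 0, eta < 1, gamma > 0, gamma < 1,
            n_resamples >= 1, subsample_fraction > 0, subsample_fraction <= 1)
  if (ncol(counts) < 10) {
    warning("fewer than 10 samples; rank-similarity statistics will be noisy")
  }
  stats <- median_rank_statistics(counts)
  f_hat <- empirical_cdf(stats$m)
  null_medians <- resample_null_medians(counts, stats$m, gamma, n_resamples,
                                        subsample_fraction, seed)
  f0_hat <- empirical_cdf(null_medians)
  pi0_hat <- estimate_pi0(stats, f_hat, f0_hat, gamma)
  if (pi0_hat <= 0.5) {
    warning("estimated non-differential proportion pi0 <= 0.5; the model is ",
            "only identifiable when more than half the taxa are non-differential")
  }
  t_hat <- choose_threshold(stats, f_hat, f0_hat, pi0_hat, eta)
  reference_set <- stats$taxon[stats$m > t_hat]
  if (!length(reference_set)) stop("empty reference set", call. = FALSE)
  structure(
    list(
      stats = stats,
      f_hat = f_hat,
      f0_hat = f0_hat,
      null_medians = null_medians,
      pi0_hat = pi0_hat,
      t_hat = t_hat,
      candidate_set = stats$taxon[stats$m > gamma],
      reference_set = reference_set,
      eta = eta, gamma = gamma,
      n_resamples = n_resamples, subsample_fraction = subsample_fraction,
      seed = seed
    ),
    class = "rsim_fit"
  )
}

#' @export
print.rsim_fit <- function(x, ...) {
  cat("Rank-similarity reference model\n")
  cat(sprintf("  taxa: %d   reference set: %d   candidate set: %d\n",
              nrow(x$stats), length(x$reference_set), length(x$candidate_set)))
  cat(sprintf("  pi0_hat = %.3f   T_hat = %.4f   (eta = %g, gamma = %g)\n",
              x$pi0_hat, x$t_hat, x$eta, x$gamma))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-taxon view of a fitted reference model
#'
#' @param x A `rsim_fit` object.
#' @param ... Unused.
#' @return A tibble with `taxon`, `m`, `in_candidate`, `in_reference`.
#' @exportS3Method generics::tidy
tidy.rsim_fit <- function(x, ...) {
  dplyr::mutate(x$stats,
                in_candidate = .data$taxon %in% x$candidate_set,
                in_reference = .data$taxon %in% x$reference_set)
}

#' One-row summary of a fitted reference model
#'
#' @param x A `rsim_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.rsim_fit <- function(x, ...) {
  tibble::tibble(
    n_taxa = nrow(x$stats),
    n_reference = length(x$reference_set),
    n_candidate = length(x$candidate_set),
    pi0_hat = x$pi0_hat,
    t_hat = x$t_hat,
    eta = x$eta,
    gamma = x$gamma,
    n_resamples = x$n_resamples,
    subsample_fraction = x$subsample_fraction,
    seed = x$seed
  )
}

#' Serialize a fitted reference model to JSON
#'
#' Stores the tuning parameters, pi0/threshold estimates, the reference-set
#' ids and the pooled null medians, so the null CDF is reconstructable.
#'
#' @param fit A `rsim_fit` object.
#' @param path Output path.
#' @export
write_reference_model <- function(fit, path) {
  stopifnot(inherits(fit, "rsim_fit"))
  jsonlite::write_json(
    list(
      eta = fit$eta, gamma = fit$gamma, pi0_hat = fit$pi0_hat, t_hat = fit$t_hat,
      n_resamples = fit$n_resamples, subsample_fraction = fit$subsample_fraction,
      seed = fit$seed,
      reference_set = fit$reference_set,
      m = stats::setNames(as.list(fit$stats$m), fit$stats$taxon),
      null_medians = fit$null_medians
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
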