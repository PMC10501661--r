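# Internal constructor for normalization results.
new_rsim_norm <- function(values, reference_set, size_factors, method) {
  structure(
    list(values = values,
         reference_set = reference_set,
         size_factors = size_factors,
         method = method),
    class = "rsim_norm"
  )
}

#' @export
print.rsim_norm <- function(x, ...) {
  cat(sprintf("Normalized count matrix (%s): %d taxa x %d samples\n",
              x$method, nrow(x$values), ncol(x$values)))
  if (length(x$reference_set)) {
    cat(sprintf("  reference set: %d taxa\n", length(x$reference_set)))
  }
  invisible(x)
}

#' Per-sample view of a normalization result
#'
#' @param x A `rsim_norm` object.
#' @param ... Unused.
#' @return A tibble with `sample`, `size_factor`, `depth`.
#' @exportS3Method generics::tidy
tidy.rsim_norm <- function(x, ...) {
  tibble::tibble(sample = colnames(x$values),
                 size_factor = unname(x$size_factors),
                 depth = unname(colSums(x$values)))
}

# Size factors are defined up to a common constant; the canonical
# representative has geometric mean 1.
gm_scale <- function(x) x / exp(mean(log(x)))

#' Reference-based normalization
#'
#' Divides every count by the sample's summed count over the reference set, so
#' the rescaled total of the reference taxa is exactly 1 in every sample --
#' the scaling used with spike-in bacteria, with the estimated
#' non-differentially-abundant taxa standing in for the spike-ins.  The raw
#' reference-set sums, rescaled to geometric mean 1, are the size factors.
#'
#' @param counts Taxa-by-samples count matrix.
#' @param reference_set Non-empty character vector of taxon ids in `counts`.
#' @return A `rsim_norm` object.
#' @export
reference_normalize <- function(counts, reference_set) {
  validate_counts(counts)
  if (!length(reference_set)) stop("reference set is empty", call. = FALSE)
  missing <- setdiff(reference_set, rownames(counts))
  if (length(missing)) {
    stop("reference taxa absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ref_sum <- colSums(counts[reference_set, , drop = FALSE])
  zero <- ref_sum <= 0
  if (any(zero)) {
    stop("zero reference-set total in sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  values <- sweep(counts, 2L, ref_sum, "/")
  new_rsim_norm(values, reference_set, gm_scale(ref_sum), method = "reference")
}

#' Rank-similarity reference normalization (end to end)
#'
#' Fits the reference model with [fit_reference_model()] and applies
#' [reference_normalize()] with the estimated reference set.
#'
#' @inheritParams fit_reference_model
#' @return A list with elements `normalized` (`rsim_norm`, method `"rsim"`)
#'   and `fit` (`rsim_fit`).
#' @export
rsim_normalize <- function(counts, eta = 0.05, gamma = 0.8, n_resamples = 100,
                           subsample_fraction = 0.5, seed = 0) {
  fit <- fit_reference_model(counts, eta = eta, gamma = gamma,
                             n_resamples = n_resamples,
                             subsample_fraction = subsample_fraction,
                             seed = seed)
  nm <- reference_normalize(counts, fit$reference_set)
  nm$method <- "rsim"
  list(normalized = nm, fit = fit)
}

#' Baseline scaling normalizers
#'
#' Self-contained comparator implementations of the standard size-factor
#' estimators, from their published definitions (not bit-compatible with the
#' edgeR/DESeq2 implementations):
#' \describe{
#'   \item{tss}{total-sum scaling; factor = column sum.}
#'   \item{uq}{75th percentile of each sample's non-zero counts.}
#'   \item{med}{median-of-ratios over taxa non-zero in every sample, against
#'     per-taxon geometric means.}
#'   \item{tmm}{trimmed (30\% M, 5\% A) weighted mean of log-ratios against the
#'     sample whose depth is closest to the median depth; factor = depth times
#'     2^TMM.}
#'   \item{gmpr}{geometric mean over other samples of the median count ratio of
#'     taxa non-zero in both samples.}
#'   \item{rarefaction}{subsamples each sample without replacement to `depth`;
#'     size factors are all 1.}
#' }
#'
#' @param counts Taxa-by-samples count matrix.
#' @param method One of `"tss"`, `"uq"`, `"med"`, `"tmm"`, `"gmpr"`,
#'   `"rarefaction"`.
#' @param depth Target depth for rarefaction (required; must not exceed the
#'   smallest sample depth).
#' @param seed Seed for rarefaction subsampling.
#' @return A `rsim_norm` object (empty reference set).
#' @export
baseline_normalize <- function(counts,
                               method = c("tss", "uq", "med", "tmm", "gmpr",
                                          "rarefaction"),
                               depth = NULL, seed = 0) {
  validate_counts(counts)
  method <- match.arg(method)
  if (method == "rarefaction") {
    if (is.null(depth)) stop("rarefaction requires a target depth", call. = FALSE)
    values <- rarefy_counts(counts, depth, seed)
    return(new_rsim_norm(values, character(0),
                         stats::setNames(rep(1, ncol(counts)), colnames(counts)),
                         method))
  }
  raw <- switch(method,
    tss = colSums(counts),
    uq = size_factors_uq(counts),
    med = size_factors_med(counts),
    tmm = size_factors_tmm(counts),
    gmpr = size_factors_gmpr(counts)
  )
  if (any(!is.finite(raw)) || any(raw <= 0)) {
    stop("non-positive or undefined size factor under method '", method, "'",
         call. = FALSE)
  }
  sf <- gm_scale(raw)
  new_rsim_norm(sweep(counts, 2L, sf, "/"), character(0),
                stats::setNames(sf, colnames(counts)), method)
}

size_factors_uq <- function(counts) {
  apply(counts, 2L, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) stop("sample with no non-zero counts", call. = FALSE)
    stats::quantile(nz, 0.75, names = FALSE)
  })
}

size_factors_med <- function(counts) {
  shared <- rowSums(counts > 0) == ncol(counts)
  if (!any(shared)) {
    stop("median-of-ratios: no taxa non-zero in all samples", call. = FALSE)
  }
  sub <- counts[shared, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub, 2L, function(x) stats::median(x / geo))
}

size_factors_gmpr <- function(counts) {
  n <- ncol(counts)
  ratios <- matrix(NA_real_, n, n)
  # the self-ratio (= 1) is included: with it the estimator is exactly
  # scale-equivariant (doubling one sample doubles only its factor)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      both <- counts[, i] > 0 & counts[, k] > 0
      if (any(both)) {
        ratios[i, k] <- stats::median(counts[both, i] / counts[both, k])
      }
    }
  }
  vapply(seq_len(n), function(i) {
    if (all(is.na(ratios[i, -i]))) {
      stop("GMPR: sample '", colnames(counts)[i],
           "' shares no non-zero taxa with any other sample", call. = FALSE)
    }
    r <- ratios[i, !is.na(ratios[i, ])]
    exp(mean(log(r)))
  }, numeric(1))
}

# Comparator-grade TMM: double-trimmed, precision-weighted mean of per-taxon
# log2 ratios against a reference sample (depth closest to the median depth).
size_factors_tmm <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  depths <- colSums(counts)
  ref <- which.min(abs(depths - stats::median(depths)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    if (i == ref) return(1)
    ok <- counts[, i] > 0 & counts[, ref] > 0
    if (!any(ok)) stop("TMM: no shared non-zero taxa with reference sample",
                       call. = FALSE)
    p_i <- counts[ok, i] / depths[i]
    p_r <- counts[ok, ref] / depths[ref]
    m <- log2(p_i / p_r)
    a <- 0.5 * log2(p_i * p_r)
    w <- 1 / ((depths[i] - counts[ok, i]) / (depths[i] * counts[ok, i]) +
              (depths[ref] - counts[ok, ref]) / (depths[ref] * counts[ok, ref]))
    keep <- m >= stats::quantile(m, trim_m) & m <= stats::quantile(m, 1 - trim_m) &
            a >= stats::quantile(a, trim_a) & a <= stats::quantile(a, 1 - trim_a)
    if (!any(keep)) keep <- rep(TRUE, length(m))
    2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  }, numeric(1))
  depths * f
}

# Multivariate-hypergeometric subsampling of one sample's reads.
rarefy_one <- function(x, depth) {
  if (sum(x) == depth) return(x)
  reads <- rep.int(seq_along(x), x)
  tabulate(sample(reads, depth), nbins = length(x))
}

#' Rarefy a count matrix to a common depth
#'
#' Subsamples each sample's reads without replacement to `depth`.
#'
#' @param counts Taxa-by-samples count matrix.
#' @param depth Target depth; must not exceed any sample's depth.
#' @param seed Integer seed.
#' @return A count matrix with all column sums equal to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = 0) {
  validate_counts(counts)
  depths <- colSums(counts)
  if (any(depth > depths)) {
    stop("rarefaction depth ", depth, " exceeds depth of sample(s): ",
         paste(colnames(counts)[depth > depths], collapse = ", "), call. = FALSE)
  }
  withr::with_seed(seed, {
    out <- apply(counts, 2L, rarefy_one, depth = depth)
  })
  dimnames(out) <- dimnames(counts)
  out
}

#' Compare estimated size factors with planted sampling fractions
#'
#' Rescales the estimates so their arithmetic mean matches the mean of the
#' truth, then reports per-sample signed relative errors, the overall
#' root-mean-square relative error, and (with group labels) group-wise mean
#' bias.
#'
#' @param estimates Positive numeric vector of estimated size factors.
#' @param truth Positive numeric vector of true sampling fractions, same length.
#' @param groups Optional per-sample group labels.
#' @return A list with `per_sample` (tibble: `sample`, `estimate`, `truth`,
#'   `rel_error`, `group`), `rmse`, and `group_bias` (tibble or `NULL`).
#' @export
compare_size_factors <- function(estimates, truth, groups = NULL) {
  if (length(estimates) != length(truth)) stop("length mismatch", call. = FALSE)
  stopifnot(all(truth > 0), all(estimates > 0))
  est <- estimates * mean(truth) / mean(estimates)
  rel <- (est - truth) / truth
  per_sample <- tibble::tibble(
    sample = if (is.null(names(estimates))) as.character(seq_along(est))
             else names(estimates),
    estimate = unname(est),
    truth = unname(truth),
    rel_error = unname(rel),
    group = if (is.null(groups)) NA_character_ else as.character(groups)
  )
  group_bias <- NULL
  if (!is.null(groups)) {
    group_bias <- dplyr::summarise(dplyr::group_by(per_sample, .data$group),
                                   mean_bias = mean(.data$rel_error),
                                   .groups = "drop")
  }
  list(per_sample = per_sample,
       rmse = sqrt(mean(rel^2)),
       group_bias = group_bias)
}
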