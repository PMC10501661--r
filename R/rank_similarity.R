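#' Spearman rank correlation of two count vectors
#'
#' Pearson correlation of mid-ranks (ties receive the average of the ranks they
#' span).  This is the similarity used throughout the reference-selection step:
#' counts of two non-differentially-abundant taxa are both monotone in the
#' per-sample sampling fraction, so their rank correlation is close to 1, and
#' zeros need no special treatment because tied zeros receive identical
#' mid-ranks in both vectors.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return A scalar in \[-1, 1\].
#' @export
taxon_spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (max(x) == min(x) || max(y) == min(y)) {
    stop("Spearman correlation undefined for a constant vector; see filter_taxa()",
         call. = FALSE)
  }
  stats::cor(rank(x), rank(y))
}

#' Median pairwise rank-similarity statistic per taxon
#'
#' For each taxon j, computes M_j = median over all taxa j' (self included, so
#' r_jj = 1 enters the median) of the Spearman correlation between the two
#' taxa's count vectors across samples.  Non-differentially-abundant taxa track
#' the sampling fraction and hence each other, pushing M_j towards 1;
#' differentially abundant taxa decorrelate from the (assumed) majority and
#' score lower.  Cost is O(d^2 n) via rank transform plus a d x d correlation.
#'
#' @param counts Taxa-by-samples count matrix with >= 3 samples and >= 3
#'   non-constant taxa (run [filter_taxa()] first).
#' @return A tibble with columns `taxon` and `m`.
#' @export
median_rank_statistics <- function(counts) {
  validate_counts(counts)
  if (nrow(counts) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (ncol(counts) < 3) stop("need at least 3 samples", call. = FALSE)
  constant <- apply(counts, 1L, function(x) max(x) == min(x))
  if (any(constant)) {
    stop("constant taxa present (", paste(utils::head(rownames(counts)[constant], 5),
                                          collapse = ", "),
         "); remove them with filter_taxa()", call. = FALSE)
  }
  r <- stats::cor(t(counts), method = "spearman")
  tibble::tibble(taxon = rownames(counts),
                 m = unname(apply(r, 1L, stats::median)))
}
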