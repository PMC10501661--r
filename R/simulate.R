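#' Simulation configuration
#'
#' Describes one synthetic microbiome experiment under the multinomial count
#' model: shared baseline absolute abundances A_j drawn log-normally, a
#' minority of differentially abundant (DA) taxa whose abundance is multiplied
#' by `signal^x_i` for a per-sample latent variable x_i, per-sample depths
#' drawn log-uniformly, and counts drawn multinomially with those depths from
#' the per-sample composition.  The planted sampling fraction is
#' c_i = depth_i / sum_j A_ij.
#'
#' Defaults (d = 200, n = 100, 10\% DA taxa, strong signal, depths on
#' \[2e3, 5e4\], log-normal sdlog 2) give realistically sparse tables.
#' Presets: weak / moderate / strong = fold change 1.5 / 2.5 / 4.
#'
#' @param d,n Numbers of taxa and samples.
#' @param prop_da Fraction of DA taxa; must be below 0.5 (identifiability
#'   requires more than half the taxa non-differential).
#' @param da_selection `"random"` or `"top_abundant"`.
#' @param latent `"binary"` (x in \{0, 1\} by group), `"continuous"`
#'   (x ~ Uniform(0, 1)) or `"none"`.
#' @param signal Fold change (>= 1) applied to DA taxa as `signal^x`; or give
#'   `preset`.
#' @param preset Optional `"weak"`, `"moderate"`, `"strong"`; overrides
#'   `signal`.
#' @param group_balance Fraction of samples in group 1 (x = 1) for binary
#'   latent structure.
#' @param depth_range Depths are drawn log-uniformly on this range.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the shared
#'   baseline abundances; `baseline_sdlog` tunes sparsity.
#' @param rarefy_group1 Optional: rarefy group-1 samples after counting.  A
#'   value in (0, 1) is a fraction of each sample's own depth; an integer >= 1
#'   is an absolute target depth.
#' @param seed Integer seed driving all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(d = 200, n = 100, prop_da = 0.1,
                       da_selection = c("random", "top_abundant"),
                       latent = c("binary", "continuous", "none"),
                       signal = 4, preset = NULL, group_balance = 0.5,
                       depth_range = c(2e3, 5e4),
                       baseline_meanlog = 0, baseline_sdlog = 2,
                       rarefy_group1 = NULL, seed = 0) {
  da_selection <- match.arg(da_selection)
  latent <- match.arg(latent)
  if (!is.null(preset)) {
    signal <- switch(match.arg(preset, c("weak", "moderate", "strong")),
                     weak = 1.5, moderate = 2.5, strong = 4)
  }
  stopifnot(d >= 3, n >= 3, prop_da >= 0, prop_da < 0.5, signal >= 1,
            group_balance > 0, group_balance < 1,
            length(depth_range) == 2, all(depth_range > 0),
            depth_range[1] <= depth_range[2], baseline_sdlog > 0)
  if (!is.null(rarefy_group1)) stopifnot(rarefy_group1 > 0)
  structure(
    list(d = d, n = n, prop_da = prop_da, da_selection = da_selection,
         latent = latent, signal = signal, group_balance = group_balance,
         depth_range = depth_range, baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog, rarefy_group1 = rarefy_group1,
         seed = seed),
    class = "sim_config"
  )
}

rarefy_target <- function(depth, spec) {
  if (spec < 1) ceiling(spec * depth) else as.integer(spec)
}

#' Generate a synthetic count matrix with planted truth
#'
#' Draws shared baseline abundances, plants DA taxa, draws depths, and samples
#' counts multinomially per sample.  If `rarefy_group1` is set in the
#' configuration, group-1 samples are additionally subsampled without
#' replacement (a pure technical depth shift).
#'
#' @param config A [sim_config()] object.
#' @return A list with `counts` (taxa-by-samples matrix), `covariates`
#'   (tibble: `sample`, `latent`, `group`), and `truth` (list: `abundances`,
#'   `sampling_fractions`, `da_taxa`, `nonda_taxa`, `latent_values`,
#'   `group_labels`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    d <- config$d; n <- config$n
    taxa <- sprintf("taxon_%03d", seq_len(d))
    samples <- sprintf("sample_%03d", seq_len(n))

    a0 <- stats::rlnorm(d, config$baseline_meanlog, config$baseline_sdlog)
    n_da <- round(config$prop_da * d)
    da_idx <- if (n_da == 0) integer(0)
              else if (config$da_selection == "random") sample.int(d, n_da)
              else order(a0, decreasing = TRUE)[seq_len(n_da)]

    x <- switch(config$latent,
      binary = {
        n1 <- round(config$group_balance * n)
        g1 <- sample.int(n, n1)
        as.numeric(seq_len(n) %in% g1)
      },
      continuous = stats::runif(n),
      none = rep(0, n)
    )
    group <- if (config$latent == "continuous") rep(1L, n) else 2L - (x > 0)

    abundances <- matrix(a0, nrow = d, ncol = n,
                         dimnames = list(taxa, samples))
    if (length(da_idx)) {
      abundances[da_idx, ] <- abundances[da_idx, ] *
        rep(config$signal^x, each = length(da_idx))
    }

    depths <- round(exp(stats::runif(n, log(config$depth_range[1]),
                                     log(config$depth_range[2]))))
    counts <- vapply(seq_len(n), function(i) {
      as.numeric(stats::rmultinom(1, depths[i], abundances[, i]))
    }, numeric(d))
    dimnames(counts) <- list(taxa, samples)

    if (!is.null(config$rarefy_group1)) {
      for (i in which(group == 1L)) {
        target <- rarefy_target(depths[i], config$rarefy_group1)
        if (target > depths[i]) {
          stop("rarefaction depth ", target, " exceeds depth of sample ",
               samples[i], call. = FALSE)
        }
        counts[, i] <- rarefy_one(counts[, i], target)
      }
    }

    truth <- list(
      abundances = abundances,
      sampling_fractions = stats::setNames(colSums(counts) / colSums(abundances),
                                           samples),
      da_taxa = taxa[sort(da_idx)],
      nonda_taxa = if (length(da_idx)) taxa[-sort(da_idx)] else taxa,
      latent_values = stats::setNames(x, samples),
      group_labels = stats::setNames(group, samples)
    )
    list(counts = counts,
         covariates = tibble::tibble(sample = samples, latent = x,
                                     group = group),
         truth = truth)
  })
}

#' Null two-group design with a rarefied group
#'
#' The global-null scenario: no taxon is differentially abundant, samples are
#' split into two random balanced groups, and group 1 is rarefied by
#' subsampling.  Any detected association between composition and group label
#' is a false positive by construction; the rarefaction plants a pure
#' sequencing-depth difference between groups.
#'
#' @param config A [sim_config()] with `prop_da = 0` and `rarefy_group1` set.
#' @return As [simulate_counts()]; `covariates$group` holds the labels.
#' @export
null_two_group <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$prop_da != 0) {
    stop("null_two_group requires prop_da = 0", call. = FALSE)
  }
  if (is.null(config$rarefy_group1)) {
    stop("null_two_group requires rarefy_group1", call. = FALSE)
  }
  cfg <- config
  cfg$latent <- "binary"
  cfg$group_balance <- 0.5
  simulate_counts(cfg)
}
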