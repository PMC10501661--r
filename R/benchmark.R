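#' Benchmark normalization methods on simulated data
#'
#' Runs generate -> normalize (each method) -> evaluate for a number of
#' replicates and aggregates per-method means and standard deviations.  The
#' scenario may be a list or a path to a flat `key = value` text file with the
#' fields: `replicates`, `methods` (comma-separated subset of rsim, tss, uq,
#' med, tmm, gmpr, rarefaction, oracle), `analyses` (comma-separated subset of
#' recovery, misclass, ttest), plus any [sim_config()] fields and the tuning
#' parameters `eta`, `gamma`, `n_resamples`, `subsample_fraction`,
#' `rarefaction_depth`, `alpha`.
#'
#' Analyses: `recovery` compares size factors to the planted sampling
#' fractions (RMSE of relative error and Pearson correlation); `misclass`
#' (rsim only) is the empirical misclassification rate of the reference set;
#' `ttest` runs per-taxon Welch tests at `alpha` and reports realized FDP and
#' sensitivity.  `oracle` is reference normalization with the true
#' non-differential taxa.
#'
#' @param scenario A list or path to a key-value scenario file.
#' @param out Optional output directory; writes `summary.tsv`, `records.json`
#'   and a `manifest.json` echoing the full configuration.
#' @return A list with `summary` (tibble, one row per method x analysis x
#'   metric) and `records` (tibble of per-replicate values).
#' @export
run_benchmark <- function(scenario, out = NULL) {
  cfg <- if (is.character(scenario)) read_scenario(scenario) else scenario
  defaults <- list(replicates = 5, methods = "rsim,tss", analyses = "recovery",
                   d = 200, n = 100, prop_da = 0.1, da_selection = "random",
                   latent = "binary", signal = 4, preset = NULL,
                   group_balance = 0.5, seed = 1, eta = 0.05, gamma = 0.8,
                   n_resamples = 100, subsample_fraction = 0.5,
                   rarefaction_depth = NULL, alpha = 0.05)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown scenario fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, cfg)
  methods <- strsplit(cfg$methods, ",")[[1]]
  analyses <- strsplit(cfg$analyses, ",")[[1]]
  valid_methods <- c("rsim", "tss", "uq", "med", "tmm", "gmpr", "rarefaction",
                     "oracle")
  valid_analyses <- c("recovery", "misclass", "ttest")
  if (length(bad <- setdiff(methods, valid_methods))) {
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(bad <- setdiff(analyses, valid_analyses))) {
    stop("unknown analysis(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("misclass" %in% analyses && !"rsim" %in% methods) {
    stop("analysis 'misclass' requires method 'rsim'", call. = FALSE)
  }
  if ("rarefaction" %in% methods && is.null(cfg$rarefaction_depth)) {
    stop("method 'rarefaction' requires rarefaction_depth", call. = FALSE)
  }

  records <- purrr::map_dfr(seq_len(cfg$replicates), function(rep) {
    sc <- sim_config(d = cfg$d, n = cfg$n, prop_da = cfg$prop_da,
                     da_selection = cfg$da_selection, latent = cfg$latent,
                     signal = cfg$signal, preset = cfg$preset,
                     group_balance = cfg$group_balance,
                     seed = cfg$seed + rep - 1)
    sim <- simulate_counts(sc)
    counts <- filter_taxa_quietly(sim$counts)
    purrr::map_dfr(methods, function(method) {
      res <- switch(method,
        rsim = rsim_normalize(counts, eta = cfg$eta, gamma = cfg$gamma,
                              n_resamples = cfg$n_resamples,
                              subsample_fraction = cfg$subsample_fraction,
                              seed = cfg$seed + rep - 1),
        oracle = list(normalized = reference_normalize(
          counts, intersect(sim$truth$nonda_taxa, rownames(counts))), fit = NULL),
        list(normalized = baseline_normalize(
          counts, method, depth = cfg$rarefaction_depth,
          seed = cfg$seed + rep - 1), fit = NULL)
      )
      out_rows <- list()
      if ("recovery" %in% analyses && method != "rarefaction") {
        cmp <- compare_size_factors(res$normalized$size_factors,
                                    sim$truth$sampling_fractions)
        out_rows$recovery <- tibble::tibble(
          replicate = rep, method = method, analysis = "recovery",
          metric = c("rmse", "pearson_cor"),
          value = c(cmp$rmse, stats::cor(cmp$per_sample$estimate,
                                         cmp$per_sample$truth)))
      }
      if ("misclass" %in% analyses && method == "rsim") {
        out_rows$misclass <- tibble::tibble(
          replicate = rep, method = method, analysis = "misclass",
          metric = "misclassification_rate",
          value = misclassification_rate(res$fit, sim$truth))
      }
      if ("ttest" %in% analyses) {
        tests <- per_taxon_tests(res$normalized, sim$covariates,
                                 test = "t_test", alpha = cfg$alpha)
        fs <- fdp_and_sensitivity(tests$taxon[tests$rejected], sim$truth)
        out_rows$ttest <- tibble::tibble(
          replicate = rep, method = method, analysis = "ttest",
          metric = c("fdp", "sensitivity"),
          value = c(fs$fdp, fs$sensitivity))
      }
      dplyr::bind_rows(out_rows)
    })
  })

  summary <- dplyr::summarise(
    dplyr::group_by(records, .data$method, .data$analysis, .data$metric),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop"
  )
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(summary, file.path(out, "summary.tsv"))
    jsonlite::write_json(records, file.path(out, "records.json"),
                         digits = NA, dataframe = "rows")
    jsonlite::write_json(
      c(cfg, list(package_version = as.character(utils::packageVersion("ranksim")))),
      file.path(out, "manifest.json"), auto_unbox = TRUE, null = "null"
    )
  }
  list(summary = summary, records = records)
}

filter_taxa_quietly <- function(counts) {
  suppressMessages(filter_taxa(counts))
}

# Flat key = value scenario parser (strings, numbers, or comma lists).
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed scenario line: ", lines[bad][1], call. = FALSE)
  vals <- lapply(kv, function(p) {
    v <- gsub('^"|"$', "", p[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[[`, "", 1))
}
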