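#' Coerce to a taxa-by-samples count matrix
#'
#' Validates and orients a microbiome count table.  The canonical internal
#' orientation is taxa as rows and samples as columns (the dominant OTU-table
#' convention); supply `orientation = "samples_by_taxa"` to transpose on the
#' way in.  Counts must be finite, integer-valued and non-negative; they are
#' stored as doubles so downstream column sums cannot overflow.
#'
#' @param x A numeric matrix with row and column names, or a data frame whose
#'   first column holds taxon ids and remaining columns hold per-sample counts.
#' @param orientation Orientation of `x`; the result is always taxa-by-samples.
#' @return A named numeric matrix (taxa x samples).
#' @examples
#' df <- data.frame(taxon = c("t1", "t2"), s1 = c(1, 0), s2 = c(2, 5))
#' as_count_matrix(df)
#' @export
as_count_matrix <- function(x, orientation = c("taxa_by_samples", "samples_by_taxa")) {
  orientation <- match.arg(orientation)
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    vals <- x[-1]
    bad <- !vapply(vals, is.numeric, logical(1))
    if (any(bad)) {
      col <- names(vals)[which(bad)[1]]
      j <- which(!grepl("^\\s*-?[0-9.eE+-]+\\s*$", as.character(vals[[which(bad)[1]]])))[1]
      stop("non-numeric entry at row '", ids[if (is.na(j)) 1 else j],
           "', column '", col, "'", call. = FALSE)
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or a data frame", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count matrix must carry row and column labels", call. = FALSE)
  }
  if (orientation == "samples_by_taxa") x <- t(x)
  validate_counts(x)
  storage.mode(x) <- "double"
  x
}

# Shared entry validation used by every operation taking counts.
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("count matrix is empty", call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | abs(counts - round(counts)) > 1e-8)
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(counts))
    stop("invalid count (negative, non-finite or non-integer) at taxon '",
         rownames(counts)[idx[1]], "', sample '", colnames(counts)[idx[2]], "'",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids", call. = FALSE)
  invisible(counts)
}

#' Read a count matrix from disk
#'
#' TSV/CSV layout: first column = taxon id, header row = sample ids.
#' MatrixMarket (`mtx`) input expects companion label files (one id per line)
#' for rows and columns, by default `rows.txt` / `cols.txt` next to the matrix.
#'
#' @param path Path to the table.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @param orientation Orientation of the stored table (see [as_count_matrix()]).
#' @param row_labels,col_labels Label files for `mtx` input.
#' @return A taxa-by-samples count matrix.
#' @export
read_count_matrix <- function(path,
                              format = c("tsv", "csv", "mtx"),
                              orientation = c("taxa_by_samples", "samples_by_taxa"),
                              row_labels = file.path(dirname(path), "rows.txt"),
                              col_labels = file.path(dirname(path), "cols.txt")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (!file.exists(row_labels) || !file.exists(col_labels)) {
      stop("mtx input needs companion label files: ", row_labels, ", ", col_labels,
           call. = FALSE)
    }
    rownames(m) <- readLines(row_labels)
    colnames(m) <- readLines(col_labels)
    return(as_count_matrix(m, orientation))
  }
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  df <- suppressWarnings(
    reader(path, show_col_types = FALSE, progress = FALSE,
           col_types = readr::cols(.default = readr::col_guess()))
  )
  as_count_matrix(as.data.frame(df), orientation)
}

#' Drop low-prevalence and constant taxa
#'
#' Taxa constant across all samples (including all-zero taxa) are always
#' removed: Spearman correlation is undefined for zero-variance vectors.  By
#' default nothing else is filtered, so zero entries are treated exactly like
#' non-zero entries downstream.
#'
#' @param counts Taxa-by-samples count matrix.
#' @param min_prevalence Minimum fraction of samples with a positive count.
#' @return The filtered count matrix; dropped taxon ids are reported via
#'   `message()` and attached as attribute `"dropped"`.
#' @export
filter_taxa <- function(counts, min_prevalence = 0) {
  validate_counts(counts)
  stopifnot(min_prevalence >= 0, min_prevalence <= 1)
  constant <- apply(counts, 1L, function(x) max(x) == min(x))
  prevalence <- rowMeans(counts > 0)
  keep <- !constant & prevalence >= min_prevalence
  if (!any(keep)) stop("no taxa survive filtering", call. = FALSE)
  dropped <- rownames(counts)[!keep]
  if (length(dropped)) {
    message("filter_taxa: dropped ", length(dropped), " taxa: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  }
  out <- counts[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Write a normalized matrix and its companions to disk
#'
#' Writes the normalized values as a TSV (taxa as rows, full double precision),
#' a companion TSV of per-sample size factors, and a plain-text file listing
#' the reference-set taxon ids one per line (empty for baseline methods with no
#' reference set).
#'
#' @param nm A `rsim_norm` object (see [reference_normalize()]).
#' @param path Output TSV for the normalized values.
#' @param factors_path,refset_path Companion outputs; defaults derive from `path`.
#' @export
write_normalized <- function(nm, path,
                             factors_path = paste0(path, ".factors.tsv"),
                             refset_path = paste0(path, ".refset.txt")) {
  stopifnot(inherits(nm, "rsim_norm"))
  if (nrow(nm$values) == 0L) stop("empty matrix (0 taxa)", call. = FALSE)
  df <- tibble::as_tibble(nm$values, rownames = "taxon")
  readr::write_tsv(df, path)
  readr::write_tsv(
    tibble::tibble(sample = colnames(nm$values), size_factor = nm$size_factors),
    factors_path
  )
  writeLines(nm$reference_set, refset_path)
  invisible(path)
}

#' Read back a normalized matrix written by [write_normalized()]
#'
#' @param path,factors_path,refset_path Paths as in [write_normalized()].
#' @return A `rsim_norm` object.
#' @export
read_normalized <- function(path,
                            factors_path = paste0(path, ".factors.tsv"),
                            refset_path = paste0(path, ".refset.txt")) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  values <- as.matrix(df[-1])
  rownames(values) <- df[[1]]
  sf <- readr::read_tsv(factors_path, show_col_types = FALSE, progress = FALSE)
  new_rsim_norm(values, readLines(refset_path),
                stats::setNames(sf$size_factor, sf$sample), method = "file")
}
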