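#' Read an expression matrix from delimited text
#'
#' Reads a samples-by-genes expression table (TSV by default, CSV accepted)
#' with one header row and one identifier column, and returns a validated
#' numeric matrix in samples-by-rows, genes-by-columns orientation.  Files
#' stored genes-in-rows are transposed on the way in.
#'
#' @param path Path to a delimited text file.  The first column holds row
#'   identifiers; the header row holds column identifiers.
#' @param genes_in_rows Logical; set \code{TRUE} when the file stores one
#'   gene per row (the matrix is transposed to the canonical orientation).
#' @param sep Field separator; \code{NULL} (default) picks \code{","} for
#'   \code{.csv} files and tab otherwise.
#' @return A numeric matrix, samples in rows (rownames = sample ids), genes
#'   in columns (colnames = gene ids).  No missing values are tolerated.
#' @seealso [write_expression()], [prefilter_genes()]
#' @export
read_expression <- function(path, genes_in_rows = FALSE, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(tab) < 2L) stop("expected an identifier column plus data columns")
  ids <- as.character(tab[[1L]])
  dat <- tab[, -1L, drop = FALSE]
  for (j in seq_along(dat)) {
    if (!is.numeric(dat[[j]])) {
      v <- suppressWarnings(as.numeric(dat[[j]]))
      bad <- which(is.na(v) & !is.na(dat[[j]]))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     dat[[j]][bad[1L]], ids[bad[1L]], names(dat)[j]))
      dat[[j]] <- v
    }
    miss <- which(is.na(dat[[j]]))
    if (length(miss))
      stop(sprintf("missing value at row '%s', column '%s'",
                   ids[miss[1L]], names(dat)[j]))
  }
  x <- as.matrix(dat)
  rownames(x) <- ids
  if (genes_in_rows) x <- t(x)
  validate_expression(x)
}

#' Write an expression matrix to delimited text
#'
#' @param x Samples-by-genes numeric matrix with identifiers.
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @return Invisibly, \code{path}.
#' @export
write_expression <- function(x, path, sep = "\t") {
  x <- validate_expression(x)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep the most expressed or most variable genes
#'
#' Robustly expressed housekeeping genes contribute little to sample
#' discrimination; restricting to the genes with the largest mean or
#' variance across samples is the usual pre-filter before graph
#' construction.  Retained genes keep their input order; ties are resolved
#' by input order (stable).
#'
#' @param x Samples-by-genes numeric matrix.
#' @param k Number of genes to keep.  \code{k >= ncol(x)} returns the input
#'   unchanged.
#' @param criterion Ranking statistic: per-gene \code{"variance"} (default)
#'   or \code{"mean"} across samples.
#' @return The matrix restricted to the top-\code{k} genes.
#' @export
prefilter_genes <- function(x, k, criterion = c("variance", "mean")) {
  x <- validate_expression(x)
  criterion <- match.arg(criterion)
  if (k < 1L) stop("k must be >= 1")
  m <- ncol(x)
  if (k >= m) return(x)
  stat <- if (criterion == "mean") colMeans(x) else apply(x, 2L, stats::var)
  keep <- sort(order(-stat, seq_len(m))[seq_len(k)])
  x[, keep, drop = FALSE]
}
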