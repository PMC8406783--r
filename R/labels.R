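#' Read sample labels from a two-column table
#'
#' Expects a header-less or headered two-column TSV
#' \code{sample_id<TAB>label}, where label is an integer in \code{1..c} or
#' the literal \code{unlabeled}.  Unlabeled samples come back as \code{NA}.
#'
#' @param path Path to the label file.
#' @param sample_ids Optional character vector; when given, labels are
#'   reordered to match and every id must be present.
#' @return An integer vector (NA = unlabeled), named by sample id, with the
#'   number of categories in attribute \code{"n_categories"}.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) != 2L) stop("label file must have exactly two columns")
  # tolerate an explicit header line
  if (tolower(tab[1L, 2L]) == "label" || tolower(tab[1L, 1L]) == "sample_id")
    tab <- tab[-1L, , drop = FALSE]
  ids <- as.character(tab[[1L]])
  raw <- as.character(tab[[2L]])
  lab <- suppressWarnings(as.integer(raw))
  unl <- tolower(raw) == "unlabeled"
  if (any(is.na(lab) & !unl))
    stop("invalid label '", raw[which(is.na(lab) & !unl)[1L]],
         "' (expected an integer or 'unlabeled')")
  lab[unl] <- NA_integer_
  names(lab) <- ids
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, ids)
    if (length(missing))
      stop("no label entry for sample(s): ", paste(missing, collapse = ", "))
    lab <- lab[sample_ids]
  }
  validate_labels(lab)
}

validate_labels <- function(labels, n_categories = NULL) {
  lab <- as.integer(labels)
  names(lab) <- names(labels)
  if (!any(!is.na(lab)))
    stop("at least one sample must be labeled")
  if (any(lab[!is.na(lab)] < 1L))
    stop("labels must be positive integers or NA/unlabeled")
  nc <- as.integer(n_categories %||% attr(labels, "n_categories") %||%
                     max(lab, na.rm = TRUE))
  if (any(lab[!is.na(lab)] > nc))
    stop("label ", max(lab, na.rm = TRUE), " exceeds n_categories = ", nc)
  attr(lab, "n_categories") <- nc
  lab
}

#' Initial category label matrix
#'
#' Builds the n-by-c binary matrix Y with \code{y[i, j] = 1} iff sample i
#' carries label j.  Unlabeled samples (NA) give an all-zero row, which is
#' what lets the propagation anchor vanish for them.
#'
#' @param labels Integer vector in \code{1..n_categories}, NA = unlabeled.
#' @param n_categories Number of categories c; defaults to
#'   \code{max(labels)} or the vector's \code{"n_categories"} attribute.
#' @return An n-by-c binary matrix.
#' @export
label_matrix <- function(labels, n_categories = NULL) {
  lab <- validate_labels(labels, n_categories)
  y <- one_hot(lab, attr(lab, "n_categories"))
  rownames(y) <- names(lab)
  y
}

#' Write / read consensus key-gene sets
#'
#' One TSV row per (category, gene), with occurrence count across restarts
#' and mean feature-selection score, sorted by category then descending
#' score.  Categories with empty sets are absent from the file body.
#'
#' @param ks A \code{key_gene_sets} object (see [consensus_key_genes()]).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_key_genes <- function(ks, path) {
  stopifnot(inherits(ks, "key_gene_sets"))
  rows <- do.call(rbind, lapply(seq_along(ks$sets), function(j) {
    s <- ks$sets[[j]]
    if (is.null(s) || nrow(s) == 0L) return(NULL)
    data.frame(category = j, s, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(category = integer(), gene_id = character(),
                       occurrence_count = integer(), mean_score = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_key_genes
#' @param n_categories Number of categories the file describes (defaults to
#'   the largest category present).
#' @param n_runs,min_count Metadata restored onto the object.
#' @export
read_key_genes <- function(path, n_categories = NULL, n_runs = NA_integer_,
                           min_count = NA_integer_) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, comment.char = "")
  nc <- n_categories %||% if (nrow(tab)) max(tab$category) else 0L
  sets <- lapply(seq_len(nc), function(j) {
    s <- tab[tab$category == j, c("gene_id", "occurrence_count", "mean_score")]
    rownames(s) <- NULL
    s
  })
  structure(list(sets = sets, n_runs = n_runs, min_count = min_count),
            class = "key_gene_sets")
}
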