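`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

lpfs_log <- function(verbose, ...) {
  if (isTRUE(verbose))
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  invisible(NULL)
}

# Shared validator for the samples x genes expression matrix.
# Row names are sample identifiers, column names gene identifiers.
validate_expression <- function(x, require_nonneg = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (samples x genes)")
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (ncol(x) < 1L) stop("need at least 1 gene")
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at sample '%s', gene '%s'",
                 rn(x)[idx[1L]], cn(x)[idx[2L]]))
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("gene_", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (require_nonneg && any(x < 0))
    stop("expression matrix must be non-negative")
  x
}

rn <- function(x) rownames(x) %||% as.character(seq_len(nrow(x)))
cn <- function(x) colnames(x) %||% as.character(seq_len(ncol(x)))

one_hot <- function(labels, n_categories) {
  n <- length(labels)
  m <- matrix(0, n, n_categories)
  ok <- !is.na(labels)
  m[cbind(which(ok), labels[ok])] <- 1
  m
}
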