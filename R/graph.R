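#' Gaussian-kernel sample similarity weights
#'
#' The sample network is a fully connected undirected graph with weights
#' \deqn{w_{ij} = \exp(-\|x_{i\cdot} - x_{j\cdot}\|^2 / (2\delta^2)),\ i \ne j,}
#' and zero diagonal.  Weights lie in [0, 1]; identical samples get weight 1.
#'
#' @param x Samples-by-genes numeric matrix (n >= 2).
#' @param delta Positive kernel bandwidth, in the units of the expression
#'   values.
#' @return An n-by-n symmetric matrix with zero diagonal, dimnames set to
#'   the sample ids.
#' @seealso [normalize_graph()], [suggest_delta()]
#' @export
gaussian_weights <- function(x, delta) {
  x <- validate_expression(x)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0)
    stop("delta must be a single positive number")
  d2 <- as.matrix(stats::dist(x))^2
  w <- exp(-d2 / (2 * delta^2))
  diag(w) <- 0
  w <- (w + t(w)) / 2  # enforce exact symmetry against fp noise
  dimnames(w) <- list(rownames(x), rownames(x))
  w
}

#' Symmetrically normalised sample graph
#'
#' From a symmetric non-negative weight matrix W with zero diagonal,
#' computes degrees \eqn{d_{ii} = \sum_j w_{ij}} and the normalised matrix
#' \eqn{Z = D^{-1/2} W D^{-1/2}}, whose spectral radius is at most 1 — the
#' property that makes the propagation system \eqn{(1+\mu)I - Z}
#' invertible for any \eqn{\mu > 0}.
#'
#' @param w Symmetric non-negative matrix with zero diagonal.
#' @return An object of class \code{sample_graph}: list with \code{w},
#'   \code{degrees}, \code{z}, and \code{n}.
#' @export
normalize_graph <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop("w must be a square matrix")
  if (any(w < 0)) stop("weights must be non-negative")
  if (any(abs(diag(w)) > 0)) stop("weight matrix must have a zero diagonal")
  if (max(abs(w - t(w))) > 1e-8 * max(1, max(abs(w))))
    stop("weight matrix must be symmetric")
  d <- rowSums(w)
  if (any(d <= 0)) {
    bad <- rn(w)[which(d <= 0)]
    stop("isolated sample(s) with zero degree: ",
         paste(bad, collapse = ", "),
         ". The graph normalisation is undefined there; try a larger delta.")
  }
  inv_sqrt_d <- 1 / sqrt(d)
  z <- w * tcrossprod(inv_sqrt_d)
  structure(list(w = w, degrees = d, z = z, n = nrow(w)),
            class = "sample_graph")
}

#' Build the normalised sample graph from expression data
#'
#' Convenience wrapper chaining [gaussian_weights()] and
#' [normalize_graph()].
#'
#' @inheritParams gaussian_weights
#' @param delta Bandwidth, or \code{"auto"} for [suggest_delta()].
#' @return A \code{sample_graph}, with the bandwidth used in
#'   \code{$delta}.
#' @export
sample_graph <- function(x, delta = "auto") {
  x <- validate_expression(x)
  if (identical(delta, "auto")) delta <- suggest_delta(x)
  g <- normalize_graph(gaussian_weights(x, delta))
  g$delta <- delta
  g
}

#' Data-driven kernel bandwidth
#'
#' The median of all pairwise sample Euclidean distances.  With this
#' bandwidth the kernel exponent \eqn{\|x_i - x_j\|^2 / (2\delta^2)} is
#' O(1) for typical pairs whatever the expression scale; it is advisory
#' only and any fixed value can be supplied instead.
#'
#' @param x Samples-by-genes numeric matrix (n >= 2).
#' @return A positive scalar.
#' @export
suggest_delta <- function(x) {
  x <- validate_expression(x)
  stats::median(stats::dist(x))
}

#' @export
print.sample_graph <- function(x, ...) {
  cat(sprintf("Sample similarity graph: %d samples\n", x$n))
  if (!is.null(x$delta)) cat(sprintf("  kernel bandwidth delta = %g\n", x$delta))
  cat(sprintf("  degree range [%g, %g]\n", min(x$degrees), max(x$degrees)))
  invisible(x)
}

#' Dump a graph's weight and normalised matrices as TSV
#'
#' @param graph A \code{sample_graph}.
#' @param path Output path prefix; writes \code{<path>.W.tsv} and
#'   \code{<path>.Z.tsv}.
#' @return Invisibly, the two paths written.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "sample_graph"))
  paths <- paste0(path, c(".W.tsv", ".Z.tsv"))
  for (i in 1:2) {
    m <- if (i == 1) graph$w else graph$z
    df <- data.frame(sample_id = rn(m), m, check.names = FALSE)
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
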