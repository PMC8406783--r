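## Core alternating solver: label propagation over the sample graph
## (closed-form H step) interleaved with multiplicative non-negative
## updates of the l2,1-regularised feature selection matrix F.

#' Joint objective of the label-propagation feature-selection model
#'
#' \deqn{\sum_{i,j} w_{ij}\|H_i/\sqrt{d_{ii}} - H_j/\sqrt{d_{jj}}\|^2
#'   + \mu\sum_i\|H_i - Y_i\|^2 + \|XF - H\|_F^2 + \beta\|F\|_{2,1}}
#' The graph-smoothness penalty is taken in squared form, which is the
#' form whose gradient the alternating solver actually uses.
#'
#' @param x Samples-by-genes matrix.
#' @param graph A [sample_graph()] built from \code{x}.
#' @param h n-by-c cluster indicator matrix (binary or continuous).
#' @param y n-by-c initial label matrix ([label_matrix()]).
#' @param fmat m-by-c non-negative feature selection matrix.
#' @param mu,beta Anchor and sparsity weights.
#' @return A single non-negative number.
#' @export
lpfs_objective <- function(x, graph, h, y, fmat, mu, beta) {
  stopifnot(inherits(graph, "sample_graph"))
  n <- nrow(x)
  c <- ncol(h)
  if (nrow(h) != n || !all(dim(y) == dim(h)) ||
      nrow(fmat) != ncol(x) || ncol(fmat) != c)
    stop("inconsistent shapes among x, h, y, fmat")
  smooth <- 2 * (sum(h^2) - sum(h * (graph$z %*% h)))
  smooth + mu * sum((h - y)^2) + sum((x %*% fmat - h)^2) +
    beta * sum(sqrt(colSums(fmat^2)))
}

#' Feature-selection subproblem objective
#'
#' \eqn{\|XF - H\|_F^2 + \beta\|F\|_{2,1}}, the part of the joint
#' objective that depends on F alone.
#'
#' @inheritParams lpfs_objective
#' @export
fs_objective <- function(fmat, x, h, beta) {
  sum((x %*% fmat - h)^2) + beta * sum(sqrt(colSums(fmat^2)))
}

# One multiplicative step with precomputed X'X and X'H.  The auxiliary
# diagonal u_jj = 1/(2 ||F^j||_2) is recomputed from the incoming F; both
# the column norms and the denominator are floored at eps so exactly-zero
# columns do not produce divisions by zero (a zero entry stays zero).
mult_update <- function(fmat, xtx, xth, beta, eps = 1e-12) {
  u <- 1 / (2 * pmax(sqrt(colSums(fmat^2)), eps))
  den <- xtx %*% fmat + fmat * rep(beta * u, each = nrow(fmat))
  fmat * xth / (den + eps)
}

#' One multiplicative update of the feature selection matrix
#'
#' \deqn{f_{ij} \leftarrow f_{ij}\,
#'   \frac{(X^T H)_{ij}}{(X^T X F + \beta F U)_{ij} + \epsilon}}
#' with \eqn{U = diag(1/(2\|F^j\|_2))} recomputed from the current F.
#' The update preserves entrywise non-negativity and never increases
#' [fs_objective()].
#'
#' @param fmat Current m-by-c non-negative F.
#' @param x Samples-by-genes non-negative matrix.
#' @param h n-by-c target indicator matrix.
#' @param beta Sparsity weight (>= 0).
#' @param eps Floor for the denominator and the column norms.
#' @return The updated F.
#' @export
update_f <- function(fmat, x, h, beta, eps = 1e-12) {
  if (any(fmat < 0)) stop("fmat must be entrywise non-negative")
  mult_update(fmat, crossprod(x), crossprod(x, h), beta, eps)
}

# Inner loop shared by solve_f() and lpfs(): iterate mult_update() from a
# given starting F until the relative change of the subproblem objective
# drops below tol.
f_inner <- function(f0, x, xtx, h, beta, tol, max_iter) {
  xth <- crossprod(x, h)
  f <- f0
  trace <- fs_objective(f, x, h, beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f <- mult_update(f, xtx, xth, beta)
    obj <- fs_objective(f, x, h, beta)
    trace <- c(trace, obj)
    if (abs(trace[it] - obj) <= tol * max(abs(trace[it]), 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(f = f, objective = trace, converged = converged,
       iterations = length(trace) - 1L)
}

#' Solve the feature-selection subproblem for fixed H
#'
#' Initialises F uniformly in (0, 1) from \code{seed} (unless
#' \code{f_init} is supplied) and applies [update_f()] until the relative
#' change of [fs_objective()] falls below \code{tol} or \code{max_iter}
#' is reached; non-convergence is a warning, not an error.
#'
#' @inheritParams update_f
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @param seed RNG seed for the random initialisation.
#' @param f_init Optional starting matrix (overrides the random draw).
#' @return A list with \code{f}, the per-iteration \code{objective}
#'   trace, \code{converged}, and \code{iterations}.
#' @export
solve_f <- function(x, h, beta, tol = 1e-4, max_iter = 500L, seed = 1L,
                    f_init = NULL) {
  x <- validate_expression(x, require_nonneg = TRUE)
  if (beta < 0) stop("beta must be >= 0")
  m <- ncol(x)
  c <- ncol(h)
  f0 <- f_init %||%
    with_seed(seed, matrix(stats::runif(m * c), m, c))
  if (any(f0 < 0)) stop("f_init must be non-negative")
  res <- f_inner(f0, x, crossprod(x), h, beta, tol, max_iter)
  if (!res$converged)
    warning("F updates did not converge within ", max_iter, " iterations")
  rownames(res$f) <- colnames(x)
  res
}

# Propagate labels given the Cholesky factor of (1+mu)I - Z.
propagate_chol <- function(chol_m, y, xf, mu) {
  b <- mu * y + xf
  h_star <- backsolve(chol_m, backsolve(chol_m, b, transpose = TRUE))
  labels <- max.col(h_star, ties.method = "first")
  h_bin <- one_hot(labels, ncol(y))
  dimnames(h_star) <- dimnames(y)
  rownames(h_bin) <- rownames(y)
  names(labels) <- rownames(y)
  list(h_star = h_star, h_bin = h_bin, labels = labels)
}

#' Closed-form label propagation step
#'
#' For fixed F, the cluster indicator solving the propagation subproblem
#' is \deqn{H^* = ((1+\mu)I - Z)^{-1}(\mu Y + XF),} computed via a
#' Cholesky solve (the system matrix is symmetric positive definite
#' because the spectral radius of Z is at most 1 and \eqn{\mu > 0}).
#' Per-sample labels are the row argmax of \eqn{H^*} (ties to the
#' smallest category index) and the binarised indicator one-hot-encodes
#' them.
#'
#' @param graph A [sample_graph()].
#' @param y n-by-c initial label matrix.
#' @param x Samples-by-genes matrix.
#' @param fmat m-by-c feature selection matrix.
#' @param mu Anchor weight (> 0).
#' @return A list with \code{h_star} (continuous), \code{h_bin}
#'   (binary indicator, rows summing to 1), and integer \code{labels}.
#' @export
solve_h <- function(graph, y, x, fmat, mu) {
  stopifnot(inherits(graph, "sample_graph"))
  if (mu <= 0) stop("mu must be > 0")
  n <- graph$n
  if (nrow(y) != n || nrow(x) != n || ncol(fmat) != ncol(y) ||
      nrow(fmat) != ncol(x))
    stop("inconsistent shapes among graph, y, x, fmat")
  m_sys <- (1 + mu) * diag(n) - graph$z
  propagate_chol(chol(m_sys), y, x %*% fmat, mu)
}

#' Fit the label-propagation feature-selection model
#'
#' Builds the Gaussian-kernel sample graph, anchors the propagation on
#' the supplied (possibly partial) labels, and alternates the
#' multiplicative F updates with the closed-form propagation step until
#' the joint objective stabilises.  The cluster indicator handed to each
#' F step is the binarised one by default; the continuous propagation
#' result is kept on the fitted object for diagnostics.
#'
#' @param x Samples-by-genes non-negative numeric matrix (rownames =
#'   sample ids, colnames = gene ids).
#' @param labels Integer vector in \code{1..n_categories}; \code{NA}
#'   marks unlabeled samples.  At least one sample must be labeled.
#' @param n_categories Number of categories c (defaults to
#'   \code{max(labels)}).
#' @param control An [lpfs_control()] list.
#' @param mu,beta,delta,seed Shortcuts overriding the corresponding
#'   control entries.
#' @return An object of class \code{lpfs} with components \code{F}
#'   (genes-by-categories, via \code{coef()}), \code{h_star},
#'   \code{h_bin}, \code{labels} (predicted categories), \code{graph},
#'   \code{y}, \code{trace} (outer objective, per-round F traces,
#'   convergence flags), and the resolved \code{control}.
#' @examples
#' sim <- simulate_expression(n_per_category = 4, n_categories = 2,
#'                            n_genes = 40, markers_per_category = 5,
#'                            effect = 3, seed = 1)
#' fit <- lpfs(sim$expression, sim$truth$labels)
#' table(predicted = fit$labels, truth = sim$truth$labels)
#' @export
lpfs <- function(x, labels, n_categories = NULL, control = lpfs_control(),
                 mu = control$mu, beta = control$beta,
                 delta = control$delta, seed = control$seed) {
  cl <- match.call()
  x <- validate_expression(x, require_nonneg = TRUE)
  lab <- validate_labels(labels, n_categories)
  if (length(lab) != nrow(x))
    stop("length(labels) must equal the number of samples")
  nc <- attr(lab, "n_categories")
  g <- sample_graph(x, delta)
  y <- label_matrix(lab, nc)
  n <- nrow(x)
  m <- ncol(x)

  chol_m <- chol((1 + mu) * diag(n) - g$z)  # factorise once; Z is fixed
  xtx <- crossprod(x)
  h <- y
  f <- with_seed(seed, matrix(stats::runif(m * nc), m, nc))
  outer_obj <- numeric(0)
  f_traces <- list()
  converged <- FALSE
  warned_empty <- FALSE
  prop <- NULL

  for (round in seq_len(control$outer_max_iter)) {
    fs <- f_inner(f, x, xtx, h, beta, control$f_tol, control$f_max_iter)
    f <- fs$f
    f_traces[[round]] <- fs$objective
    prop <- propagate_chol(chol_m, y, x %*% f, mu)
    if (!warned_empty && any(colSums(prop$h_bin) == 0)) {
      warning("empty category in the cluster indicator (no sample assigned ",
              "to category ",
              paste(which(colSums(prop$h_bin) == 0), collapse = ", "),
              "); the fit continues but may be unstable")
      warned_empty <- TRUE
    }
    h <- if (control$h_update == "binary") prop$h_bin else prop$h_star
    outer_obj[round] <- lpfs_objective(x, g, h, y, f, mu, beta)
    lpfs_log(control$verbose, sprintf("outer round %d: objective %.6g",
                                      round, outer_obj[round]))
    if (round > 1 &&
        abs(outer_obj[round] - outer_obj[round - 1L]) <=
          control$outer_tol * max(abs(outer_obj[round - 1L]), 1e-12)) {
      converged <- TRUE
      break
    }
  }

  rownames(f) <- colnames(x)
  colnames(f) <- paste0("category_", seq_len(nc))
  structure(list(
    F = f,
    h_star = prop$h_star,
    h_bin = prop$h_bin,
    labels = prop$labels,
    graph = g,
    y = y,
    input_labels = lab,
    n_categories = nc,
    trace = list(outer_objective = outer_obj, f_objective = f_traces,
                 converged = converged, rounds_used = length(outer_obj),
                 empty_category = warned_empty),
    control = control, mu = mu, beta = beta, delta = g$delta, seed = seed,
    call = cl), class = "lpfs")
}

#' @export
print.lpfs <- function(x, ...) {
  cat("Label-propagation feature selection fit\n")
  cat(sprintf("  %d samples, %d genes, %d categories\n",
              nrow(x$h_star), nrow(x$F), x$n_categories))
  cat(sprintf("  mu = %g, beta = %g, delta = %g\n", x$mu, x$beta, x$delta))
  cat(sprintf("  outer rounds: %d (%s), objective %.6g\n",
              x$trace$rounds_used,
              if (x$trace$converged) "converged" else "iteration cap",
              utils::tail(x$trace$outer_objective, 1)))
  invisible(x)
}

#' @export
coef.lpfs <- function(object, ...) object$F

#' @export
fitted.lpfs <- function(object, ...) object$h_star

#' Predict category scores or labels
#'
#' For new samples, per-category scores are the projection of their
#' expression through the fitted feature selection matrix,
#' \eqn{X_{new} F}; labels are the row argmax.  Without \code{newdata}
#' the training-sample propagation result is returned.
#'
#' @param object A fitted \code{lpfs} object.
#' @param newdata Optional samples-by-genes matrix; gene columns are
#'   matched by name against the fitted genes.
#' @param type \code{"class"} for integer labels, \code{"scores"} for the
#'   n-by-c score matrix.
#' @param ... Unused.
#' @export
predict.lpfs <- function(object, newdata = NULL,
                         type = c("class", "scores"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(if (type == "class") object$labels else object$h_star)
  }
  genes <- rownames(object$F)
  if (is.null(colnames(newdata)) || !all(genes %in% colnames(newdata)))
    stop("newdata must carry all fitted genes as named columns")
  scores <- newdata[, genes, drop = FALSE] %*% object$F
  if (type == "scores") return(scores)
  lab <- max.col(scores, ties.method = "first")
  names(lab) <- rownames(newdata)
  lab
}

#' @export
summary.lpfs <- function(object, n_top = 5L, ...) {
  f <- object$F
  top <- lapply(seq_len(ncol(f)), function(j) {
    ord <- order(-f[, j], seq_len(nrow(f)))[seq_len(min(n_top, nrow(f)))]
    data.frame(gene_id = rownames(f)[ord], score = f[ord, j])
  })
  names(top) <- colnames(f)
  structure(list(fit = object, top_genes = top,
                 category_sizes = colSums(object$h_bin),
                 agreement = if (any(!is.na(object$input_labels)))
                   mean(object$labels[!is.na(object$input_labels)] ==
                          object$input_labels[!is.na(object$input_labels)])
                 else NA_real_),
            class = "summary.lpfs")
}

#' @export
print.summary.lpfs <- function(x, ...) {
  print(x$fit)
  cat("  samples per predicted category: ",
      paste(x$category_sizes, collapse = ", "), "\n")
  if (!is.na(x$agreement))
    cat(sprintf("  agreement with supplied labels: %.1f%%\n",
                100 * x$agreement))
  cat("  top genes per category:\n")
  for (nm in names(x$top_genes)) {
    tg <- x$top_genes[[nm]]
    cat(sprintf("    %s: %s\n", nm,
                paste(sprintf("%s (%.3g)", tg$gene_id, tg$score),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Plot the objective trace of a fit
#'
#' @param x A fitted \code{lpfs} object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lpfs <- function(x, ...) {
  obj <- x$trace$outer_objective
  graphics::plot(seq_along(obj), obj, type = "b", pch = 19,
                 xlab = "outer round", ylab = "joint objective",
                 main = "LPFS objective trace", ...)
  invisible(x)
}
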