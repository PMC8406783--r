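## Synthetic multi-class expression data with planted per-category
## marker genes, emulating a genotype-by-age design: every category gets
## a disjoint block of markers whose mean is shifted upward by a fixed
## number of noise standard deviations.

#' Simulate expression data with planted category markers
#'
#' Each sample of category k draws gene g from
#' \eqn{N(base\_mean + effect \cdot noise\_sd \cdot 1\{g \in markers_k\},
#' noise\_sd)}, truncated at zero.  Marker positions are drawn without
#' replacement among the genes (disjoint across categories);
#' identifiers and all draws are deterministic given \code{seed}.
#' Defaults mirror a six-category design with eight samples per
#' category, 300 genes and 10 markers per category at effect size 2.
#'
#' @param n_per_category Samples per category.
#' @param n_categories Number of categories c.
#' @param n_genes Total genes m (must satisfy
#'   \code{n_categories * markers_per_category <= n_genes}).
#' @param markers_per_category Planted markers per category.
#' @param effect Mean shift of a marker in its own category, in units of
#'   \code{noise_sd}.
#' @param base_mean Background expression level (log2-like scale).
#' @param noise_sd Within-gene standard deviation.
#' @param seed RNG seed.
#' @return A list of class \code{lpfs_simulation}: \code{expression}
#'   (samples-by-genes matrix) and \code{truth} (labels, per-category
#'   marker gene ids, and the generating parameters).
#' @export
simulate_expression <- function(n_per_category = 8L, n_categories = 6L,
                                n_genes = 300L, markers_per_category = 10L,
                                effect = 2, base_mean = 7, noise_sd = 1,
                                seed = 1L) {
  stopifnot(n_per_category >= 1, n_categories >= 1, n_genes >= 1,
            markers_per_category >= 0, noise_sd > 0)
  if (n_categories * markers_per_category > n_genes)
    stop("n_categories * markers_per_category must not exceed n_genes")
  n <- n_per_category * n_categories
  labels <- rep(seq_len(n_categories), each = n_per_category)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  sample_ids <- sprintf("sample_%03d", seq_len(n))
  sim <- with_seed(seed, {
    marker_pos <- if (markers_per_category > 0)
      sample.int(n_genes, n_categories * markers_per_category)
    else integer(0)
    markers <- split(marker_pos,
                     rep(seq_len(n_categories),
                         each = markers_per_category))
    means <- matrix(base_mean, n, n_genes)
    for (k in seq_len(n_categories))
      means[labels == k, markers[[k]]] <-
        base_mean + effect * noise_sd
    vals <- means + matrix(stats::rnorm(n * n_genes, sd = noise_sd),
                           n, n_genes)
    list(x = pmax(vals, 0), markers = markers)
  })
  x <- sim$x
  dimnames(x) <- list(sample_ids, gene_ids)
  names(labels) <- sample_ids
  marker_ids <- lapply(seq_len(n_categories), function(k)
    gene_ids[sim$markers[[k]]])
  structure(list(
    expression = x,
    truth = list(labels = labels, markers = marker_ids, effect = effect,
                 base_mean = base_mean, noise_sd = noise_sd,
                 n_categories = n_categories, seed = seed)),
    class = "lpfs_simulation")
}

#' @export
print.lpfs_simulation <- function(x, ...) {
  tr <- x$truth
  cat(sprintf("Synthetic expression data: %d samples x %d genes, %d categories\n",
              nrow(x$expression), ncol(x$expression), tr$n_categories))
  cat(sprintf("  %d markers/category, effect %g SD, base mean %g, noise SD %g\n",
              length(tr$markers[[1L]]), tr$effect, tr$base_mean, tr$noise_sd))
  invisible(x)
}

#' Mask a fraction of the true labels, stratified per category
#'
#' Keeps \code{round(labeled_fraction * n_k)} labeled samples in every
#' category (uniformly chosen) and sets the rest to \code{NA}, producing
#' a partial labelling for semi-supervised fits.
#'
#' @param truth The \code{truth} component of a [simulate_expression()]
#'   result (or any list with \code{labels} and \code{n_categories}).
#' @param labeled_fraction Fraction in (0, 1] of labels to keep per
#'   category; must leave at least one labeled sample per category.
#' @param seed RNG seed for the mask.
#' @return Integer label vector with \code{NA} for masked samples and the
#'   \code{"n_categories"} attribute set.
#' @export
make_partial_labels <- function(truth, labeled_fraction, seed = 1L) {
  if (labeled_fraction <= 0 || labeled_fraction > 1)
    stop("labeled_fraction must be in (0, 1]")
  labels <- truth$labels
  nc <- truth$n_categories %||% max(labels)
  keep <- with_seed(seed, {
    unlist(lapply(seq_len(nc), function(k) {
      idx <- which(labels == k)
      n_keep <- round(labeled_fraction * length(idx))
      if (n_keep < 1L)
        stop("labeled_fraction too small: category ", k,
             " would lose all labels")
      if (n_keep == length(idx)) idx else sample(idx, n_keep)
    }))
  })
  out <- rep(NA_integer_, length(labels))
  out[keep] <- labels[keep]
  names(out) <- names(labels)
  attr(out, "n_categories") <- nc
  out
}
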