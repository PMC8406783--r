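## Rank-product gene ranking, iterative elimination, and the
## multi-restart consensus protocol.

#' Rank-product discriminability ranking of genes
#'
#' Within each category column of the feature selection matrix, genes are
#' ranked descending by their score (rank 1 = largest; ties get the
#' average rank).  A gene's rank product is the geometric mean of its
#' per-column ranks: a gene that dominates at least one category earns a
#' rank near 1 there and a small geometric mean, while a flat,
#' uninformative row sits mid-table in every column and sorts last.
#'
#' @param fmat m-by-c non-negative feature selection matrix (rownames =
#'   gene ids).
#' @return An object of class \code{gene_ranking}: \code{gene_ids},
#'   \code{rp_value} (in [1, m]), and \code{order} — the permutation
#'   sorting genes from most to least discriminative (ascending rank
#'   product, ties by input order).
#' @export
rank_product <- function(fmat) {
  if (!is.matrix(fmat)) fmat <- as.matrix(fmat)
  if (any(fmat < 0)) stop("fmat must be entrywise non-negative")
  m <- nrow(fmat)
  ranks <- apply(fmat, 2L, function(col) rank(-col, ties.method = "average"))
  ranks <- matrix(ranks, nrow = m)  # guard m = 1 collapse
  rp <- exp(rowMeans(log(ranks)))
  structure(list(gene_ids = rownames(fmat) %||% as.character(seq_len(m)),
                 rp_value = rp,
                 order = order(rp, seq_len(m))),
            class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, n = 10L, ...) {
  k <- min(n, length(x$rp_value))
  cat(sprintf("Gene ranking over %d genes (rank product, smaller = more discriminative)\n",
              length(x$rp_value)))
  top <- x$order[seq_len(k)]
  cat("  top:", paste(sprintf("%s (%.3g)", x$gene_ids[top], x$rp_value[top]),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Remove the least discriminative genes
#'
#' Drops the \code{r} genes with the largest rank product from the
#' expression matrix; surviving genes keep their input order.  Asking to
#' remove all genes is clipped so that at least one survives (with a
#' warning).
#'
#' @param x Samples-by-genes matrix.
#' @param ranking A [rank_product()] result computed on the same genes.
#' @param r Number of genes to remove (0 is a no-op).
#' @return The reduced matrix.
#' @export
remove_low_ranking <- function(x, ranking, r) {
  stopifnot(inherits(ranking, "gene_ranking"))
  m <- ncol(x)
  if (length(ranking$rp_value) != m)
    stop("ranking covers ", length(ranking$rp_value),
         " genes but x has ", m)
  if (r <= 0) return(x)
  if (r >= m) {
    warning("removal of ", r, " genes clipped to ", m - 1L,
            " so one gene survives")
    r <- m - 1L
  }
  keep <- sort(ranking$order[seq_len(m - r)])
  x[, keep, drop = FALSE]
}

#' Per-category key genes from a feature selection matrix
#'
#' Category j's key set is the \code{s} genes with the largest scores in
#' column j (ties to the smaller row index).  Sets of different
#' categories may overlap; \code{s >= m} returns every gene.
#'
#' @param fmat m-by-c non-negative matrix with gene rownames.
#' @param s Number of genes per category.
#' @return A list (one element per category) of named numeric vectors:
#'   values are the column scores, names the gene ids, in descending
#'   score order.
#' @export
extract_key_genes <- function(fmat, s) {
  if (s < 1) stop("s must be >= 1")
  m <- nrow(fmat)
  ids <- rownames(fmat) %||% as.character(seq_len(m))
  k <- min(s, m)
  lapply(seq_len(ncol(fmat)), function(j) {
    ord <- order(-fmat[, j], seq_len(m))[seq_len(k)]
    stats::setNames(fmat[ord, j], ids[ord])
  })
}

#' Consensus key-gene sets across randomised restarts
#'
#' A gene enters category j's consensus set when it appears in that
#' category's key set in at least \code{min_count} of the runs — the
#' "more than 50 of 100" rule is \code{min_count = 51}.  Reported scores
#' are the mean of the gene's selection score over the runs in which it
#' appeared.
#'
#' @param runs Non-empty list of [extract_key_genes()] results, one per
#'   restart; all must have the same number of categories.
#' @param min_count Minimum occurrence count (<= number of runs).
#' @return An object of class \code{key_gene_sets}: \code{sets} (one
#'   data frame per category with \code{gene_id}, \code{occurrence_count},
#'   \code{mean_score}, sorted by descending mean score then gene id),
#'   \code{n_runs}, and \code{min_count}.
#' @export
consensus_key_genes <- function(runs, min_count) {
  if (!length(runs)) stop("runs must be a non-empty list")
  ncat <- vapply(runs, length, 1L)
  if (length(unique(ncat)) != 1L)
    stop("runs disagree on the number of categories: ",
         paste(unique(ncat), collapse = " vs "))
  if (min_count > length(runs))
    stop("min_count (", min_count, ") exceeds the number of runs (",
         length(runs), ")")
  sets <- lapply(seq_len(ncat[1L]), function(j) {
    genes <- sort(unique(unlist(lapply(runs, function(r) names(r[[j]])))))
    if (!length(genes))
      return(data.frame(gene_id = character(), occurrence_count = integer(),
                        mean_score = numeric()))
    count <- integer(length(genes))
    total <- numeric(length(genes))
    names(count) <- names(total) <- genes
    for (r in runs) {
      v <- r[[j]]
      count[names(v)] <- count[names(v)] + 1L
      total[names(v)] <- total[names(v)] + v
    }
    keep <- count >= min_count
    out <- data.frame(gene_id = genes[keep],
                      occurrence_count = count[keep],
                      mean_score = total[keep] / count[keep],
                      stringsAsFactors = FALSE)
    out <- out[order(-out$mean_score, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  structure(list(sets = sets, n_runs = length(runs),
                 min_count = as.integer(min_count)),
            class = "key_gene_sets")
}

#' Per-gene prioritisation scores from consensus key-gene sets
#'
#' Scores every gene in \code{gene_ids} by its largest mean selection
#' score across the per-category consensus sets; genes in no set score 0.
#' This is the default ranking used to compare selected genes against a
#' gold standard (e.g. with [roc_auc()] / [aupr()]).
#'
#' @param ks A \code{key_gene_sets} object.
#' @param gene_ids Genes to score (typically all genes of the input
#'   matrix).
#' @return Named numeric vector over \code{gene_ids}.
#' @export
gene_scores <- function(ks, gene_ids) {
  stopifnot(inherits(ks, "key_gene_sets"))
  score <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
  for (s in ks$sets) {
    known <- s$gene_id %in% gene_ids
    score[s$gene_id[known]] <- pmax(score[s$gene_id[known]],
                                    s$mean_score[known])
  }
  score
}

#' @export
print.key_gene_sets <- function(x, ...) {
  cat(sprintf("Consensus key genes over %d runs (min occurrences %d)\n",
              x$n_runs, x$min_count))
  for (j in seq_along(x$sets)) {
    s <- x$sets[[j]]
    cat(sprintf("  category %d: %d genes", j, nrow(s)))
    if (nrow(s))
      cat(" — ", paste(utils::head(s$gene_id, 5L), collapse = ", "),
          if (nrow(s) > 5L) ", ..." else "", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Iterative fitting with rank-product gene elimination
#'
#' Runs the full fit, ranks genes by rank product of the fitted feature
#' selection matrix, removes the least discriminative
#' \code{control$removal_size} genes, and repeats for
#' \code{control$inner_rounds} rounds.  Each round rebuilds the sample
#' graph from the reduced matrix, so the similarity structure sharpens as
#' noise genes disappear.
#'
#' @inheritParams lpfs
#' @param seed RNG seed for this run's random F initialisations.
#' @return An object of class \code{lpfs_iteration}: \code{rounds}, a
#'   list with one entry per round (\code{fit}, \code{ranking},
#'   \code{retained} gene ids after that round's removal,
#'   \code{n_genes} entering the round), and \code{final}, the last
#'   round's fit.
#' @export
iterate_lpfs <- function(x, labels, n_categories = NULL,
                         control = lpfs_control(), seed = control$seed) {
  x <- validate_expression(x, require_nonneg = TRUE)
  rounds <- vector("list", control$inner_rounds)
  xc <- x
  for (r in seq_len(control$inner_rounds)) {
    fit <- lpfs(xc, labels, n_categories, control = control, seed = seed)
    ranking <- rank_product(coef(fit))
    xnew <- remove_low_ranking(xc, ranking, control$removal_size)
    rounds[[r]] <- list(fit = fit, ranking = ranking,
                        retained = colnames(xnew), n_genes = ncol(xc))
    lpfs_log(control$verbose,
             sprintf("elimination round %d: %d -> %d genes",
                     r, ncol(xc), ncol(xnew)))
    xc <- xnew
  }
  structure(list(rounds = rounds, final = rounds[[length(rounds)]]$fit,
                 surviving = colnames(xc), control = control, seed = seed),
            class = "lpfs_iteration")
}

#' @export
print.lpfs_iteration <- function(x, ...) {
  counts <- vapply(x$rounds, function(r) r$n_genes, 1L)
  cat(sprintf("Iterative LPFS: %d rounds, gene counts %s -> %d surviving\n",
              length(x$rounds), paste(counts, collapse = " -> "),
              length(x$surviving)))
  invisible(x)
}

#' Full randomised-restart protocol with consensus key genes
#'
#' Executes [iterate_lpfs()] \code{control$repetitions} times with seeds
#' \code{seed, seed + 1, ...}, extracts each restart's per-category key
#' genes from the final round's feature selection matrix, and forms the
#' consensus sets.  Restarts that fail (e.g. every sample drawn into one
#' category) are logged and skipped; the protocol errors only when more
#' than half of the restarts fail.
#'
#' @inheritParams lpfs
#' @param seed Base seed; restart r uses \code{seed + r - 1}.
#' @return An object of class \code{lpfs_protocol}: \code{consensus}
#'   (a \code{key_gene_sets}), \code{run_sets} (per-restart key sets),
#'   \code{failures}, \code{n_warnings}, and the resolved
#'   \code{control}.
#' @export
lpfs_protocol <- function(x, labels, n_categories = NULL,
                          control = lpfs_control(), seed = control$seed) {
  x <- validate_expression(x, require_nonneg = TRUE)
  reps <- control$repetitions
  if (control$consensus_min_count > reps)
    stop("consensus_min_count exceeds the number of repetitions")
  lpfs_log(control$verbose,
           sprintf("protocol: %d repetitions, base seed %d, %d genes",
                   reps, seed, ncol(x)))
  run_sets <- vector("list", reps)
  failures <- character(0)
  n_warn <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch(
      withCallingHandlers(
        {
          it <- iterate_lpfs(x, labels, n_categories, control = control,
                             seed = seed + r - 1L)
          s <- control$s %||% length(it$surviving)
          extract_key_genes(coef(it$final), s)
        },
        warning = function(w) {
          n_warn <<- n_warn + 1L
          lpfs_log(control$verbose, "run ", r, " warning: ",
                   conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("run %d: %s", r, conditionMessage(res)))
      lpfs_log(control$verbose, "run ", r, " failed: ", conditionMessage(res))
    } else {
      run_sets[[r]] <- res
    }
  }
  ok <- !vapply(run_sets, is.null, TRUE)
  if (sum(!ok) > reps / 2)
    stop("more than half of the protocol runs failed:\n",
         paste(failures, collapse = "\n"))
  consensus <- consensus_key_genes(run_sets[ok], control$consensus_min_count)
  consensus$n_runs <- reps  # count failed restarts in the denominator
  structure(list(consensus = consensus, run_sets = run_sets,
                 failures = failures, n_warnings = n_warn,
                 control = control, seed = seed),
            class = "lpfs_protocol")
}

#' @export
print.lpfs_protocol <- function(x, ...) {
  cat(sprintf("LPFS protocol: %d repetitions (%d failed, %d warnings)\n",
              x$control$repetitions, length(x$failures), x$n_warnings))
  print(x$consensus)
  invisible(x)
}
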