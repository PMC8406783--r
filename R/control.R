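#' Control parameters for LPFS fitting and the key-gene protocol
#'
#' Collects every tunable of the method in one place, in the spirit of
#' \code{glm.control}.  The defaults are the settings used for the
#' Huntington's-disease striatum analysis the method was developed on:
#' anchor weight \code{mu = 0.2}, sparsity weight \code{beta = 0.2},
#' kernel bandwidth \code{delta = 200} for that data's expression scale
#' (pass \code{"auto"} to use the median pairwise sample distance instead),
#' 1000 genes removed per elimination round, 5 rounds, 100 randomised
#' restarts, and consensus membership for genes appearing in more than 50
#' of the 100 restarts (i.e. at least \code{consensus_min_count = 51}).
#'
#' @param mu Label-anchor weight in (0,1): balances the propagated label
#'   against the initial label of each sample.
#' @param beta Sparsity weight in (0,1) on the l2,1 norm of the feature
#'   selection matrix.
#' @param delta Gaussian kernel bandwidth (same units as the expression
#'   values), or \code{"auto"} for [suggest_delta()].
#' @param s Number of top genes kept per category when extracting key
#'   genes; \code{NULL} keeps every gene surviving the final round.
#' @param inner_rounds Gene-elimination rounds per restart.
#' @param removal_size Genes removed per elimination round.
#' @param repetitions Randomised restarts of the whole process.
#' @param consensus_min_count Minimum occurrences (out of
#'   \code{repetitions}) for a gene to enter the consensus set; the default
#'   51 encodes "more than 50 of 100" strictly.
#' @param f_tol,f_max_iter Relative-change tolerance and iteration cap for
#'   the multiplicative F updates.
#' @param outer_tol,outer_max_iter Same, for the outer alternation.
#' @param h_update Whether the F subproblem sees the binarised cluster
#'   indicator (\code{"binary"}, default) or the continuous propagation
#'   result (\code{"continuous"}).
#' @param seed Base RNG seed; restart r uses \code{seed + r - 1}.
#' @param verbose Emit timestamped progress messages.
#' @return A list of class \code{lpfs_control}.
#' @export
lpfs_control <- function(mu = 0.2, beta = 0.2, delta = "auto", s = NULL,
                         inner_rounds = 5L, removal_size = 1000L,
                         repetitions = 100L, consensus_min_count = 51L,
                         f_tol = 1e-4, f_max_iter = 500L,
                         outer_tol = 1e-4, outer_max_iter = 50L,
                         h_update = c("binary", "continuous"),
                         seed = 1L, verbose = FALSE) {
  h_update <- match.arg(h_update)
  stopifnot(mu > 0, beta >= 0,
            f_tol > 0, outer_tol > 0,
            f_max_iter >= 1, outer_max_iter >= 1,
            inner_rounds >= 1, removal_size >= 0,
            repetitions >= 1, consensus_min_count >= 1)
  if (!identical(delta, "auto")) {
    delta <- as.numeric(delta)
    if (!is.finite(delta) || delta <= 0) stop("delta must be positive or 'auto'")
  }
  if (!is.null(s) && s < 1) stop("s must be >= 1 (or NULL for all genes)")
  structure(list(mu = mu, beta = beta, delta = delta, s = s,
                 inner_rounds = as.integer(inner_rounds),
                 removal_size = as.integer(removal_size),
                 repetitions = as.integer(repetitions),
                 consensus_min_count = as.integer(consensus_min_count),
                 f_tol = f_tol, f_max_iter = as.integer(f_max_iter),
                 outer_tol = outer_tol,
                 outer_max_iter = as.integer(outer_max_iter),
                 h_update = h_update, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "lpfs_control")
}

#' Read control parameters from a YAML file
#'
#' Field names mirror [lpfs_control()]; unknown keys are an error so typos
#' do not silently fall back to defaults.  Values given in \code{...}
#' (e.g. CLI flags) override file values.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file is read.
#' @return An \code{lpfs_control} object.
#' @export
read_lpfs_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(lpfs_control))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(lpfs_control, vals)
}

#' @export
print.lpfs_control <- function(x, ...) {
  cat("LPFS control parameters:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}
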