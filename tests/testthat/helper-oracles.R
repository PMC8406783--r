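# Independent brute-force oracles used to check the package's
# implementations.  Everything here is deliberately naive (explicit
# loops, explicit enumeration) and shares no code with R/.

# Joint objective, term by term, as an explicit double loop over pairs.
brute_objective <- function(x, w, h, y, fmat, mu, beta) {
  n <- nrow(h)
  d <- rowSums(w)
  smooth <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      diff <- h[i, ] / sqrt(d[i]) - h[j, ] / sqrt(d[j])
      smooth <- smooth + w[i, j] * sum(diff^2)
    }
  }
  anchor <- 0
  for (i in seq_len(n)) anchor <- anchor + sum((h[i, ] - y[i, ])^2)
  fit <- sum((x %*% fmat - h)^2)
  l21 <- 0
  for (j in seq_len(ncol(fmat))) l21 <- l21 + sqrt(sum(fmat[, j]^2))
  smooth + mu * anchor + fit + beta * l21
}

# The quadratic the closed-form propagation step minimises, written via
# the pairwise smoothness sum:
#   (1/2) sum_ij w_ij ||H_i/sqrt(d_i) - H_j/sqrt(d_j)||^2 - ||H||_F^2
#     + mu ||H - Y||_F^2 + ||XF - H||_F^2
# (positive definite Hessian 2((1+mu)I - Z) for mu > 0).
brute_h_objective <- function(hvec, w, y, xf, mu) {
  n <- nrow(y)
  h <- matrix(hvec, n, ncol(y))
  d <- rowSums(w)
  smooth <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      diff <- h[i, ] / sqrt(d[i]) - h[j, ] / sqrt(d[j])
      smooth <- smooth + w[i, j] * sum(diff^2)
    }
  }
  smooth / 2 - sum(h^2) + mu * sum((h - y)^2) + sum((xf - h)^2)
}

# Projected-gradient non-negative least squares, one column at a time:
# min ||X f - h||^2 s.t. f >= 0.  Convergence is judged on blocks of
# iterations because single projected-gradient steps shrink long before
# the iterate reaches the optimum.
pg_nnls <- function(x, h, max_blocks = 2000, block = 500, tol = 1e-10) {
  xtx <- crossprod(x)
  step <- 1 / (2 * max(abs(eigen(xtx, symmetric = TRUE,
                                 only.values = TRUE)$values)))
  f <- matrix(0, ncol(x), ncol(h))
  for (j in seq_len(ncol(h))) {
    fj <- rep(0, ncol(x))
    xth <- crossprod(x, h[, j])
    obj_old <- Inf
    for (b in seq_len(max_blocks)) {
      for (it in seq_len(block)) {
        fj <- pmax(fj - step * 2 * (xtx %*% fj - xth), 0)
      }
      obj <- sum((x %*% fj - h[, j])^2)
      if (abs(obj_old - obj) <= tol * max(obj_old, 1e-12)) break
      obj_old <- obj
    }
    f[, j] <- fj
  }
  f
}

# Rank product by explicit counting: descending rank with average ties.
brute_rank_product <- function(fmat) {
  m <- nrow(fmat)
  c <- ncol(fmat)
  rp <- numeric(m)
  for (i in seq_len(m)) {
    prod_rank <- 1
    for (j in seq_len(c)) {
      greater <- sum(fmat[, j] > fmat[i, j])
      ties <- sum(fmat[, j] == fmat[i, j])
      prod_rank <- prod_rank * (greater + (ties + 1) / 2)
    }
    rp[i] <- prod_rank^(1 / c)
  }
  rp
}

# Metric oracles ------------------------------------------------------

brute_hamming <- function(pred, truth, n_categories) {
  total <- 0
  for (i in seq_along(pred)) {
    for (j in seq_len(n_categories)) {
      total <- total + abs((pred[i] == j) - (truth[i] == j))
    }
  }
  total / (length(pred) * n_categories)
}

brute_one_error <- function(scores, truth) {
  errs <- 0
  for (i in seq_len(nrow(scores))) {
    best <- 1
    for (j in seq_len(ncol(scores))) if (scores[i, j] > scores[i, best]) best <- j
    if (best != truth[i]) errs <- errs + 1
  }
  errs / nrow(scores)
}

brute_coverage <- function(scores, truth) {
  total <- 0
  for (i in seq_len(nrow(scores))) {
    rank <- 1
    for (j in seq_len(ncol(scores))) {
      if (scores[i, j] > scores[i, truth[i]]) rank <- rank + 1
      else if (scores[i, j] == scores[i, truth[i]] && j < truth[i])
        rank <- rank + 1
    }
    total <- total + (rank - 1)
  }
  total / nrow(scores)
}

brute_auc <- function(scores, truth) {
  pos <- which(truth == 1)
  neg <- which(truth == 0)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      if (scores[p] > scores[q]) total <- total + 1
      else if (scores[p] == scores[q]) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

brute_aupr <- function(scores, truth) {
  thr <- sort(unique(scores), decreasing = TRUE)
  p_total <- sum(truth == 1)
  area <- 0
  recall_prev <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(called & truth == 1)
    precision <- tp / sum(called)
    recall <- tp / p_total
    area <- area + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  area
}

brute_welch_t <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  if (ma == mb) return(0)
  abs(ma - mb) / sqrt(var(a) / length(a) + var(b) / length(b))
}

# Small non-negative random matrix with ids, for quick cases.
random_expression <- function(n, m, seed) {
  set.seed(seed)
  x <- matrix(runif(n * m, 0.1, 5), n, m,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("g", seq_len(m))))
  x
}
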