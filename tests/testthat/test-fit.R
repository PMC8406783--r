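make_instance <- function(n, m, c, seed) {
  x <- random_expression(n, m, seed)
  g <- sample_graph(x, delta = suggest_delta(x))
  lab <- rep_len(seq_len(c), n)
  y <- label_matrix(lab, c)
  rownames(y) <- rownames(x)
  list(x = x, g = g, y = y, lab = lab, c = c)
}

test_that("joint objective matches the brute-force term-by-term sum", {
  for (seed in 1:4) {
    inst <- make_instance(6, 5, 2, seed + 50)
    set.seed(seed)
    h <- matrix(runif(6 * 2), 6, 2)
    fmat <- matrix(runif(5 * 2), 5, 2)
    expect_equal(
      lpfs_objective(inst$x, inst$g, h, inst$y, fmat, mu = 0.3, beta = 0.4),
      brute_objective(inst$x, inst$g$w, h, inst$y, fmat, 0.3, 0.4),
      tolerance = 1e-10)
  }
})

test_that("joint objective vanishes on the all-zero configuration and the smoothness null space", {
  inst <- make_instance(5, 4, 2, 61)
  zero_h <- matrix(0, 5, 2)
  zero_f <- matrix(0, 4, 2)
  expect_equal(lpfs_objective(inst$x, inst$g, zero_h, zero_h, zero_f,
                              mu = 0.2, beta = 0.2), 0)
  # rows proportional to sqrt(d) have identical normalised rows: first term 0
  h <- outer(sqrt(inst$g$degrees), c(1, 2))
  obj <- lpfs_objective(inst$x, inst$g, h, h, zero_f, mu = 0.2, beta = 0)
  smooth <- obj - sum((inst$x %*% zero_f - h)^2)
  expect_equal(smooth, 0, tolerance = 1e-8)
})

test_that("multiplicative F update: fixed point, zero absorption, non-negativity", {
  set.seed(71)
  x <- random_expression(6, 4, 71)
  h <- matrix(runif(12), 6, 2)
  f <- matrix(runif(8), 4, 2)
  f[2, 1] <- 0
  f2 <- update_f(f, x, h, beta = 0.2)
  expect_true(all(f2 >= 0))
  expect_equal(unname(f2[2, 1]), 0)  # multiplicative zero stays zero

  # a KKT point is (numerically) stationary: construct H = X F0 so the
  # beta = 0 residual vanishes at F0 > 0
  f0 <- matrix(runif(8, 0.5, 1), 4, 2)
  h0 <- x %*% f0
  f_next <- update_f(f0, x, h0, beta = 0)
  expect_equal(f_next, f0, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(update_f(-f0, x, h0, beta = 0), "non-negative")
})

test_that("F-subproblem objective never increases along multiplicative updates", {
  set.seed(72)
  for (case in 1:10) {
    x <- random_expression(6, 4, 72 + case)
    h <- matrix(runif(12), 6, 2)
    beta <- runif(1, 0, 0.5)
    f <- matrix(runif(8), 4, 2)
    obj <- fs_objective(f, x, h, beta)
    for (it in 1:50) {
      f <- update_f(f, x, h, beta)
      obj_new <- fs_objective(f, x, h, beta)
      expect_lte(obj_new, obj * (1 + 1e-10) + 1e-12)
      obj <- obj_new
    }
  }
})

test_that("solve_f: seeded determinism and decay toward zero for a zero target", {
  x <- random_expression(8, 3, 81)
  h <- matrix(0, 8, 2)
  res <- suppressWarnings(solve_f(x, h, beta = 0.2, tol = 1e-8,
                                  max_iter = 200, seed = 3))
  # objective beta * ||F||_{2,1} decreases toward 0
  expect_lt(tail(res$objective, 1), res$objective[1])
  expect_true(all(res$f >= 0))

  h2 <- matrix(runif(16), 8, 2)
  a <- solve_f(x, h2, beta = 0.1, seed = 7)
  b <- solve_f(x, h2, beta = 0.1, seed = 7)
  expect_identical(a$f, b$f)
  c_ <- solve_f(x, h2, beta = 0.1, seed = 8, tol = 1e-10, max_iter = 5000)
  d_ <- solve_f(x, h2, beta = 0.1, seed = 9, tol = 1e-10, max_iter = 5000)
  expect_equal(tail(c_$objective, 1), tail(d_$objective, 1),
               tolerance = 1e-3)
})

test_that("with beta = 0 solve_f matches a projected-gradient NNLS oracle", {
  set.seed(91)
  x <- random_expression(8, 3, 91)
  h <- matrix(runif(8 * 3), 8, 3)
  res <- solve_f(x, h, beta = 0, tol = 1e-12, max_iter = 20000, seed = 1)
  f_oracle <- pg_nnls(x, h)
  expect_equal(sum((x %*% res$f - h)^2), sum((x %*% f_oracle - h)^2),
               tolerance = 1e-4)
})

test_that("closed-form propagation satisfies its linear system and limits", {
  for (seed in 1:5) {
    inst <- make_instance(8, 6, 3, 100 + seed)
    set.seed(seed)
    fmat <- matrix(runif(6 * 3), 6, 3)
    pr <- solve_h(inst$g, inst$y, inst$x, fmat, mu = 0.2)
    lhs <- ((1 + 0.2) * diag(8) - inst$g$z) %*% pr$h_star
    rhs <- 0.2 * inst$y + inst$x %*% fmat
    expect_lt(norm(lhs - rhs, "F"), 1e-8 * norm(rhs, "F"))
    expect_equal(rowSums(pr$h_bin), rep(1, 8), ignore_attr = TRUE)
    expect_equal(pr$labels, max.col(pr$h_star, ties.method = "first"),
                 ignore_attr = TRUE)
  }

  # anchor term dominates for huge mu: labels reproduce Y
  inst <- make_instance(10, 5, 2, 111)
  pr <- solve_h(inst$g, inst$y, inst$x, matrix(0, 5, 2), mu = 1e6)
  expect_equal(unname(pr$labels), inst$lab)
})

test_that("propagation in a disconnected graph spreads each block's label", {
  # two complete blocks {1,2,3} and {4,5,6}, one labeled sample per block
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 0.8; w[4:6, 4:6] <- 0.6
  diag(w) <- 0
  g <- normalize_graph(w)
  y <- matrix(0, 6, 2); y[1, 1] <- 1; y[4, 2] <- 1
  x <- random_expression(6, 4, 121)
  pr <- solve_h(g, y, x, matrix(0, 4, 2), mu = 0.2)
  expect_equal(unname(pr$labels), c(1, 1, 1, 2, 2, 2))
})

test_that("closed form agrees with a generic numerical minimizer of the propagation quadratic", {
  for (seed in 1:3) {
    inst <- make_instance(5, 4, 2, 130 + seed)
    set.seed(seed)
    fmat <- matrix(runif(8), 4, 2)
    xf <- inst$x %*% fmat
    pr <- solve_h(inst$g, inst$y, inst$x, fmat, mu = 0.2)
    opt <- optim(runif(10), brute_h_objective, w = inst$g$w, y = inst$y,
                 xf = xf, mu = 0.2, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    obj_closed <- brute_h_objective(as.vector(pr$h_star), inst$g$w,
                                    inst$y, xf, 0.2)
    expect_equal(obj_closed, opt$value, tolerance = 1e-4)
    expect_lte(obj_closed, opt$value + 1e-8)
  }
})

test_that("permuting sample order permutes the propagation result identically", {
  inst <- make_instance(7, 5, 2, 141)
  fmat <- matrix(runif(10), 5, 2)
  pr <- solve_h(inst$g, inst$y, inst$x, fmat, mu = 0.2)
  perm <- c(3, 1, 7, 2, 6, 5, 4)
  gp <- normalize_graph(inst$g$w[perm, perm])
  prp <- solve_h(gp, inst$y[perm, ], inst$x[perm, ], fmat, mu = 0.2)
  expect_equal(prp$h_star, pr$h_star[perm, ], tolerance = 1e-10)
})

test_that("full fit recovers strongly separated synthetic categories", {
  sim <- simulate_expression(n_per_category = 8, n_categories = 3,
                             n_genes = 120, markers_per_category = 8,
                             effect = 3, seed = 7)
  fit <- lpfs(sim$expression, sim$truth$labels)
  expect_gte(mclust::adjustedRandIndex(fit$labels, sim$truth$labels), 0.9)
  expect_true(all(coef(fit) >= 0))
  # each round's F-subproblem trace is non-increasing
  for (tr in fit$trace$f_objective)
    expect_lte(max(diff(tr) / pmax(abs(tr[-length(tr)]), 1e-12)), 1e-10)
  # seeded fits are bit-identical
  fit2 <- lpfs(sim$expression, sim$truth$labels)
  expect_identical(coef(fit), coef(fit2))
  # huge anchor weight reproduces the input labels exactly
  fit_mu <- lpfs(sim$expression, sim$truth$labels, mu = 1e6)
  expect_equal(unname(fit_mu$labels), unname(sim$truth$labels))
})

test_that("fit methods expose coefficients, predictions and summaries", {
  sim <- simulate_expression(n_per_category = 5, n_categories = 2,
                             n_genes = 50, markers_per_category = 5,
                             effect = 3, seed = 9)
  fit <- lpfs(sim$expression, sim$truth$labels)
  expect_identical(coef(fit), fit$F)
  expect_identical(predict(fit), fit$labels)
  expect_equal(dim(predict(fit, type = "scores")), c(10L, 2L))
  newx <- sim$expression[1:3, ]
  expect_equal(unname(predict(fit, newdata = newx)),
               unname(fit$labels[1:3]))
  s <- summary(fit)
  expect_s3_class(s, "summary.lpfs")
  expect_output(print(s), "top genes")
  expect_output(print(fit), "converged|iteration cap")
})

test_that("semi-supervised fit works from partial labels", {
  sim <- simulate_expression(n_per_category = 8, n_categories = 2,
                             n_genes = 80, markers_per_category = 8,
                             effect = 3, seed = 17)
  partial <- make_partial_labels(sim$truth, labeled_fraction = 0.5, seed = 2)
  expect_equal(sum(!is.na(partial)), 8)
  fit <- lpfs(sim$expression, partial)
  expect_gte(mclust::adjustedRandIndex(fit$labels, sim$truth$labels), 0.9)
})
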