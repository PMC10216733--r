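test_that("soft thresholding matches its closed form and a 1-D grid search", {
  expect_equal(soft_threshold(c(2, -0.5, 0.1), 0.5), c(1.5, 0, 0))
  set.seed(1)
  z <- rnorm(10)
  expect_equal(soft_threshold(z, 0), z)
  # prox property: minimizes 0.5 (x - z)^2 + lam |x| per coordinate
  lam <- 0.3
  grid <- seq(-4, 4, by = 1e-4)
  for (zi in z[1:4]) {
    brute <- grid[which.min(0.5 * (grid - zi)^2 + lam * abs(grid))]
    expect_equal(soft_threshold(zi, lam), brute, tolerance = 1e-3)
  }
})

test_that("the objective matches an explicit loop recomputation", {
  set.seed(2)
  n <- 12; q <- 5; p <- 4; tt <- 3
  X <- matrix(rnorm(n * q), n, q)
  Ys <- lapply(1:tt, function(t) matrix(rnorm(n * p), n, p))
  u <- rnorm(q); V <- matrix(rnorm(p * tt), p, tt)
  hg <- build_knn_hypergraph(X, k = 3)
  L1 <- hypergraph_laplacian(hg)
  L2s <- lapply(Ys, function(y)
    hypergraph_laplacian(build_knn_hypergraph(y, k = 3)))
  cfg <- penalty_config(lam1 = 0.3, lam2 = 0.2, lamt = 0.4,
                        beta1 = 0.5, beta2 = 0.6)

  # independent term-by-term recomputation with explicit loops
  corr <- 0
  for (t in 1:tt) for (i in 1:n)
    corr <- corr + sum(X[i, ] * u) * sum(Ys[[t]][i, ] * V[, t])
  l1 <- sum(abs(u))
  l21 <- 0
  for (j in 1:p) l21 <- l21 + sqrt(sum(V[j, ]^2))
  fus <- 0
  for (t in 1:(tt - 1)) fus <- fus + sqrt(sum((V[, t + 1] - V[, t])^2))
  xu <- as.numeric(X %*% u)
  hg1 <- sum(xu * (L1 %*% xu))
  hg2 <- 0
  for (t in 1:tt) {
    yv <- as.numeric(Ys[[t]] %*% V[, t])
    hg2 <- hg2 + sum(yv * (L2s[[t]] %*% yv))
  }
  expected <- -corr + cfg$lam1 * l1 + cfg$lam2 * l21 + cfg$lamt * fus +
    cfg$beta1 * hg1 + cfg$beta2 * hg2
  expect_equal(scca_objective(u, V, X, Ys, L1, L2s, cfg), expected,
               tolerance = 1e-12)

  # degenerate reductions
  expect_equal(scca_objective(numeric(q), matrix(0, p, tt), X, Ys,
                              L1, L2s, cfg), 0)
  cfg0 <- penalty_config()
  expect_equal(scca_objective(u, V[, 1, drop = FALSE], X, Ys[1], cfg = cfg0),
               -sum((X %*% u) * (Ys[[1]] %*% V[, 1])))
})

test_that("the u block matches closed forms and a 2-D grid oracle", {
  # orthonormal design: penalty-free minimizer of the Lagrangian block is c
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  A <- diag(6)                       # X'X for orthonormal X
  c_vec <- rnorm(6)
  u <- update_u(rnorm(6), A, c_vec, lam1 = 0, max_iter = 500, tol = 1e-12)
  expect_equal(u, c_vec, tolerance = 1e-6)
  # lasso null condition
  u0 <- update_u(rnorm(6), A, c_vec, lam1 = max(abs(c_vec)) * 1.01,
                 max_iter = 500, tol = 1e-12)
  expect_true(all(u0 == 0))

  # p = 2 toy against a dense grid search (step 1e-3)
  A2 <- matrix(c(2, 0.5, 0.5, 1.5), 2, 2)
  c2 <- c(1, -0.7); lam <- 0.25
  u2 <- update_u(c(0, 0), A2, c2, lam, max_iter = 2000, tol = 1e-12)
  g <- seq(-1.5, 1.5, by = 1e-3)
  gr <- expand.grid(x = g, y = g)
  f <- 0.5 * (A2[1, 1] * gr$x^2 + 2 * A2[1, 2] * gr$x * gr$y +
                A2[2, 2] * gr$y^2) - c2[1] * gr$x - c2[2] * gr$y +
    lam * (abs(gr$x) + abs(gr$y))
  best <- gr[which.min(f), ]
  expect_equal(u2, c(best$x, best$y), tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("the V block fuses, nulls and matches a derivative-free oracle", {
  set.seed(4)
  n <- 30; p <- 4; tt <- 3
  Ys <- lapply(1:tt, function(t) scale(matrix(rnorm(n * p), n, p)))
  As <- lapply(Ys, crossprod)
  Bs <- lapply(1:tt, function(t) rnorm(p))

  # fusion limit: huge temporal penalty equalizes the columns
  cfg_fuse <- penalty_config(lamt = 1e6, inner_max_iter = 2000,
                             inner_tol = 1e-12)
  Vf <- update_V(matrix(rnorm(p * tt), p, tt), As, Bs, cfg_fuse)
  expect_lt(max(abs(Vf - Vf[, 1])), 1e-4)

  # group-lasso null: penalty above the largest row norm of the linear term
  Bmat <- do.call(cbind, Bs)
  lam2_null <- max(sqrt(rowSums(Bmat^2))) * 1.01
  cfg_null <- penalty_config(lam2 = lam2_null, inner_max_iter = 2000,
                             inner_tol = 1e-12)
  V0 <- update_V(matrix(rnorm(p * tt), p, tt) * 0.1, As, Bs, cfg_null)
  expect_lt(max(abs(V0)), 1e-6)

  # q = 2, T = 2 toy against a multi-restart derivative-free minimizer
  p2 <- 2; t2 <- 2
  As2 <- list(matrix(c(2, 0.3, 0.3, 1), 2, 2),
              matrix(c(1.5, -0.2, -0.2, 2.5), 2, 2))
  Bs2 <- list(c(0.8, -0.5), c(0.3, 0.9))
  cfg2 <- penalty_config(lam2 = 0.2, lamt = 0.3, inner_max_iter = 5000,
                         inner_tol = 1e-14)
  V2 <- update_V(matrix(0.1, p2, t2), As2, Bs2, cfg2)
  fobj <- function(v) {
    V <- matrix(v, p2, t2)
    s <- 0
    for (t in 1:t2) s <- s + 0.5 * sum(V[, t] * (As2[[t]] %*% V[, t])) -
        sum(V[, t] * Bs2[[t]])
    s + cfg2$lam2 * sum(sqrt(rowSums(V^2))) +
      cfg2$lamt * sqrt(sum((V[, 2] - V[, 1])^2))
  }
  set.seed(5)
  oracle <- min(sapply(1:20, function(i)
    optim(rnorm(4, sd = 0.5), fobj, method = "Nelder-Mead",
          control = list(maxit = 5000, reltol = 1e-12))$value))
  expect_lte(fobj(as.numeric(V2)), oracle + 1e-4)
})

test_that("the penalty-free solver reproduces classical CCA", {
  cv <- make_coupled_views(n = 50, p = 5, q = 4, noise = 1, seed = 6)
  cfg <- penalty_config(max_iter = 300, tol = 1e-12)
  m <- fit_tgscca(cv$X, cv$Ys, cfg)
  Xs <- standardize_columns(cv$X); Ys <- standardize_columns(cv$Ys[[1]])
  rho <- cancor(Xs, Ys)$cor[1]
  expect_lt(abs(ccc(Xs, m$u, Ys, m$V[, 1]) - rho), 1e-4)
  expect_equal(sqrt(sum((Xs %*% m$u)^2)), 1, tolerance = 1e-8)
})

test_that("exactly orthogonal views with an L1 penalty give a zero gene vector", {
  set.seed(7)
  n <- 200; q <- 6; p <- 5
  X <- scale(matrix(rnorm(n * q), n, q), scale = FALSE)
  Yraw <- matrix(rnorm(n * p), n, p)
  # project X's column space (and the constant) out of Y
  P <- diag(n) - cbind(1, X) %*% solve(crossprod(cbind(1, X)),
                                       t(cbind(1, X)))
  Y <- P %*% Yraw
  m <- fit_tgscca(X, list(Y), penalty_config(lam1 = 0.1))
  expect_true(all(m$u == 0))
  expect_true(m$diagnostics$all_zero ||
                sqrt(sum((standardize_columns(X) %*% m$u)^2)) == 0)
})

test_that("the objective trace is monotone on random penalized instances", {
  for (s in 1:6) {
    set.seed(s)
    cv <- make_coupled_views(n = 40, p = 6, q = 8, n_time = 3,
                             noise = 1, seed = s)
    L1 <- hypergraph_laplacian(build_knn_hypergraph(cv$X, k = 4))
    L2s <- lapply(cv$Ys, function(y)
      hypergraph_laplacian(build_knn_hypergraph(y, k = 4)))
    pen <- 10^runif(5, -3, 0)
    cfg <- penalty_config(lam1 = pen[1], lam2 = pen[2], lamt = pen[3],
                          beta1 = pen[4], beta2 = pen[5])
    m <- fit_hbtgscca(cv$X, cv$Ys, L1, L2s, cfg)
    expect_true(all(diff(m$objective_trace) <= 1e-10))
    # scale-constraint feasibility at return
    Xs <- standardize_columns(cv$X)
    expect_lte(sqrt(sum((Xs %*% m$u)^2)), 1 + 1e-8)
    for (t in 1:3) {
      Yt <- standardize_columns(cv$Ys[[t]])
      expect_lte(sqrt(sum((Yt %*% m$V[, t])^2)), 1 + 1e-8)
    }
  }
})

test_that("TGSCCA is exactly the zero-beta special case and collapses over identical views", {
  cv <- make_coupled_views(n = 30, p = 4, q = 5, n_time = 2, seed = 8)
  cfg <- penalty_config(lam1 = 0.05, lam2 = 0.05, lamt = 0.05)
  a <- fit_tgscca(cv$X, cv$Ys, cfg)
  b <- fit_hbtgscca(cv$X, cv$Ys, L1 = NULL, L2s = NULL, cfg)
  expect_identical(a$u, b$u)
  expect_identical(a$V, b$V)

  # identical phenotype views at T = 4 reduce to the T = 1 solution
  cv1 <- make_coupled_views(n = 40, p = 5, q = 6, n_time = 1, seed = 9)
  cfg0 <- penalty_config(max_iter = 300, tol = 1e-12)
  m1 <- fit_tgscca(cv1$X, cv1$Ys, cfg0)
  m4 <- fit_tgscca(cv1$X, rep(cv1$Ys, 4), cfg0)
  expect_equal(m4$u, m1$u, tolerance = 1e-6)
  expect_equal(max(abs(m4$V - m4$V[, 1])), 0, tolerance = 1e-6)
})

test_that("increasing the hypergraph weight smooths the projected gene scores", {
  cv <- make_coupled_views(n = 40, p = 6, q = 8, n_time = 2, seed = 10)
  L1 <- hypergraph_laplacian(build_knn_hypergraph(cv$X, k = 4))
  L2s <- lapply(cv$Ys, function(y)
    hypergraph_laplacian(build_knn_hypergraph(y, k = 4)))
  Xs <- standardize_columns(cv$X)
  smoothness <- sapply(c(0, 0.1, 10), function(b1) {
    cfg <- penalty_config(lam1 = 0.01, lam2 = 0.01, beta1 = b1,
                          beta2 = 0.01, max_iter = 200, tol = 1e-10)
    m <- fit_hbtgscca(cv$X, cv$Ys, L1, L2s, cfg)
    xu <- Xs %*% m$u
    as.numeric(t(xu) %*% L1 %*% xu)
  })
  expect_true(all(diff(smoothness) <= 1e-8))
})
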