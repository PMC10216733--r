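# Shared fixtures: small planted-correlation two-view datasets.

# one latent factor drives both views; returns plain matrices
make_coupled_views <- function(n = 50, p = 5, q = 4, n_time = 1,
                               strength = 1, noise = 1, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  X <- z %*% t(runif(q, 0.5, 1)) * strength +
    matrix(rnorm(n * q, 0, noise), n, q)
  Ys <- lapply(seq_len(n_time), function(t)
    z %*% t(runif(p, 0.5, 1)) * strength +
      matrix(rnorm(n * p, 0, noise), n, p))
  list(X = X, Ys = Ys, z = z)
}

# random hypergraph via KNN on random points
random_knn_hypergraph <- function(n, k, d = 3, seed = 1,
                                  weighting = "uniform") {
  set.seed(seed)
  build_knn_hypergraph(matrix(rnorm(n * d), n, d), k = k,
                       weighting = weighting)
}
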