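## KNN hypergraphs over samples and the normalized hypergraph Laplacian
## Lh = I - Dv^{-1/2} H W De^{-1} H' Dv^{-1/2}.

new_hypergraph <- function(incidence, edge_weights) {
  incidence <- as.matrix(incidence)
  if (!all(incidence %in% c(0, 1)))
    stop("incidence entries must be 0/1", call. = FALSE)
  if (any(edge_weights <= 0))
    stop("edge weights must be positive", call. = FALSE)
  if (length(edge_weights) != ncol(incidence))
    stop("one weight per hyperedge required", call. = FALSE)
  edge_deg <- colSums(incidence)
  if (any(edge_deg == 0)) stop("empty hyperedge", call. = FALSE)
  structure(list(n_vertices = nrow(incidence),
                 incidence = incidence,
                 edge_weights = as.numeric(edge_weights),
                 vertex_degrees = vertex_degrees(incidence, edge_weights),
                 edge_degrees = edge_deg),
            class = "hypergraph")
}

#' Weighted vertex degrees of a hypergraph
#'
#' `d(v) = sum_e w(e) H(v, e)`.
#'
#' @param incidence N x Ne binary incidence matrix H.
#' @param edge_weights positive hyperedge weights w.
#' @return numeric vector of length N.
#' @export
vertex_degrees <- function(incidence, edge_weights) {
  incidence <- as.matrix(incidence)
  if (length(edge_weights) != ncol(incidence))
    stop("`edge_weights` must have one entry per hyperedge", call. = FALSE)
  if (any(edge_weights < 0))
    stop("edge weights must be non-negative", call. = FALSE)
  as.numeric(incidence %*% edge_weights)
}

#' Build a KNN hypergraph over samples
#'
#' One hyperedge per sample (centroid), containing that sample and its k
#' nearest neighbors, so every hyperedge has degree k + 1 and the incidence
#' matrix is N x N. Distance ties are broken by ascending sample index.
#'
#' @param data samples x features matrix.
#' @param k number of neighbors, `1 <= k <= N - 1`.
#' @param metric distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param weighting `"uniform"` gives every hyperedge weight 1;
#'   `"heat"` weights edge e by
#'   `sum_{v in e} exp(-dist(v, centroid)^2 / sigma^2)` with `sigma` the
#'   mean pairwise distance.
#' @return an object of class `hypergraph`.
#' @export
build_knn_hypergraph <- function(data, k = 5L,
                                 metric = "euclidean",
                                 weighting = c("uniform", "heat")) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("`data` must not contain NAs", call. = FALSE)
  n <- nrow(data)
  k <- check_count(k, "k")
  if (k >= n)
    stop(sprintf("`k` (%d) must be smaller than the number of samples (%d)",
                 k, n), call. = FALSE)
  weighting <- match.arg(weighting)
  d <- as.matrix(stats::dist(data, method = metric))
  incidence <- matrix(0, n, n)
  for (v in seq_len(n)) {
    ## order() on (distance, index) => deterministic tie-break by index
    nb <- order(d[, v], seq_len(n))
    nb <- setdiff(nb, v)[seq_len(k)]
    incidence[c(v, nb), v] <- 1
  }
  if (weighting == "uniform") {
    w <- rep(1, n)
  } else {
    sig <- mean(d[upper.tri(d)])
    if (!is.finite(sig) || sig <= 0) sig <- 1
    w <- vapply(seq_len(n), function(e) {
      members <- which(incidence[, e] == 1)
      sum(exp(-d[members, e]^2 / sig^2))
    }, numeric(1))
  }
  dimnames(incidence) <- list(rownames(data), rownames(data))
  new_hypergraph(incidence, w)
}

#' Normalized hypergraph Laplacian
#'
#' `Lh = I - Dv^{-1/2} H W De^{-1} H' Dv^{-1/2}` with Dv/De the vertex and
#' hyperedge degree diagonals and W the diagonal of hyperedge weights. The
#' result is symmetric and positive semidefinite, with
#' `Lh %*% sqrt(d(v)) = 0`.
#'
#' @param hg a `hypergraph`.
#' @return N x N numeric matrix.
#' @export
hypergraph_laplacian <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  dv <- hg$vertex_degrees
  if (any(dv <= 0)) {
    bad <- which(dv <= 0)
    stop(sprintf("isolated vertex (degree 0) at index %s",
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  dv_isqrt <- 1 / sqrt(dv)
  hw <- sweep(hg$incidence, 2L, hg$edge_weights / hg$edge_degrees, `*`)
  theta <- (dv_isqrt * (hw %*% t(hg$incidence))) *
    rep(dv_isqrt, each = hg$n_vertices)
  lh <- diag(hg$n_vertices) - theta
  (lh + t(lh)) / 2
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("hypergraph: %d vertices, %d hyperedges, edge degree %s\n",
              x$n_vertices, ncol(x$incidence),
              paste(range(x$edge_degrees), collapse = "-")))
  invisible(x)
}
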