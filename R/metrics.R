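## Evaluation metrics: canonical correlation, R-squared, feature ranking,
## support recovery, clustering indices.

#' Canonical correlation coefficient
#'
#' Pearson correlation between the projected scores `X u` and `Yt vt`.
#'
#' @param X n x q view.
#' @param u weight vector for X.
#' @param Yt n x p view.
#' @param vt weight vector for Yt.
#' @return scalar in \[-1, 1\].
#' @export
ccc <- function(X, u, Yt, vt) {
  xu <- as.numeric(as.matrix(X) %*% u)
  yv <- as.numeric(as.matrix(Yt) %*% vt)
  if (stats::sd(xu) == 0 || stats::sd(yv) == 0)
    stop("undefined canonical correlation: zero-variance projection",
         call. = FALSE)
  stats::cor(xu, yv)
}

#' Per-time canonical correlations of a fitted model
#'
#' @param model a `canonical_model`.
#' @param X gene view.
#' @param Ys list of phenotype views (same feature order as at fit time).
#' @param standardize column-standardize the views first (matching the
#'   default preprocessing of the fitters).
#' @return list with `per_time` (length-T vector) and `mean`.
#' @export
ccc_scores <- function(model, X, Ys, standardize = TRUE) {
  Ys <- as_view_list(Ys)
  if (standardize) {
    X <- standardize_columns(X)
    Ys <- lapply(Ys, standardize_columns)
  }
  per_time <- vapply(seq_along(Ys), function(t)
    ccc(X, model$u, Ys[[t]], model$V[, t]), numeric(1))
  names(per_time) <- colnames(model$V)
  list(per_time = per_time, mean = mean(per_time))
}

#' R-squared with population (divisor-n) variance
#'
#' `1 - MSE / Var`, both moments computed with divisor n.
#'
#' @param y_true observed values (length >= 2, nonconstant).
#' @param y_pred predictions of the same length.
#' @return scalar (1 = perfect, 0 = mean predictor).
#' @export
r2_score <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  if (length(y_true) < 2L) stop("need at least 2 observations",
                                call. = FALSE)
  v <- mean((y_true - mean(y_true))^2)
  if (v == 0) stop("undefined R-squared: constant `y_true`", call. = FALSE)
  1 - mean((y_true - y_pred)^2) / v
}

#' Top-k features by absolute weight
#'
#' @param weights numeric weight vector.
#' @param names feature names (defaults to `names(weights)`).
#' @param k how many to return (`k <= length(weights)`).
#' @return data.frame with columns `feature` and `abs_weight`, sorted by
#'   non-increasing absolute weight; ties broken by feature name.
#' @export
top_k_features <- function(weights, names = NULL, k) {
  if (is.null(names)) names <- base::names(weights)
  if (is.null(names)) names <- sprintf("f%d", seq_along(weights))
  if (length(names) != length(weights))
    stop("`names` must match `weights` in length", call. = FALSE)
  k <- check_count(k, "k")
  if (k > length(weights))
    stop("`k` exceeds the number of features", call. = FALSE)
  ord <- order(-abs(weights), names)
  sel <- ord[seq_len(k)]
  data.frame(feature = names[sel], abs_weight = abs(weights)[sel],
             row.names = NULL)
}

#' Support recovery against a planted truth
#'
#' Supports are `|w| > zero_tol`. Precision of an empty estimated support
#' is 0 by convention; F1 is 0 when precision + recall is 0.
#'
#' @param estimated,truth equal-length weight (or logical mask) vectors.
#' @param zero_tol threshold below which a weight counts as zero.
#' @return list with `precision`, `recall`, `f1`.
#' @export
support_recovery <- function(estimated, truth, zero_tol = 1e-8) {
  if (length(estimated) != length(truth))
    stop("length mismatch", call. = FALSE)
  est <- if (is.logical(estimated)) estimated else abs(estimated) > zero_tol
  tru <- if (is.logical(truth)) truth else abs(truth) > zero_tol
  tp <- sum(est & tru)
  precision <- if (sum(est) == 0) 0 else tp / sum(est)
  recall <- if (sum(tru) == 0) 0 else tp / sum(tru)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

## pair-counting confusion over all sample pairs
pair_counts <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  c(tp = sum(same_a & same_b), fp = sum(!same_a & same_b),
    fn = sum(same_a & !same_b), tn = sum(!same_a & !same_b))
}

#' Adjusted Rand index (pair-counting form)
#'
#' @param labels_a,labels_b two labelings of the same samples.
#' @return scalar; 1 for identical partitions, ~0 for independent ones.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(0)
  (sum_ij - expected) / (maximum - expected)
}

#' Normalized mutual information (geometric normalization)
#'
#' `I(A; B) / sqrt(H(A) H(B))`, in \[0, 1\].
#'
#' @param labels_a,labels_b two labelings of the same samples.
#' @return scalar NMI.
#' @export
normalized_mutual_information <- function(labels_a, labels_b) {
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  pjk <- tab / n
  mi <- 0
  for (j in seq_along(pj)) for (k in seq_along(pk)) {
    if (pjk[j, k] > 0)
      mi <- mi + pjk[j, k] * log(pjk[j, k] / (pj[j] * pk[k]))
  }
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  ha <- ent(pj); hb <- ent(pk)
  if (ha == 0 || hb == 0) return(0)
  as.numeric(mi / sqrt(ha * hb))
}

#' Internal and external clustering indices
#'
#' Internal: mean silhouette width ("contour coefficient"),
#' Calinski-Harabasz, Davies-Bouldin. External (when `labels_true` given):
#' pairwise F-score / precision / recall, NMI, adjusted Rand index.
#'
#' @param data samples x features matrix.
#' @param labels_pred predicted cluster assignments (>= 2 clusters for the
#'   internal indices).
#' @param labels_true optional reference labels.
#' @return named list of index values.
#' @export
clustering_indices <- function(data, labels_pred, labels_true = NULL) {
  data <- as.matrix(data)
  labels_pred <- as.integer(factor(labels_pred))
  k <- length(unique(labels_pred))
  if (k < 2L)
    stop("undefined internal indices: a single cluster", call. = FALSE)
  n <- nrow(data)

  sil <- cluster::silhouette(labels_pred, stats::dist(data))
  out <- list(silhouette = mean(sil[, "sil_width"]))

  centers <- do.call(rbind, lapply(split(seq_len(n), labels_pred),
                                   function(ix)
                                     colMeans(data[ix, , drop = FALSE])))
  overall <- colMeans(data)
  sizes <- as.numeric(table(labels_pred))
  between <- sum(sizes * rowSums(sweep(centers, 2L, overall)^2))
  within_per <- vapply(seq_len(k), function(cl) {
    ix <- which(labels_pred == cl)
    sum(sweep(data[ix, , drop = FALSE], 2L, centers[cl, ])^2)
  }, numeric(1))
  within <- sum(within_per)
  out$calinski_harabasz <-
    if (within == 0) Inf else (between / (k - 1)) / (within / (n - k))

  s_i <- vapply(seq_len(k), function(cl) {
    ix <- which(labels_pred == cl)
    mean(sqrt(rowSums(sweep(data[ix, , drop = FALSE], 2L,
                            centers[cl, ])^2)))
  }, numeric(1))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      dij <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (dij == 0) Inf else (s_i[i] + s_i[j]) / dij
    }, numeric(1)))
  }, numeric(1)))
  out$davies_bouldin <- db

  if (!is.null(labels_true)) {
    pc <- pair_counts(labels_true, labels_pred)
    precision <- if (pc["tp"] + pc["fp"] == 0) 0 else
      unname(pc["tp"] / (pc["tp"] + pc["fp"]))
    recall <- if (pc["tp"] + pc["fn"] == 0) 0 else
      unname(pc["tp"] / (pc["tp"] + pc["fn"]))
    out$precision <- precision
    out$recall <- recall
    out$f_score <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    out$nmi <- normalized_mutual_information(labels_true, labels_pred)
    out$adjusted_rand <- adjusted_rand_index(labels_true, labels_pred)
  }
  out
}
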