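## Temporally constrained group-sparse CCA with hypergraph smoothness
## penalties, fit by alternating block proximal-gradient updates.
##
## Minimization objective (reported by `scca_objective`):
##   -sum_t u' X' Yt vt + lam1 ||u||_1 + lam2 ||V||_{2,1}
##   + lamt sum_{t<T} ||v_{t+1} - v_t||  + beta1 (Xu)' L1 (Xu)
##   + beta2 sum_t (Yt vt)' L2t (Yt vt),
## subject to score-scale constraints ||Xu|| <= 1, ||Yt vt|| <= 1. Block
## candidates are produced by proximal-gradient descent of the Lagrangian
## form (constraint quadratics 0.5*||Xu||^2, 0.5*||Yt vt||^2); the gene
## block is rescaled onto the unit-score sphere and a candidate is accepted
## only if the constraint-form objective does not increase, so the recorded
## trace is monotone by construction and the penalty-free alternation is
## exactly the classical alternating-regression CCA power iteration.

#' Elementwise soft-thresholding
#'
#' `sign(z) * pmax(|z| - lam, 0)`, the proximal operator of `lam * ||.||_1`.
#'
#' @param z numeric vector or matrix.
#' @param lam non-negative threshold.
#' @return object of the same shape as `z`.
#' @export
soft_threshold <- function(z, lam) {
  if (lam < 0) stop("`lam` must be non-negative", call. = FALSE)
  sign(z) * pmax(abs(z) - lam, 0)
}

#' Penalty and solver configuration for the canonical models
#'
#' @param lam1 L1 penalty on the gene weight vector u.
#' @param lam2 L2,1 (row-group) penalty on the phenotype weight matrix V.
#' @param lamt temporal fused penalty on consecutive columns of V.
#' @param beta1,beta2 hypergraph smoothness weights for the gene and
#'   phenotype projected scores.
#' @param max_iter outer alternation cap.
#' @param tol relative objective-change stopping tolerance.
#' @param inner_max_iter,inner_tol proximal-gradient inner-loop controls.
#' @param fused `"l2"` (group fused, default) or `"l1"` for the temporal
#'   difference penalty.
#' @param scale_metric quadratic used for the scale constraints in the
#'   block candidates. `"covariance"` (default) uses `X'X` / `Yt'Yt`, so
#'   the penalty-free fit is exactly classical CCA; `"identity"` uses the
#'   diagonal approximation `n I` of the standardized covariance (the
#'   PMA-style convention), under which the L1 block update thresholds
#'   marginal correlations — the better choice when the support of the
#'   weights is the quantity of interest and signal features are strongly
#'   inter-correlated.
#' @return an object of class `penalty_config`.
#' @export
penalty_config <- function(lam1 = 0, lam2 = 0, lamt = 0,
                           beta1 = 0, beta2 = 0,
                           max_iter = 100L, tol = 1e-5,
                           inner_max_iter = 200L, inner_tol = 1e-8,
                           fused = c("l2", "l1"),
                           scale_metric = c("covariance", "identity")) {
  structure(list(lam1 = check_nonneg(lam1, "lam1"),
                 lam2 = check_nonneg(lam2, "lam2"),
                 lamt = check_nonneg(lamt, "lamt"),
                 beta1 = check_nonneg(beta1, "beta1"),
                 beta2 = check_nonneg(beta2, "beta2"),
                 max_iter = check_count(max_iter, "max_iter"),
                 tol = check_nonneg(tol, "tol"),
                 inner_max_iter = check_count(inner_max_iter,
                                              "inner_max_iter"),
                 inner_tol = check_nonneg(inner_tol, "inner_tol"),
                 fused = match.arg(fused),
                 scale_metric = match.arg(scale_metric)),
            class = "penalty_config")
}

fused_term <- function(V, fused) {
  tt <- ncol(V)
  if (tt < 2L) return(0)
  d <- V[, -1L, drop = FALSE] - V[, -tt, drop = FALSE]
  if (fused == "l2") sum(sqrt(colSums(d^2))) else sum(abs(d))
}

#' Canonical-model objective (minimization form)
#'
#' Negated summed cross-view correlation plus the sparsity, temporal-fusion
#' and hypergraph-smoothness penalties. With `scale_penalty = TRUE` the
#' Lagrangian scale quadratics `0.5 ||Xu||^2 + 0.5 sum_t ||Yt vt||^2` that
#' the optimizer actually descends are added.
#'
#' @param u gene weight vector (length q).
#' @param V phenotype weight matrix (p x T).
#' @param X n x q gene view.
#' @param Ys list of T n x p phenotype views.
#' @param L1 optional n x n gene-view hypergraph Laplacian.
#' @param L2s optional list of T phenotype Laplacians (or a single matrix
#'   recycled over time).
#' @param cfg a [penalty_config()].
#' @param scale_penalty include the internal scale quadratics.
#' @return scalar objective value.
#' @export
scca_objective <- function(u, V, X, Ys, L1 = NULL, L2s = NULL,
                           cfg = penalty_config(), scale_penalty = FALSE) {
  Ys <- as_view_list(Ys)
  tt <- length(Ys)
  if (ncol(V) != tt) stop("V must have one column per time point",
                          call. = FALSE)
  if (length(u) != ncol(X)) stop("length(u) != ncol(X)", call. = FALSE)
  if (nrow(V) != ncol(Ys[[1L]])) stop("nrow(V) != ncol(Yt)", call. = FALSE)
  L2s <- recycle_laplacians(L2s, tt)
  xu <- as.numeric(X %*% u)
  val <- 0
  for (t in seq_len(tt)) {
    yv <- as.numeric(Ys[[t]] %*% V[, t])
    val <- val - sum(xu * yv)
    if (cfg$beta2 > 0 && !is.null(L2s[[t]]))
      val <- val + cfg$beta2 * sum(yv * (L2s[[t]] %*% yv))
    if (scale_penalty) val <- val + 0.5 * sum(yv^2)
  }
  if (cfg$beta1 > 0 && !is.null(L1))
    val <- val + cfg$beta1 * sum(xu * (L1 %*% xu))
  if (scale_penalty) val <- val + 0.5 * sum(xu^2)
  val + cfg$lam1 * sum(abs(u)) + cfg$lam2 * sum(sqrt(rowSums(V^2))) +
    cfg$lamt * fused_term(V, cfg$fused)
}

as_view_list <- function(Ys) {
  if (is.matrix(Ys)) list(Ys) else Ys
}

recycle_laplacians <- function(L2s, tt) {
  if (is.null(L2s)) return(vector("list", tt))
  if (is.matrix(L2s)) return(rep(list(L2s), tt))
  if (length(L2s) != tt)
    stop("need one phenotype Laplacian per time point", call. = FALSE)
  L2s
}

## ---- block updates ---------------------------------------------------

## ISTA with backtracking on f(u) = 0.5 u'Au - u'c + lam1 ||u||_1
#' Block update of the gene weight vector
#'
#' Proximal-gradient (soft-thresholding) descent of the u-block objective
#' with V held fixed; exposed mainly for inspection and testing.
#'
#' @param u starting value.
#' @param A q x q PSD matrix `X'X + 2 beta1 X'L1X` of the smooth quadratic.
#' @param c_vec linear term `sum_t X'Yt vt`.
#' @param lam1 L1 penalty.
#' @param max_iter,tol inner-loop controls.
#' @return updated u.
#' @export
update_u <- function(u, A, c_vec, lam1, max_iter = 200L, tol = 1e-8) {
  L <- max(1e-12, norm(A, "2"))
  s <- 1 / L
  fval <- function(u) 0.5 * sum(u * (A %*% u)) - sum(u * c_vec)
  cur_f <- fval(u)
  for (it in seq_len(max_iter)) {
    grad <- as.numeric(A %*% u) - c_vec
    if (any(!is.finite(grad)))
      stop("non-finite gradient in the u update", call. = FALSE)
    u_new <- soft_threshold(u - s * grad, s * lam1)
    step_ok <- {
      dv <- u_new - u
      fval(u_new) <= cur_f + sum(grad * dv) + sum(dv^2) / (2 * s)
    }
    if (!step_ok) { s <- s / 2; next }
    delta <- max(abs(u_new - u))
    u <- u_new; cur_f <- fval(u)
    if (delta < tol) break
  }
  u
}

## prox of lam2 * sum_j ||row_j|| (row-group soft threshold)
prox_rowgroup <- function(V, lam) {
  if (lam <= 0) return(V)
  nr <- sqrt(rowSums(V^2))
  shrink <- ifelse(nr > 0, pmax(0, 1 - lam / nr), 0)
  V * shrink
}

## prox of lam * sum_t ||v_{t+1} - v_t|| (chain group-fused penalty),
## computed exactly through its dual: projected gradient on
## min_{||u_t|| <= lam} 0.5 * ||Z - U D'||_F^2 with D the T x (T-1)
## difference operator; the prox is Z - U D'. For the "l1" variant the
## dual balls are entrywise intervals [-lam, lam].
prox_chain_fused <- function(V, lam, fused = "l2", max_iter = 200L,
                             tol = 1e-10) {
  tt <- ncol(V)
  if (lam <= 0 || tt < 2L) return(V)
  D <- matrix(0, tt, tt - 1L)
  for (t in seq_len(tt - 1L)) { D[t, t] <- -1; D[t + 1L, t] <- 1 }
  U <- matrix(0, nrow(V), tt - 1L)
  step <- 1 / 4                                 # ||D'D||_2 <= 4
  for (it in seq_len(max_iter)) {
    G <- (V - U %*% t(D)) %*% D
    U_new <- U + step * G
    if (fused == "l2") {
      for (t in seq_len(tt - 1L)) {
        nu <- sqrt(sum(U_new[, t]^2))
        if (nu > lam) U_new[, t] <- U_new[, t] * (lam / nu)
      }
    } else {
      U_new <- pmin(pmax(U_new, -lam), lam)
    }
    delta <- max(abs(U_new - U))
    U <- U_new
    if (delta < tol) break
  }
  V - U %*% t(D)
}

#' Block update of the phenotype weight matrix
#'
#' Proximal-gradient descent of the V-block objective with u held fixed.
#' The composite nonsmooth term (row-group sparsity plus the temporal
#' chain-fused penalty) is handled by alternating closed-form proximal
#' passes; every accepted step is checked against the full block objective,
#' so the block value never increases.
#'
#' @param V starting p x T matrix.
#' @param As list of T PSD matrices `Yt'Yt + 2 beta2 Yt'L2t Yt`.
#' @param Bs list of T linear terms `Yt'X u`.
#' @param cfg a [penalty_config()].
#' @return updated V.
#' @export
update_V <- function(V, As, Bs, cfg) {
  tt <- ncol(V)
  smooth_val <- function(V) {
    v <- 0
    for (t in seq_len(tt))
      v <- v + 0.5 * sum(V[, t] * (As[[t]] %*% V[, t])) -
        sum(V[, t] * Bs[[t]])
    v
  }
  nonsmooth_val <- function(V)
    cfg$lam2 * sum(sqrt(rowSums(V^2))) + cfg$lamt * fused_term(V, cfg$fused)
  L <- max(1e-12, max(vapply(As, function(a) norm(a, "2"), numeric(1))))
  s <- 1 / L
  total <- smooth_val(V) + nonsmooth_val(V)
  for (it in seq_len(cfg$inner_max_iter)) {
    G <- V
    for (t in seq_len(tt))
      G[, t] <- as.numeric(As[[t]] %*% V[, t]) - Bs[[t]]
    if (any(!is.finite(G)))
      stop("non-finite gradient in the V update", call. = FALSE)
    Z <- V - s * G
    ## composite nonsmooth term: one pass of each prox (row-group, then
    ## exact chain-fused); the acceptance check below absorbs the
    ## composition error
    P <- prox_rowgroup(Z, s * cfg$lam2)
    P <- prox_chain_fused(P, s * cfg$lamt, cfg$fused)
    new_total <- smooth_val(P) + nonsmooth_val(P)
    if (new_total > total) { s <- s / 2
      if (s < 1e-18) break
      next }
    delta <- max(abs(P - V))
    V <- P; total <- new_total
    if (delta < cfg$inner_tol) break
  }
  V
}

## ---- full fits -------------------------------------------------------

#' Fit the hypergraph-regularized temporal sparse CCA model
#'
#' Alternates proximal-gradient block updates of the gene weight vector u
#' and the phenotype weight matrix V. Initialization is the rank-1 SVD of
#' `X' Ybar` with `Ybar` the time-averaged phenotype view. Under the
#' default covariance scale metric every block step is accepted only if
#' the objective does not increase (monotone `objective_trace`; exact
#' classical CCA at zero penalties); under
#' `scale_metric = "identity"` the classic PMA-style alternation of
#' normalized soft-thresholded correlation steps is run instead, stopping
#' on iterate change, and the trace is recorded for diagnostics only. At
#' return the projected scores are rescaled onto the unit constraint set.
#'
#' @param X n x q gene view (column-standardized internally by default).
#' @param Ys list of T n x p phenotype views.
#' @param L1 optional n x n gene hypergraph Laplacian (needed when
#'   `beta1 > 0`).
#' @param L2s optional phenotype Laplacian(s) (list of T, or one matrix;
#'   needed when `beta2 > 0`).
#' @param cfg a [penalty_config()].
#' @param standardize column-standardize the views before fitting.
#' @return an object of class `canonical_model` with elements `u`, `V`,
#'   `objective_trace` (monotone non-increasing), `hyperparams`,
#'   `converged`, `n_iter`, `diagnostics`.
#' @export
fit_hbtgscca <- function(X, Ys, L1 = NULL, L2s = NULL,
                         cfg = penalty_config(), standardize = TRUE) {
  Ys <- as_view_list(Ys)
  X <- as.matrix(X)
  Ys <- lapply(Ys, as.matrix)
  tt <- length(Ys)
  n <- nrow(X)
  if (any(vapply(Ys, nrow, integer(1)) != n))
    stop("all views must share the sample dimension", call. = FALSE)
  if (cfg$beta1 > 0 && is.null(L1))
    stop("beta1 > 0 requires a gene-view Laplacian `L1`", call. = FALSE)
  if (cfg$beta2 > 0 && is.null(L2s))
    stop("beta2 > 0 requires phenotype Laplacian(s) `L2s`", call. = FALSE)
  if (standardize) {
    X <- standardize_columns(X)
    Ys <- lapply(Ys, standardize_columns)
  }
  L2s <- recycle_laplacians(L2s, tt)
  q <- ncol(X); p <- ncol(Ys[[1L]])

  ## precomputed block quadratics (scale quadratic + hypergraph quadratic).
  ## "covariance": X'X / Yt'Yt, giving exact CCA at zero penalties.
  ## "identity": the PMA-style diagonal approximation; paired with the
  ## correlation-scale linear terms below, the L1/L2,1 penalties then
  ## threshold (time-averaged) sample correlations, so the standard
  ## tuning grid spans "keep everything" to "keep nothing".
  scale_cov <- is.null(cfg$scale_metric) || cfg$scale_metric == "covariance"
  A_u <- if (scale_cov) crossprod(X) else diag(q)
  if (cfg$beta1 > 0) A_u <- A_u + 2 * cfg$beta1 * crossprod(X, L1 %*% X)
  As <- lapply(seq_len(tt), function(t) {
    a <- if (scale_cov) crossprod(Ys[[t]]) else diag(p)
    if (cfg$beta2 > 0 && !is.null(L2s[[t]]))
      a <- a + 2 * cfg$beta2 * crossprod(Ys[[t]], L2s[[t]] %*% Ys[[t]])
    a
  })
  c_scale <- if (scale_cov) 1 else tt * sqrt(n)
  b_scale <- if (scale_cov) 1 else sqrt(n)

  ## rank-1 SVD init on the time-averaged cross-product
  ybar <- Reduce(`+`, Ys) / tt
  sv <- svd(crossprod(X, ybar), nu = 1L, nv = 1L)
  u <- sv$u[, 1L]
  v0 <- sv$v[, 1L]
  su <- l2norm(X %*% u); if (su > 0) u <- u / su
  V <- matrix(v0, p, tt)
  for (t in seq_len(tt)) {
    sv_t <- l2norm(Ys[[t]] %*% V[, t])
    if (sv_t > 0) V[, t] <- V[, t] / sv_t
  }

  feas_obj <- function(u, V)
    scca_objective(u, V, X, Ys, L1, L2s, cfg, scale_penalty = FALSE)

  trace <- feas_obj(u, V)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(cfg$max_iter)) {
    prev <- utils::tail(trace, 1L)
    cur <- prev
    u_old <- u; V_old <- V

    c_vec <- numeric(q)
    for (t in seq_len(tt))
      c_vec <- c_vec + as.numeric(crossprod(X, Ys[[t]] %*% V[, t]))
    u_new <- update_u(u, A_u, c_vec / c_scale, cfg$lam1,
                      cfg$inner_max_iter, cfg$inner_tol)
    su <- l2norm(X %*% u_new)
    if (su > 0) u_new <- u_new / su
    if (scale_cov) {
      ## covariance metric: accept only non-increasing steps, so the
      ## recorded trace descends monotonically
      obj_u <- feas_obj(u_new, V)
      if (obj_u <= cur) { u <- u_new; cur <- obj_u }
    } else {
      u <- u_new
    }

    Bs <- lapply(seq_len(tt),
                 function(t) as.numeric(crossprod(Ys[[t]], X %*% u)) /
                   b_scale)
    V_new <- update_V(V, As, Bs, cfg)
    ## common rescale keeps fused-equal columns equal while restoring the
    ## candidate to the constraint boundary max_t ||Yt vt|| = 1
    vn <- max(vapply(seq_len(tt),
                     function(t) l2norm(Ys[[t]] %*% V_new[, t]),
                     numeric(1)))
    if (vn > 0) V_new <- V_new / vn
    if (scale_cov) {
      obj_v <- feas_obj(u, V_new)
      if (obj_v <= cur) { V <- V_new; cur <- obj_v }
    } else {
      V <- V_new
      cur <- feas_obj(u, V)
    }

    trace <- c(trace, cur)
    done <- if (scale_cov)
      abs(prev - cur) <= cfg$tol * max(1, abs(prev))
    else
      max(abs(u - u_old)) <= cfg$tol && max(abs(V - V_old)) <= cfg$tol
    if (done) {
      converged <- TRUE
      break
    }
  }

  ## final rescale onto the constraint set: unit gene score; a single
  ## common factor for V so fused-equal columns stay equal
  su <- l2norm(X %*% u)
  if (su > 0) u <- u / su
  vnorms <- vapply(seq_len(tt),
                   function(t) l2norm(Ys[[t]] %*% V[, t]), numeric(1))
  if (max(vnorms) > 0) V <- V / max(vnorms)
  all_zero <- su == 0 && all(V == 0)

  names(u) <- colnames(X)
  rownames(V) <- colnames(Ys[[1L]])
  colnames(V) <- if (!is.null(names(Ys))) names(Ys)
                 else sprintf("T%d", seq_len(tt))
  structure(list(u = u, V = V, objective_trace = trace,
                 hyperparams = cfg, converged = converged, n_iter = iter,
                 diagnostics = list(all_zero = all_zero,
                                    score_norm_u = su)),
            class = "canonical_model")
}

#' Fit the temporally constrained group-sparse CCA baseline
#'
#' Identical to [fit_hbtgscca()] with both hypergraph weights set to zero;
#' no Laplacians are required.
#'
#' @inheritParams fit_hbtgscca
#' @return a `canonical_model`.
#' @export
fit_tgscca <- function(X, Ys, cfg = penalty_config(), standardize = TRUE) {
  cfg$beta1 <- 0
  cfg$beta2 <- 0
  fit_hbtgscca(X, Ys, L1 = NULL, L2s = NULL, cfg = cfg,
               standardize = standardize)
}

#' @export
print.canonical_model <- function(x, ...) {
  cat(sprintf(paste0("canonical_model: %d gene weights (%d nonzero), ",
                     "%d x %d phenotype weights, %s after %d iterations\n"),
              length(x$u), sum(x$u != 0), nrow(x$V), ncol(x$V),
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}
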