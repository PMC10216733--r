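## Study-level drivers: hyperparameter grid search with k-fold CV, the
## noise sweep comparing TGSCCA with the hypergraph/deep-subspace variant,
## the full pipeline on delimited-text views, the top-gene regression
## check, and the reconstruction-versus-raw clustering comparison.

#' Penalty grid in the standard tuning range
#'
#' Cartesian grid over the five penalties with values
#' `{0.0001, 0.001, 0.01, 0.1, 1}`. By default `beta1 = beta2` and
#' `lam2 = lamt` are tied, giving 125 points; `full = TRUE` unties
#' everything (3125 points). `include_beta = FALSE` fixes both hypergraph
#' weights at 0 (the TGSCCA grid, 25 points).
#'
#' @param values penalty values to sweep.
#' @param full untie all five penalties.
#' @param include_beta sweep the hypergraph weights.
#' @return data.frame with columns lam1, lam2, lamt, beta1, beta2.
#' @export
penalty_grid <- function(values = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
                         full = FALSE, include_beta = TRUE) {
  if (full) {
    g <- expand.grid(lam1 = values, lam2 = values, lamt = values,
                     beta1 = if (include_beta) values else 0,
                     beta2 = if (include_beta) values else 0)
  } else {
    g <- expand.grid(lam1 = values, lam2 = values,
                     beta1 = if (include_beta) values else 0)
    g$lamt <- g$lam2
    g$beta2 <- g$beta1
  }
  g[, c("lam1", "lam2", "lamt", "beta1", "beta2")]
}

build_laplacians <- function(X, Ys, knn_k, shared_y = FALSE) {
  L1 <- hypergraph_laplacian(build_knn_hypergraph(X, k = knn_k))
  if (shared_y) {
    ybar <- Reduce(`+`, Ys) / length(Ys)
    L2 <- hypergraph_laplacian(build_knn_hypergraph(ybar, k = knn_k))
    L2s <- rep(list(L2), length(Ys))
  } else {
    L2s <- lapply(Ys, function(y)
      hypergraph_laplacian(build_knn_hypergraph(y, k = knn_k)))
  }
  list(L1 = L1, L2s = L2s)
}

#' Cross-validated hyperparameter grid search
#'
#' Scores every grid point by k-fold cross-validation on the training
#' samples: fit on the in-fold data, score the mean held-out canonical
#' correlation across time points; folds where the held-out projection is
#' degenerate are dropped (recorded as `NA`).
#'
#' @param X training gene view.
#' @param Ys list of training phenotype views.
#' @param grid data.frame from [penalty_grid()] (or any subset of it).
#' @param folds number of CV folds.
#' @param knn_k hypergraph neighborhood size (used when any beta > 0).
#' @param seed fold-assignment seed.
#' @param base_cfg [penalty_config()] supplying solver controls.
#' @param shared_y_laplacian build one phenotype Laplacian from the
#'   time-averaged view instead of one per time point.
#' @param select `"best"` returns the CV-score argmax; `"1se"` applies the
#'   one-standard-error parsimony rule — among grid points whose CV score
#'   is within one standard error of the best, the one with the largest
#'   penalties (ordered by lam1, then lam2, lamt, beta1, beta2) wins.
#'   Use `"1se"` when the sparsity pattern itself is the quantity of
#'   interest; near-tied CV scores otherwise pick an arbitrary density.
#' @return list with `best` (a [penalty_config()]), `best_score`, and
#'   `table` (the grid with a `cv_ccc` column).
#' @export
grid_search <- function(X, Ys, grid = penalty_grid(), folds = 5L,
                        knn_k = 5L, seed = 1L,
                        base_cfg = penalty_config(),
                        shared_y_laplacian = FALSE,
                        select = c("best", "1se")) {
  select <- match.arg(select)
  Ys <- as_view_list(Ys)
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- check_count(folds, "folds", min = 2L)
  if (n < folds) stop("fewer samples than folds", call. = FALSE)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))

  need_hg <- any(grid$beta1 > 0 | grid$beta2 > 0)
  fold_data <- lapply(seq_len(folds), function(f) {
    tr <- which(fold_id != f)
    dat <- list(tr = tr, te = which(fold_id == f))
    if (need_hg) {
      dat$lap <- build_laplacians(X[tr, , drop = FALSE],
                                  lapply(Ys, function(y)
                                    y[tr, , drop = FALSE]),
                                  knn_k = min(knn_k, length(tr) - 1L),
                                  shared_y = shared_y_laplacian)
    }
    dat
  })

  fold_mat <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- base_cfg
    cfg$lam1 <- g$lam1; cfg$lam2 <- g$lam2; cfg$lamt <- g$lamt
    cfg$beta1 <- g$beta1; cfg$beta2 <- g$beta2
    vapply(fold_data, function(fd) {
      tryCatch({
        Xtr <- X[fd$tr, , drop = FALSE]
        Ytr <- lapply(Ys, function(y) y[fd$tr, , drop = FALSE])
        fit <- if (cfg$beta1 > 0 || cfg$beta2 > 0)
          fit_hbtgscca(Xtr, Ytr, fd$lap$L1, fd$lap$L2s, cfg)
        else fit_tgscca(Xtr, Ytr, cfg)
        Xte <- X[fd$te, , drop = FALSE]
        Yte <- lapply(Ys, function(y) y[fd$te, , drop = FALSE])
        ccc_scores(fit, Xte, Yte)$mean
      }, error = function(e) NA_real_)
    }, numeric(1))
  }, numeric(folds))

  scores <- apply(fold_mat, 2L, function(fs)
    if (all(is.na(fs))) NA_real_ else mean(fs, na.rm = TRUE))
  table <- cbind(grid, cv_ccc = scores)
  best_i <- which.max(scores)
  if (select == "1se") {
    fs_best <- fold_mat[, best_i]
    se <- stats::sd(fs_best, na.rm = TRUE) /
      sqrt(max(1, sum(!is.na(fs_best))))
    if (!is.finite(se)) se <- 0
    ok <- which(!is.na(scores) & scores >= scores[best_i] - se)
    ord <- order(grid$lam1[ok], grid$lam2[ok], grid$lamt[ok],
                 grid$beta1[ok], grid$beta2[ok], decreasing = TRUE)
    best_i <- ok[ord[1L]]
  }
  g <- grid[best_i, ]
  best <- base_cfg
  best$lam1 <- g$lam1; best$lam2 <- g$lam2; best$lamt <- g$lamt
  best$beta1 <- g$beta1; best$beta2 <- g$beta2
  list(best = best, best_score = scores[best_i], table = table)
}

## deep-subspace reconstruction of a simulated dataset's two views; the
## phenotype views share one model trained on the time-concatenated data
reconstruct_views <- function(gene_view, pheno_views, labels = NULL,
                              epochs = 60L, arch = NULL, seed = 1L,
                              lam_se = 1, lam_l1 = 0.01) {
  n <- nrow(gene_view)
  if (is.null(labels)) labels <- rep(1L, n)
  gene_model <- train_reconstruction_network(
    gene_view, labels, arch = arch, epochs = epochs, lam_se = lam_se,
    lam_l1 = lam_l1, seed = seed)
  gene_rec <- reconstruct(gene_model, gene_view)

  concat <- do.call(rbind, pheno_views)
  rownames(concat) <- sprintf("%s_%s",
                              rep(names(pheno_views) %||%
                                    seq_along(pheno_views),
                                  each = n),
                              rep(rownames(pheno_views[[1L]]) %||%
                                    seq_len(n),
                                  times = length(pheno_views)))
  pheno_model <- train_reconstruction_network(
    concat, rep(labels, times = length(pheno_views)), arch = arch,
    epochs = epochs, lam_se = lam_se, lam_l1 = lam_l1, seed = seed + 1L)
  concat_rec <- reconstruct(pheno_model, concat)
  pheno_rec <- lapply(seq_along(pheno_views), function(t) {
    m <- concat_rec[(t - 1L) * n + seq_len(n), , drop = FALSE]
    dimnames(m) <- dimnames(pheno_views[[t]])
    m
  })
  names(pheno_rec) <- names(pheno_views)
  list(gene = gene_rec, pheno = pheno_rec,
       models = list(gene = gene_model, pheno = pheno_model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noise sweep comparing TGSCCA and the hypergraph/deep-subspace variant
#'
#' For every noise level and seed: simulate a coupled dataset, split 4:1,
#' select penalties by [grid_search()] on the training samples, refit, and
#' record the per-time-point test canonical correlations for both
#' algorithms under identical splits (paired design). The hypergraph
#' variant reconstructs both views with the deep subspace model before the
#' split and builds its Laplacians on the reconstructed training samples.
#'
#' @param noise_levels noise standard deviations to sweep.
#' @param n_seeds replicates per level.
#' @param sim_config base [simulation_config()] (its `noise_sigma` and
#'   `seed` are overridden per run).
#' @param grid penalty grid for [grid_search()] (use a single row to skip
#'   tuning).
#' @param folds CV folds within the training split.
#' @param knn_k hypergraph neighborhood size.
#' @param epochs reconstruction training epochs for the deep-subspace arm.
#' @param base_cfg solver controls.
#' @param seed master seed; run seeds are derived from it.
#' @param algorithms any of `"tgscca"`, `"dshbtgscca"`.
#' @param out_dir if given, the tidy results CSV (and a line plot per
#'   noise level when ggplot2 is installed) are written there.
#' @return data.frame with columns algorithm, noise, seed, time, ccc.
#' @export
run_noise_sweep <- function(noise_levels = 1:5, n_seeds = 10L,
                            sim_config = simulation_config(),
                            grid = penalty_grid(), folds = 5L,
                            knn_k = 5L, epochs = 60L,
                            base_cfg = penalty_config(),
                            seed = 1L,
                            algorithms = c("tgscca", "dshbtgscca"),
                            out_dir = NULL) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  rows <- list()
  for (noise in noise_levels) {
    for (s in seq_len(n_seeds)) {
      run_seed <- (seed * 10000L + round(noise * 100) * 100L + s) %%
        .Machine$integer.max
      cfg_sim <- sim_config
      cfg_sim$noise_sigma <- noise
      cfg_sim$seed <- run_seed
      ds <- simulate_joint_longitudinal(cfg_sim)
      split <- train_test_split_41(ds, seed = run_seed)

      for (alg in algorithms) {
        if (alg == "dshbtgscca") {
          rec <- reconstruct_views(ds$gene_view, ds$pheno_views,
                                   epochs = epochs, seed = run_seed)
          gene_all <- rec$gene; pheno_all <- rec$pheno
          g <- grid
        } else {
          gene_all <- ds$gene_view; pheno_all <- ds$pheno_views
          g <- grid; g$beta1 <- 0; g$beta2 <- 0
          g <- unique(g)
        }
        tr <- split$train$idx; te <- split$test$idx
        Xtr <- gene_all[tr, , drop = FALSE]
        Ytr <- lapply(pheno_all, function(m) m[tr, , drop = FALSE])
        Xte <- gene_all[te, , drop = FALSE]
        Yte <- lapply(pheno_all, function(m) m[te, , drop = FALSE])

        if (nrow(g) > 1L) {
          gs <- grid_search(Xtr, Ytr, grid = g, folds = folds,
                            knn_k = knn_k, seed = run_seed,
                            base_cfg = base_cfg)
          cfg <- gs$best
        } else {
          cfg <- base_cfg
          cfg$lam1 <- g$lam1; cfg$lam2 <- g$lam2; cfg$lamt <- g$lamt
          cfg$beta1 <- g$beta1; cfg$beta2 <- g$beta2
        }
        fit <- if (cfg$beta1 > 0 || cfg$beta2 > 0) {
          lap <- build_laplacians(Xtr, Ytr,
                                  knn_k = min(knn_k, length(tr) - 1L))
          fit_hbtgscca(Xtr, Ytr, lap$L1, lap$L2s, cfg)
        } else fit_tgscca(Xtr, Ytr, cfg)
        cccs <- ccc_scores(fit, Xte, Yte)$per_time
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, noise = noise, seed = s,
          time = seq_along(cccs), ccc = as.numeric(cccs))
      }
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(res, file.path(out_dir, "noise_sweep.csv"),
                     row.names = FALSE)
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      agg <- stats::aggregate(ccc ~ algorithm + noise + time, res, mean)
      for (nl in unique(agg$noise)) {
        d <- agg[agg$noise == nl, ]
        gp <- ggplot2::ggplot(d, ggplot2::aes(
          x = time, y = ccc, colour = algorithm)) +
          ggplot2::geom_line() + ggplot2::geom_point() +
          ggplot2::labs(title = sprintf("noise sigma = %g", nl),
                        x = "time point", y = "mean test CCC")
        ggplot2::ggsave(file.path(out_dir,
                                  sprintf("noise_%g.png", nl)),
                        gp, width = 5, height = 4, dpi = 120)
      }
    }
  }
  res
}

#' Full association pipeline on two views
#'
#' Standardize, optionally deep-subspace reconstruct both views, build KNN
#' hypergraph Laplacians on the reconstructed training samples, split 4:1,
#' tune penalties by cross-validated grid search, fit the canonical model,
#' and report per-time test canonical correlations plus the top-ranked
#' phenotype and gene features.
#'
#' @param gene gene view: matrix or CSV path (`sample_id` first column).
#' @param phenos list of phenotype views (matrices or CSV paths), ordered
#'   by time.
#' @param labels optional per-sample labels (vector, or CSV path with
#'   columns `sample_id,label`) guiding the reconstruction.
#' @param grid penalty grid.
#' @param folds,knn_k,epochs,base_cfg,seed as in [run_noise_sweep()].
#' @param reconstruct_views_flag set `FALSE` to run the raw-data arm.
#' @param shared_y_laplacian single phenotype Laplacian from the
#'   time-averaged view.
#' @param top_pheno,top_gene how many features to rank.
#' @return list with `report` (ccc per time, mean, top feature tables),
#'   `model`, `best_cfg`, `cv_table`, `split`.
#' @export
run_full_pipeline <- function(gene, phenos, labels = NULL,
                              grid = penalty_grid(), folds = 5L,
                              knn_k = 5L, epochs = 60L,
                              base_cfg = penalty_config(), seed = 1L,
                              reconstruct_views_flag = TRUE,
                              shared_y_laplacian = FALSE,
                              top_pheno = 10L, top_gene = 20L) {
  gene <- if (is.character(gene)) read_view(gene) else as.matrix(gene)
  phenos <- lapply(phenos, function(p)
    if (is.character(p)) read_view(p) else as.matrix(p))
  ids <- rownames(gene)
  for (p in phenos) {
    if (!identical(rownames(p), ids)) {
      bad <- union(setdiff(rownames(p), ids), setdiff(ids, rownames(p)))
      stop("sample-ID mismatch across views: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (is.character(labels)) {
    lab_df <- utils::read.csv(labels)
    labels <- lab_df$label[match(ids, lab_df$sample_id)]
    if (anyNA(labels)) stop("labels missing for some sample IDs",
                            call. = FALSE)
  }

  if (reconstruct_views_flag) {
    rec <- reconstruct_views(gene, phenos, labels = labels,
                             epochs = epochs, seed = seed)
    gene_u <- rec$gene; phenos_u <- rec$pheno
  } else {
    gene_u <- gene; phenos_u <- phenos
  }

  idx <- split_indices_41(nrow(gene_u), seed = seed)
  Xtr <- gene_u[idx$train, , drop = FALSE]
  Ytr <- lapply(phenos_u, function(m) m[idx$train, , drop = FALSE])
  Xte <- gene_u[idx$test, , drop = FALSE]
  Yte <- lapply(phenos_u, function(m) m[idx$test, , drop = FALSE])

  gs <- grid_search(Xtr, Ytr, grid = grid, folds = folds, knn_k = knn_k,
                    seed = seed, base_cfg = base_cfg,
                    shared_y_laplacian = shared_y_laplacian)
  cfg <- gs$best
  model <- if (cfg$beta1 > 0 || cfg$beta2 > 0) {
    lap <- build_laplacians(Xtr, Ytr,
                            knn_k = min(knn_k, nrow(Xtr) - 1L),
                            shared_y = shared_y_laplacian)
    fit_hbtgscca(Xtr, Ytr, lap$L1, lap$L2s, cfg)
  } else fit_tgscca(Xtr, Ytr, cfg)

  scores <- ccc_scores(model, Xte, Yte)
  ## rank phenotype features by the time-mean absolute weight
  v_mean <- rowMeans(abs(model$V))
  report <- list(
    ccc_per_time = scores$per_time,
    mean_ccc = scores$mean,
    top_pheno = top_k_features(v_mean, rownames(model$V),
                               min(top_pheno, nrow(model$V))),
    top_gene = top_k_features(model$u, names(model$u),
                              min(top_gene, length(model$u))))
  list(report = report, model = model, best_cfg = cfg,
       cv_table = gs$table, split = idx)
}

## ---- regression check -------------------------------------------------

ridge_fit <- function(Xtr, ytr, lambda) {
  xm <- colMeans(Xtr); ym <- mean(ytr)
  Xc <- sweep(Xtr, 2L, xm)
  beta <- solve(crossprod(Xc) + lambda * diag(ncol(Xc)),
                crossprod(Xc, ytr - ym))
  list(beta = as.numeric(beta), xm = xm, intercept = ym)
}

## evidence-maximization Bayesian ridge (conjugate Gaussian linear model;
## hyperpriors updated by fixed-point iteration on the marginal likelihood)
bayes_ridge_fit <- function(Xtr, ytr, max_iter = 100L, tol = 1e-6) {
  xm <- colMeans(Xtr); ym <- mean(ytr)
  Xc <- sweep(Xtr, 2L, xm); yc <- ytr - ym
  n <- nrow(Xc); p <- ncol(Xc)
  XtX <- crossprod(Xc); Xty <- as.numeric(crossprod(Xc, yc))
  alpha <- 1; beta_prec <- 1 / max(stats::var(yc), 1e-12)
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  for (it in seq_len(max_iter)) {
    S_inv <- beta_prec * XtX + alpha * diag(p)
    m <- beta_prec * solve(S_inv, Xty)
    gamma <- sum(beta_prec * ev / (alpha + beta_prec * ev))
    alpha_new <- gamma / max(sum(m^2), 1e-12)
    resid <- yc - as.numeric(Xc %*% m)
    beta_new <- max(n - gamma, 1e-6) / max(sum(resid^2), 1e-12)
    if (abs(alpha_new - alpha) < tol * alpha &&
        abs(beta_new - beta_prec) < tol * beta_prec) {
      alpha <- alpha_new; beta_prec <- beta_new
      break
    }
    alpha <- alpha_new; beta_prec <- beta_new
  }
  S_inv <- beta_prec * XtX + alpha * diag(p)
  m <- beta_prec * solve(S_inv, Xty)
  list(beta = as.numeric(m), xm = xm, intercept = ym)
}

#' Regress phenotype features on selected top genes
#'
#' For each phenotype feature: split the samples 4:1, fit the chosen
#' regressor of the feature on the selected gene columns, and score the
#' held-out predictions with [r2_score()].
#'
#' @param gene_view samples x genes matrix.
#' @param pheno_view samples x phenotype-features matrix.
#' @param top_genes character vector of gene names (columns of
#'   `gene_view`) to use as predictors.
#' @param method `"linear"`, `"ridge"` or `"bayes"`.
#' @param ridge_lambda ridge penalty (ridge method only).
#' @param seed split seed.
#' @return list with `per_feature` (named R-squared vector) and `mean`.
#' @export
regression_eval <- function(gene_view, pheno_view, top_genes,
                            method = c("linear", "ridge", "bayes"),
                            ridge_lambda = 1, seed = 1L) {
  method <- match.arg(method)
  gene_view <- as.matrix(gene_view); pheno_view <- as.matrix(pheno_view)
  if (length(top_genes) < 1L)
    stop("need at least one predictor gene", call. = FALSE)
  if (!all(top_genes %in% colnames(gene_view)))
    stop("unknown gene(s): ",
         paste(setdiff(top_genes, colnames(gene_view)), collapse = ", "),
         call. = FALSE)
  X <- gene_view[, top_genes, drop = FALSE]
  idx <- split_indices_41(nrow(X), seed = seed)
  Xtr <- X[idx$train, , drop = FALSE]; Xte <- X[idx$test, , drop = FALSE]

  r2s <- vapply(seq_len(ncol(pheno_view)), function(j) {
    ytr <- pheno_view[idx$train, j]; yte <- pheno_view[idx$test, j]
    pred <- switch(method,
      linear = {
        fit <- stats::lm.fit(cbind(1, Xtr), ytr)
        as.numeric(cbind(1, Xte) %*% fit$coefficients)
      },
      ridge = {
        fit <- ridge_fit(Xtr, ytr, ridge_lambda)
        fit$intercept + as.numeric(sweep(Xte, 2L, fit$xm) %*% fit$beta)
      },
      bayes = {
        fit <- bayes_ridge_fit(Xtr, ytr)
        fit$intercept + as.numeric(sweep(Xte, 2L, fit$xm) %*% fit$beta)
      })
    r2_score(yte, pred)
  }, numeric(1))
  names(r2s) <- colnames(pheno_view)
  list(per_feature = r2s, mean = mean(r2s))
}

#' Clustering with and without deep subspace reconstruction
#'
#' Runs k-means (k = number of label classes) with `n_restarts`
#' independently seeded restarts on the raw data and on the reconstructed
#' data, scoring each run with the internal and external clustering
#' indices.
#'
#' @param data samples x features matrix.
#' @param labels true class labels (>= 2 classes).
#' @param n_restarts k-means restarts per arm.
#' @param epochs,arch reconstruction training controls.
#' @param reconstruct_enabled set `FALSE` to score the raw data in both
#'   arms (ablation identity).
#' @param seed master seed.
#' @return list with `summary` (data.frame: index, arm, mean, sd) and
#'   `runs` (per-restart index values).
#' @export
clustering_comparison <- function(data, labels, n_restarts = 20L,
                                  epochs = 150L, arch = NULL,
                                  reconstruct_enabled = TRUE, seed = 1L) {
  data <- as.matrix(data)
  k <- length(unique(labels))
  if (k < 2L) stop("need at least 2 label classes", call. = FALSE)
  arms <- list(raw = data)
  arms$reconstructed <- if (reconstruct_enabled) {
    model <- train_reconstruction_network(data, labels, arch = arch,
                                          epochs = epochs, seed = seed)
    reconstruct(model, data)
  } else data

  runs <- list()
  for (arm in names(arms)) {
    for (r in seq_len(n_restarts)) {
      km <- with_seed(seed + r, stats::kmeans(arms[[arm]], centers = k,
                                              nstart = 1L))
      idx <- clustering_indices(arms[[arm]], km$cluster, labels)
      runs[[length(runs) + 1L]] <-
        data.frame(arm = arm, restart = r,
                   index = names(idx), value = as.numeric(unlist(idx)))
    }
  }
  runs <- do.call(rbind, runs)
  summary <- stats::aggregate(value ~ index + arm, runs,
                              function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(index = summary$index, arm = summary$arm,
                        mean = summary$value[, "mean"],
                        sd = summary$value[, "sd"])
  list(summary = summary, runs = runs)
}
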