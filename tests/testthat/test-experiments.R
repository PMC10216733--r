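test_that("the penalty grid enumerates the standard tuning range", {
  g <- penalty_grid()
  expect_equal(nrow(g), 125)
  for (col in names(g))
    expect_true(all(g[[col]] %in% c(1e-4, 1e-3, 1e-2, 1e-1, 1)))
  expect_equal(sort(unique(g$lam1)), c(1e-4, 1e-3, 1e-2, 1e-1, 1))
  expect_true(all(g$beta1 == g$beta2) && all(g$lam2 == g$lamt))
  expect_equal(nrow(penalty_grid(full = TRUE)), 3125)
  gt <- penalty_grid(include_beta = FALSE)
  expect_equal(nrow(gt), 25)
  expect_true(all(gt$beta1 == 0) && all(gt$beta2 == 0))
})

test_that("grid search returns a one-row table for a single-point grid", {
  cv <- make_coupled_views(n = 40, p = 4, q = 5, n_time = 2, seed = 1)
  g <- data.frame(lam1 = 0.01, lam2 = 0.01, lamt = 0.01,
                  beta1 = 0, beta2 = 0)
  gs <- grid_search(cv$X, cv$Ys, grid = g, folds = 4, seed = 1)
  expect_equal(nrow(gs$table), 1)
  expect_equal(gs$best$lam1, 0.01)
  expect_true(is.finite(gs$best_score))
})

test_that("grid search picks a sparsity level that generalizes", {
  cv <- make_coupled_views(n = 160, p = 6, q = 10, n_time = 2,
                           strength = 2, noise = 1, seed = 2)
  tr <- 1:100; te <- 101:160
  g <- data.frame(lam1 = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
                  lam2 = 0.01, lamt = 0.01, beta1 = 0, beta2 = 0)
  gs <- grid_search(cv$X[tr, ], lapply(cv$Ys, function(y) y[tr, ]),
                    grid = g, folds = 5, seed = 3)
  expect_equal(nrow(gs$table), 5)
  # refit every grid point on the full training split; the CV winner's
  # test CCC should be at least the median of the exhaustive table
  test_ccc <- sapply(seq_len(nrow(g)), function(i) {
    cfg <- penalty_config(lam1 = g$lam1[i], lam2 = g$lam2[i],
                          lamt = g$lamt[i])
    m <- fit_tgscca(cv$X[tr, ], lapply(cv$Ys, function(y) y[tr, ]), cfg)
    ccc_scores(m, cv$X[te, ], lapply(cv$Ys, function(y) y[te, ]))$mean
  })
  # small slack: several lam1 levels are statistically tied and CV picks
  # among them with sampling noise far below 0.01 CCC
  winner <- which(g$lam1 == gs$best$lam1)
  expect_gte(test_ccc[winner], median(test_ccc) - 0.01)
})

test_that("the noise sweep emits the paired bookkeeping and round-trips", {
  g <- data.frame(lam1 = 0.01, lam2 = 0.01, lamt = 0.01,
                  beta1 = 0.1, beta2 = 0.1)
  dir <- withr::local_tempdir()
  res <- run_noise_sweep(noise_levels = 1, n_seeds = 1,
                         sim_config = simulation_config(
                           n_samples = 40, p_pheno = 6, q_gene = 10,
                           n_timepoints = 4),
                         grid = g, epochs = 10, seed = 5, out_dir = dir)
  expect_equal(nrow(res), 2 * 4)          # 2 algorithms x 4 time points
  expect_setequal(unique(res$algorithm), c("tgscca", "dshbtgscca"))
  expect_true(all(res$ccc >= -1 & res$ccc <= 1))
  back <- read.csv(file.path(dir, "noise_sweep.csv"))
  expect_equal(back$ccc, res$ccc)
})

test_that("the full pipeline runs from CSV files and reports ranked features", {
  ds <- simulate_joint_longitudinal(simulation_config(
    n_samples = 50, p_pheno = 8, q_gene = 12, n_timepoints = 2,
    noise_sigma = 1, seed = 6))
  dir <- withr::local_tempdir()
  write_simulation(ds, dir)
  g <- data.frame(lam1 = 0.01, lam2 = 0.01, lamt = 0.01,
                  beta1 = 0.1, beta2 = 0.1)
  out <- run_full_pipeline(
    file.path(dir, "gene.csv"),
    list(file.path(dir, "pheno_T1.csv"), file.path(dir, "pheno_T2.csv")),
    grid = g, folds = 3, epochs = 10, seed = 7,
    top_pheno = 5, top_gene = 8)
  expect_length(out$report$ccc_per_time, 2)
  expect_equal(nrow(out$report$top_pheno), 5)
  expect_equal(nrow(out$report$top_gene), 8)
  expect_true(all(diff(out$report$top_gene$abs_weight) <= 0))
  expect_s3_class(out$model, "canonical_model")

  # ablation arm: same schema without reconstruction
  out_raw <- run_full_pipeline(
    file.path(dir, "gene.csv"),
    list(file.path(dir, "pheno_T1.csv"), file.path(dir, "pheno_T2.csv")),
    grid = g, folds = 3, seed = 7, reconstruct_views_flag = FALSE,
    top_pheno = 5, top_gene = 8)
  expect_identical(names(out_raw$report), names(out$report))

  # sample-ID mismatch is reported
  bad <- ds$gene_view
  rownames(bad)[1] <- "OTHER"
  expect_error(run_full_pipeline(bad, ds$pheno_views[1:2], grid = g),
               "sample-ID mismatch")
})

test_that("regression recovers exact linear structure and respects limits", {
  set.seed(8)
  n <- 60
  genes <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, sprintf("GENE_%02d", 1:10)))
  coefs <- runif(5, 1, 2)
  pheno <- cbind(genes[, 1:5] %*% coefs,
                 genes[, 1:5] %*% rev(coefs) + 3)
  colnames(pheno) <- c("ROI_1", "ROI_2")
  r <- regression_eval(genes, pheno, sprintf("GENE_%02d", 1:5), "linear",
                       seed = 1)
  expect_equal(unname(r$per_feature), c(1, 1), tolerance = 1e-10)

  # ridge at vanishing penalty equals the linear solution
  rr <- regression_eval(genes, pheno, sprintf("GENE_%02d", 1:5), "ridge",
                        ridge_lambda = 1e-10, seed = 1)
  expect_equal(rr$per_feature, r$per_feature, tolerance = 1e-6)

  # independent phenotype: out-of-sample R^2 stays small
  r2_null <- sapply(1:10, function(s) {
    set.seed(100 + s)
    g2 <- matrix(rnorm(500 * 5), 500, 5,
                 dimnames = list(NULL, sprintf("G%d", 1:5)))
    y <- matrix(rnorm(500), 500, 1, dimnames = list(NULL, "R1"))
    regression_eval(g2, y, sprintf("G%d", 1:5), "linear", seed = s)$mean
  })
  expect_true(all(r2_null <= 0.1))

  # Bayesian ridge shrinks but still explains a strong linear signal
  rb <- regression_eval(genes, pheno, sprintf("GENE_%02d", 1:5), "bayes",
                        seed = 1)
  expect_gt(rb$mean, 0.95)
  expect_error(regression_eval(genes, pheno, character(0), "linear"),
               "at least one")
})

test_that("clustering comparison reports both arms and the ablation identity", {
  ms <- simulate_multisubspace(15, 12, 3, 3, noise_sigma = 0.2, seed = 9)
  cc <- clustering_comparison(ms$data, ms$labels, n_restarts = 5,
                              epochs = 40, seed = 1)
  expect_setequal(unique(cc$summary$arm), c("raw", "reconstructed"))
  expect_setequal(unique(cc$summary$index),
                  c("silhouette", "calinski_harabasz", "davies_bouldin",
                    "precision", "recall", "f_score", "nmi",
                    "adjusted_rand"))
  # reconstruction disabled: the two arms are identical distributions
  cc0 <- clustering_comparison(ms$data, ms$labels, n_restarts = 5,
                               reconstruct_enabled = FALSE, seed = 1)
  raw <- cc0$runs[cc0$runs$arm == "raw", c("index", "restart", "value")]
  rec <- cc0$runs[cc0$runs$arm == "reconstructed",
                  c("index", "restart", "value")]
  expect_equal(raw$value, rec$value)
})
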