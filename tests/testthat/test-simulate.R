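test_that("signed-uniform draws stay in the mixture support and match its moments", {
  set.seed(1)
  x <- sample_signed_uniform(1e5)
  expect_true(all(abs(x) >= 0.5 & abs(x) <= 1))
  # mixture is symmetric with E|x| = 0.75
  expect_lt(abs(mean(x)), 0.01)
  expect_lt(abs(mean(abs(x)) - 0.75), 0.01)
  expect_error(sample_signed_uniform(0), "k")
})

test_that("default simulation reproduces the reference shapes", {
  ds <- simulate_joint_longitudinal(simulation_config(seed = 3))
  expect_equal(dim(ds$gene_view), c(200, 450))
  expect_length(ds$pheno_views, 4)
  for (m in ds$pheno_views) expect_equal(dim(m), c(200, 90))
  expect_length(ds$true_alpha, 90)
  expect_length(ds$true_beta, 450)
  # masked-out features carry exactly zero true weight
  expect_true(all(ds$true_alpha[!ds$pheno_mask] == 0))
  expect_true(all(ds$true_beta[!ds$gene_mask] == 0))
  expect_true(all(abs(ds$true_alpha[ds$pheno_mask]) >= 0.5))
})

test_that("simulation is bit-identical under an identical configuration", {
  a <- simulate_joint_longitudinal(simulation_config(
    n_samples = 30, p_pheno = 8, q_gene = 12, seed = 11))
  b <- simulate_joint_longitudinal(simulation_config(
    n_samples = 30, p_pheno = 8, q_gene = 12, seed = 11))
  expect_identical(a, b)
  c <- simulate_joint_longitudinal(simulation_config(
    n_samples = 30, p_pheno = 8, q_gene = 12, seed = 12))
  expect_false(identical(a$gene_view, c$gene_view))
})

test_that("noiseless drift-free fully-correlated phenotypes are rank one", {
  ds <- simulate_joint_longitudinal(simulation_config(
    n_samples = 40, p_pheno = 10, q_gene = 15, noise_sigma = 0,
    drift_sigma = 0, frac_correlated_pheno = 1, seed = 5))
  for (m in ds$pheno_views) {
    expect_equal(m, outer(ds$latent, ds$true_alpha), ignore_attr = TRUE)
    expect_equal(qr(m)$rank, 1)
  }
})

test_that("the shared latent factor couples the two views", {
  ds <- simulate_joint_longitudinal(simulation_config(
    n_samples = 2000, p_pheno = 20, q_gene = 30, noise_sigma = 1,
    latent_sigma = 1, frac_correlated_pheno = 1, frac_correlated_gene = 1,
    seed = 7))
  r <- cor(ds$pheno_views[[1]] %*% ds$true_alpha,
           ds$gene_view %*% ds$true_beta)
  expect_gt(r, 0.9)
})

test_that("temporal drift has the configured entrywise variance", {
  ds <- simulate_joint_longitudinal(simulation_config(
    n_samples = 300, p_pheno = 40, q_gene = 5, n_timepoints = 4,
    drift_sigma = sqrt(0.1), seed = 9))
  for (i in 1:3) {
    d <- ds$pheno_views[[i + 1]] - ds$pheno_views[[i]]
    expect_lt(abs(var(as.numeric(d)) - 0.1), 0.005)
  }
})

test_that("multi-subspace generator plants the promised structure", {
  ms <- simulate_multisubspace(30, 20, 3, 3, noise_sigma = 0, seed = 2)
  expect_equal(dim(ms$data), c(90, 20))
  expect_equal(sort(unique(ms$labels)), 1:3)
  for (cl in 1:3) {
    block <- ms$data[ms$labels == cl, ]
    expect_lte(qr(block, tol = 1e-8)$rank, 3)
  }
  # principal angles between recovered and planted bases, low noise; a
  # large per-class sample keeps the SVD estimate of each basis tight
  ms2 <- simulate_multisubspace(100, 20, 3, 3, noise_sigma = 0.01, seed = 2)
  for (cl in 1:3) {
    block <- ms2$data[ms2$labels == cl, ]
    rec_basis <- svd(t(block))$u[, 1:3]
    s <- svd(crossprod(rec_basis, ms2$bases[[cl]]))$d
    angles <- acos(pmin(1, s))
    expect_lt(max(angles), 1e-2)
  }
  expect_error(simulate_multisubspace(10, 5, 5, 2), "subspace_dim")
})

test_that("the 4:1 split partitions every view consistently", {
  expect_error(split_indices_41(4), "at least 5")
  s5 <- split_indices_41(5, seed = 1)
  expect_length(s5$train, 4); expect_length(s5$test, 1)
  s200 <- split_indices_41(200, seed = 1)
  expect_length(s200$train, 160); expect_length(s200$test, 40)
  expect_identical(s200, split_indices_41(200, seed = 1))
  expect_setequal(c(s200$train, s200$test), 1:200)

  ds <- simulate_joint_longitudinal(simulation_config(
    n_samples = 25, p_pheno = 4, q_gene = 6, seed = 3))
  sp <- train_test_split_41(ds, seed = 2)
  expect_equal(nrow(sp$train$gene_view), 20)
  expect_equal(nrow(sp$test$pheno_views[[2]]), 5)
  expect_identical(rownames(sp$train$gene_view),
                   rownames(sp$train$pheno_views[[4]]))
})

test_that("simulation round-trips through the CSV writers", {
  ds <- simulate_joint_longitudinal(simulation_config(
    n_samples = 12, p_pheno = 5, q_gene = 7, n_timepoints = 2, seed = 4))
  dir <- withr::local_tempdir()
  files <- write_simulation(ds, dir)
  gene_back <- read_view(file.path(dir, "gene.csv"))
  expect_equal(gene_back, ds$gene_view, tolerance = 1e-12)
  t2 <- read_view(file.path(dir, "pheno_T2.csv"))
  expect_equal(t2, ds$pheno_views[[2]], tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_beta, ds$true_beta, tolerance = 1e-12)
  expect_equal(truth$config$n_samples, 12)
})
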