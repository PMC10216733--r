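## Coupled latent-factor simulator: one static gene-expression view plus a
## drifting sequence of longitudinal phenotype views sharing a per-sample
## latent signal.

#' Simulation configuration
#'
#' Bundles the knobs of the coupled two-view generator. Defaults reproduce
#' the reference simulation design: n = 200 samples, 90 phenotype features
#' (ROIs), 450 gene features, 4 time points, latent signal of unit standard
#' deviation, half of the features in each view carrying signal, and a
#' between-visit random-walk drift with variance 0.1.
#'
#' @param n_samples number of samples n.
#' @param p_pheno number of phenotype features per time point.
#' @param q_gene number of gene features.
#' @param n_timepoints number of longitudinal visits T.
#' @param noise_sigma standard deviation of the additive Gaussian noise e.
#' @param latent_sigma standard deviation of the shared latent factor.
#' @param frac_correlated_pheno fraction of phenotype features carrying the
#'   latent signal.
#' @param frac_correlated_gene fraction of gene features carrying the latent
#'   signal.
#' @param drift_sigma standard deviation of each entry of the per-visit
#'   drift increment (default `sqrt(0.1)`, i.e. drift variance 0.1).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @return an object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(n_samples = 200L, p_pheno = 90L,
                              q_gene = 450L, n_timepoints = 4L,
                              noise_sigma = 1, latent_sigma = 1,
                              frac_correlated_pheno = 0.5,
                              frac_correlated_gene = 0.5,
                              drift_sigma = sqrt(0.1), seed = 1L) {
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples"),
    p_pheno = check_count(p_pheno, "p_pheno"),
    q_gene = check_count(q_gene, "q_gene"),
    n_timepoints = check_count(n_timepoints, "n_timepoints"),
    noise_sigma = check_nonneg(noise_sigma, "noise_sigma"),
    latent_sigma = check_nonneg(latent_sigma, "latent_sigma"),
    frac_correlated_pheno = check_fraction(frac_correlated_pheno,
                                           "frac_correlated_pheno"),
    frac_correlated_gene = check_fraction(frac_correlated_gene,
                                          "frac_correlated_gene"),
    drift_sigma = check_nonneg(drift_sigma, "drift_sigma"),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  structure(cfg, class = "simulation_config")
}

#' Signed-uniform weight draws
#'
#' Draws k independent values from the mixture U(-1,-0.5) ∪ U(0.5,1):
#' magnitude uniform on \[0.5, 1\], sign Bernoulli(1/2). Used for the
#' planted canonical weight vectors, so every signal feature has a weight
#' bounded away from zero.
#'
#' @param k number of draws (>= 1).
#' @return numeric vector of length k with 0.5 <= |value| <= 1.
#' @export
sample_signed_uniform <- function(k) {
  k <- check_count(k, "k")
  sgn <- ifelse(stats::runif(k) < 0.5, -1, 1)
  sgn * stats::runif(k, 0.5, 1)
}

#' Generate a coupled gene/longitudinal-phenotype dataset
#'
#' A latent factor eps ~ N(0, latent_sigma^2) is drawn per sample. Signal
#' columns of the first phenotype matrix are `eps * alpha_j + e`, signal
#' columns of the gene view are `eps * beta_j + e`, with e ~
#' N(0, noise_sigma^2) i.i.d.; non-signal columns are pure noise and carry
#' true weight exactly 0. Later visits follow a random walk
#' `T[i+1] = T[i] + dV` with i.i.d. N(0, drift_sigma^2) entries.
#'
#' @param config a [simulation_config()].
#' @return an object of class `simulated_dataset`: a list with `gene_view`
#'   (n x q matrix), `pheno_views` (list of T n x p matrices), `true_alpha`,
#'   `true_beta`, `latent`, `pheno_mask`, `gene_mask`, and `config`.
#' @export
simulate_joint_longitudinal <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples; p <- config$p_pheno; q <- config$q_gene
  tt <- config$n_timepoints
  with_seed(config$seed, {
    sample_ids <- sprintf("S%04d", seq_len(n))
    roi_names <- sprintf("ROI_%03d", seq_len(p))
    gene_names <- sprintf("GENE_%04d", seq_len(q))

    n_cor_p <- round(config$frac_correlated_pheno * p)
    n_cor_q <- round(config$frac_correlated_gene * q)
    pheno_mask <- rep(FALSE, p); gene_mask <- rep(FALSE, q)
    if (n_cor_p > 0) pheno_mask[sample.int(p, n_cor_p)] <- TRUE
    if (n_cor_q > 0) gene_mask[sample.int(q, n_cor_q)] <- TRUE

    true_alpha <- numeric(p); true_beta <- numeric(q)
    if (n_cor_p > 0) true_alpha[pheno_mask] <- sample_signed_uniform(n_cor_p)
    if (n_cor_q > 0) true_beta[gene_mask] <- sample_signed_uniform(n_cor_q)

    latent <- stats::rnorm(n, 0, config$latent_sigma)

    gene_view <- outer(latent, true_beta) +
      matrix(stats::rnorm(n * q, 0, config$noise_sigma), n, q)
    dimnames(gene_view) <- list(sample_ids, gene_names)

    t1 <- outer(latent, true_alpha) +
      matrix(stats::rnorm(n * p, 0, config$noise_sigma), n, p)
    pheno_views <- vector("list", tt)
    pheno_views[[1L]] <- t1
    if (tt > 1L) for (i in seq_len(tt - 1L)) {
      pheno_views[[i + 1L]] <- pheno_views[[i]] +
        matrix(stats::rnorm(n * p, 0, config$drift_sigma), n, p)
    }
    for (i in seq_len(tt)) dimnames(pheno_views[[i]]) <-
      list(sample_ids, roi_names)
    names(pheno_views) <- sprintf("T%d", seq_len(tt))

    structure(list(gene_view = gene_view, pheno_views = pheno_views,
                   true_alpha = true_alpha, true_beta = true_beta,
                   latent = latent, pheno_mask = pheno_mask,
                   gene_mask = gene_mask, config = config),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset: %d samples, %d genes, %d x %d phenotype views\n",
    nrow(x$gene_view), ncol(x$gene_view), length(x$pheno_views),
    ncol(x$pheno_views[[1L]])))
  cat(sprintf("  signal features: %d/%d phenotype, %d/%d gene\n",
              sum(x$pheno_mask), length(x$pheno_mask),
              sum(x$gene_mask), length(x$gene_mask)))
  invisible(x)
}

#' Generate labeled multi-subspace data
#'
#' Each class lives on its own low-dimensional linear subspace of the
#' ambient space: an orthonormal basis is drawn per class, samples are
#' random coefficient combinations of the basis plus isotropic Gaussian
#' noise. Used to exercise the label-guided subspace reconstruction stage.
#'
#' @param n_per_class samples per class.
#' @param ambient_dim ambient feature dimension.
#' @param subspace_dim dimension of each class subspace
#'   (< `ambient_dim`).
#' @param n_classes number of classes.
#' @param noise_sigma standard deviation of the additive noise.
#' @param seed integer seed.
#' @return list with `data` (matrix, rows = samples), `labels` (integer
#'   vector), and `bases` (list of ambient_dim x subspace_dim orthonormal
#'   bases, one per class).
#' @export
simulate_multisubspace <- function(n_per_class = 30L, ambient_dim = 20L,
                                   subspace_dim = 3L, n_classes = 3L,
                                   noise_sigma = 0.1, seed = 1L) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  ambient_dim <- check_count(ambient_dim, "ambient_dim")
  subspace_dim <- check_count(subspace_dim, "subspace_dim")
  n_classes <- check_count(n_classes, "n_classes")
  noise_sigma <- check_nonneg(noise_sigma, "noise_sigma")
  if (subspace_dim >= ambient_dim)
    stop("`subspace_dim` must be smaller than `ambient_dim`", call. = FALSE)
  with_seed(seed, {
    blocks <- vector("list", n_classes)
    bases <- vector("list", n_classes)
    for (cl in seq_len(n_classes)) {
      basis <- qr.Q(qr(matrix(stats::rnorm(ambient_dim * subspace_dim),
                              ambient_dim, subspace_dim)))
      coefs <- matrix(stats::rnorm(n_per_class * subspace_dim),
                      n_per_class, subspace_dim)
      blocks[[cl]] <- coefs %*% t(basis) +
        matrix(stats::rnorm(n_per_class * ambient_dim, 0, noise_sigma),
               n_per_class, ambient_dim)
      bases[[cl]] <- basis
    }
    data <- do.call(rbind, blocks)
    rownames(data) <- sprintf("S%04d", seq_len(nrow(data)))
    colnames(data) <- sprintf("F_%03d", seq_len(ambient_dim))
    list(data = data,
         labels = rep(seq_len(n_classes), each = n_per_class),
         bases = bases)
  })
}

#' 4:1 train/test sample indices
#'
#' Draws a single random 80/20 partition of `1:n` (no stratification); the
#' same index sets must be applied to every view of a multi-view dataset.
#'
#' @param n number of samples (>= 5).
#' @param seed integer seed making the partition deterministic.
#' @return list with integer vectors `train` and `test` (sorted).
#' @export
split_indices_41 <- function(n, seed = 1L) {
  n <- check_count(n, "n")
  if (n < 5L) stop("need at least 5 samples for a 4:1 split", call. = FALSE)
  n_test <- round(n / 5)
  with_seed(seed, {
    test <- sort(sample.int(n, n_test))
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Split a simulated dataset 4:1 into train and test views
#'
#' Applies a single [split_indices_41()] partition to the gene view and to
#' every phenotype view alike.
#'
#' @param dataset a `simulated_dataset`.
#' @param seed integer seed.
#' @return list with elements `train` and `test`, each a list holding
#'   `gene_view`, `pheno_views` and the row indices used (`idx`).
#' @export
train_test_split_41 <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  idx <- split_indices_41(nrow(dataset$gene_view), seed)
  take <- function(rows) list(
    gene_view = dataset$gene_view[rows, , drop = FALSE],
    pheno_views = lapply(dataset$pheno_views,
                         function(m) m[rows, , drop = FALSE]),
    idx = rows)
  list(train = take(idx$train), test = take(idx$test))
}

#' Write a simulated dataset to delimited text
#'
#' One CSV per phenotype time point (`pheno_T1.csv`, ...), one gene CSV
#' (`gene.csv`), each with a `sample_id` first column, plus `truth.json`
#' holding the planted weights, masks and configuration.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_view <- function(m, path) {
    df <- data.frame(sample_id = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  files <- character(0)
  files <- c(files, write_view(dataset$gene_view, file.path(dir, "gene.csv")))
  for (i in seq_along(dataset$pheno_views)) {
    files <- c(files, write_view(dataset$pheno_views[[i]],
                                 file.path(dir, sprintf("pheno_T%d.csv", i))))
  }
  truth <- list(true_alpha = dataset$true_alpha,
                true_beta = dataset$true_beta,
                latent = dataset$latent,
                pheno_mask = dataset$pheno_mask,
                gene_mask = dataset$gene_mask,
                config = unclass(dataset$config))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(files, truth_path))
}

#' Read a view matrix written by [write_simulation()]
#'
#' @param path CSV with a `sample_id` first column.
#' @return numeric matrix with sample IDs as row names.
#' @export
read_view <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "sample_id")
    stop("expected a `sample_id` first column in ", path, call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}
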