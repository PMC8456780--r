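test_that("cell QC applies the stated strict/inclusive bounds", {
  # cell1: exactly 1000 UMI (removed, strict >); cell2: 1001 UMI across 501
  # genes, ~5% mito (retained); cell3: high mito fraction (removed)
  n_genes <- 600
  m <- matrix(0L, 3, n_genes)
  colnames(m) <- c("MT-ND1", sprintf("g%03d", seq_len(n_genes - 1)))
  m[1, 2:501] <- 2L                      # 1000 UMI over 500 genes
  m[2, 2:501] <- 1L; m[2, 502] <- 451L; m[2, 1] <- 50L   # 1001+? recompute
  m[2, ] <- 0L; m[2, 2:502] <- 1L; m[2, 503] <- 450L; m[2, 1] <- 50L
  # cell2: 501 ones + 450 + 50 mito = 1001 total over 503 genes, 5.0% mito
  m[3, 2:600] <- 2L; m[3, 1] <- 1000L    # ~46% mito
  x <- cm_from_dense(m)
  th <- qc_thresholds(min_umi = 1000, min_genes = 500,
                      max_mito_fraction = 0.10)
  kept <- filter_cells(x, th)
  expect_identical(cell_ids(kept), cell_ids(x)[2])
  # vacuous thresholds retain everything
  all_kept <- filter_cells(x, qc_thresholds(min_umi = 0, min_genes = 0,
                                            max_mito_fraction = 1))
  expect_equal(n_cells(all_kept), 3)
  # filtering is idempotent
  expect_identical(cell_ids(filter_cells(kept, th)), cell_ids(kept))
})

test_that("a sample without configured thresholds is a configuration error", {
  x <- random_counts(10, 20, samples = rep(c("a", "b"), each = 5))
  expect_error(filter_cells(x, list(a = qc_thresholds())), "\\bb\\b")
})

test_that("gene filter keeps genes detected in at least min_cells cells", {
  m <- matrix(0L, 12, 3)
  m[1:9, 1] <- 1L                        # 9 cells: removed at min_cells=10
  m[1:10, 2] <- 1L                       # exactly 10: kept (inclusive)
  m[, 3] <- 1L
  x <- cm_from_dense(m)
  expect_identical(gene_ids(filter_genes(x, 10)), gene_ids(x)[2:3])
  expect_identical(gene_ids(filter_genes(x, 0)), gene_ids(x))
})

test_that("normalisation matches the closed form and conserves totals", {
  m <- matrix(0L, 2, 3)
  m[1, ] <- c(1L, 1L, 2L)
  m[2, 2] <- 7L                          # single expressed gene
  x <- cm_from_dense(m)
  norm <- normalize_counts(x)
  expect_equal(as.numeric(norm$values[1, ]),
               log(c(2501, 2501, 5001)), tolerance = 1e-12)
  expect_equal(as.numeric(norm$values[2, 2]), log(10001), tolerance = 1e-12)
  # back-transformed per-cell totals equal the scale factor
  y <- random_counts(50, 40, seed = 8)
  ny <- normalize_counts(y)
  totals <- Matrix::rowSums(expm1(as.matrix(ny$values)))
  expect_equal(unname(totals), rep(1e4, 50), tolerance = 1e-6)
})

test_that("an all-zero cell yields an all-zero row with a warning", {
  m <- matrix(c(0L, 0L, 3L, 4L), 2, 2, byrow = TRUE)
  expect_warning(norm <- normalize_counts(cm_from_dense(m)), "zero total")
  expect_equal(as.numeric(norm$values[1, ]), c(0, 0))
})

test_that("HVG selection recovers genes with inflated dispersion", {
  set.seed(21)
  n_cells <- 400; n_genes <- 2000; n_hot <- 100
  mu <- rgamma(n_genes, 0.7, rate = 0.4) + 0.05
  size <- rep(2, n_genes)
  size[seq_len(n_hot)] <- 0.2            # 10x inflated dispersion
  m <- vapply(seq_len(n_genes), function(g)
    rnbinom(n_cells, mu = mu[g], size = size[g]), numeric(n_cells))
  x <- cm_from_dense(m)
  hvg <- select_hvg(normalize_counts(x))
  hot <- gene_ids(x)[seq_len(n_hot)]
  expect_gte(sum(hot %in% hvg$selected_genes), 90)
})

test_that("constant and ribosomal/mitochondrial genes are never selected", {
  set.seed(4)
  m <- matrix(rnbinom(300 * 300, mu = 3, size = 2), 300, 300)
  m[, 1] <- 5L                           # constant gene
  m[, 2] <- rnbinom(300, mu = 3, size = 0.05)  # wildly variable
  x <- cm_from_dense(m)
  colnames(x$counts)[1:3] <- c("CONST", "RPL3", "MT-CO1")
  m2 <- as.matrix(x$counts); m2[, 3] <- m2[, 2]
  x <- cm_from_dense(m2); colnames(x$counts)[1:3] <- c("CONST", "RPL3", "MT-CO1")
  hvg <- select_hvg(normalize_counts(x))
  expect_false("CONST" %in% hvg$selected_genes)
  expect_false("RPL3" %in% hvg$selected_genes)
  expect_false("MT-CO1" %in% hvg$selected_genes)
  # the same variability on a regular symbol is selected
  expect_true(any(hvg$per_gene$selected))
})

test_that("PCA captures rank structure and fixes the component sign", {
  set.seed(6)
  # rank-1 expression structure: every gene is a positive multiple of the
  # same cell profile, so after per-gene standardisation the matrix has
  # exactly one non-trivial direction
  a <- rexp(200) + 0.1; b <- rexp(150) + 0.1
  vals <- Matrix::Matrix(outer(a, b), sparse = TRUE)
  dimnames(vals) <- list(sprintf("c%03d", 1:200), sprintf("g%03d", 1:150))
  norm <- structure(list(values = as(vals, "CsparseMatrix"),
                         sample_of_cell = rep("s", 200),
                         scale_total = 1e4, log_base = "e"),
                    class = "NormalizedMatrix")
  emb <- run_pca(norm, colnames(vals), n_pcs = 5, sd_cap = Inf)
  sdev <- attr(emb, "sdev")
  expect_gte(sdev[1]^2 / 150, 0.999)     # standardised columns have var 1
  rot <- attr(emb, "rotation")
  expect_true(all(vapply(seq_len(5), function(j)
    rot[which.max(abs(rot[, j])), j] > 0, TRUE)))
  expect_error(run_pca(norm, colnames(vals)[1:10], n_pcs = 40), "n_pcs")
})

test_that("PCA equals a dense SVD oracle and ignores gene order", {
  x <- random_counts(80, 60, mu = 4, seed = 9)
  norm <- normalize_counts(x)
  emb <- run_pca(norm, gene_ids(x), n_pcs = 4, sd_cap = Inf)
  xs <- scale(as.matrix(norm$values))
  sv <- svd(xs)                          # dense oracle
  for (j in 1:4) {
    cosine <- abs(sum(emb$coords[, j] * sv$u[, j] * sv$d[j])) /
      (sqrt(sum(emb$coords[, j]^2)) * sv$d[j] * sqrt(sum(sv$u[, j]^2)))
    expect_equal(cosine, 1, tolerance = 1e-6)
  }
  # permuting genes leaves the embedding unchanged (same HVG set)
  perm <- sample(n_genes(x))
  norm_p <- norm; norm_p$values <- norm$values[, perm]
  emb_p <- run_pca(norm_p, gene_ids(x), n_pcs = 4, sd_cap = Inf)
  expect_equal(emb_p$coords, emb$coords, tolerance = 1e-8)
})
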