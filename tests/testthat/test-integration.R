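# Helper: marker tables for a small simulated dataset, using the planted
# type labels as clusters (matching-machinery tests should not depend on
# the clustering stage).
sim_markers <- function(counts, types) {
  suppressWarnings(find_markers(normalize_counts(counts), types))
}

test_that("the gene-set database counts, names and floors sets correctly", {
  sim <- simulate_counts(sim_config(n_batches = 2, n_types = 3,
                                    cells_per_batch = 240, n_genes = 500,
                                    markers_per_type = 15, seed = 51))
  xs <- split_by_sample(sim$counts)
  mks <- lapply(names(xs), function(b)
    sim_markers(xs[[b]], sim$truth$type[sim$truth$batch == b]))
  names(mks) <- names(xs)
  db <- build_cluster_geneset_db(mks)
  expect_length(db, 6)                       # 2 samples x 3 clusters
  parsed <- scellintegrate:::.parse_sc_name(names(db$sets))
  expect_setequal(parsed$sample, names(xs))
  expect_equal(nrow(unique(parsed)), 6)      # names parse back bijectively
  # a cluster with too few markers is dropped with a warning
  mk_weak <- mks[[1]]
  mk_weak$is_marker[mk_weak$cluster == "T1"] <- FALSE
  mk_weak$is_marker[mk_weak$cluster == "T1"][1:3] <- TRUE
  expect_warning(db2 <- build_cluster_geneset_db(list(a = mk_weak)),
                 "excluded")
  expect_length(db2, 2)
  # a sample with no usable cluster is an error naming the sample
  mk_none <- mks[[1]]
  mk_none$is_marker <- FALSE
  expect_error(suppressWarnings(
    build_cluster_geneset_db(list(badsample = mk_none))), "badsample")
})

test_that("a duplicated sample matches to its own counterpart clusters", {
  sim <- simulate_counts(sim_config(n_batches = 1, n_types = 4,
                                    cells_per_batch = 300, n_genes = 500,
                                    markers_per_type = 15, seed = 52))
  mk <- sim_markers(sim$counts, sim$truth$type)
  mks <- list(s1 = mk, s2 = mk)
  db <- build_cluster_geneset_db(mks)
  match <- compute_match_matrix(mks, db, n_perm = 150, seed = 4)
  expect_true(all(match >= 0))
  for (rn in rownames(match)) {
    cl <- sub("^s[12]\\|", "", rn)
    best <- colnames(match)[which.max(match[rn, ])]
    expect_equal(sub("^s[12]\\|", "", best), cl)
  }
  meta <- match_clusters(match)
  # every meta-cluster spans both copies of the duplicated sample
  expect_true(all(meta$status == "common"))
  expect_equal(length(meta$status), 4)
})

test_that("samples with disjoint cell types share no match score", {
  sim <- simulate_counts(sim_config(n_batches = 1, n_types = 6,
                                    cells_per_batch = 600, n_genes = 600,
                                    markers_per_type = 15, seed = 53))
  in_s1 <- sim$truth$type %in% c("T1", "T2", "T3")
  x1 <- subset_count_matrix(sim$counts, cells = which(in_s1))
  x2 <- subset_count_matrix(sim$counts, cells = which(!in_s1))
  mks <- list(s1 = sim_markers(x1, sim$truth$type[in_s1]),
              s2 = sim_markers(x2, sim$truth$type[!in_s1]))
  db <- build_cluster_geneset_db(mks)
  match <- compute_match_matrix(mks, db, n_perm = 150, seed = 5)
  cross <- match[grepl("^s1", rownames(match)),
                 grepl("^s2", colnames(match))]
  expect_true(all(cross == 0))
})

test_that("meta-clustering recovers a planted shared/unique structure", {
  # 3 samples, 4 shared types, 1 type unique to sample 3; block-structured
  # scores with positive same-type entries and zeros elsewhere
  set.seed(54)
  rows <- c(outer(1:4, 1:2, function(cl, s) scellintegrate:::.sc_name(
    paste0("s", s), cl)), scellintegrate:::.sc_name("s3", 1:5))
  m <- matrix(0, 13, 13, dimnames = list(rows, rows))
  type_of <- c(1:4, 1:4, 1:5)
  for (i in 1:13) for (j in 1:13)
    if (type_of[i] == type_of[j]) m[i, j] <- 2.5 + runif(1, 0, 0.3)
  meta <- match_clusters(m)
  expect_equal(length(meta$status), 5)
  tab <- table(meta$assignment$meta, type_of)
  expect_true(all(rowSums(tab > 0) == 1))    # meta-clusters are type-pure
  unique_meta <- meta$assignment$meta[13]    # the s3-only type
  expect_equal(unname(meta$status[as.character(unique_meta)]), "unique")
  expect_equal(sum(meta$status == "common"), 4)
  # an all-zero matrix falls back to every cluster unique
  z <- matrix(0, 4, 4, dimnames = list(rows[1:4], rows[1:4]))
  expect_warning(mz <- match_clusters(z), "unique")
  expect_true(all(mz$status == "unique"))
})

test_that("prior rows carry the stated mass and sum to one", {
  assignment <- data.frame(sample = rep("s1", 5), cluster = as.character(1:5),
                           meta = 1:5)
  meta <- structure(list(assignment = assignment,
                         status = setNames(rep("unique", 5), 1:5), k = 5),
                    class = "MetaClusterMap")
  p <- build_prior_matrix(meta, rep("s1", 3), c("2", "4", "4"),
                          confidence = 0.9)
  expect_equal(unname(p[1, ]), c(0.025, 0.9, 0.025, 0.025, 0.025))
  expect_equal(unname(rowSums(p)), rep(1, 3), tolerance = 1e-9)
  u <- build_prior_matrix(meta, rep("s1", 2), c("1", "3"), confidence = 1 / 5)
  expect_true(all(abs(u - 0.2) < 1e-12))     # uninformative prior
  expect_error(build_prior_matrix(meta, "s1", "9"), "absent")
})

test_that("single-batch correction is the identity", {
  set.seed(55)
  z <- matrix(rnorm(200 * 8), 200, 8)
  out <- harmony_correct(z, rep("only", 200))
  expect_equal(out$coords, z, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a constant batch offset is largely removed", {
  set.seed(56)
  n <- 600
  z <- matrix(rnorm(n * 10), n, 10)
  b <- rep(c("a", "b"), each = n / 2)
  z[b == "b", 1] <- z[b == "b", 1] + 5
  out <- harmony_correct(z, b, params = harmony_params(K = 4, seed = 1))
  gap_before <- 5
  gap_after <- sqrt(sum((colMeans(out$coords[b == "a", ]) -
                           colMeans(out$coords[b == "b", ]))^2))
  expect_lte(gap_after, 0.05 * gap_before)
  expect_equal(dim(out$coords), dim(z))
})

test_that("the correction is exactly translation-equivariant", {
  set.seed(57)
  z <- matrix(rnorm(300 * 6), 300, 6)
  b <- rep(c("a", "b"), 150)
  p <- harmony_params(K = 3, seed = 2)
  out1 <- harmony_correct(z, b, params = p)
  out2 <- harmony_correct(z + 7.5, b, params = p)
  expect_equal(out2$coords, out1$coords + 7.5, tolerance = 1e-10)
})

test_that("an uninformative prior reproduces the unsupervised path exactly", {
  set.seed(58)
  n <- 300
  z <- matrix(rnorm(n * 6), n, 6)
  b <- rep(c("a", "b"), n / 2)
  assignment <- data.frame(sample = "s", cluster = as.character(1:4),
                           meta = 1:4)
  meta <- structure(list(assignment = assignment,
                         status = setNames(rep("unique", 4), 1:4), k = 4),
                    class = "MetaClusterMap")
  cl_of_cell <- as.character(rep_len(1:4, n))
  flat <- build_prior_matrix(meta, rep("s", n), cl_of_cell,
                             confidence = 1 / 4)
  sup <- harmony_correct(z, b, prior = flat,
                         params = harmony_params(seed = 3))
  unsup <- harmony_correct(z, b, params = harmony_params(K = 4, seed = 3))
  expect_equal(sup$coords, unsup$coords, tolerance = 1e-12)
})

test_that("degenerate harmony inputs are rejected", {
  z <- matrix(rnorm(40), 10, 4)
  z[1, 1] <- NA
  expect_error(harmony_correct(z, rep(c("a", "b"), 5)), "finite")
  expect_error(run_supervised_integration(list(a = random_counts(10, 5))),
               "requires >= 2 samples")
})
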