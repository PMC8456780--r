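# Planted-truth evaluation of the cluster-matching stage on the bundled
# 3-batch benchmark: the quantitative surface on which the supervised
# integration is validated.

#' Evaluate cluster matching against the planted truth of the benchmark
#'
#' Runs the per-sample stage (QC, normalisation, HVG, PCA, SNN/Louvain,
#' markers) and the GSEA matching stage on [default_benchmark()] for one
#' generator seed, then scores the meta-cluster map against the planted cell
#' types. Each sample-cluster is labelled by its majority planted type;
#' correspondence accuracy is the fraction of sample-cluster pairs whose
#' co-assignment (same vs different meta-cluster) agrees with their
#' type labels (a Rand index, 1 when the matching is perfect), and
#' `unique_ok` records whether every meta-cluster holding the batch-unique
#' type is flagged `"unique"` while all shared-type meta-clusters are
#' `"common"`.
#'
#' @param seed generator seed for [default_benchmark()]
#' @param n_perm GSEA permutations for the matching stage (default 300)
#' @param config overrides as in [run_supervised_integration()]
#' @return list with `accuracy`, `unique_ok`, `n_meta`, the `meta` map and
#'   the per-sample-cluster majority `type`
#' @export
benchmark_cluster_matching <- function(seed = 20210914, n_perm = 300,
                                       config = list()) {
  sim <- default_benchmark(seed = seed)
  cfg <- modifyList(list(qc = qc_thresholds(), min_cells_per_gene = 10,
                         hvg_alpha = 0.05, n_pcs = 40, knn_k = 30,
                         resolution = 1, log2fc_min = 1.5, padj_max = 0.05,
                         freq_min = 0.3, n_perm = n_perm, seed = 1),
                    config)
  xs <- split_by_sample(sim$counts)
  staged <- lapply(names(xs), function(s) .process_sample(xs[[s]], s, cfg))
  names(staged) <- names(xs)
  markers <- lapply(staged, `[[`, "markers")
  db <- build_cluster_geneset_db(markers)
  match <- compute_match_matrix(markers, db, n_perm = cfg$n_perm,
                                seed = cfg$seed)
  meta <- match_clusters(match)
  # majority planted type of every sample-cluster
  sc_type <- vapply(seq_len(nrow(meta$assignment)), function(i) {
    s <- meta$assignment$sample[i]
    cl <- meta$assignment$cluster[i]
    in_cl <- staged[[s]]$clusters$labels == as.integer(cl)
    cells <- cell_ids(staged[[s]]$filtered)[in_cl]
    names(which.max(table(sim$truth$type[match(cells,
                                               cell_ids(sim$counts))])))
  }, "")
  n <- length(sc_type)
  pair_ok <- 0L; pair_n <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_type <- sc_type[i] == sc_type[j]
    same_meta <- meta$assignment$meta[i] == meta$assignment$meta[j]
    pair_n <- pair_n + 1L
    if (same_type == same_meta) pair_ok <- pair_ok + 1L
  }
  unique_type <- "T5"                        # present only in batch 3
  metas_of_unique <- unique(meta$assignment$meta[sc_type == unique_type])
  metas_of_shared <- unique(meta$assignment$meta[sc_type != unique_type])
  unique_ok <- length(metas_of_unique) >= 1 &&
    all(meta$status[as.character(metas_of_unique)] == "unique") &&
    all(meta$status[as.character(metas_of_shared)] == "common")
  list(accuracy = pair_ok / pair_n, unique_ok = unique_ok,
       n_meta = length(meta$status), meta = meta, type = sc_type)
}
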