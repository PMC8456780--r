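# End-to-end orchestration with artifact writing and a run manifest. The
# heavy lifting lives in run_supervised_integration(); this wrapper handles
# input ingestion (10x directories listed in a metadata TSV, or the bundled
# simulator), TSV/JSON outputs and stage logging.

.log_stage <- function(...) message(sprintf("[%s] %s",
                                            format(Sys.time(), "%H:%M:%S"),
                                            sprintf(...)))

#' Run the full integration workflow and write its artifacts
#'
#' Stages: ingest (10x directories from a metadata TSV, or the bundled
#' benchmark simulator) -> per-sample preprocessing/clustering/markers ->
#' GSEA cluster matching -> supervised correction -> signature scoring and
#' integration metrics. All randomness flows from the single `seed`.
#' Outputs written under `out_dir`: `embedding_pca.tsv`,
#' `embedding_corrected.tsv`, `meta_clusters.tsv`, `match_matrix.tsv`,
#' `clusters.tsv`, `markers.tsv`, `lineage_calls.tsv` and `metrics.json`
#' (when gene sets are available), plus `manifest.json`.
#'
#' @param metadata path to a sample metadata TSV with columns `sample_id`,
#'   `tissue`, `path` (10x directory); ignored when `simulate = TRUE`
#' @param out_dir output directory
#' @param simulate use [default_benchmark()] instead of reading data
#' @param gmt optional GMT file of lineage signatures for scoring; when
#'   simulating, the planted truth sets are used by default
#' @param config configuration overrides passed to
#'   [run_supervised_integration()]
#' @param seed master seed
#' @return the result list of [run_supervised_integration()], invisibly,
#'   with `calls` and `metrics` added when scoring ran
#' @export
run_pipeline <- function(metadata = NULL, out_dir, simulate = FALSE,
                         gmt = NULL, config = list(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- seed
  sets <- NULL
  if (simulate) {
    .log_stage("simulate: generating the default 3-batch benchmark")
    sim <- default_benchmark(seed = seed)
    samples <- split_by_sample(sim$counts)
    sets <- truth_gene_sets(sim$truth)
    config$qc <- config$qc %||% qc_thresholds(min_umi = 500, min_genes = 200)
  } else {
    if (is.null(metadata)) stop("either metadata or simulate=TRUE is required")
    md <- read_sample_metadata(metadata)
    if (nrow(md) < 2) stop("integration requires >= 2 samples")
    if (is.null(md$path)) stop("metadata needs a 'path' column of 10x directories")
    .log_stage("ingest: reading %d samples", nrow(md))
    samples <- lapply(seq_len(nrow(md)), function(i) {
      x <- read_10x_matrix(md$path[i], sample = md$sample_id[i])
      x$tissue_of_sample <- setNames(md$tissue[i], md$sample_id[i])
      x
    })
    names(samples) <- md$sample_id
    qc_cols <- intersect(c("min_umi", "max_umi", "min_genes", "max_genes",
                           "max_mito_fraction"), names(md))
    if (length(qc_cols) && is.null(config$qc)) {
      config$qc <- setNames(lapply(seq_len(nrow(md)), function(i)
        do.call(qc_thresholds, as.list(md[i, qc_cols]))), md$sample_id)
    }
  }
  if (!is.null(gmt)) sets <- read_gmt(gmt)
  .log_stage("integrate: %d samples", length(samples))
  res <- run_supervised_integration(samples, config = config)
  .write_tsv(data.frame(cell = rownames(res$pca$coords), res$pca$coords),
             file.path(out_dir, "embedding_pca.tsv"))
  .write_tsv(data.frame(cell = rownames(res$corrected$coords),
                        res$corrected$coords),
             file.path(out_dir, "embedding_corrected.tsv"))
  .write_tsv(res$meta$assignment, file.path(out_dir, "meta_clusters.tsv"))
  .write_tsv(as.data.frame(unclass(res$match)),
             file.path(out_dir, "match_matrix.tsv"), row_names = TRUE)
  clusters_df <- data.frame(cell = cell_ids(res$merged),
                            sample = res$merged$sample_of_cell,
                            cluster = unlist(lapply(res$per_sample,
                                                    function(p) p$clusters$labels),
                                             use.names = FALSE))
  .write_tsv(clusters_df, file.path(out_dir, "clusters.tsv"))
  .write_tsv(do.call(rbind, res$markers), file.path(out_dir, "markers.tsv"))
  if (!is.null(sets)) {
    .log_stage("score: %d gene sets", length(sets))
    sc <- aucell_score(res$norm, sets, seed = seed)
    calls <- classify_lineage(sc)
    .write_tsv(calls, file.path(out_dir, "lineage_calls.tsv"))
    .write_tsv(lineage_composition(calls, res$merged$sample_of_cell),
               file.path(out_dir, "composition.tsv"))
    .log_stage("metrics: kBET / LISI before and after correction")
    before <- integration_metrics(res$pca, res$merged$sample_of_cell,
                                  calls$label, seed = seed)
    after <- integration_metrics(res$corrected, res$merged$sample_of_cell,
                                 calls$label, seed = seed)
    metrics <- list(before = list(median_ilisi = before$median_ilisi,
                                  median_clisi = before$median_clisi,
                                  kbet_mean = before$kbet$mean_acceptance),
                    after = list(median_ilisi = after$median_ilisi,
                                 median_clisi = after$median_clisi,
                                 kbet_mean = after$kbet$mean_acceptance))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$calls <- calls
    res$metrics <- metrics
  }
  write_manifest(res$manifest, file.path(out_dir, "manifest.json"))
  .log_stage("done: artifacts in %s", out_dir)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
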