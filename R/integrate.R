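# GSEA-driven cross-sample cluster matching -> meta-clusters -> per-cell
# cluster priors -> diversity-penalised soft-clustering batch correction.
# This is the supervised integration path: per-sample marker gene sets are
# assembled into a database, every cluster's ranked marker list is scored
# against every set by preranked GSEA, the resulting match-score matrix is
# cut into meta-clusters, and the meta-cluster membership supplies the prior
# probabilities that steer the correction step.

.sc_name <- function(sample, cluster) paste(sample, cluster, sep = "|")

.parse_sc_name <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  data.frame(sample = vapply(parts, `[[`, "", 1),
             cluster = vapply(parts, function(p) paste(p[-1], collapse = "|"), ""))
}

#' Build the per-cluster marker gene-set database
#'
#' One gene set per (sample, cluster), named `"sample|cluster"`, holding
#' that cluster's significant up-regulated markers (`is_marker` and
#' positive log2 fold change), capped at the top `top_n` by rank score.
#' Clusters with fewer than `min_markers` usable markers are excluded with
#' a warning; a sample contributing no usable cluster is an error.
#'
#' @param markers_by_sample named list of `MarkerTable`s, one per sample
#' @param min_markers minimum usable markers per cluster (default 5)
#' @param top_n marker cap per set (default 100)
#' @return a [GeneSetCollection]
#' @export
build_cluster_geneset_db <- function(markers_by_sample, min_markers = 5,
                                     top_n = 100) {
  stopifnot(is.list(markers_by_sample), !is.null(names(markers_by_sample)))
  sets <- list(); prov <- character(0)
  for (s in names(markers_by_sample)) {
    mk <- markers_by_sample[[s]]
    usable <- 0
    for (cl in unique(mk$cluster)) {
      sub <- mk[mk$cluster == cl & mk$is_marker & mk$log2fc > 0, ]
      if (nrow(sub) < min_markers) {
        warning(sprintf("cluster %s of sample %s has %d markers (< %d); excluded",
                        cl, s, nrow(sub), min_markers))
        next
      }
      sub <- sub[order(-sub$rank_score), ]
      nm <- .sc_name(s, cl)
      sets[[nm]] <- utils::head(sub$gene, top_n)
      prov <- c(prov, sprintf("top markers of cluster %s in sample %s", cl, s))
      usable <- usable + 1
    }
    if (usable == 0)
      stop("sample '", s, "' contributed no cluster with >= ", min_markers,
           " markers; cannot build the matching database", call. = FALSE)
  }
  GeneSetCollection(sets, provenance = prov)
}

#' Cross-sample cluster-matching score matrix
#'
#' For every (sample, cluster), preranked GSEA of its full ranked marker
#' list is run against every gene set in the database. An entry is the
#' positive NES where `p_adj < padj_cutoff`, else 0, so the matrix is
#' non-negative; self-sample columns are retained (the self-match acts as a
#' scale anchor). Rows cover all clusters with a marker table; columns are
#' the database sets.
#'
#' @param markers_by_sample named list of `MarkerTable`s
#' @param db the [GeneSetCollection] from [build_cluster_geneset_db()]
#' @param n_perm,seed permutation settings (row `i` uses `seed + i`)
#' @param padj_cutoff significance cutoff (default 0.25)
#' @param stat `"nes"` (default, normalises for set size) or `"es"`
#' @return a numeric `MatchScoreMatrix` (rows: sample-clusters, cols: db
#'   sets)
#' @export
compute_match_matrix <- function(markers_by_sample, db, n_perm = 1000,
                                 seed = 1, padj_cutoff = 0.25,
                                 stat = c("nes", "es")) {
  stat <- match.arg(stat)
  rows <- unlist(lapply(names(markers_by_sample), function(s)
    .sc_name(s, unique(markers_by_sample[[s]]$cluster))))
  mat <- matrix(0, length(rows), length(db$sets),
                dimnames = list(rows, names(db$sets)))
  i <- 0
  for (s in names(markers_by_sample)) {
    for (cl in unique(markers_by_sample[[s]]$cluster)) {
      i <- i + 1
      ranked <- preranked_scores(markers_by_sample[[s]], cl)
      res <- suppressWarnings(
        gsea_preranked(ranked, db, n_perm = n_perm, seed = seed + i))
      val <- if (stat == "nes") res$nes else res$es
      keep <- val > 0 & res$p_adj < padj_cutoff
      if (any(keep)) mat[.sc_name(s, cl), res$set_name[keep]] <- val[keep]
    }
  }
  class(mat) <- c("MatchScoreMatrix", class(mat))
  mat
}

#' Group sample-clusters into meta-clusters
#'
#' Hierarchical clustering (average linkage) of the match-matrix rows under
#' correlation distance of their score profiles. The tree is cut at the
#' number of groups `k` maximising the mean silhouette width over
#' `k` between the largest per-sample cluster count and the number of
#' sample-clusters (singleton partitions score 0). Meta-clusters spanning a
#' single sample are flagged `"unique"`, the rest `"common"`.
#'
#' @param match a `MatchScoreMatrix`
#' @return a `MetaClusterMap`: list with `assignment` (data.frame `sample`,
#'   `cluster`, `meta`), `status` (per meta-cluster `"common"`/`"unique"`),
#'   `k`, and the silhouette profile `silhouette_by_k`
#' @export
match_clusters <- function(match) {
  stopifnot(is.matrix(match), all(match >= 0))
  n <- nrow(match)
  info <- .parse_sc_name(rownames(match))
  if (all(match == 0)) {
    warning("all-zero match matrix: every sample-cluster is unique")
    meta <- seq_len(n)
    assignment <- cbind(info, meta = meta)
    status <- setNames(rep("unique", n), seq_len(n))
    return(structure(list(assignment = assignment, status = status, k = n,
                          silhouette_by_k = NULL),
                     class = "MetaClusterMap"))
  }
  cm <- suppressWarnings(cor(t(match)))
  cm[!is.finite(cm)] <- 0                   # zero-variance profiles
  d <- as.dist(1 - cm)
  hc <- hclust(d, method = "average")
  kmin <- max(table(info$sample))
  kmax <- n
  ks <- seq(max(2, min(kmin, kmax)), kmax)
  sil <- vapply(ks, function(k) {
    if (k >= n) return(0)                   # all singletons
    cut <- cutree(hc, k = k)
    mean(cluster::silhouette(cut, d)[, "sil_width"])
  }, 0)
  k <- ks[which.max(sil)]
  meta <- if (k >= n) seq_len(n) else cutree(hc, k = k)
  assignment <- cbind(info, meta = as.integer(meta))
  status <- vapply(sort(unique(assignment$meta)), function(m) {
    if (length(unique(assignment$sample[assignment$meta == m])) >= 2)
      "common" else "unique"
  }, "")
  names(status) <- sort(unique(assignment$meta))
  structure(list(assignment = assignment, status = status, k = k,
                 silhouette_by_k = setNames(sil, ks)),
            class = "MetaClusterMap")
}

#' @exportS3Method base::print
print.MetaClusterMap <- function(x, ...) {
  cat(sprintf("MetaClusterMap: %d sample-clusters -> %d meta-clusters (%d common, %d unique)\n",
              nrow(x$assignment), length(x$status),
              sum(x$status == "common"), sum(x$status == "unique")))
  invisible(x)
}

#' Per-cell prior probabilities over meta-clusters
#'
#' A cell whose sample-cluster maps to meta-cluster `m` receives
#' probability `confidence` on `m` and `(1 - confidence)/(M - 1)` on each
#' of the other `M - 1` meta-clusters; rows sum to one. With
#' `confidence = 1/M` the prior is uniform and the supervised correction
#' reduces exactly to the unsupervised one.
#'
#' @param meta a `MetaClusterMap`
#' @param sample_of_cell,cluster_of_cell per-cell sample label and
#'   (within-sample) cluster label
#' @param confidence prior mass on the own meta-cluster (default 0.9)
#' @return a `PriorMatrix`: numeric matrix cells x meta-clusters with
#'   attribute `confidence`
#' @export
build_prior_matrix <- function(meta, sample_of_cell, cluster_of_cell,
                               confidence = 0.9) {
  stopifnot(is(meta, "MetaClusterMap"),
            length(sample_of_cell) == length(cluster_of_cell),
            confidence > 0, confidence <= 1)
  key <- .sc_name(sample_of_cell, cluster_of_cell)
  map_key <- .sc_name(meta$assignment$sample, meta$assignment$cluster)
  idx <- match(key, map_key)
  if (anyNA(idx))
    stop("cells belong to sample-clusters absent from the meta-cluster map: ",
         paste(utils::head(unique(key[is.na(idx)]), 5), collapse = ", "))
  metas <- sort(unique(meta$assignment$meta))
  M <- length(metas)
  m_of_cell <- match(meta$assignment$meta[idx], metas)
  if (M == 1) {
    p <- matrix(1, length(key), 1)
  } else {
    p <- matrix((1 - confidence) / (M - 1), length(key), M)
    p[cbind(seq_along(key), m_of_cell)] <- confidence
  }
  colnames(p) <- paste0("meta", metas)
  class(p) <- c("PriorMatrix", class(p))
  attr(p, "confidence") <- confidence
  p
}

#' Parameters of the diversity-penalised soft-clustering correction
#'
#' @param K number of soft clusters; `NULL` means `ncol(prior)` when a
#'   prior is supplied, else `min(100, floor(n/30))`
#' @param sigma entropy temperature of the soft assignment (default 0.1)
#' @param theta diversity-penalty strength (default 2)
#' @param lambda ridge strength of the per-cluster correction (default 1;
#'   the intercept is never penalised)
#' @param max_iter,tol outer-loop control: stop when the mean absolute
#'   change in soft assignments falls below `tol` (default 1e-4) or after
#'   `max_iter` iterations (default 20)
#' @param prior_weight exponent `w` with which the prior enters the
#'   assignment step multiplicatively (default 0.9)
#' @param seed integer seed for the centroid initialisation
#' @return list of class `harmony_params`
#' @export
harmony_params <- function(K = NULL, sigma = 0.1, theta = 2, lambda = 1,
                           max_iter = 20, tol = 1e-4, prior_weight = 0.9,
                           seed = 1) {
  stopifnot(sigma > 0, theta >= 0, lambda > 0, max_iter >= 1, tol > 0,
            prior_weight > 0, prior_weight <= 1)
  structure(list(K = K, sigma = sigma, theta = theta, lambda = lambda,
                 max_iter = max_iter, tol = tol,
                 prior_weight = prior_weight, seed = seed),
            class = "harmony_params")
}

.row_normalize <- function(m) {
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  m / rs
}

.unit_rows <- function(m) {
  rn <- sqrt(rowSums(m^2))
  rn[rn == 0] <- 1
  m / rn
}

#' Diversity-penalised soft-clustering batch correction with cluster priors
#'
#' Iterative two-step correction in embedding space. (1) Cells are softly
#' assigned to `K` clusters by cosine distance to the cluster centroids
#' with entropy temperature `sigma`; each assignment is multiplied by a
#' diversity factor `((E+1)/(O+1))^theta` penalising clusters whose batch
#' composition deviates from the global one, and - when a prior is supplied
#' - by `prior^w`; rows are then renormalised. (2) Per cluster, batch and
#' covariate effects are removed from the original embedding by
#' ridge-regularised weighted linear regression (penalty `lambda` on all
#' design columns except the intercept, whose contribution is never
#' subtracted). The loop repeats until the mean absolute change in
#' assignments drops below `tol`. Cosine distances are computed on the
#' column-centred embedding, which makes the whole correction exactly
#' translation-equivariant. With a single batch and no covariates the input
#' is returned unchanged.
#'
#' @param embedding an [Embedding] (or matrix), cells x d
#' @param batch batch label per cell
#' @param covariates optional data.frame / vector of additional categorical
#'   covariates (e.g. donor)
#' @param prior optional `PriorMatrix` (cells x K); forces `K = ncol(prior)`
#' @param params a [harmony_params()] object
#' @return an [Embedding] named `"harmony"` with attributes `iterations`,
#'   `delta` (final assignment change) and `R` (final soft assignments)
#' @export
harmony_correct <- function(embedding, batch, covariates = NULL,
                            prior = NULL, params = harmony_params()) {
  z0 <- if (is(embedding, "Embedding")) embedding$coords else as.matrix(embedding)
  if (!all(is.finite(z0))) stop("embedding contains non-finite values")
  n <- nrow(z0)
  batch <- factor(batch)
  stopifnot(length(batch) == n)
  cov_df <- NULL
  if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)
    cov_df <- cov_df[, vapply(cov_df, function(v) length(unique(v)) > 1, TRUE),
                     drop = FALSE]
    if (!ncol(cov_df)) cov_df <- NULL
  }
  if (nlevels(batch) < 2 && is.null(cov_df)) {
    out <- Embedding(z0, name = "harmony")
    attr(out, "iterations") <- 0L
    attr(out, "delta") <- 0
    return(out)
  }
  K <- if (!is.null(prior)) ncol(prior)
       else if (!is.null(params$K)) params$K
       else max(2L, min(100L, floor(n / 30)))
  if (!is.null(prior)) {
    stopifnot(nrow(prior) == n)
    log_prior_w <- params$prior_weight * log(pmax(unclass(prior), 1e-12))
  }
  # design: intercept + batch dummies (+ covariate dummies); ridge on all
  # non-intercept columns
  df <- data.frame(batch = batch)
  if (!is.null(cov_df)) df <- cbind(df, lapply(cov_df, factor))
  phi <- model.matrix(~ ., data = df)
  pen <- rep(params$lambda, ncol(phi)); pen[1] <- 0
  b_idx <- as.integer(batch)
  b_freq <- as.numeric(table(batch)) / n
  zc <- z0
  r_prev <- NULL
  iters <- 0L; delta <- Inf
  for (it in seq_len(params$max_iter)) {
    iters <- it
    y <- .unit_rows(sweep(zc, 2, colMeans(zc)))
    if (it == 1) {
      set.seed(params$seed)
      uniq <- !duplicated(round(y, 10))
      if (sum(uniq) < K) {
        cent <- y[sample(which(uniq), sum(uniq)), , drop = FALSE]
        cent <- cent[rep_len(seq_len(nrow(cent)), K), , drop = FALSE]
      } else {
        cent <- kmeans(y, centers = K, iter.max = 25, nstart = 2)$centers
      }
    }
    d2 <- 2 * (1 - y %*% t(.unit_rows(cent)))          # n x K
    logr <- -d2 / params$sigma
    logr <- logr - apply(logr, 1, max)                 # numeric stability
    rm0 <- .row_normalize(exp(logr))
    if (params$theta > 0 && nlevels(batch) > 1) {
      o <- t(rm0) %*% (diag(nlevels(batch))[b_idx, , drop = FALSE])  # K x B
      e <- colSums(rm0) %o% b_freq
      penalty <- ((e + 1) / (o + 1))^params$theta      # K x B
      rm <- rm0 * t(penalty)[b_idx, , drop = FALSE]
    } else rm <- rm0
    if (!is.null(prior)) rm <- rm * exp(log_prior_w)
    r <- .row_normalize(rm)
    cent <- t(r) %*% y
    if (!is.null(r_prev)) {
      delta <- mean(abs(r - r_prev))
      if (delta < params$tol) { r_prev <- r; break }
    }
    r_prev <- r
    # correction step: remove batch/covariate effects per soft cluster
    corr <- matrix(0, n, ncol(z0))
    for (k in seq_len(K)) {
      rw <- r[, k]
      phir <- phi * rw
      a <- crossprod(phi, phir) + diag(pen, ncol(phi))
      wk <- solve(a, crossprod(phir, z0))
      wk[1, ] <- 0                                     # keep cluster centroid
      corr <- corr + phir %*% wk
    }
    zc <- z0 - corr
  }
  dimnames(zc) <- dimnames(z0)
  out <- Embedding(zc, name = "harmony")
  attr(out, "iterations") <- iters
  attr(out, "delta") <- delta
  attr(out, "R") <- r_prev
  out
}

# One sample through QC -> normalisation -> HVG -> PCA -> SNN/Louvain ->
# markers. Shared by the integration driver and the benchmark evaluator.
.process_sample <- function(x, s, cfg) {
  x <- filter_cells(x, if (is(cfg$qc, "qc_thresholds")) cfg$qc else cfg$qc[[s]])
  x <- filter_genes(x, cfg$min_cells_per_gene)
  if (n_cells(x) < 50)
    stop("sample '", s, "' has fewer than 50 cells after QC")
  norm <- normalize_counts(x)
  hvg <- select_hvg(norm, alpha = cfg$hvg_alpha)
  npc <- min(cfg$n_pcs, length(hvg$selected_genes) - 1, n_cells(x) - 1)
  pca <- run_pca(norm, hvg, n_pcs = npc)
  snn <- build_snn_graph(pca, k = min(cfg$knn_k, n_cells(x) - 1),
                         seed = cfg$seed)
  cl <- louvain_communities(snn, seed = cfg$seed, resolution = cfg$resolution)
  mk <- suppressWarnings(
    find_markers(norm, cl, log2fc_min = cfg$log2fc_min,
                 padj_max = cfg$padj_max, freq_min = cfg$freq_min))
  list(filtered = x, clusters = cl, markers = mk,
       hvg_n = length(hvg$selected_genes))
}

#' End-to-end GSEA-supervised integration of multiple samples
#'
#' Orchestrates the full pipeline: per-sample QC filtering, normalisation,
#' HVG selection, PCA, SNN/Louvain clustering and marker detection; then
#' cross-sample cluster matching by preranked GSEA, meta-cluster
#' identification, prior construction, and the supervised correction of the
#' joint PCA embedding (batch = sample; tissue enters as a covariate when
#' informative).
#'
#' @param samples named list of single-sample [CountMatrix] objects, or one
#'   multi-sample [CountMatrix] (split internally); at least 2 samples
#' @param config named list overriding defaults: `qc` ([qc_thresholds()] or
#'   per-sample list), `min_cells_per_gene` (10), `hvg_alpha` (0.05),
#'   `n_pcs` (40), `knn_k` (30), `resolution` (1), `log2fc_min` (1.5),
#'   `padj_max` (0.05), `freq_min` (0.3), `n_perm` (1000),
#'   `prior_confidence` (0.9), `harmony` ([harmony_params()]), `seed` (1)
#' @return list with elements `pca` (joint embedding before correction),
#'   `corrected` (after), `meta` (`MetaClusterMap`), `match`
#'   (`MatchScoreMatrix`), `prior`, `merged` (joint filtered
#'   [CountMatrix]), `norm` (joint `NormalizedMatrix`), `per_sample`
#'   (clusters, markers, cell ids per sample) and `manifest`
#' @export
run_supervised_integration <- function(samples, config = list()) {
  if (is(samples, "CountMatrix")) samples <- split_by_sample(samples)
  if (length(samples) < 2) stop("integration requires >= 2 samples")
  if (is.null(names(samples)))
    names(samples) <- sprintf("sample%d", seq_along(samples))
  cfg <- modifyList(list(qc = qc_thresholds(), min_cells_per_gene = 10,
                         hvg_alpha = 0.05, n_pcs = 40, knn_k = 30,
                         resolution = 1, log2fc_min = 1.5, padj_max = 0.05,
                         freq_min = 0.3, n_perm = 1000,
                         prior_confidence = 0.9,
                         harmony = harmony_params(), seed = 1),
                    config)
  t0 <- proc.time()[["elapsed"]]
  staged <- lapply(names(samples), function(s)
    .process_sample(samples[[s]], s, cfg))
  names(staged) <- names(samples)
  filtered <- lapply(staged, `[[`, "filtered")
  markers_by_sample <- lapply(staged, `[[`, "markers")
  per_sample <- lapply(staged, function(st)
    list(clusters = st$clusters, n_cells = n_cells(st$filtered),
         cell_ids = cell_ids(st$filtered), hvg_n = st$hvg_n))
  db <- build_cluster_geneset_db(markers_by_sample)
  match <- compute_match_matrix(markers_by_sample, db, n_perm = cfg$n_perm,
                                seed = cfg$seed)
  meta <- match_clusters(match)
  merged <- merge_count_matrices(filtered)
  cell_sample <- merged$sample_of_cell
  cell_cluster <- unlist(lapply(names(per_sample), function(s)
    per_sample[[s]]$clusters$labels), use.names = FALSE)
  prior <- build_prior_matrix(meta, cell_sample, cell_cluster,
                              confidence = cfg$prior_confidence)
  norm_j <- normalize_counts(merged)
  hvg_j <- select_hvg(norm_j, alpha = cfg$hvg_alpha)
  npc <- min(cfg$n_pcs, length(hvg_j$selected_genes) - 1,
             n_cells(merged) - 1)
  pca_j <- run_pca(norm_j, hvg_j, n_pcs = npc)
  hp <- cfg$harmony
  hp$seed <- cfg$seed
  tissue <- if (!is.null(merged$tissue_of_sample))
    unname(merged$tissue_of_sample[cell_sample]) else NULL
  covar <- if (!is.null(tissue) && length(unique(tissue)) > 1)
    data.frame(tissue = tissue) else NULL
  corrected <- harmony_correct(pca_j, batch = cell_sample,
                               covariates = covar, prior = prior,
                               params = hp)
  manifest <- list(samples = names(samples),
                   n_cells = vapply(per_sample, `[[`, 0, "n_cells"),
                   n_meta_clusters = length(meta$status),
                   parameters = cfg[setdiff(names(cfg), c("qc", "harmony"))],
                   harmony = unclass(hp), seed = cfg$seed,
                   elapsed_sec = proc.time()[["elapsed"]] - t0)
  list(pca = pca_j, corrected = corrected, meta = meta, match = match,
       prior = prior, merged = merged, norm = norm_j,
       per_sample = per_sample, markers = markers_by_sample,
       manifest = manifest)
}
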