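# Cosine kNN graph with shared-nearest-neighbour weights, and Louvain
# community detection on the weighted graph.

# Exact cosine kNN, computed block-wise to bound memory. Returns an n x k
# matrix of neighbour indices (self excluded); ties in similarity are broken
# by ascending cell index for determinism.
.cosine_knn <- function(coords, k, block = 1024L) {
  n <- nrow(coords)
  rn <- sqrt(rowSums(coords^2))
  rn[rn == 0] <- 1
  y <- coords / rn
  nn <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    sim <- y[idx, , drop = FALSE] %*% t(y)      # |idx| x n
    for (r in seq_along(idx)) {
      i <- idx[r]
      s <- sim[r, ]
      s[i] <- -Inf                              # exclude self
      ord <- order(-s, seq_len(n))              # ties -> ascending index
      nn[i, ] <- ord[seq_len(k)]
    }
  }
  nn
}

#' Build a shared-nearest-neighbour graph
#'
#' For each cell the `k` nearest neighbours under cosine distance are found
#' (exact search). Any pair of cells `i, j` is connected with weight
#' `|N(i) intersect N(j)| / k`, the normalised shared-neighbour count;
#' zero-weight pairs are dropped, and optionally edges with weight at or
#' below `prune` as well. The graph is undirected with no self edges and
#' weights in \[0, 1\].
#'
#' @param embedding an [Embedding] (or numeric matrix) of cell coordinates
#' @param k neighbours per cell (default 30); must be `< #cells`
#' @param seed kept for interface stability; the exact search is
#'   deterministic and does not consume randomness
#' @param prune drop edges with weight `<= prune` (default 0, i.e. only
#'   zero-weight pairs are dropped)
#' @return an `SNNGraph`: list with the `igraph` object `graph`, the
#'   neighbour index matrix `nn`, `k` and `metric = "cosine"`
#' @export
build_snn_graph <- function(embedding, k = 30, seed = 1, prune = 0) {
  coords <- if (is(embedding, "Embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  if (k >= n) stop(sprintf("k=%d must be smaller than the number of cells (%d)", k, n))
  nn <- .cosine_knn(coords, k)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)             # (i,j) -> |N(i) ^ N(j)|
  diag(shared) <- 0
  shared <- Matrix::drop0(shared)
  w <- shared / k
  if (prune > 0) {
    w@x[w@x <= prune] <- 0
    w <- Matrix::drop0(w)
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(rownames(coords)))
    igraph::V(g)$name <- rownames(coords)
  structure(list(graph = g, nn = nn, k = k, metric = "cosine"),
            class = "SNNGraph")
}

#' @exportS3Method base::print
print.SNNGraph <- function(x, ...) {
  cat(sprintf("SNNGraph: %d cells, %d edges, k=%d (%s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$k, x$metric))
  invisible(x)
}

#' Louvain community detection on an SNN graph
#'
#' Multilevel modularity optimisation on the weighted graph, deterministic
#' for a fixed seed. Labels are relabelled to be contiguous `1..n_clusters`
#' in order of first appearance.
#'
#' @param graph an `SNNGraph` (or an `igraph` object with edge weights)
#' @param seed integer seed
#' @param resolution Louvain resolution parameter (default 1)
#' @return a `ClusterAssignment`: list with integer `labels`, `n_clusters`,
#'   `seed`, `resolution` and the weighted `modularity` of the partition
#' @export
louvain_communities <- function(graph, seed = 1, resolution = 1) {
  g <- if (is(graph, "SNNGraph")) graph$graph else graph
  if (!igraph::is_igraph(g) || igraph::vcount(g) == 0)
    stop("need a non-empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                resolution = resolution)
  memb <- igraph::membership(cl)
  labels <- as.integer(factor(memb, levels = unique(memb)))
  mod <- igraph::modularity(g, labels, weights = igraph::E(g)$weight)
  structure(list(labels = labels, n_clusters = max(labels),
                 seed = seed, resolution = resolution, modularity = mod),
            class = "ClusterAssignment")
}

#' @exportS3Method base::print
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells in %d clusters (modularity %.4f)\n",
              length(x$labels), x$n_clusters, x$modularity))
  invisible(x)
}

#' Weighted modularity of a labelling, recomputed from first principles
#'
#' Independent dense recomputation of the standard weighted-modularity
#' formula `Q = sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j) / 2m`; used to
#' audit the value reported by [louvain_communities()].
#'
#' @param graph an `SNNGraph` or weighted `igraph`
#' @param labels integer cluster label per vertex
#' @return modularity value
#' @export
modularity_from_labels <- function(graph, labels) {
  g <- if (is(graph, "SNNGraph")) graph$graph else graph
  a <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE)
  m2 <- sum(a)                                  # 2m
  if (m2 == 0) return(0)
  deg <- Matrix::rowSums(a)
  q <- 0
  for (c in unique(labels)) {
    idx <- which(labels == c)
    q <- q + sum(a[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
  }
  q
}
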