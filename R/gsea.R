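# Preranked GSEA: weighted Kolmogorov-Smirnov running-sum enrichment score
# (weight exponent 1), a gene-label permutation null with size-matched
# random sets, and the cluster-annotation matrix built from positive NES.

.order_ranked <- function(ranked) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  ranked[order(-ranked$score, ranked$gene), , drop = FALSE]
}

# Enrichment score evaluated only at hit positions: O(s) per evaluation.
# pos: sorted hit positions in the ranked list; w: |score| at those
# positions; N: ranked-list length. Exactly reproduces the extremum of the
# dense running sum (hits increment |score|/sum, misses decrement 1/(N-s));
# the dense curve is piecewise linear between hits, so its extrema lie
# immediately after a hit or immediately before the next one.
.es_from_hits <- function(pos, w, N) {
  s <- length(pos)
  miss <- 1 / (N - s)
  sw <- sum(w)
  cw <- if (sw > 0) cumsum(w) / sw else seq_len(s) / s
  gap <- (pos - seq_len(s)) * miss
  after <- cw - gap                         # value at position pos_j
  before <- c(0, cw[-s]) - gap              # value at position pos_j - 1
  vals <- c(before, after)
  at <- c(pos - 1L, pos)
  keep <- at >= 1L
  vals <- vals[keep]; at <- at[keep]
  o <- order(at)                            # dense which.max takes first index
  vals <- vals[o]; at <- at[o]
  vals[[which.max(abs(vals))]]
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Weighted Kolmogorov-Smirnov statistic with weight exponent 1: walking
#' down the ranked list, a gene in the set increments the running sum by
#' `|score| / sum(|score| over set)` and a gene outside decrements it by
#' `1 / (N - set size)`. The enrichment score is the signed maximum
#' deviation; the leading edge contains the set genes at or before the
#' extremum (positive score) or at or after it (negative score).
#'
#' @param ranked data.frame with columns `gene`, `score` (re-sorted
#'   defensively by decreasing score, ties lexicographic)
#' @param set character vector of gene symbols
#' @return list with `es`, the full `running` sum, `leading_edge`, the
#'   extremum position `peak`, and `undefined = TRUE` when the set does not
#'   intersect the ranked list or leaves no misses
#' @export
enrichment_score <- function(ranked, set) {
  ranked <- .order_ranked(ranked)
  N <- nrow(ranked)
  hit <- ranked$gene %in% set
  s <- sum(hit)
  if (s == 0 || s == N)
    return(list(es = NA_real_, running = NULL, leading_edge = character(0),
                peak = NA_integer_, undefined = TRUE))
  w <- abs(ranked$score)
  sw <- sum(w[hit])
  step <- ifelse(hit, if (sw > 0) w / sw else 1 / s, -1 / (N - s))
  step[hit & sw == 0] <- 1 / s
  running <- cumsum(step)
  peak <- which.max(abs(running))
  es <- running[[peak]]
  le <- if (es >= 0) ranked$gene[hit & seq_len(N) <= peak]
        else ranked$gene[hit & seq_len(N) >= peak]
  list(es = es, running = running, leading_edge = le, peak = peak,
       undefined = FALSE)
}

#' Preranked GSEA with a gene-label permutation null
#'
#' For each gene set, the observed enrichment score is compared to
#' `n_perm` scores of size-matched random gene sets drawn from the ranked
#' list. `p = (1 + #{same-sign |es_perm| >= |es|}) / (n_perm + 1)` and
#' `NES = es / mean(|es_perm|)` over same-sign permutations; when no
#' permutation shares the sign the NES is reported at the +/-10 sentinel
#' cap. P-values are BH-adjusted across sets. Sets with no gene in the
#' ranked list, or spanning the entire list, are skipped with a warning.
#'
#' @param ranked data.frame with columns `gene`, `score`
#' @param sets a [GeneSetCollection]
#' @param n_perm permutations (default 1000, minimum 100)
#' @param seed integer seed; results are exactly reproducible
#' @return data.frame with one row per scored set: `set_name`, `size`,
#'   `es`, `nes`, `p`, `p_adj`, `leading_edge` (comma-joined), `n_perm`,
#'   `seed`
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, seed = 1) {
  stopifnot(is(sets, "GeneSetCollection"), n_perm >= 100)
  ranked <- .order_ranked(ranked)
  N <- nrow(ranked)
  w_all <- abs(ranked$score)
  set.seed(seed)
  rows <- list()
  for (nm in names(sets$sets)) {
    pos <- sort(which(ranked$gene %in% sets$sets[[nm]]))
    s <- length(pos)
    if (s == 0 || s == N) {
      warning("set '", nm, "' skipped (", if (s == 0) "no overlap with"
              else "spans entire", " ranked list)")
      next
    }
    obs <- enrichment_score(ranked, sets$sets[[nm]])
    perm <- vapply(seq_len(n_perm), function(b) {
      idx <- sort.int(sample.int(N, s))
      .es_from_hits(idx, w_all[idx], N)
    }, 0)
    if (obs$es == 0) {
      p <- 1; nes <- 0
    } else {
      same <- perm * sign(obs$es) > 0
      p <- (1 + sum(same & abs(perm) >= abs(obs$es))) / (n_perm + 1)
      nes <- if (any(same)) obs$es / mean(abs(perm[same])) else sign(obs$es) * 10
      nes <- sign(nes) * min(abs(nes), 10)
    }
    rows[[nm]] <- data.frame(set_name = nm, size = s, es = obs$es,
                             nes = nes, p = p,
                             leading_edge = paste(obs$leading_edge,
                                                  collapse = ","),
                             n_perm = n_perm, seed = seed,
                             row.names = NULL)
  }
  if (!length(rows))
    return(data.frame(set_name = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      p_adj = numeric(0), leading_edge = character(0),
                      n_perm = integer(0), seed = integer(0)))
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  rownames(res) <- NULL
  res[, c("set_name", "size", "es", "nes", "p", "p_adj", "leading_edge",
          "n_perm", "seed")]
}

#' Cluster-annotation matrix of positive enrichment scores
#'
#' Runs preranked GSEA of every cluster's ranked marker scores against a
#' curated gene-set collection and assembles the clusters x sets matrix of
#' positive NES at `p_adj < padj_cutoff` (0.25 by default, the usual GSEA
#' exploration cutoff); all other entries are 0, so the matrix is
#' non-negative. Row order follows cluster id.
#'
#' @param markers a `MarkerTable` covering all clusters
#' @param curated a [GeneSetCollection] of curated signatures
#' @param n_perm,seed passed to [gsea_preranked()] (each cluster uses
#'   `seed + row index` so rows are independent but reproducible)
#' @param padj_cutoff significance cutoff for retaining a positive NES
#' @return numeric matrix, clusters x sets
#' @export
annotate_clusters <- function(markers, curated, n_perm = 1000, seed = 1,
                              padj_cutoff = 0.25) {
  cl_ids <- unique(markers$cluster)
  cl_ids <- cl_ids[order(suppressWarnings(as.numeric(cl_ids)), cl_ids)]
  mat <- matrix(0, length(cl_ids), length(curated$sets),
                dimnames = list(cl_ids, names(curated$sets)))
  for (i in seq_along(cl_ids)) {
    ranked <- preranked_scores(markers, cl_ids[i])
    res <- suppressWarnings(
      gsea_preranked(ranked, curated, n_perm = n_perm, seed = seed + i))
    keep <- res$nes > 0 & res$p_adj < padj_cutoff
    if (any(keep)) mat[i, res$set_name[keep]] <- res$nes[keep]
  }
  mat
}
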