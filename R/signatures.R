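# Gene-signature scoring: rank-AUC (AUCell-style) and mean-expression
# scores, threshold-based lineage classification and group comparisons.

#' Rank-AUC signature scores (AUCell-style)
#'
#' Per cell, genes are ranked by decreasing expression; ties are broken by
#' a fixed gene order obtained from one seeded global shuffle, so the score
#' is invariant to any monotone transformation of a cell's values. The
#' recovery curve of a set's genes over the top `ceil(rank_fraction * N)`
#' ranks is integrated and normalised by the maximal area achievable by a
#' same-size set fully front-loaded, giving an AUC in \[0, 1\].
#'
#' @param norm a `NormalizedMatrix`
#' @param sets a [GeneSetCollection]
#' @param rank_fraction top fraction of the ranking integrated (default
#'   0.05; must be in (0, 0.5\])
#' @param seed seed for the tie-breaking shuffle
#' @return a `SignatureScores`: list with `auc` (cells x sets),
#'   `mean_score = NULL`, `rank_fraction`, `threshold_rank`
#' @export
aucell_score <- function(norm, sets, rank_fraction = 0.05, seed = 1) {
  stopifnot(is(norm, "NormalizedMatrix"), is(sets, "GeneSetCollection"),
            rank_fraction > 0, rank_fraction <= 0.5)
  x <- norm$values
  n <- nrow(x); N <- ncol(x)
  thr <- as.integer(ceiling(rank_fraction * N))
  set.seed(seed)
  tiebreak <- sample.int(N)                     # one global shuffle
  set_idx <- lapply(sets$sets, function(g) {
    i <- match(g, colnames(x))
    i[!is.na(i)]
  })
  empty <- lengths(set_idx) == 0
  if (any(empty))
    warning("set(s) with no gene in the panel score 0: ",
            paste(names(sets$sets)[empty], collapse = ", "))
  max_area <- vapply(lengths(set_idx), function(s) {
    if (s == 0) return(1)
    s_eff <- min(s, thr)
    s_eff * (s_eff + 1) / 2 + (thr - s_eff) * s_eff
  }, 0)
  auc <- matrix(0, n, length(set_idx),
                dimnames = list(rownames(x), names(sets$sets)))
  xt <- Matrix::t(x)                            # genes x cells: fast columns
  for (i in seq_len(n)) {
    xi <- xt[, i]
    ord <- order(-xi, tiebreak)
    rank_of_gene <- integer(N)
    rank_of_gene[ord] <- seq_len(N)
    for (j in seq_along(set_idx)) {
      if (empty[j]) next
      h <- rank_of_gene[set_idx[[j]]]
      h <- h[h <= thr]
      if (length(h)) auc[i, j] <- sum(thr - h + 1) / max_area[j]
    }
  }
  structure(list(auc = auc, mean_score = NULL,
                 rank_fraction = rank_fraction, threshold_rank = thr),
            class = "SignatureScores")
}

#' Mean-expression signature scores
#'
#' Per cell, the arithmetic mean of the normalised log expression over each
#' set's genes present in the panel.
#'
#' @param norm a `NormalizedMatrix`
#' @param sets a [GeneSetCollection]
#' @return a `SignatureScores` with the `mean_score` matrix filled in
#' @export
mean_signature_score <- function(norm, sets) {
  stopifnot(is(norm, "NormalizedMatrix"), is(sets, "GeneSetCollection"))
  x <- norm$values
  ms <- matrix(0, nrow(x), length(sets$sets),
               dimnames = list(rownames(x), names(sets$sets)))
  for (j in seq_along(sets$sets)) {
    idx <- match(sets$sets[[j]], colnames(x))
    idx <- idx[!is.na(idx)]
    if (!length(idx)) {
      warning("set '", names(sets$sets)[j], "' has no gene in the panel")
      next
    }
    ms[, j] <- Matrix::rowSums(x[, idx, drop = FALSE]) / length(idx)
  }
  structure(list(auc = NULL, mean_score = ms, rank_fraction = NA_real_,
                 threshold_rank = NA_integer_),
            class = "SignatureScores")
}

#' @exportS3Method base::print
print.SignatureScores <- function(x, ...) {
  m <- if (!is.null(x$auc)) x$auc else x$mean_score
  cat(sprintf("SignatureScores: %d cells x %d sets (%s)\n", nrow(m), ncol(m),
              if (!is.null(x$auc)) sprintf("rank-AUC, top %.0f%%",
                                           100 * x$rank_fraction)
              else "mean expression"))
  invisible(x)
}

#' Classify cells into lineages by thresholded argmax signature score
#'
#' A cell is assigned the label of its maximum-scoring set among those with
#' a score strictly greater than `threshold`; cells with no score above
#' threshold are `"unclassified"`, and exact ties between top scores are
#' `"unclassified"` with the tie flag set.
#'
#' @param scores a `SignatureScores` (the `auc` matrix is used)
#' @param lineage_sets set names to consider (default: all scored sets)
#' @param threshold score cutoff, strict (default 0.15)
#' @return a `LineageCall`: data.frame with `cell`, `label`, `score`,
#'   `tie`; attribute `threshold`
#' @export
classify_lineage <- function(scores, lineage_sets = NULL, threshold = 0.15) {
  stopifnot(is(scores, "SignatureScores"), !is.null(scores$auc))
  m <- scores$auc
  if (!is.null(lineage_sets)) {
    miss <- setdiff(lineage_sets, colnames(m))
    if (length(miss)) stop("unscored set(s): ", paste(miss, collapse = ", "))
    m <- m[, lineage_sets, drop = FALSE]
  }
  top <- apply(m, 1, max)
  label <- colnames(m)[apply(m, 1, which.max)]
  tie <- apply(m, 1, function(r) sum(r == max(r)) > 1)
  label[top <= threshold | tie] <- "unclassified"
  out <- data.frame(cell = rownames(m), label = label, score = top,
                    tie = tie & top > threshold, row.names = NULL)
  attr(out, "threshold") <- threshold
  class(out) <- c("LineageCall", "data.frame")
  out
}

#' Per-group lineage composition table
#'
#' Counts and fractions of classified cells per lineage within each group
#' (e.g. batch or tissue).
#'
#' @param calls a `LineageCall`
#' @param groups group label per cell
#' @return data.frame with `group`, `label`, `n`, `fraction`
#' @export
lineage_composition <- function(calls, groups) {
  stopifnot(length(groups) == nrow(calls))
  tab <- table(group = groups, label = calls$label)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("group", "label", "n")
  tot <- tapply(df$n, df$group, sum)
  df$fraction <- df$n / as.numeric(tot[df$group])
  df[order(df$group, df$label), ]
}

#' Pairwise group comparison of signature scores
#'
#' Two-sided Wilcoxon rank-sum test per set and group pair, BH-adjusted
#' across all comparisons, with significance tiers at 0.05 / 0.01 / 0.001.
#' Groups with fewer than 3 cells are skipped.
#'
#' @param scores a `SignatureScores`
#' @param groups group label per cell
#' @return data.frame with `set`, `group1`, `group2`, `p`, `p_adj`, `tier`
#' @export
compare_group_scores <- function(scores, groups) {
  stopifnot(is(scores, "SignatureScores"))
  m <- if (!is.null(scores$auc)) scores$auc else scores$mean_score
  stopifnot(length(groups) == nrow(m))
  groups <- as.character(groups)
  sizes <- table(groups)
  use <- names(sizes)[sizes >= 3]
  if (length(use) < 2) stop("need >= 2 groups with >= 3 cells")
  pairs <- utils::combn(sort(use), 2)
  rows <- list()
  for (s in colnames(m)) for (q in seq_len(ncol(pairs))) {
    g1 <- pairs[1, q]; g2 <- pairs[2, q]
    p <- wilcoxon_rank_sum(m[groups == g1, s], m[groups == g2, s],
                           exact = FALSE)
    rows[[length(rows) + 1]] <- data.frame(set = s, group1 = g1,
                                           group2 = g2, p = p)
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$tier <- cut(res$p_adj, c(-Inf, 0.001, 0.01, 0.05, Inf),
                  labels = c("***", "**", "*", "ns"))
  res
}
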