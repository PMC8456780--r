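# Marker-gene statistics: Wilcoxon rank-sum on log-normalised expression,
# Fisher's exact test on expressing-cell frequencies, the two combined by
# Fisher's method (chi-square, 4 df), BH adjustment, marker thresholds and
# the GSEA pre-ranking score.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both groups have at most 8 observations and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction. The switch can be forced with `exact`.
#'
#' @param a,b numeric vectors, both non-empty
#' @param exact logical or `NULL` (auto)
#' @return two-sided p-value
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- length(a) <= 8 && length(b) <= 8 && !ties
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided",
                exact = exact, correct = TRUE)$p.value)
}

# Vectorised normal-approximation rank-sum p for one cluster-vs-rest split.
# ranksum_in: per-gene sum of (whole-panel) ranks over in-cluster cells;
# tie_term: per-gene sum(t^3 - t) over tie groups. Matches
# wilcox.test(exact = FALSE, correct = TRUE).
.wilcox_vec <- function(ranksum_in, n_in, n_out, tie_term) {
  u <- ranksum_in - n_in * (n_in + 1) / 2
  z <- u - n_in * n_out / 2
  n <- n_in + n_out
  sigma <- sqrt((n_in * n_out / 12) * ((n + 1) - tie_term / (n * (n - 1))))
  z <- (z - sign(z) * 0.5) / sigma
  p <- 2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE))
  p[!is.finite(z)] <- 1                        # sigma == 0: constant gene
  pmin(p, 1)
}

#' Two-sided Fisher's exact test on a 2x2 expressing-frequency table
#'
#' Tests whether the fraction of expressing cells (raw count > 0) differs
#' between a cluster and the remaining cells. Two-sided in the usual sense:
#' the p-value sums the probabilities of all tables at most as probable as
#' the observed one under the hypergeometric null.
#'
#' @param n_expr_in expressing cells in the cluster
#' @param n_in cluster size
#' @param n_expr_out expressing cells outside
#' @param n_out size of the complement
#' @return two-sided p-value
#' @export
fisher_exact_frequency <- function(n_expr_in, n_in, n_expr_out, n_out) {
  if (n_expr_in > n_in || n_expr_out > n_out ||
      any(c(n_expr_in, n_in, n_expr_out, n_out) < 0))
    stop("inconsistent counts: expressing cells cannot exceed group size")
  m <- n_expr_in + n_expr_out                   # expressing in the population
  if (m == 0 || m == n_in + n_out) return(1)    # degenerate table
  supp <- max(0, m - n_out):min(m, n_in)
  d <- dhyper(supp, m, n_in + n_out - m, n_in)
  obs <- dhyper(n_expr_in, m, n_in + n_out - m, n_in)
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Combine two p-values with Fisher's method
#'
#' `X = -2(ln p1 + ln p2)` referred to the upper tail of a chi-square with
#' 4 degrees of freedom, which has the closed form `exp(-X/2)(1 + X/2)`.
#' Zeros are floored at 1e-300 before taking logs. Vectorised.
#'
#' @param p1,p2 p-values in (0, 1\]
#' @return combined p-value(s)
#' @export
combine_fisher <- function(p1, p2) {
  p1 <- pmax(p1, 1e-300); p2 <- pmax(p2, 1e-300)
  x <- -2 * (log(p1) + log(p2))
  pchisq(x, df = 4, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH with monotonicity enforcement, capped at 1.
#'
#' @param p vector of p-values in \[0, 1\]
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

# Tie term sum(t^3 - t) for one numeric vector (whole panel of cells).
.tie_term <- function(x) {
  r <- rle(sort(x))$lengths
  sum(r^3 - r)
}

#' Identify cluster marker genes with the combined rank/frequency statistic
#'
#' Each cluster is compared to all other cells. Per gene: a Wilcoxon
#' rank-sum test on the log-normalised values (vectorised normal
#' approximation with tie and continuity correction), a Fisher's exact test
#' on the expressing-cell frequencies, the two p-values combined by
#' Fisher's method (4 df) and BH-adjusted across genes within the cluster.
#' The fold change is
#' `log2((mean de-logged expression in cluster + pseudocount) /
#'        (mean outside + pseudocount))`.
#' A gene is flagged as a marker when `|log2fc| >= log2fc_min`,
#' `p_adj < padj_max` and `freq_in > freq_min` (defaults 1.5 / 0.05 / 0.3;
#' the frequency cutoff is strict). Markers are ranked by `p_adj`, then
#' `|log2fc|`. Clusters with fewer than `min_cluster_size` cells are
#' skipped with a warning.
#'
#' @param norm a `NormalizedMatrix`
#' @param clusters a `ClusterAssignment` or an integer/character label per
#'   cell
#' @param log2fc_min,padj_max,freq_min marker cutoffs
#' @param pseudocount added to both means before the ratio (default 1)
#' @param min_cluster_size smallest testable cluster (default 3)
#' @return a `MarkerTable`: data.frame with one row per (cluster, gene) and
#'   columns `cluster`, `gene`, `log2fc`, `p_wilcoxon`, `p_fisher`,
#'   `p_combined`, `p_adj`, `freq_in`, `freq_out`, `rank_score`,
#'   `is_marker`
#' @export
find_markers <- function(norm, clusters, log2fc_min = 1.5, padj_max = 0.05,
                         freq_min = 0.3, pseudocount = 1,
                         min_cluster_size = 3) {
  stopifnot(is(norm, "NormalizedMatrix"))
  labels <- if (is(clusters, "ClusterAssignment")) clusters$labels else clusters
  stopifnot(length(labels) == nrow(norm$values))
  labels <- as.character(labels)
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_cluster_size]
  if (length(small)) {
    warning("skipping cluster(s) with fewer than ", min_cluster_size,
            " cells: ", paste(small, collapse = ", "))
  }
  use <- setdiff(names(sizes), small)
  if (length(use) < 2)
    stop("need at least 2 clusters of usable size")
  x <- norm$values
  n <- nrow(x); G <- ncol(x)
  fct <- factor(labels)
  # per-cluster expressing-cell counts and de-logged expression sums
  ind <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(fct), x = 1,
                              dims = c(n, nlevels(fct)),
                              dimnames = list(NULL, levels(fct)))
  xpos <- x
  xpos@x <- rep(1, length(xpos@x))
  expr_counts <- as.matrix(Matrix::crossprod(xpos, ind))   # G x C
  e <- .delog(norm)
  expr_sums <- as.matrix(Matrix::crossprod(e, ind))        # G x C
  tot_expr <- Matrix::colSums(e)
  tot_cnt <- Matrix::colSums(xpos)
  # whole-panel ranks: per-gene rank sums by cluster + tie terms
  ranksums <- matrix(0, G, nlevels(fct))
  tie_terms <- numeric(G)
  for (g in seq_len(G)) {
    xg <- x[, g]
    r <- rank(xg, ties.method = "average")
    rs <- rowsum(r, fct)
    ranksums[g, ] <- rs[, 1]
    tie_terms[g] <- .tie_term(xg)
  }
  out <- vector("list", length(use))
  names(out) <- use
  for (cl in use) {
    j <- match(cl, levels(fct))
    n_in <- sizes[[cl]]; n_out <- n - n_in
    mean_in <- expr_sums[, j] / n_in
    mean_out <- (tot_expr - expr_sums[, j]) / n_out
    log2fc <- log2((mean_in + pseudocount) / (mean_out + pseudocount))
    p_w <- .wilcox_vec(ranksums[, j], n_in, n_out, tie_terms)
    ein <- expr_counts[, j]
    eout <- tot_cnt - ein
    p_f <- vapply(seq_len(G), function(g)
      fisher_exact_frequency(ein[g], n_in, eout[g], n_out), 0)
    p_c <- combine_fisher(p_w, p_f)
    p_a <- bh_adjust(p_c)
    freq_in <- ein / n_in
    freq_out <- eout / n_out
    rank_score <- log2fc * (-log10(pmax(p_a, 1e-300)))
    df <- data.frame(cluster = cl, gene = colnames(x), log2fc = log2fc,
                     p_wilcoxon = p_w, p_fisher = p_f, p_combined = p_c,
                     p_adj = p_a, freq_in = freq_in, freq_out = freq_out,
                     rank_score = rank_score,
                     is_marker = abs(log2fc) >= log2fc_min &
                       p_a < padj_max & freq_in > freq_min,
                     row.names = NULL)
    out[[cl]] <- df[order(df$p_adj, -abs(df$log2fc)), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "thresholds") <- list(log2fc_min = log2fc_min,
                                  padj_max = padj_max, freq_min = freq_min,
                                  pseudocount = pseudocount)
  class(res) <- c("MarkerTable", "data.frame")
  res
}

#' Preranked gene list for GSEA from a marker table
#'
#' Scores are `log2fc * (-log10 p_adj)`, sorted in decreasing order with
#' ties broken lexicographically by gene symbol, so strong up-regulation
#' with small adjusted p sorts first and strong down-regulation last.
#'
#' @param markers a `MarkerTable`
#' @param cluster cluster id present in the table
#' @return data.frame with columns `gene`, `score`, ordered
#' @export
preranked_scores <- function(markers, cluster) {
  sub <- markers[markers$cluster == as.character(cluster), ]
  if (!nrow(sub)) stop("cluster '", cluster, "' not present in marker table")
  sub <- sub[order(-sub$rank_score, sub$gene), ]
  data.frame(gene = sub$gene, score = sub$rank_score, row.names = NULL)
}
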