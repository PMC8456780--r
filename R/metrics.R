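# Integration-quality metrics: kBET acceptance rate (chi-square test of
# local vs global batch composition) and LISI (inverse Simpson index of
# labels in perplexity-calibrated Gaussian neighbourhoods).

# Euclidean kNN indices among a fixed pool of points. Ties are broken by
# ascending index (deterministic) or, with random_ties = TRUE, by a fresh
# random ordering per query cell so that degenerate geometries (many
# coincident points) yield exchangeable neighbourhoods rather than one
# shared neighbour list.
.euclid_knn <- function(coords, k, random_ties = FALSE, block = 1024L) {
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  nn <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") -
      2 * coords[idx, , drop = FALSE] %*% t(coords)
    for (r in seq_along(idx)) {
      i <- idx[r]
      d <- d2[r, ]
      d[i] <- Inf
      tb <- if (random_ties) sample.int(n) else seq_len(n)
      ord <- order(d, tb)
      nn[i, ] <- ord[seq_len(k)]
    }
  }
  nn
}

#' kBET: acceptance rate of local batch composition
#'
#' Within each evaluated group (e.g. an annotated cell type), up to
#' `subsample` cells are drawn; for each, the batch composition of its `k0`
#' nearest neighbours (Euclidean, within the group) is tested against the
#' group's global batch composition with a chi-square goodness-of-fit test.
#' When any expected count falls below 5 the test falls back to a seeded
#' Monte-Carlo multinomial p-value (2,000 draws). The acceptance rate is
#' the fraction of tested cells with `p >= alpha`: near `1 - alpha` for
#' well-mixed batches and near 0 for separated ones. Groups with a single
#' batch accept trivially (rate 1); groups smaller than `k0 + 1` are
#' skipped with a warning.
#'
#' @param embedding an [Embedding] or matrix of coordinates
#' @param batch batch label per cell
#' @param group evaluation group label per cell (default: one group)
#' @param k0 neighbourhood size; default `min(ceil(0.1 * group size), 100)`
#' @param alpha significance level (default 0.05)
#' @param subsample cells tested per group (default 1000)
#' @param seed integer seed (subsampling, tie-breaking, Monte-Carlo)
#' @return a `MetricReport`-style list: `acceptance` (named per group),
#'   `mean_acceptance`, and `params`
#' @export
kbet_acceptance <- function(embedding, batch, group = NULL, k0 = NULL,
                            alpha = 0.05, subsample = 1000, seed = 1) {
  coords <- if (is(embedding, "Embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  batch <- factor(batch)
  stopifnot(length(batch) == n)
  if (is.null(group)) group <- rep("all", n)
  group <- as.character(group)
  set.seed(seed)
  acc <- c()
  for (g in sort(unique(group))) {
    idx <- which(group == g)
    bg <- droplevels(batch[idx])
    k0g <- if (is.null(k0)) min(ceiling(0.1 * length(idx)), 100) else k0
    if (length(idx) < k0g + 1) {
      warning("group '", g, "' smaller than k0+1; skipped")
      next
    }
    if (nlevels(bg) < 2) { acc[g] <- 1; next }
    p_global <- as.numeric(table(bg)) / length(idx)
    nn <- .euclid_knn(coords[idx, , drop = FALSE], k0g, random_ties = TRUE)
    tested <- if (length(idx) > subsample) sample(seq_along(idx), subsample)
              else seq_along(idx)
    pvals <- vapply(tested, function(r) {
      obs <- tabulate(as.integer(bg[nn[r, ]]), nbins = nlevels(bg))
      expected <- k0g * p_global
      if (any(expected < 5)) {
        suppressWarnings(chisq.test(obs, p = p_global,
                                    simulate.p.value = TRUE,
                                    B = 2000)$p.value)
      } else {
        suppressWarnings(chisq.test(obs, p = p_global)$p.value)
      }
    }, 0)
    acc[g] <- mean(pvals >= alpha)
  }
  list(acceptance = acc, mean_acceptance = mean(acc),
       params = list(k0 = k0, alpha = alpha, subsample = subsample,
                     seed = seed))
}

#' LISI: inverse Simpson index of labels in Gaussian neighbourhoods
#'
#' Per cell, weights over its `3 * perplexity` nearest neighbours are
#' calibrated by bisection on the Gaussian bandwidth so that the weight
#' entropy matches `log(perplexity)`; the score is the inverse Simpson
#' index of the weighted label distribution. With batch labels (iLISI) the
#' score approaches the number of batches for perfect mixing; with
#' cell-type labels (cLISI) it approaches 1 for pure neighbourhoods.
#'
#' @param embedding an [Embedding] or matrix
#' @param labels label per cell
#' @param perplexity target perplexity (default 30); a warning is given
#'   when fewer than `3 * perplexity` other cells exist
#' @return numeric vector of per-cell scores in `[1, #labels]`
#' @export
lisi <- function(embedding, labels, perplexity = 30) {
  coords <- if (is(embedding, "Embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  labels <- factor(labels)
  stopifnot(length(labels) == n)
  if (nlevels(labels) == 1) return(rep(1, n))
  k <- min(n - 1, 3 * perplexity)
  if (n - 1 < 3 * perplexity)
    warning("fewer than 3*perplexity cells; LISI may be unstable")
  nn <- .euclid_knn(coords, k)
  target <- log(perplexity)
  lab_int <- as.integer(labels)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((coords[nn[i, ], , drop = FALSE] -
                         matrix(coords[i, ], k, ncol(coords),
                                byrow = TRUE))^2))
    w <- .calibrate_gaussian(d, target)
    pl <- rowsum(w, lab_int[nn[i, ]])
    scores[i] <- 1 / sum(pl^2)
  }
  scores
}

# Bisection on the Gaussian precision beta so that the Shannon entropy of
# w_j ~ exp(-beta d_j^2) matches the target; returns normalised weights.
.calibrate_gaussian <- function(d, target, tol = 1e-5, max_iter = 64) {
  d2 <- d^2
  beta <- 1 / max(mean(d2), .Machine$double.eps)
  lo <- 0; hi <- Inf
  for (it in seq_len(max_iter)) {
    w <- exp(-beta * (d2 - min(d2)))
    w <- w / sum(w)
    h <- -sum(w[w > 0] * log(w[w > 0]))
    if (abs(h - target) < tol) break
    if (h > target) {            # too flat: increase precision
      lo <- beta
      beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- (lo + hi) / 2
    }
  }
  w
}

#' Inverse Simpson index of a weighted label distribution
#'
#' Closed-form helper: given normalised weights and their labels, returns
#' `1 / sum_l p_l^2`. Exposed for auditability of the LISI computation.
#'
#' @param weights normalised neighbour weights
#' @param labels label per neighbour
#' @return inverse Simpson index
#' @export
inverse_simpson <- function(weights, labels) {
  pl <- rowsum(weights / sum(weights), as.character(labels))
  1 / sum(pl^2)
}

#' Summarise integration quality before/after correction
#'
#' Convenience wrapper computing median iLISI (batch mixing), median cLISI
#' (label purity) and kBET acceptance on one embedding.
#'
#' @param embedding an [Embedding] or matrix
#' @param batch batch label per cell
#' @param label cell-type/lineage label per cell
#' @param perplexity LISI perplexity
#' @param seed seed for kBET
#' @return list with `median_ilisi`, `median_clisi`, `kbet`
#' @export
integration_metrics <- function(embedding, batch, label, perplexity = 30,
                                seed = 1) {
  il <- lisi(embedding, batch, perplexity = perplexity)
  cl <- lisi(embedding, label, perplexity = perplexity)
  kb <- kbet_acceptance(embedding, batch, group = label, seed = seed)
  list(median_ilisi = median(il), median_clisi = median(cl), kbet = kb,
       ilisi = il, clisi = cl)
}
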