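# QC filtering, library-size normalisation, HVG selection and PCA: the
# per-sample processing performed before clustering and integration.

#' Quality-control thresholds for cell filtering
#'
#' A cell passes when UMI count is strictly greater than `min_umi` and at
#' most `max_umi`, detected genes strictly greater than `min_genes` and at
#' most `max_genes`, and mitochondrial fraction at most
#' `max_mito_fraction`. The strict/inclusive senses mirror common droplet QC
#' practice (e.g. "UMI counts > 1,000" but "at most 10% mitochondrial").
#' Mitochondrial genes are recognised by the symbol prefix `MT-`
#' (case-insensitive).
#'
#' @param min_umi,max_umi UMI bounds (strict lower, inclusive upper)
#' @param min_genes,max_genes detected-gene bounds (strict lower, inclusive
#'   upper)
#' @param max_mito_fraction maximum mitochondrial fraction in \[0,1\]
#' @param min_cells_per_gene gene filter: minimum cells a gene must be
#'   detected in (inclusive), applied by [filter_genes()]
#' @return an object of class `qc_thresholds`
#' @export
qc_thresholds <- function(min_umi = 1000, max_umi = Inf,
                          min_genes = 500, max_genes = Inf,
                          max_mito_fraction = 0.10,
                          min_cells_per_gene = 10) {
  stopifnot(min_umi <= max_umi, min_genes <= max_genes,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            min_cells_per_gene >= 0)
  structure(list(min_umi = min_umi, max_umi = max_umi,
                 min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_thresholds")
}

.is_mito <- function(genes) grepl("^MT-", genes, ignore.case = TRUE)
.is_ribo_or_mito <- function(genes)
  grepl("^(RPS|RPL|MT-)", genes, ignore.case = TRUE)

#' Filter cells on QC thresholds, per sample
#'
#' Thresholds can be one [qc_thresholds()] object applied to all samples or
#' a named list with one entry per sample; a sample without thresholds is a
#' configuration error. Filtering is applied cell-wise, so samples are
#' processed individually even inside a merged matrix.
#'
#' @param x a [CountMatrix]
#' @param thresholds a `qc_thresholds` or named list of them keyed by sample
#' @return the filtered [CountMatrix]
#' @export
filter_cells <- function(x, thresholds = qc_thresholds()) {
  stopifnot(is(x, "CountMatrix"))
  samples <- unique(x$sample_of_cell)
  if (is(thresholds, "qc_thresholds")) {
    thresholds <- setNames(rep(list(thresholds), length(samples)), samples)
  }
  miss <- setdiff(samples, names(thresholds))
  if (length(miss))
    stop("no QC thresholds configured for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  umi <- Matrix::rowSums(x$counts)
  ngene <- Matrix::rowSums(x$counts > 0)
  mito_idx <- .is_mito(gene_ids(x))
  mito <- if (any(mito_idx)) {
    Matrix::rowSums(x$counts[, mito_idx, drop = FALSE]) / pmax(umi, 1)
  } else rep(0, n_cells(x))
  keep <- vapply(seq_len(n_cells(x)), function(i) {
    th <- thresholds[[x$sample_of_cell[i]]]
    umi[i] > th$min_umi && umi[i] <= th$max_umi &&
      ngene[i] > th$min_genes && ngene[i] <= th$max_genes &&
      mito[i] <= th$max_mito_fraction
  }, TRUE)
  subset_count_matrix(x, cells = which(keep))
}

#' Keep genes detected in at least `min_cells` cells
#'
#' @param x a [CountMatrix]
#' @param min_cells inclusive lower bound on the number of cells with a
#'   nonzero count
#' @return the filtered [CountMatrix]
#' @export
filter_genes <- function(x, min_cells = 10) {
  stopifnot(is(x, "CountMatrix"), min_cells >= 0)
  ncells_per_gene <- Matrix::colSums(x$counts > 0)
  subset_count_matrix(x, genes = which(ncells_per_gene >= min_cells))
}

#' Library-size normalise and log-transform counts
#'
#' Each cell's counts are scaled so the library sums to `scale_total`
#' (default 10,000) and transformed with the natural `log1p`:
#' `value = ln(1 + scale_total * count / total)`. Zeros stay zero, so the
#' result remains sparse; a cell with an all-zero library yields an all-zero
#' row with a warning.
#'
#' @param x a [CountMatrix]
#' @param scale_total target library size
#' @return a `NormalizedMatrix`: list with sparse `values` (cells x genes,
#'   log scale), `sample_of_cell`, `scale_total`, `log_base = "e"`
#' @export
normalize_counts <- function(x, scale_total = 1e4) {
  stopifnot(is(x, "CountMatrix"), n_cells(x) > 0, n_genes(x) > 0)
  tot <- Matrix::rowSums(x$counts)
  if (any(tot == 0))
    warning(sum(tot == 0), " cell(s) with zero total count produce all-zero rows")
  s <- ifelse(tot > 0, scale_total / tot, 0)
  v <- Matrix::Diagonal(x = s) %*% x$counts
  v <- as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(x$counts)
  structure(list(values = v, sample_of_cell = x$sample_of_cell,
                 scale_total = scale_total, log_base = "e"),
            class = "NormalizedMatrix")
}

#' @exportS3Method base::print
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d cells x %d genes (log1p, total %g)\n",
              nrow(x$values), ncol(x$values), x$scale_total))
  invisible(x)
}

# De-logged normalised expression (scaled counts), kept sparse.
.delog <- function(norm) {
  v <- norm$values
  v@x <- expm1(v@x)
  v
}

#' Select highly variable genes by a mean-variability trend
#'
#' Fits the squared coefficient of variation of de-logged normalised
#' expression against the reciprocal mean with a gamma-family GLM
#' (identity link), `cv2 ~ a0 + a1/mean`, and selects genes whose cv2 sits
#' significantly above the trend: the per-gene statistic
#' `(n-1) * cv2 / fitted_cv2` is referred to a chi-square distribution with
#' `n-1` degrees of freedom and BH-adjusted across tested genes. Ribosomal
#' (`RPS*`/`RPL*`) and mitochondrial (`MT-*`) genes are excluded from the
#' selection (they still inform the trend fit).
#'
#' @param norm a `NormalizedMatrix`
#' @param alpha BH-adjusted significance cutoff (default 0.05)
#' @param min_mean_quantile quantile of positive gene means below which
#'   genes are excluded from the trend fit (they are still tested)
#' @return an `HVGResult`: list with `selected_genes`, `fit_params`
#'   (`a0`, `a1`), and a per-gene data.frame `per_gene`
#' @export
select_hvg <- function(norm, alpha = 0.05, min_mean_quantile = 0.25) {
  stopifnot(is(norm, "NormalizedMatrix"))
  e <- .delog(norm)
  n <- nrow(e)
  m <- Matrix::colSums(e) / n
  msq <- Matrix::colSums(e^2) / n
  v <- (msq - m^2) * n / max(n - 1, 1)
  tested <- m > 0 & v > 0
  if (sum(tested) < 100)
    stop("need at least 100 genes with nonzero mean and variance to fit the trend")
  cv2 <- rep(NA_real_, length(m))
  cv2[tested] <- v[tested] / m[tested]^2
  fit_idx <- tested & m >= quantile(m[tested], min_mean_quantile)
  df_fit <- data.frame(cv2 = cv2[fit_idx], recip = 1 / m[fit_idx])
  ls <- lm(cv2 ~ recip, data = df_fit)
  fit <- tryCatch(
    glm(cv2 ~ recip, data = df_fit, family = Gamma(link = "identity"),
        start = pmax(coef(ls), c(1e-4, 1e-4))),
    error = function(e) ls, warning = function(w) ls)
  a <- coef(fit)
  if (any(!is.finite(a)))
    stop("degenerate mean-variability fit (singular design); coefficients: ",
         paste(format(a), collapse = ", "))
  fitted_cv2 <- a[1] + a[2] / m
  stat <- (n - 1) * cv2 / fitted_cv2
  p <- rep(NA_real_, length(m))
  p[tested] <- pchisq(stat[tested], df = n - 1, lower.tail = FALSE)
  p_adj <- rep(NA_real_, length(m))
  p_adj[tested] <- p.adjust(p[tested], method = "BH")
  excluded <- .is_ribo_or_mito(colnames(e))
  sel <- tested & !excluded & !is.na(p_adj) & p_adj < alpha &
    cv2 > fitted_cv2
  per_gene <- data.frame(gene = colnames(e), mean = m, cv2 = cv2,
                         fitted_cv2 = fitted_cv2,
                         residual = cv2 - fitted_cv2,
                         p = p, p_adj = p_adj,
                         excluded = excluded, selected = sel,
                         row.names = NULL)
  structure(list(selected_genes = colnames(e)[sel],
                 fit_params = c(a0 = unname(a[1]), a1 = unname(a[2])),
                 per_gene = per_gene),
            class = "HVGResult")
}

#' @exportS3Method base::print
print.HVGResult <- function(x, ...) {
  cat(sprintf("HVGResult: %d genes selected (trend cv2 = %.3g + %.3g/mean)\n",
              length(x$selected_genes), x$fit_params[1], x$fit_params[2]))
  invisible(x)
}

#' Principal-component embedding of the HVG submatrix
#'
#' Truncated SVD of the column-centred, per-gene unit-scaled HVG submatrix
#' of the log-normalised values. Scaled values are clipped at
#' `sd_cap` standard deviations to bound outlier leverage. Components are
#' ordered by decreasing singular value and the sign of each component is
#' fixed so that its largest-magnitude gene loading is positive.
#'
#' @param norm a `NormalizedMatrix`
#' @param hvg an `HVGResult`, or a character vector of gene symbols
#' @param n_pcs number of components (default 40); must be smaller than
#'   both the number of cells and the number of HVGs
#' @param sd_cap clip scaled values at +/- this many SDs (default 10)
#' @return an [Embedding] named `"pca"`, with attributes `sdev` (component
#'   standard deviations) and `rotation` (gene loadings)
#' @export
run_pca <- function(norm, hvg, n_pcs = 40, sd_cap = 10) {
  stopifnot(is(norm, "NormalizedMatrix"))
  genes <- if (is(hvg, "HVGResult")) hvg$selected_genes else as.character(hvg)
  genes <- intersect(genes, colnames(norm$values))
  n <- nrow(norm$values)
  if (n_pcs >= min(n, length(genes)))
    stop(sprintf("n_pcs=%d must be < min(#cells=%d, #HVGs=%d)",
                 n_pcs, n, length(genes)))
  x <- as.matrix(norm$values[, genes, drop = FALSE])
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  x[x > sd_cap] <- sd_cap
  x[x < -sd_cap] <- -sd_cap
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  u <- sv$u; v <- sv$v; d <- sv$d[seq_len(n_pcs)]
  for (j in seq_len(n_pcs)) {               # sign convention
    jmax <- which.max(abs(v[, j]))
    if (v[jmax, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  coords <- u %*% diag(d, n_pcs)
  dimnames(coords) <- list(rownames(norm$values),
                           paste0("PC", seq_len(n_pcs)))
  emb <- Embedding(coords, name = "pca")
  attr(emb, "sdev") <- d / sqrt(max(n - 1, 1))
  rownames(v) <- genes
  attr(emb, "rotation") <- v
  emb
}
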