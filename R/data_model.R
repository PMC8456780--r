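#' Sparse UMI count matrix with sample annotation
#'
#' The central container of the package: a sparse cells x genes matrix of
#' non-negative integer UMI counts, together with the sample each cell came
#' from and (optionally) the tissue of each sample. Cell barcodes and gene
#' symbols are kept as the dimnames of the sparse matrix and must be unique.
#'
#' @param counts matrix-like, cells x genes, non-negative integers. Coerced
#'   to `dgCMatrix`. Row names are cell barcodes, column names gene symbols;
#'   defaults are generated when absent.
#' @param sample_of_cell character vector, one sample label per cell.
#'   Defaults to a single sample `"sample1"`.
#' @param tissue_of_sample optional named character vector mapping sample
#'   label to tissue label.
#' @return an object of class `CountMatrix`: a list with elements `counts`,
#'   `sample_of_cell`, `tissue_of_sample`.
#' @export
CountMatrix <- function(counts, sample_of_cell = NULL, tissue_of_sample = NULL) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("gene%05d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("cell barcodes must be unique")
  if (anyDuplicated(colnames(counts)))
    stop("gene symbols must be unique")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  if (is.null(sample_of_cell)) sample_of_cell <- rep("sample1", nrow(counts))
  sample_of_cell <- as.character(sample_of_cell)
  if (length(sample_of_cell) != nrow(counts))
    stop("sample_of_cell must have one entry per cell")
  if (!is.null(tissue_of_sample)) {
    missing_s <- setdiff(unique(sample_of_cell), names(tissue_of_sample))
    if (length(missing_s))
      stop("tissue_of_sample lacks samples: ", paste(missing_s, collapse = ", "))
  }
  structure(list(counts = counts,
                 sample_of_cell = sample_of_cell,
                 tissue_of_sample = tissue_of_sample),
            class = "CountMatrix")
}

#' @exportS3Method base::print
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes, %d sample(s), %.1f%% nonzero\n",
              n_cells(x), n_genes(x), length(unique(x$sample_of_cell)),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' Number of cells / genes in a CountMatrix
#' @param x a `CountMatrix`
#' @return integer count
#' @export
n_cells <- function(x) nrow(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) ncol(x$counts)

#' Cell barcodes and gene symbols of a CountMatrix
#' @param x a `CountMatrix`
#' @return character vector
#' @export
cell_ids <- function(x) rownames(x$counts)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$counts)

#' Subset a CountMatrix by cell or gene index
#'
#' @param x a `CountMatrix`
#' @param cells,genes integer, logical or character index; `NULL` keeps all.
#' @return a `CountMatrix`
#' @export
subset_count_matrix <- function(x, cells = NULL, genes = NULL) {
  stopifnot(is(x, "CountMatrix"))
  if (is.null(cells)) cells <- seq_len(n_cells(x))
  if (is.character(cells)) cells <- match(cells, cell_ids(x))
  if (is.null(genes)) genes <- seq_len(n_genes(x))
  out <- x
  out$counts <- x$counts[cells, genes, drop = FALSE]
  out$sample_of_cell <- x$sample_of_cell[cells]
  out
}

#' Split a CountMatrix into one CountMatrix per sample
#' @param x a `CountMatrix`
#' @return named list of `CountMatrix`, one per sample label
#' @export
split_by_sample <- function(x) {
  stopifnot(is(x, "CountMatrix"))
  out <- lapply(split(seq_len(n_cells(x)), x$sample_of_cell),
                function(i) subset_count_matrix(x, cells = i))
  out
}

#' Merge CountMatrix objects over their common genes
#'
#' Cells are concatenated; the gene panel is the intersection of the inputs'
#' panels (order taken from the first input).
#'
#' @param xs named list of `CountMatrix` objects; names become sample labels
#'   when an input carries a single unnamed default sample.
#' @return a `CountMatrix`
#' @export
merge_count_matrices <- function(xs) {
  stopifnot(length(xs) >= 1, all(vapply(xs, is, TRUE, "CountMatrix")))
  common <- Reduce(intersect, lapply(xs, gene_ids))
  if (!length(common)) stop("no genes shared across samples")
  if (is.null(names(xs))) names(xs) <- sprintf("sample%d", seq_along(xs))
  mats <- list(); samp <- character(0); tiss <- NULL
  for (nm in names(xs)) {
    xi <- xs[[nm]]
    m <- xi$counts[, common, drop = FALSE]
    s <- xi$sample_of_cell
    if (length(unique(s)) == 1 && unique(s) == "sample1" && nm != "sample1") {
      s <- rep(nm, length(s))
    }
    rownames(m) <- paste(s, rownames(m), sep = ":")
    mats[[nm]] <- m
    samp <- c(samp, s)
    if (!is.null(xi$tissue_of_sample)) tiss <- c(tiss, xi$tissue_of_sample)
  }
  CountMatrix(do.call(rbind, mats), sample_of_cell = samp,
              tissue_of_sample = if (is.null(tiss)) NULL else tiss[!duplicated(names(tiss))])
}

#' Gene set collection
#'
#' A named list of character vectors of gene symbols, as read from a GMT
#' file. Set names must be unique and sets non-empty; duplicate symbols
#' within a set are dropped keeping the first occurrence.
#'
#' @param sets named list of character vectors
#' @param provenance optional character vector (one free-text entry per set)
#' @return an object of class `GeneSetCollection`
#' @export
GeneSetCollection <- function(sets, provenance = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene set names must be present and unique")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("every gene set must be non-empty")
  if (is.null(provenance)) provenance <- rep("", length(sets))
  structure(list(sets = sets, provenance = provenance),
            class = "GeneSetCollection")
}

#' @exportS3Method base::print
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Low-dimensional embedding of cells
#'
#' @param coords numeric matrix, cells x d, finite entries; row names are
#'   cell ids.
#' @param name label such as `"pca"` or `"harmony"`.
#' @return an object of class `Embedding`
#' @export
Embedding <- function(coords, name = "embedding") {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("embedding coordinates must be finite")
  structure(list(coords = coords, name = name, d = ncol(coords)),
            class = "Embedding")
}

#' @exportS3Method base::print
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding '%s': %d cells x %d dims\n", x$name,
              nrow(x$coords), x$d))
  invisible(x)
}
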