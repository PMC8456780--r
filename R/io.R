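# Readers/writers for the plain-text formats the pipeline touches:
# 10x-style Matrix Market triplets + barcode/feature lists, GMT gene sets,
# TSV tables and a JSON run manifest.

.find_10x_file <- function(dir_path, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    f <- file.path(dir_path, paste0(stem, ext))
    if (file.exists(f)) return(f)
  }
  stop(sprintf("10x directory '%s' is missing a file matching: %s",
               dir_path, paste(stems, collapse = " | ")), call. = FALSE)
}

#' Read a 10x Genomics-style sparse count directory
#'
#' Expects a Matrix Market triplet file (`matrix.mtx[.gz]`) plus a barcode
#' list (`barcodes.tsv[.gz]`) and a gene list, either v2-style
#' (`genes.tsv[.gz]`) or v3-style (`features.tsv[.gz]`); the layout is
#' auto-detected by filename. Gene identity is the symbol column; duplicate
#' symbols are disambiguated with a numeric suffix and recorded in the
#' `renamed_genes` attribute. The matrix is returned cells x genes
#' irrespective of the on-disk orientation (10x writes genes x cells).
#'
#' @param dir_path directory containing the three files
#' @param sample sample label attached to every cell (default: directory
#'   base name)
#' @return a [CountMatrix]
#' @export
read_10x_matrix <- function(dir_path, sample = basename(normalizePath(dir_path))) {
  mtx_f <- .find_10x_file(dir_path, "matrix.mtx")
  bc_f  <- .find_10x_file(dir_path, "barcodes.tsv")
  gn_f  <- .find_10x_file(dir_path, c("features.tsv", "genes.tsv"))
  m <- tryCatch(Matrix::readMM(mtx_f),
                error = function(e) stop(sprintf("cannot parse '%s': %s",
                                                 mtx_f, conditionMessage(e)),
                                         call. = FALSE))
  barcodes <- read.delim(bc_f, header = FALSE, colClasses = "character")[[1]]
  genes_tab <- read.delim(gn_f, header = FALSE, colClasses = "character")
  symbols <- if (ncol(genes_tab) >= 2) genes_tab[[2]] else genes_tab[[1]]
  if (nrow(m) != length(symbols))
    stop(sprintf("matrix has %d rows but gene list '%s' has %d entries",
                 nrow(m), gn_f, length(symbols)), call. = FALSE)
  if (ncol(m) != length(barcodes))
    stop(sprintf("matrix has %d columns but barcode list '%s' has %d entries",
                 ncol(m), bc_f, length(barcodes)), call. = FALSE)
  renamed <- symbols[duplicated(symbols)]
  symbols <- make.unique(symbols, sep = ".")
  m <- Matrix::t(m)                      # on disk genes x cells -> cells x genes
  dimnames(m) <- list(barcodes, symbols)
  out <- CountMatrix(m, sample_of_cell = rep(sample, nrow(m)))
  attr(out, "renamed_genes") <- unique(renamed)
  out
}

#' Write a CountMatrix as a 10x-style directory
#'
#' Writes `matrix.mtx` (genes x cells), `features.tsv` and `barcodes.tsv`,
#' uncompressed. Round-trips through [read_10x_matrix()] exactly.
#'
#' @param x a [CountMatrix]
#' @param dir_path output directory (created if needed)
#' @return `dir_path`, invisibly
#' @export
write_10x_matrix <- function(x, dir_path) {
  stopifnot(is(x, "CountMatrix"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir_path, "matrix.mtx"))
  writeLines(cell_ids(x), file.path(dir_path, "barcodes.tsv"))
  feat <- data.frame(id = gene_ids(x), symbol = gene_ids(x),
                     type = "Gene Expression")
  write.table(feat, file.path(dir_path, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir_path)
}

#' Read gene sets from a GMT file
#'
#' One tab-separated line per set: name, description, then gene symbols.
#' Duplicate symbols within a set are de-duplicated keeping the first
#' occurrence; duplicate set names are an error.
#'
#' @param path GMT file
#' @return a [GeneSetCollection] (descriptions kept as provenance)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", bad[1]),
         call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate gene set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  GeneSetCollection(sets, provenance = vapply(fields, `[[`, "", 2))
}

#' Write a GeneSetCollection to a GMT file
#' @param sets a [GeneSetCollection]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is(sets, "GeneSetCollection"))
  lines <- vapply(seq_along(sets$sets), function(i) {
    paste(c(names(sets$sets)[i],
            if (nzchar(sets$provenance[i])) sets$provenance[i] else "na",
            sets$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Downsample to an equal number of cells per group
#'
#' Samples exactly `n_per_group` cells without replacement from every group,
#' reproducibly for a fixed seed. Used to compare compositions or
#' trajectories across tissues without being driven by capture depth.
#'
#' @param x a [CountMatrix]
#' @param n_per_group cells to keep per group
#' @param group_by `"sample"`, `"tissue"`, or a character vector with one
#'   label per cell
#' @param seed integer seed
#' @return a [CountMatrix] with `n_per_group` cells per group
#' @export
downsample_equal <- function(x, n_per_group, group_by = "sample", seed = 1) {
  stopifnot(is(x, "CountMatrix"), n_per_group >= 1)
  groups <- if (length(group_by) == 1 && group_by == "sample") {
    x$sample_of_cell
  } else if (length(group_by) == 1 && group_by == "tissue") {
    if (is.null(x$tissue_of_sample)) stop("no tissue annotation present")
    unname(x$tissue_of_sample[x$sample_of_cell])
  } else {
    stopifnot(length(group_by) == n_cells(x))
    as.character(group_by)
  }
  sizes <- table(groups)
  small <- names(sizes)[sizes < n_per_group]
  if (length(small))
    stop(sprintf("groups smaller than n_per_group=%d: %s", n_per_group,
                 paste(small, collapse = ", ")), call. = FALSE)
  set.seed(seed)
  keep <- unlist(lapply(split(seq_along(groups), groups),
                        function(i) sort(sample(i, n_per_group))),
                 use.names = FALSE)
  subset_count_matrix(x, cells = sort(keep))
}

#' Read a sample metadata table
#'
#' TSV with at least columns `sample_id` and `tissue`; optional per-sample
#' QC columns `min_umi`, `max_umi`, `min_genes`, `max_genes`,
#' `max_mito_fraction` override the defaults in [qc_thresholds()].
#'
#' @param path TSV file
#' @return data.frame with one row per sample
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("sample metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  md
}

#' Write a run manifest as JSON
#'
#' Records input paths, parameters, seeds and package version alongside any
#' stage outputs, so every artifact can be traced to the run that made it.
#'
#' @param manifest named list
#' @param path output JSON file
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path) {
  manifest$package <- "scellintegrate"
  manifest$version <- as.character(packageVersion("scellintegrate"))
  manifest$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.write_tsv <- function(df, path, row_names = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = row_names)
  invisible(path)
}
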