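#' Cell-by-gene count matrix with metadata
#'
#' The substrate of all expression-based stages: a sparse cells x genes
#' matrix of non-negative integer counts together with per-cell and per-gene
#' metadata. Per-cell QC statistics (number of detected genes, total counts,
#' mitochondrial and ribosomal percentages) are computed from the counts at
#' construction time and recomputed whenever cells or genes are subset, so
#' they are always consistent with the stored matrix.
#'
#' @param counts sparse or dense cells x genes matrix of non-negative
#'   integer counts; rownames are cell barcodes, colnames gene symbols.
#' @param cell_meta data.frame with one row per cell; must contain columns
#'   `sample` and `barcode`. QC columns are (re)computed.
#' @param gene_meta data.frame with one row per gene; must contain columns
#'   `symbol`, `chrom`, `start`. Logical flag columns `mito`, `ribo` and
#'   `immunoglobulin` are derived from symbol prefixes when absent
#'   (`MT-` for mitochondrial, `RPL`/`RPS` for ribosomal, `IGK`/`IGL`/`IGH`
#'   for immunoglobulin).
#' @return an object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta, gene_meta) {
  counts <- as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  counts <- as(counts, "CsparseMatrix")
  assert_that(all(counts@x >= 0), "counts must be non-negative")
  assert_that(all(counts@x == round(counts@x)), "counts must be integral")
  assert_that(nrow(cell_meta) == nrow(counts),
              "cell_meta rows must match count matrix rows")
  assert_that(nrow(gene_meta) == ncol(counts),
              "gene_meta rows must match count matrix columns")
  assert_that(all(c("sample", "barcode") %in% names(cell_meta)),
              "cell_meta needs 'sample' and 'barcode' columns")
  assert_that(all(c("symbol", "chrom", "start") %in% names(gene_meta)),
              "gene_meta needs 'symbol', 'chrom' and 'start' columns")
  rownames(counts) <- cell_meta$barcode
  colnames(counts) <- gene_meta$symbol
  if (is.null(gene_meta$mito))
    gene_meta$mito <- startsWith(gene_meta$symbol, "MT-")
  if (is.null(gene_meta$ribo))
    gene_meta$ribo <- startsWith(gene_meta$symbol, "RPL") |
      startsWith(gene_meta$symbol, "RPS")
  if (is.null(gene_meta$immunoglobulin))
    gene_meta$immunoglobulin <- startsWith(gene_meta$symbol, "IGK") |
      startsWith(gene_meta$symbol, "IGL") |
      startsWith(gene_meta$symbol, "IGH")
  obj <- structure(list(counts = counts,
                        cell_meta = cell_meta,
                        gene_meta = gene_meta),
                   class = "cell_matrix")
  recompute_qc(obj)
}

#' Recompute per-cell QC statistics from the counts
#'
#' @param x a [cell_matrix()].
#' @return `x` with refreshed `n_genes_detected`, `total_counts`,
#'   `pct_mito`, `pct_ribo` columns in `cell_meta`.
#' @export
recompute_qc <- function(x) {
  stopifnot(inherits(x, "cell_matrix"))
  cm <- x$counts
  tot <- Matrix::rowSums(cm)
  ng <- Matrix::rowSums(cm > 0)
  mito <- Matrix::rowSums(cm[, x$gene_meta$mito, drop = FALSE])
  ribo <- Matrix::rowSums(cm[, x$gene_meta$ribo, drop = FALSE])
  x$cell_meta$n_genes_detected <- as.integer(ng)
  x$cell_meta$total_counts <- as.numeric(tot)
  x$cell_meta$pct_mito <- ifelse(tot > 0, 100 * mito / tot, 0)
  x$cell_meta$pct_ribo <- ifelse(tot > 0, 100 * ribo / tot, 0)
  x
}

#' Subset a cell_matrix by cells and/or genes
#'
#' QC statistics are recomputed on the subset so that invariants hold.
#'
#' @param x a [cell_matrix()].
#' @param cells logical/integer index over cells (default all).
#' @param genes logical/integer index over genes (default all).
#' @return the subset `cell_matrix`.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  out <- x
  out$counts <- x$counts[cells, genes, drop = FALSE]
  out$cell_meta <- x$cell_meta[cells, , drop = FALSE]
  out$gene_meta <- x$gene_meta[genes, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  rownames(out$gene_meta) <- NULL
  recompute_qc(out)
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes, %d sample(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample))))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Write a cell_matrix as 10x-style Matrix Market triplets
#'
#' Writes `matrix.mtx` (genes x cells, the 10x orientation),
#' `features.tsv`, `barcodes.tsv` and a `cells.tsv` metadata table into
#' `dir`.
#'
#' @param x a [cell_matrix()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_10x <- function(x, dir) {
  stopifnot(inherits(x, "cell_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  write.table(x$gene_meta, file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(x$cell_meta$barcode, file.path(dir, "barcodes.tsv"))
  write.table(x$cell_meta, file.path(dir, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cell_matrix from a directory written by [write_10x()]
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and optionally `cells.tsv`.
#' @return a [cell_matrix()].
#' @export
read_10x <- function(dir) {
  m <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- read.table(file.path(dir, "features.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  bc <- readLines(file.path(dir, "barcodes.tsv"))
  cells_path <- file.path(dir, "cells.tsv")
  if (file.exists(cells_path)) {
    cells <- read.table(cells_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  } else {
    cells <- data.frame(sample = "sample1", barcode = bc,
                        stringsAsFactors = FALSE)
  }
  cell_matrix(m, cells, genes)
}
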