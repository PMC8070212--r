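#' Construct a cell dataset
#'
#' The central container of the package: a sparse genes x cells count matrix
#' together with per-gene and per-cell metadata tibbles. All downstream stages
#' (normalization, PCA, clustering, trajectory, binned differential
#' expression) read from and write into this object; per-cell results
#' (cluster, cell type, pseudotime, branch) accumulate as columns of
#' `cell_meta` so they can be inspected and joined with ordinary dplyr verbs.
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes in rows,
#'   cells in columns.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param gene_short_names character vector of display names (e.g. MGI
#'   symbols), same length as `gene_ids`. Marker tables and the bin-DE table
#'   are keyed by short name, mirroring common 10x `features.tsv` usage.
#' @param barcodes character vector of unique cell barcodes (columns).
#' @param genotype single label, or vector per cell, stored in `cell_meta`.
#'
#' @return An object of class `cell_dataset`: a list with elements `counts`
#'   (dgCMatrix), `gene_meta` (tibble: gene_id, gene_short_name), `cell_meta`
#'   (tibble: barcode, genotype, ...), and, once computed, `size_factors`,
#'   `norm` (log-normalized sparse layer) and `pca`.
#' @export
cell_dataset <- function(counts, gene_ids, gene_short_names, barcodes,
                         genotype = NA_character_) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  # pattern/logical sparse inputs (e.g. all-zero MatrixMarket files) lack an
  # x slot; route everything through a numeric general CsparseMatrix
  counts <- methods::as(methods::as(methods::as(
    counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length (", length(gene_ids), ") != matrix rows (",
         nrow(counts), ")")
  if (length(gene_short_names) != nrow(counts))
    stop("gene_short_names length != matrix rows")
  if (length(barcodes) != ncol(counts))
    stop("barcodes length (", length(barcodes), ") != matrix columns (",
         ncol(counts), ")")
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes: ",
         paste(utils::head(unique(barcodes[duplicated(barcodes)]), 5),
               collapse = ", "))
  if (any(counts@x < 0)) stop("counts must be non-negative")
  rownames(counts) <- gene_ids
  colnames(counts) <- barcodes
  structure(
    list(
      counts = counts,
      gene_meta = tibble::tibble(gene_id = as.character(gene_ids),
                                 gene_short_name = as.character(gene_short_names)),
      cell_meta = tibble::tibble(barcode = as.character(barcodes),
                                 genotype = rep_len(as.character(genotype),
                                                    length(barcodes))),
      size_factors = NULL,
      norm = NULL,
      pca = NULL
    ),
    class = "cell_dataset"
  )
}

#' @exportS3Method base::print
print.cell_dataset <- function(x, ...) {
  cat("<cell_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells\n", sep = "")
  gt <- unique(x$cell_meta$genotype)
  cat("  genotype: ", paste(gt, collapse = ", "), "\n", sep = "")
  cat("  layers: counts",
      if (!is.null(x$norm)) ", norm", if (!is.null(x$pca)) ", pca", "\n",
      sep = "")
  extra <- setdiff(names(x$cell_meta), c("barcode", "genotype"))
  if (length(extra))
    cat("  cell_meta: ", paste(extra, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

n_cells <- function(ds) ncol(ds$counts)
n_genes <- function(ds) nrow(ds$counts)

#' Subset a cell dataset by cells (and optionally genes)
#'
#' Keeps metadata, size factors and the normalized layer aligned. PCA results
#' are dropped because scores are only valid for the fitted cell set.
#'
#' @param ds a [cell_dataset].
#' @param cells logical/integer/character index into cells.
#' @param genes logical/integer/character index into genes (default: all).
#' @return A `cell_dataset`.
#' @export
subset_cells <- function(ds, cells, genes = NULL) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.character(cells)) cells <- match(cells, ds$cell_meta$barcode)
  if (is.null(genes)) genes <- seq_len(n_genes(ds))
  if (is.character(genes)) genes <- match(genes, ds$gene_meta$gene_id)
  out <- ds
  out$counts <- ds$counts[genes, cells, drop = FALSE]
  out$gene_meta <- ds$gene_meta[genes, ]
  out$cell_meta <- ds$cell_meta[cells, ]
  if (!is.null(ds$size_factors)) out$size_factors <- ds$size_factors[cells]
  if (!is.null(ds$norm)) out$norm <- ds$norm[genes, cells, drop = FALSE]
  out$pca <- NULL
  out
}

# resolve gene short names to row indices, erroring on unknowns
match_short_names <- function(ds, short_names) {
  idx <- match(short_names, ds$gene_meta$gene_short_name)
  if (anyNA(idx))
    stop("unknown gene short name(s): ",
         paste(short_names[is.na(idx)], collapse = ", "))
  idx
}
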