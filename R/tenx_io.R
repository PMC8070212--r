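#' Write a cell dataset as a 10x-style triplet directory
#'
#' Writes `matrix.mtx` (MatrixMarket integer triplet, genes x cells),
#' `features.tsv` (gene_id, gene_short_name) and `barcodes.tsv` into `dir`.
#' The files round-trip bit-exactly through [load_tenx()].
#'
#' @param ds a [cell_dataset].
#' @param dir output directory; created if missing.
#' @return `dir`, invisibly.
#' @export
write_tenx <- function(ds, dir) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (n_cells(ds) == 0 || n_genes(ds) == 0)
    stop("refusing to write an empty dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("could not create directory: ", dir)
  Matrix::writeMM(ds$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(ds$gene_meta, file.path(dir, "features.tsv"),
                   col_names = FALSE)
  readr::write_tsv(ds$cell_meta["barcode"], file.path(dir, "barcodes.tsv"),
                   col_names = FALSE)
  invisible(dir)
}

#' Load a 10x-style triplet directory
#'
#' Reads `matrix.mtx` + `features.tsv` + `barcodes.tsv` as written by
#' CellRanger-style pipelines (and by [write_tenx()]). `features.tsv` must
#' carry at least two columns; the second is taken as the gene short-name
#' column used throughout annotation and differential expression.
#'
#' @param dir directory containing the three files.
#' @param genotype label stored on every cell (the expected layout is one
#'   triplet directory per genotype).
#' @return A [cell_dataset].
#' @export
load_tenx <- function(dir, genotype = NA_character_) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing 10x file(s): ", paste(missing, collapse = ", "))
  m <- Matrix::readMM(paths[1])
  feats <- readr::read_tsv(paths[2], col_names = FALSE, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (ncol(feats) < 2)
    stop("features.tsv has ", ncol(feats),
         " column(s); need at least 2 (gene_id, gene_short_name)")
  bc <- readr::read_tsv(paths[3], col_names = FALSE, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))[[1]]
  if (nrow(feats) != nrow(m))
    stop("features.tsv rows (", nrow(feats), ") != matrix rows (", nrow(m), ")")
  if (length(bc) != ncol(m))
    stop("barcodes.tsv rows (", length(bc), ") != matrix columns (", ncol(m), ")")
  cell_dataset(m, feats[[1]], feats[[2]], bc, genotype = genotype)
}
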