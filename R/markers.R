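#' Per-cluster marker table
#'
#' Scores every gene in every cluster by `marker_score = sensitivity x
#' specificity`, where sensitivity is the fraction of the cluster's cells
#' expressing the gene (count > 0) and specificity is the cluster's mean
#' normalized expression divided by the sum of all clusters' mean normalized
#' expressions. The top `top_n` genes per cluster by score are returned with
#' dense ranks.
#'
#' @param ds a clustered, normalized [cell_dataset].
#' @param top_n markers retained per cluster (default 25).
#' @return A tibble: cluster, gene_id, gene (short name), fraction_expressing,
#'   specificity, marker_score, rank.
#' @export
top_markers <- function(ds, top_n = 25) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.null(ds$norm)) stop("run normalize_cells() first")
  cl <- ds$cell_meta$cluster
  if (is.null(cl)) stop("run leiden_cluster() first")
  clusters <- sort(unique(cl))
  if (any(tabulate(match(cl, clusters)) == 0)) stop("empty cluster")
  # cluster indicator (cells x clusters), scaled to means
  ind <- Matrix::sparseMatrix(i = seq_along(cl), j = match(cl, clusters),
                              x = 1, dims = c(length(cl), length(clusters)))
  csize <- Matrix::colSums(ind)
  mean_norm <- as.matrix(ds$norm %*% ind) / rep(csize, each = n_genes(ds))
  frac_expr <- as.matrix((ds$counts > 0) %*% ind) / rep(csize, each = n_genes(ds))
  tot <- rowSums(mean_norm)
  spec <- mean_norm / ifelse(tot == 0, Inf, tot)   # all-zero gene -> spec 0
  score <- frac_expr * spec
  purrr::map_dfr(seq_along(clusters), function(j) {
    o <- order(score[, j], decreasing = TRUE)[seq_len(min(top_n, n_genes(ds)))]
    tibble::tibble(
      cluster = clusters[j],
      gene_id = ds$gene_meta$gene_id[o],
      gene = ds$gene_meta$gene_short_name[o],
      fraction_expressing = unname(frac_expr[o, j]),
      specificity = unname(spec[o, j]),
      marker_score = unname(score[o, j]),
      rank = seq_along(o)
    )
  })
}

#' Filter a marker table by fraction expressing
#'
#' Removes rows whose `fraction_expressing` is strictly less than `min_frac`;
#' rows exactly at the threshold are retained. Ranks are re-densified within
#' cluster.
#'
#' @param markers a [top_markers()] tibble.
#' @param min_frac threshold (default 0.10).
#' @return The filtered tibble.
#' @export
filter_markers <- function(markers, min_frac = 0.10) {
  stopifnot(is.data.frame(markers), nrow(markers) > 0)
  out <- dplyr::filter(markers, .data$fraction_expressing >= min_frac)
  if (nrow(out) == 0)
    warning("all markers fall below the fraction-expressing threshold ",
            min_frac)
  out |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(dplyr::desc(.data$marker_score), .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Annotate clusters by overlap with reference marker sets
#'
#' Each cluster is assigned the reference cell type whose marker set shares
#' the most genes with the cluster's (filtered) marker list. Ties are broken
#' by the larger summed `marker_score` of the overlapping genes, then
#' lexicographically; clusters overlapping no type are labelled `"Unknown"`.
#'
#' @param markers a filtered marker tibble (see [filter_markers()]).
#' @param ref reference tibble with columns `cell_type`, `gene`.
#' @return A tibble: cluster, cell_type, overlap_count, overlap_genes
#'   (comma-separated).
#' @export
annotate_clusters <- function(markers, ref) {
  stopifnot(is.data.frame(ref), all(c("cell_type", "gene") %in% names(ref)))
  if (nrow(ref) == 0) stop("reference marker table is empty")
  types <- sort(unique(ref$cell_type))
  markers |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(d, key) {
      per_type <- purrr::map_dfr(types, function(ty) {
        hit <- d$gene %in% ref$gene[ref$cell_type == ty]
        tibble::tibble(cell_type = ty, overlap_count = sum(hit),
                       score_sum = sum(d$marker_score[hit]),
                       overlap_genes = paste(d$gene[hit], collapse = ","))
      })
      best <- per_type |>
        dplyr::arrange(dplyr::desc(.data$overlap_count),
                       dplyr::desc(.data$score_sum), .data$cell_type) |>
        dplyr::slice(1)
      if (best$overlap_count == 0)
        best <- tibble::tibble(cell_type = "Unknown", overlap_count = 0L,
                               score_sum = 0, overlap_genes = "")
      dplyr::select(best, "cell_type", "overlap_count", "overlap_genes")
    }) |>
    dplyr::ungroup()
}

#' Propagate cluster annotations to cells
#'
#' @param ds a clustered [cell_dataset].
#' @param annotation an [annotate_clusters()] tibble.
#' @return The dataset with a `cell_type` column in `cell_meta`.
#' @export
apply_annotation <- function(ds, annotation) {
  stopifnot(inherits(ds, "cell_dataset"))
  idx <- match(ds$cell_meta$cluster, annotation$cluster)
  if (anyNA(idx))
    stop("cluster(s) without annotation: ",
         paste(unique(ds$cell_meta$cluster[is.na(idx)]), collapse = ", "))
  ds$cell_meta$cell_type <- annotation$cell_type[idx]
  ds
}

#' Re-annotate cells by direct marker expression
#'
#' Programmatic replacement for interactive UMAP-based cell picking: cells
#' whose mean normalized expression over `type_markers` strictly exceeds the
#' `quantile` threshold of that score across all cells are re-labelled
#' `type_label`. Intended to rescue small populations (e.g. enteroendocrine
#' cells) that clustering merged into larger clusters. A heuristic; see the
#' package vignette.
#'
#' @param ds an annotated [cell_dataset].
#' @param type_markers character vector of gene short names.
#' @param type_label label to assign.
#' @param quantile threshold quantile in (0, 1) (default 0.99).
#' @return The dataset with updated `cell_type`.
#' @export
rescue_by_expression <- function(ds, type_markers, type_label,
                                 quantile = 0.99) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.null(ds$norm)) stop("run normalize_cells() first")
  if (is.null(ds$cell_meta$cell_type)) stop("annotate cells first")
  rows <- match_short_names(ds, type_markers)
  score <- Matrix::colMeans(ds$norm[rows, , drop = FALSE])
  thr <- stats::quantile(score, quantile, names = FALSE)
  hit <- score > thr
  ds$cell_meta$cell_type[hit] <- type_label
  ds
}
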