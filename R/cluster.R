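#' k-nearest-neighbour graph in PC space
#'
#' Builds the undirected union of directed Euclidean k-NN edges over the
#' rows of a score matrix. Distances are computed blockwise from
#' cross-products so the graph scales to a few thousand cells without an
#' external index.
#'
#' By default edges are weighted by the Jaccard similarity of the two cells'
#' neighbour sets, which expresses how embedded an edge is in its local
#' neighbourhood; with these weights, constant-Potts-model resolutions of
#' order 1e-2 partition a few-thousand-cell graph into tens of clusters.
#'
#' @param scores numeric matrix, observations in rows.
#' @param k neighbours per observation (`k < nrow(scores)`).
#' @param weighting `"jaccard"` (default) or `"none"`.
#' @return An igraph undirected graph with `nrow(scores)` vertices (and a
#'   `weight` edge attribute under Jaccard weighting).
#' @export
knn_graph <- function(scores, k, weighting = c("jaccard", "none")) {
  weighting <- match.arg(weighting)
  n <- nrow(scores)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (", n, ")")
  sq <- rowSums(scores^2)
  block <- 1024L
  nbr <- matrix(0L, nrow = n, ncol = k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") -
      2 * tcrossprod(scores[idx, , drop = FALSE], scores)
    for (r in seq_along(idx)) {
      o <- order(d2[r, ])
      nbr[idx[r], ] <- o[o != idx[r]][seq_len(k)]
    }
  }
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.integer(t(nbr)), x = 1, dims = c(n, n))
  u <- (a + Matrix::t(a)) > 0
  idx <- Matrix::which(Matrix::triu(u, 1), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  if (weighting == "jaccard") {
    shared <- Matrix::tcrossprod(a)[idx]
    igraph::E(g)$weight <- shared / (2 * k - shared)
  }
  g
}

#' Leiden clustering of cells in PC space
#'
#' Clusters cells by Leiden community detection (constant Potts model
#' objective, where small resolutions such as 1e-2 are meaningful
#' inter-cluster density thresholds) on the k-NN graph of PCA scores.
#' Cluster ids are relabelled densely from 1 in decreasing size order, and
#' the partition is deterministic under `seed`.
#'
#' @param ds a [cell_dataset] with `$pca` set (see [run_pca()]).
#' @param k k-NN parameter (default 40).
#' @param resolution Leiden resolution; larger values give more clusters.
#' @param seed integer seed.
#' @param n_iterations Leiden refinement iterations.
#' @param min_cluster_cells clusters smaller than this are dissolved and
#'   their cells reassigned to the nearest surviving cluster centroid
#'   (default 5; constant-Potts partitions of noisy k-NN graphs shed a dust
#'   of singletons that cannot support marker statistics).
#' @return The dataset with integer `cluster` column in `cell_meta` and the
#'   parameters recorded in `ds$clustering`.
#' @export
leiden_cluster <- function(ds, k = 40, resolution = 1e-2, seed = 1L,
                           n_iterations = 10, min_cluster_cells = 5) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.null(ds$pca)) stop("run run_pca() first")
  memb <- leiden_membership(ds$pca$scores, k, resolution, seed, n_iterations,
                            min_cluster_cells = min_cluster_cells)
  ds$cell_meta$cluster <- memb
  ds$clustering <- list(k = k, resolution = resolution, seed = seed,
                        min_cluster_cells = min_cluster_cells)
  ds
}

leiden_membership <- function(scores, k, resolution, seed, n_iterations = 10,
                              weighting = "jaccard", min_cluster_cells = 1) {
  g <- knn_graph(scores, k, weighting = weighting)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "CPM",
                               resolution = resolution,
                               weights = igraph::E(g)$weight,
                               n_iterations = n_iterations)
  memb <- as.integer(igraph::membership(cl))
  memb <- merge_small_clusters(scores, memb, min_cluster_cells)
  # dense ids 1..K in decreasing size order (ties by first appearance)
  sizes <- sort(table(memb), decreasing = TRUE)
  as.integer(match(memb, as.integer(names(sizes))))
}

# dissolve clusters below the size floor: each of their cells joins the
# nearest (Euclidean, centroid) cluster at or above the floor
merge_small_clusters <- function(scores, memb, min_cells) {
  if (min_cells <= 1) return(memb)
  sizes <- table(memb)
  big <- as.integer(names(sizes)[sizes >= min_cells])
  if (length(big) == 0 || length(big) == length(sizes)) return(memb)
  cents <- t(vapply(big, function(c)
    colMeans(scores[memb == c, , drop = FALSE]), numeric(ncol(scores))))
  small <- which(!memb %in% big)
  d2 <- outer(rowSums(scores[small, , drop = FALSE]^2), rowSums(cents^2), "+") -
    2 * tcrossprod(scores[small, , drop = FALSE], cents)
  memb[small] <- big[max.col(-d2)]
  memb
}

#' Re-cluster the cells of selected clusters
#'
#' Re-runs Leiden on the k-NN graph built from the selected cells' own PCA
#' scores, to resolve substructure inside one or more parent clusters.
#' Nested labels are recorded as `"<parent>.<child>"`.
#'
#' @param ds a clustered [cell_dataset].
#' @param cluster_ids parent cluster ids to subset.
#' @param k,resolution,seed Leiden parameters for the re-run.
#' @return A tibble with columns `barcode`, `parent_cluster`, `subcluster`
#'   (dense within the subset) and `nested_label`.
#' @export
subset_recluster <- function(ds, cluster_ids, k = 10, resolution = 1e-2,
                             seed = 1L) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.null(ds$cell_meta$cluster)) stop("run leiden_cluster() first")
  if (!all(cluster_ids %in% ds$cell_meta$cluster))
    stop("unknown cluster id(s): ",
         paste(setdiff(cluster_ids, ds$cell_meta$cluster), collapse = ", "))
  sel <- which(ds$cell_meta$cluster %in% cluster_ids)
  if (length(sel) <= k)
    stop("subset has ", length(sel), " cells; choose k smaller than that ",
         "(currently ", k, ")")
  memb <- leiden_membership(ds$pca$scores[sel, , drop = FALSE], k, resolution,
                            seed)
  tibble::tibble(
    barcode = ds$cell_meta$barcode[sel],
    parent_cluster = ds$cell_meta$cluster[sel],
    subcluster = memb,
    nested_label = paste0(ds$cell_meta$cluster[sel], ".", memb)
  )
}
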