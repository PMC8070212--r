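#' Build a minimum-spanning-tree principal graph from node coordinates
#'
#' Lower-level constructor used by [learn_graph()]: given node coordinates
#' (one row per node), connects all nodes by their Euclidean minimum spanning
#' tree and decomposes the tree into branch segments (maximal paths whose
#' interior nodes have degree 2).
#'
#' @param nodes numeric matrix of node coordinates.
#' @param node_cluster optional integer/character label per node.
#' @return A list of class `principal_graph`: `nodes`, `node_cluster`,
#'   `edges` (tibble: from, to, length, branch), `tree` (igraph), `root`
#'   (NULL until [order_cells()]).
#' @export
mst_graph <- function(nodes, node_cluster = seq_len(nrow(nodes))) {
  nodes <- as.matrix(nodes)
  n <- nrow(nodes)
  if (n == 1) {
    warning("single node: degenerate principal graph with no edges")
    return(structure(list(nodes = nodes, node_cluster = node_cluster,
                          edges = tibble::tibble(from = integer(), to = integer(),
                                                 length = numeric(),
                                                 branch = character()),
                          tree = igraph::make_empty_graph(1, directed = FALSE),
                          root = NULL),
                     class = "principal_graph"))
  }
  d <- as.matrix(stats::dist(nodes))
  # explicit complete edge list: duplicate nodes give legitimate
  # zero-length edges, which an adjacency-matrix build would drop
  pairs <- t(utils::combn(n, 2))
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  tree <- igraph::mst(g, weights = d[pairs])
  el <- igraph::as_edgelist(tree, names = FALSE)
  len <- d[el]
  edges <- tibble::tibble(from = as.integer(el[, 1]), to = as.integer(el[, 2]),
                          length = as.numeric(len))
  edges$branch <- branch_segments(edges, n)
  structure(list(nodes = nodes, node_cluster = node_cluster, edges = edges,
                 tree = tree, root = NULL),
            class = "principal_graph")
}

# group tree edges into maximal paths: two edges share a segment iff they
# meet at a node of degree 2. Labels are "B1".."Bm", ordered by the smallest
# node id in each segment for determinism.
branch_segments <- function(edges, n_nodes) {
  deg <- tabulate(c(edges$from, edges$to), n_nodes)
  parent <- seq_len(nrow(edges))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (v in which(deg == 2)) {
    inc <- which(edges$from == v | edges$to == v)
    parent[find(inc[2])] <- find(inc[1])
  }
  comp <- vapply(seq_len(nrow(edges)), find, integer(1))
  key <- vapply(split(pmin(edges$from, edges$to), comp), min, numeric(1))
  lab <- stats::setNames(paste0("B", rank(key, ties.method = "first")),
                         names(key))
  unname(lab[as.character(comp)])
}

#' Learn a principal graph over clustered cells
#'
#' Computes one or more centroid nodes per cluster in PC space (k-means
#' sub-centroids when `nodes_per_cluster > 1`) and connects them by their
#' Euclidean minimum spanning tree. This is a deliberately simple,
#' deterministic stand-in for iterative principal-graph optimisers: for
#' branching topologies resolved by clustering it recovers the same tree
#' structure, and all downstream statistics depend only on the tree and the
#' cells' projections onto it.
#'
#' @param ds a clustered [cell_dataset] with `$pca`.
#' @param nodes_per_cluster centroids per cluster (default 1; more refines
#'   geodesics within elongated clusters).
#' @param seed seed for the k-means sub-centroids.
#' @return A `principal_graph` (see [mst_graph()]).
#' @export
learn_graph <- function(ds, nodes_per_cluster = 1, seed = 1L) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.null(ds$pca)) stop("run run_pca() first")
  cl <- ds$cell_meta$cluster
  if (is.null(cl)) stop("run leiden_cluster() first")
  clusters <- sort(unique(cl))
  if (length(clusters) < 2)
    warning("fewer than 2 clusters: the principal graph is degenerate")
  set.seed(seed)
  cents <- list(); labs <- list()
  for (c in clusters) {
    x <- ds$pca$scores[cl == c, , drop = FALSE]
    # kmeans needs strictly fewer centres than (distinct) points
    kk <- max(1L, min(nodes_per_cluster, nrow(unique(x)) - 1L))
    if (kk > 1) {
      km <- stats::kmeans(x, centers = kk, nstart = 5, iter.max = 50)
      cents[[length(cents) + 1]] <- km$centers
      labs[[length(labs) + 1]] <- rep(c, kk)
    } else {
      cents[[length(cents) + 1]] <- matrix(colMeans(x), nrow = 1)
      labs[[length(labs) + 1]] <- c
    }
  }
  mst_graph(do.call(rbind, cents), unlist(labs))
}

#' Order cells in pseudotime along a principal graph
#'
#' Projects each cell onto the nearest point of the nearest tree edge and
#' assigns pseudotime as the geodesic (along-tree) distance from the root
#' node to that projected point; the root projects to pseudotime 0. The root
#' is either an explicit node id or the node of the cluster annotated
#' `root_type` that is farthest (in tree distance) from the rest of the
#' graph, i.e. the tip of the stem compartment.
#'
#' @param ds a clustered, annotated [cell_dataset] with `$pca`.
#' @param graph a `principal_graph` from [learn_graph()].
#' @param root explicit root node id (overrides `root_type`).
#' @param root_type cell-type annotation defining the root cluster
#'   (default `"Stem"`).
#' @return The dataset with `pseudotime`, `branch` and `graph_edge` columns
#'   in `cell_meta`, and `ds$trajectory` set to the rooted graph.
#' @export
order_cells <- function(ds, graph, root = NULL, root_type = "Stem") {
  stopifnot(inherits(ds, "cell_dataset"), inherits(graph, "principal_graph"))
  if (nrow(graph$edges) == 0) stop("degenerate principal graph: no edges")
  n_nodes <- nrow(graph$nodes)
  if (is.null(root)) {
    if (is.null(ds$cell_meta$cell_type))
      stop("no cell_type annotation; pass an explicit root node id")
    cl_of_type <- ds$cell_meta$cluster[ds$cell_meta$cell_type == root_type]
    if (length(cl_of_type) == 0)
      stop("no cluster annotated '", root_type, "'")
    # the root compartment is taken as the *largest* cluster of the root
    # type (fragmented transitional clusters can share its annotation);
    # within it, the node farthest from the rest of the tree is the tip
    big <- as.integer(names(which.max(table(cl_of_type))))
    cand <- which(graph$node_cluster == big)
    if (length(cand) == 0)
      stop("no graph node belongs to a cluster annotated '", root_type, "'")
    dall <- igraph::distances(graph$tree, weights = edge_weights(graph))
    root <- cand[which.max(rowSums(dall[cand, , drop = FALSE]))]
  }
  if (!root %in% seq_len(n_nodes)) stop("root node id ", root, " not in graph")

  proj <- project_cells(ds$pca$scores, graph)
  d_root <- igraph::distances(graph$tree, v = root,
                              weights = edge_weights(graph))[1, ]
  e <- graph$edges[proj$edge, ]
  pt <- pmin(d_root[e$from] + proj$offset, d_root[e$to] + e$length - proj$offset)
  ds$cell_meta$pseudotime <- pmax(as.numeric(pt), 0)  # clamp -0.0 roundoff
  ds$cell_meta$branch <- e$branch
  ds$cell_meta$graph_edge <- proj$edge
  graph$root <- root
  ds$trajectory <- graph
  ds
}

edge_weights <- function(graph) {
  el <- igraph::as_edgelist(graph$tree, names = FALSE)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  ekey <- paste(pmin(graph$edges$from, graph$edges$to),
                pmax(graph$edges$from, graph$edges$to))
  graph$edges$length[match(key, ekey)]
}

# nearest-edge projection of score rows onto tree edges; returns the edge
# index, the arc-length offset from the edge's `from` node, and the distance
project_cells <- function(scores, graph) {
  n <- nrow(scores)
  best_d2 <- rep(Inf, n); best_e <- integer(n); best_off <- numeric(n)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$nodes[graph$edges$from[i], ]
    b <- graph$nodes[graph$edges$to[i], ]
    ab <- b - a
    len2 <- sum(ab^2)
    xa <- sweep(scores, 2, a, "-")
    tt <- if (len2 > 0) pmin(1, pmax(0, (xa %*% ab) / len2)) else rep(0, n)
    d2 <- rowSums((xa - tcrossprod(tt, ab))^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; best_e[upd] <- i
    best_off[upd] <- tt[upd] * sqrt(len2)
  }
  list(edge = best_e, offset = best_off, dist = sqrt(best_d2))
}

#' Linearly rescale pseudotime to a fixed maximum
#'
#' Pseudotime from [order_cells()] is in PC-space geodesic units, which are
#' not comparable across separately learned trajectories. Rescaling both
#' genotypes to a common maximum makes unit-width bins mean the same thing
#' in both.
#'
#' @param pt numeric pseudotime vector (or a [cell_dataset]).
#' @param max_units target maximum.
#' @return Rescaled vector (or dataset with rescaled `pseudotime`).
#' @export
rescale_pseudotime <- function(pt, max_units) {
  if (inherits(pt, "cell_dataset")) {
    pt$cell_meta$pseudotime <- rescale_pseudotime(pt$cell_meta$pseudotime,
                                                  max_units)
    return(pt)
  }
  m <- max(pt)
  if (!is.finite(m) || m <= 0) stop("pseudotime must have a positive maximum")
  pt * (max_units / m)
}

#' @exportS3Method base::print
print.principal_graph <- function(x, ...) {
  cat("<principal_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", length(unique(x$edges$branch)), " branch segments",
      if (!is.null(x$root)) paste0(", root ", x$root), "\n", sep = "")
  invisible(x)
}
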