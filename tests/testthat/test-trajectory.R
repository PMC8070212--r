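# helper: wrap a score matrix + cluster labels into a minimal dataset that
# learn_graph()/order_cells() accept
scores_dataset <- function(scores, cluster, cell_type = NULL) {
  n <- nrow(scores)
  ds <- cell_dataset(matrix(1L, 2, n), c("g1", "g2"), c("g1", "g2"),
                     sprintf("c%04d", seq_len(n)))
  ds$pca <- structure(list(scores = scores, loadings = NULL,
                           explained_variance = rep(1, ncol(scores)),
                           n_pc = ncol(scores)),
                      class = "fatebin_pca")
  ds$cell_meta$cluster <- cluster
  if (!is.null(cell_type)) ds$cell_meta$cell_type <- cell_type
  ds
}

test_that("collinear centroids give a path graph with additive lengths", {
  g <- mst_graph(cbind(c(0, 1, 2), 0))
  expect_equal(nrow(g$edges), 2)
  expect_equal(sum(g$edges$length), 2)
  deg <- tabulate(c(g$edges$from, g$edges$to), 3)
  expect_equal(sort(deg), c(1, 1, 2))              # a path, not a star
  expect_equal(length(unique(g$edges$branch)), 1)  # one maximal segment
})

test_that("the MST matches exhaustive spanning-tree enumeration", {
  # Y-shaped layout: hub at origin, three arms
  y_nodes <- rbind(c(0, 0), c(2, 0), c(-1.5, 1.5), c(-1.5, -1.5))
  g <- mst_graph(y_nodes)
  d <- as.matrix(dist(y_nodes))
  expect_equal(sum(g$edges$length), mst_exhaustive_weight(d))
  hub_degree <- tabulate(c(g$edges$from, g$edges$to), 4)[1]
  expect_equal(hub_degree, 3)                      # the Y is reproduced
  expect_equal(length(unique(g$edges$branch)), 3)  # three branch segments

  # random 6-node configurations
  for (s in 1:5) {
    set.seed(s)
    nodes <- matrix(rnorm(12), 6, 2)
    g <- mst_graph(nodes)
    expect_equal(nrow(g$edges), 5)                 # tree: |E| = |V| - 1
    expect_equal(sum(g$edges$length),
                 mst_exhaustive_weight(as.matrix(dist(nodes))),
                 tolerance = 1e-12)
  }
})

test_that("duplicate centroids yield a zero-length edge but stay a tree", {
  g <- mst_graph(rbind(c(0, 0), c(0, 0), c(3, 0)))
  expect_equal(nrow(g$edges), 2)
  expect_equal(min(g$edges$length), 0)
  expect_true(igraph::is_connected(g$tree))
})

test_that("pseudotime is geodesic distance from the root", {
  # path of nodes at x = 0, 1, 3 (edges 1.0 and 2.0); one cell per node
  nodes <- cbind(c(0, 1, 3), 0)
  scores <- nodes
  ds <- scores_dataset(scores, cluster = 1:3,
                       cell_type = c("Stem", "Mid", "End"))
  g <- mst_graph(nodes, node_cluster = 1:3)
  ds <- order_cells(ds, g, root = 1)
  expect_equal(ds$cell_meta$pseudotime, c(0, 1, 3))  # additivity along path

  # halfway along the second edge
  ds2 <- scores_dataset(rbind(nodes, c(2, 0)), cluster = c(1:3, 2),
                        cell_type = "x")
  ds2 <- order_cells(ds2, g, root = 1)
  expect_equal(ds2$cell_meta$pseudotime[4], 2)

  # annotated root selection hits the stem tip
  ds3 <- order_cells(ds, g, root_type = "Stem")
  expect_equal(ds3$trajectory$root, 1)
  expect_error(order_cells(ds, g, root = 99), "not in graph")
  expect_error(order_cells(ds, g, root_type = "NoSuchType"), "no cluster")
})

test_that("pseudotime is invariant to cell order and rigid rotation", {
  set.seed(41)
  t_true <- sort(runif(120, 0, 10))
  scores <- cbind(t_true, 0.3 * rnorm(120), 0.3 * rnorm(120))
  cl <- as.integer(cut(t_true, 4))
  ds <- scores_dataset(scores, cl, cell_type = ifelse(cl == 1, "Stem", "Rest"))
  g <- learn_graph(ds, seed = 1)
  p1 <- order_cells(ds, g)$cell_meta$pseudotime

  # rigid rotation of the embedding
  qr_rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  ds_rot <- scores_dataset(scores %*% qr_rot, cl,
                           cell_type = ds$cell_meta$cell_type)
  g_rot <- learn_graph(ds_rot, seed = 1)
  p2 <- order_cells(ds_rot, g_rot)$cell_meta$pseudotime
  expect_equal(p2, p1, tolerance = 1e-8)

  # permutation of cells
  perm <- sample(120)
  ds_perm <- scores_dataset(scores[perm, ], cl[perm],
                            cell_type = ds$cell_meta$cell_type[perm])
  g_perm <- learn_graph(ds_perm, seed = 1)
  p3 <- order_cells(ds_perm, g_perm)$cell_meta$pseudotime
  expect_equal(p3, p1[perm], tolerance = 1e-8)
})

test_that("a noisy linear lineage is ordered with Spearman >= 0.9", {
  set.seed(42)
  n <- 400
  t_true <- runif(n, 0, 10)
  scores <- cbind(t_true, matrix(rnorm(n * 3, sd = 0.5), n, 3))
  cl <- as.integer(cut(t_true, 5))
  ds <- scores_dataset(scores, cl, cell_type = ifelse(cl == 1, "Stem", "Rest"))
  g <- learn_graph(ds, nodes_per_cluster = 3, seed = 1)
  ds <- order_cells(ds, g)
  expect_gt(cor(ds$cell_meta$pseudotime, t_true, method = "spearman"), 0.9)
})

test_that("pseudotime rescaling is linear, monotone and guarded", {
  expect_equal(rescale_pseudotime(c(0, 5, 10), 20), c(0, 10, 20))
  pt <- c(0.3, 2, 7.7)
  expect_equal(rescale_pseudotime(pt, max(pt)), pt)    # identity at own max
  expect_equal(order(rescale_pseudotime(pt, 3)), order(pt))
  expect_error(rescale_pseudotime(c(0, 0, 0), 10), "positive maximum")
})

test_that("degenerate graphs warn or error cleanly", {
  expect_warning(g <- mst_graph(matrix(c(1, 2), 1, 2)), "single node")
  ds <- scores_dataset(matrix(rnorm(20), 10, 2), cluster = rep(1L, 10))
  # one cluster warns twice: once for the cluster count, once for the
  # resulting single-node graph
  expect_warning(expect_warning(g1 <- learn_graph(ds, seed = 1),
                                "fewer than 2 clusters"),
                 "single node")
  g1node <- suppressWarnings(mst_graph(matrix(c(1, 2), 1, 2)))
  expect_error(order_cells(ds, g1node), "degenerate")
})
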