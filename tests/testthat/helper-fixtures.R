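# Small deterministic fixtures shared across test files.

# tiny hand-built dataset: 4 genes x 3 cells
tiny_dataset <- function() {
  counts <- matrix(c(
    5, 0, 2,
    0, 3, 1,
    1, 1, 0,
    0, 0, 0
  ), nrow = 4, byrow = TRUE)
  cell_dataset(counts,
               gene_ids = paste0("G", 1:4),
               gene_short_names = c("Alpha", "Beta", "Gamma", "Delta"),
               barcodes = paste0("C", 1:3),
               genotype = "WT")
}

# small simulated experiment reused by clustering/trajectory tests
small_sim <- function(seed = 42, n_wt = 700, n_ko = 500, n_genes = 500) {
  simulate_dataset(sim_config(
    n_cells_wt = n_wt, n_cells_ko = n_ko, n_genes = n_genes,
    markers_per_type = 12, n_gradient_genes = 80, seed = seed))
}

# run a dataset through normalize -> pca -> cluster -> annotate
prep_dataset <- function(sim, genotype = "WT", n_pc = 14, k = 25,
                         resolution = 1e-2, seed = 1) {
  ds <- normalize_cells(sim$datasets[[genotype]])
  ds <- run_pca(ds, n_pc = n_pc, seed = seed)
  ds <- leiden_cluster(ds, k = k, resolution = resolution, seed = seed)
  mk <- filter_markers(top_markers(ds), 0.10)
  apply_annotation(ds, annotate_clusters(mk, reference_markers(sim)))
}

# well-separated Gaussian blobs in a score matrix
make_blobs <- function(centers, n_per, sd = 1, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(stats::rnorm(n_per * ncol(centers), sd = sd), ncol = ncol(centers)) +
      rep(centers[i, ], each = n_per)))
  list(scores = x, label = rep(seq_len(nrow(centers)), each = n_per))
}

# adjusted Rand index (used to compare partitions to planted labels)
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sum_ij <- comb2(tab)
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
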