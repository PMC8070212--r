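# a hand-built trajectory: root -> hub, then two arms (A up, B right);
# marker expressed only on arm B. Returns an ordered, normalized dataset.
branch_fixture <- function(n_per = 60, marker_on = "B", seed = 1) {
  set.seed(seed)
  nodes <- rbind(c(0, 0), c(4, 0), c(4, 4), c(8, 0), c(12, 0))
  arm <- c("root", "hub", "A", "B", "B")
  t_of <- function(seg) runif(n_per, 0, 1)
  cells <- rbind(
    cbind(runif(n_per, 0, 4), 0),                    # root -> hub
    cbind(4, runif(n_per, 0, 4)),                    # arm A
    cbind(runif(n_per, 4, 12), 0))                   # arm B
  cells <- cells + matrix(rnorm(length(cells), sd = 0.15), ncol = 2)
  lab <- rep(c("trunk", "A", "B"), each = n_per)
  n <- nrow(cells)
  counts <- matrix(rpois(3 * n, 2) + 1L, nrow = 3)
  counts[1, lab == marker_on] <- counts[1, lab == marker_on] + 25L
  ds <- cell_dataset(counts, c("marker", "g2", "g3"),
                     c("Atoh1", "Other", "Third"), sprintf("c%04d", 1:n),
                     genotype = "WT")
  ds <- normalize_cells(ds)
  ds$pca <- structure(list(scores = cells, loadings = NULL,
                           explained_variance = c(1, 1), n_pc = 2),
                      class = "fatebin_pca")
  ds$cell_meta$cluster <- rep(1:3, each = n_per)
  ds$cell_meta$cell_type <- rep(c("Stem", "A", "B"), each = n_per)
  g <- mst_graph(nodes, node_cluster = c(1, 1, 2, 3, 3))
  ds <- order_cells(ds, g, root = 1)
  list(ds = ds, lab = lab)
}

test_that("the marker-high arm is selected with high recall", {
  fx <- branch_fixture()
  b <- identify_branch(fx$ds, "Atoh1", quantile = 0.5)
  sel <- fx$ds$cell_meta$barcode %in% b$barcodes
  expect_gt(mean(sel[fx$lab == "B"]), 0.9)       # recall on the true arm
  expect_lt(mean(sel[fx$lab == "A"]), 0.15)      # the other arm is excluded
  expect_error(identify_branch(fx$ds, "NoSuchGene"), "unknown gene")
})

test_that("quantile 0 selects the whole tree and uniform markers error", {
  fx <- branch_fixture()
  expect_warning(b <- identify_branch(fx$ds, "Atoh1", quantile = 0),
                 "whole tree")
  expect_setequal(b$edges, seq_len(nrow(fx$ds$trajectory$edges)))

  flat <- fx$ds
  flat$norm[1, ] <- 1   # identical mean on every edge
  expect_error(identify_branch(flat, "Atoh1", quantile = 0.75),
               "no edge exceeds")
})

test_that("branch selection extends downstream past the threshold run", {
  # marker high only on the proximal half of arm B: distal cells must still
  # be captured by the downstream extension
  fx <- branch_fixture()
  ds <- fx$ds
  distal <- ds$pca$scores[, 1] > 8 & fx$lab == "B"
  ds$norm[1, distal] <- 0
  b <- identify_branch(ds, "Atoh1", quantile = 0.6)
  sel <- ds$cell_meta$barcode %in% b$barcodes
  expect_gt(mean(sel[distal]), 0.9)
})

# branch fit fixture: expression is an exact or noisy function of pseudotime
fit_fixture <- function(f, n = 80, sd = 0, genotype = "WT", seed = 1) {
  set.seed(seed)
  t <- seq(0, 5, length.out = n)
  y <- f(t) + rnorm(n, sd = sd)
  ds <- cell_dataset(matrix(1L, 2, n), c("g1", "g2"), c("Target", "Other"),
                     sprintf("%s%04d", genotype, 1:n), genotype = genotype)
  ds$size_factors <- rep(1, n)
  ds$norm <- methods::as(methods::as(
    rbind(y, 0), "CsparseMatrix"), "generalMatrix")
  dimnames(ds$norm) <- dimnames(ds$counts)
  ds$cell_meta$pseudotime <- t
  ds
}

test_that("a noiseless quadratic is interpolated exactly at degree >= 2", {
  ds <- fit_fixture(function(t) t^2)
  # summary.lm warns on an exactly interpolated fit; that is the point here
  fit <- suppressWarnings(
    fit_branch_gene(ds, ds$cell_meta$barcode, "Target", degree = 2))
  expect_lt(max(abs(predict(fit, ds$cell_meta$pseudotime) -
                      ds$cell_meta$pseudotime^2)), 1e-10)
  expect_lt(fit$f_p_value, 1e-10)
})

test_that("a constant gene has null coefficients and an n.s. F-test", {
  ds <- fit_fixture(function(t) rep(2, length(t)), sd = 0.3, seed = 2)
  fit <- fit_branch_gene(ds, ds$cell_meta$barcode, "Target", degree = 3)
  expect_true(all(abs(fit$coefficients[-1]) < 1))
  expect_gt(fit$f_p_value, 0.05)
})

test_that("polynomial fits equal the raw normal-equations solution", {
  set.seed(3)
  t <- runif(10, 0, 4)
  y <- 1 + 0.5 * t - 0.2 * t^2 + rnorm(10, sd = 0.3)
  ds <- fit_fixture(function(t) t, n = 10)
  ds$cell_meta$pseudotime <- t
  ds$norm[1, ] <- y
  fit <- fit_branch_gene(ds, ds$cell_meta$barcode, "Target", degree = 2)
  beta <- normal_eq_poly(t, y, 2)
  grid <- seq(min(t), max(t), length.out = 20)
  expect_lt(max(abs(predict(fit, grid) -
                      (beta[1] + beta[2] * grid + beta[3] * grid^2))), 1e-8)
})

test_that("fit preconditions are enforced", {
  ds <- fit_fixture(function(t) t, n = 4)
  expect_error(fit_branch_gene(ds, ds$cell_meta$barcode, "Target", degree = 3),
               "need >=")
  ds2 <- fit_fixture(function(t) t, n = 20)
  ds2$cell_meta$pseudotime <- rep(1, 20)
  expect_error(fit_branch_gene(ds2, ds2$cell_meta$barcode, "Target"),
               "zero pseudotime variance")
})

test_that("identical genotypes show no divergence; planted slopes are found", {
  wt <- fit_fixture(function(t) 1 + t, sd = 0.2, genotype = "WT", seed = 4)
  ko_same <- fit_fixture(function(t) 1 + t, sd = 0.2, genotype = "TKO", seed = 4)
  f1 <- fit_branch_gene(wt, wt$cell_meta$barcode, "Target")
  f2 <- fit_branch_gene(ko_same, ko_same$cell_meta$barcode, "Target")
  cmp <- compare_fits(f1, f2)
  expect_equal(cmp$slope_difference, 0, tolerance = 1e-10)
  expect_gt(cmp$p_value, 0.99)

  # TKO gains 2t beyond t* = 2.5: mean slope difference ~ 2 * (2.5/5) = 1
  ko_div <- fit_fixture(function(t) 1 + t + 2 * pmax(t - 2.5, 0), sd = 0.2,
                        genotype = "TKO", seed = 5)
  f3 <- fit_branch_gene(ko_div, ko_div$cell_meta$barcode, "Target")
  cmp2 <- compare_fits(f1, f3)
  expect_gt(cmp2$slope_difference, 0.5)
  expect_lt(cmp2$p_value, 1e-6)

  # swapping genotypes negates the difference and keeps p
  cmp_swap <- compare_fits(f3, f1)
  expect_equal(cmp_swap$slope_difference, -cmp2$slope_difference)
  expect_equal(cmp_swap$p_value, cmp2$p_value)
})

test_that("the divergence t-statistic agrees with a parametric bootstrap", {
  wt <- fit_fixture(function(t) 1 + 0.6 * t, sd = 0.4, genotype = "WT",
                    seed = 6)
  ko <- fit_fixture(function(t) 1 + 0.9 * t, sd = 0.4, genotype = "TKO",
                    seed = 7)
  f1 <- fit_branch_gene(wt, wt$cell_meta$barcode, "Target")
  f2 <- fit_branch_gene(ko, ko$cell_meta$barcode, "Target")
  cmp <- compare_fits(f1, f2)
  lo <- cmp$support[1]; hi <- cmp$support[2]
  tev <- c(f1$t, f2$t); tev <- tev[tev >= lo & tev <= hi]
  tc <- tev - mean(tev)
  lin_slope <- function(fit) matrix(
    colSums(tc * fatebin:::branch_design(fit, tev)) / sum(tc^2), nrow = 1)
  a1 <- lin_slope(f1)
  a2 <- lin_slope(f2)
  set.seed(8)
  draws <- replicate(5000, {
    b1 <- MASS::mvrnorm(1, f1$coefficients, f1$vcov)
    b2 <- MASS::mvrnorm(1, f2$coefficients, f2$vcov)
    as.numeric(a2 %*% b2 - a1 %*% b1)
  })
  expect_equal(sd(draws), cmp$std_error, tolerance = 0.05)
  expect_lt(abs(mean(draws) - cmp$slope_difference),
            3 * sd(draws) / sqrt(5000))
})

test_that("divergent genes require significance in all three tests", {
  # between-genotype shift without pseudotime dependence must be excluded
  wt <- fit_fixture(function(t) rep(1, length(t)), sd = 0.2, seed = 9)
  ko <- fit_fixture(function(t) rep(3, length(t)), sd = 0.2,
                    genotype = "TKO", seed = 10)
  res <- branch_divergence(wt, ko, wt$cell_meta$barcode,
                           ko$cell_meta$barcode, "Target")
  expect_equal(call_divergent_genes(res), character(0))
  expect_equal(call_divergent_genes(res, alpha = 0), character(0))

  wt2 <- fit_fixture(function(t) 1 + t, sd = 0.2, seed = 11)
  ko2 <- fit_fixture(function(t) 1 + t + 1.5 * pmax(t - 2, 0), sd = 0.2,
                     genotype = "TKO", seed = 12)
  res2 <- branch_divergence(wt2, ko2, wt2$cell_meta$barcode,
                            ko2$cell_meta$barcode, c("Target", "Other"))
  expect_equal(call_divergent_genes(res2), "Target")
  expect_true(all(call_divergent_genes(res2, 0.001) %in%
                    call_divergent_genes(res2, 0.05)))
  expect_equal(glance(res2)$n_divergent, 1)
})

test_that("null divergence p-values are uniform", {
  set.seed(13)
  n_genes <- 400; n <- 150
  t_wt <- runif(n, 0, 5); t_ko <- runif(n, 0, 5)
  mk <- function(t, genotype) {
    y <- matrix(2 + 0.5 * t, n_genes, n, byrow = TRUE) +
      matrix(rnorm(n_genes * n, sd = 0.5), n_genes)
    ds <- cell_dataset(matrix(1L, n_genes, n), paste0("g", seq_len(n_genes)),
                       paste0("Gene", seq_len(n_genes)),
                       sprintf("%s%04d", genotype, seq_len(n)),
                       genotype = genotype)
    ds$size_factors <- rep(1, n)
    ds$norm <- methods::as(methods::as(y, "CsparseMatrix"), "generalMatrix")
    ds$cell_meta$pseudotime <- t
    ds
  }
  wt <- mk(t_wt, "WT"); ko <- mk(t_ko, "TKO")
  res <- branch_divergence(wt, ko, wt$cell_meta$barcode, ko$cell_meta$barcode,
                           paste0("Gene", seq_len(n_genes)))
  p <- res$results$p_value
  expect_true(all(is.finite(p)))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
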