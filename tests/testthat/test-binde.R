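# two small datasets with controlled counts for combine tests
combine_fixture <- function() {
  wt <- cell_dataset(matrix(1:6, 3), paste0("g", 1:3), paste0("n", 1:3),
                     c("a", "b"), genotype = "WT")
  ko <- cell_dataset(matrix(7:12, 3), paste0("g", 1:3), paste0("n", 1:3),
                     c("c", "d"), genotype = "TKO")
  list(wt = wt, ko = ko)
}

test_that("combining concatenates cells over the shared gene universe", {
  fx <- combine_fixture()
  comb <- combine_datasets(fx$wt, fx$ko)
  expect_equal(ncol(comb$counts), 4)
  expect_equal(comb$cell_meta$genotype, c("WT", "WT", "TKO", "TKO"))

  # overlapping barcodes get suffixed
  ko2 <- fx$ko; ko2$cell_meta$barcode <- c("a", "d")
  colnames(ko2$counts) <- c("a", "d")
  comb2 <- combine_datasets(fx$wt, ko2)
  expect_equal(ncol(comb2$counts), 4)
  expect_false(anyDuplicated(comb2$cell_meta$barcode) > 0)

  # shuffled gene order in one input is realigned by gene id
  ko3 <- fx$ko
  ko3$counts <- ko3$counts[c(3, 1, 2), ]
  ko3$gene_meta <- ko3$gene_meta[c(3, 1, 2), ]
  comb3 <- combine_datasets(fx$wt, ko3)
  expect_equal(as.numeric(comb3$counts[, 3]),
               as.numeric(fx$ko$counts[comb3$gene_meta$gene_id, 1]))

  # partial overlap intersects with a warning; none errors
  ko4 <- fx$ko; ko4$gene_meta$gene_id <- c("g2", "g3", "gX")
  rownames(ko4$counts) <- ko4$gene_meta$gene_id
  expect_warning(comb4 <- combine_datasets(fx$wt, ko4), "intersecting")
  expect_equal(nrow(comb4$counts), 2)
  ko5 <- fx$ko; ko5$gene_meta$gene_id <- paste0("x", 1:3)
  rownames(ko5$counts) <- ko5$gene_meta$gene_id
  expect_error(combine_datasets(fx$wt, ko5), "no genes in common")
})

test_that("binning is a half-open floor partition", {
  expect_equal(bin_cells(c(0.2, 0.9, 1.5, 2.0)), c(0L, 0L, 1L, 2L))
  expect_equal(bin_cells(c(0.2, 1.9, 2.1), width = 2), c(0L, 0L, 1L))
  pt <- runif(500, 0, 17)
  b <- bin_cells(pt)
  expect_equal(sum(table(b)), 500)                       # partition
  expect_true(all(pt >= b & pt < b + 1))
  expect_error(bin_cells(c(1, -0.1)), "non-negative")
  expect_error(bin_cells(c(1, NA)), "finite")
})

# synthetic combined dataset with direct control of per-bin counts
binde_fixture <- function(n_per = 120, n_genes = 12, fold = 1, disp = 0.4,
                          bins = 3, seed = 1, true_sf = FALSE) {
  set.seed(seed)
  n <- 2 * n_per * bins
  genotype <- rep(rep(c("WT", "TKO"), each = n_per), bins)
  pt <- rep(seq_len(bins) - 0.5, each = 2 * n_per)
  sf <- rlnorm(n, 0, 0.2)
  mu <- outer(rep(0.8, n_genes), sf)
  mu[, genotype == "TKO"] <- mu[, genotype == "TKO"] * fold
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / disp),
                   nrow = n_genes)
  counts[1, ] <- counts[1, ] + 1L   # keep gene 1 clear of all-zero bins
  ds <- cell_dataset(counts, paste0("g", seq_len(n_genes)),
                     paste0("Gene", seq_len(n_genes)),
                     sprintf("c%05d", seq_len(n)))
  ds$cell_meta$genotype <- genotype
  ds$cell_meta$pseudotime <- pt
  ds <- normalize_cells(ds)
  # a fold applied to *every* gene is a depth shift that estimated size
  # factors absorb; coefficient-recovery tests use the generating factors
  if (true_sf)
    ds$size_factors <- stats::setNames(sf, ds$cell_meta$barcode)
  ds
}

test_that("a planted four-fold genotype effect is recovered as ln 4", {
  ds <- binde_fixture(n_per = 200, n_genes = 25, fold = 4, disp = 0.2,
                      bins = 1, seed = 2, true_sf = TRUE)
  res <- fit_bin_regressions(ds, alpha = 0.05)
  expect_equal(mean(res$long$estimate), log(4), tolerance = 0.05)
  expect_true(all(res$long$p_value < 0.05))
  expect_equal(nrow(res$wide), 25)
})

test_that("the genotype coefficient matches an independent IRLS solver", {
  ds <- binde_fixture(n_per = 80, n_genes = 2, fold = 2.5, seed = 3,
                      true_sf = TRUE)
  lsf <- log(unname(ds$size_factors))
  g <- factor(ds$cell_meta$genotype, levels = c("WT", "TKO"))
  x <- stats::model.matrix(~g)
  for (gene in 1:2) {
    y <- as.numeric(ds$counts[gene, ])
    fit <- fatebin:::nb_genotype_fit(y, g, lsf, x = x)
    expect_equal(fit$family, "negbin")
    oracle <- irls_nb_oracle(y, x, lsf, theta = fit$theta)
    expect_lt(abs(fit$estimate - oracle$coefficients[2]), 1e-6)
    expect_lt(abs(fit$std_error - sqrt(oracle$cov[2, 2])), 1e-6)
  }
})

test_that("the wide table holds exactly the significant genotype terms", {
  ds <- binde_fixture(n_per = 60, n_genes = 30, fold = 1.6, bins = 4, seed = 4)
  res <- fit_bin_regressions(ds, alpha = 0.05)
  long_sig <- res$long[!is.na(res$long$p_value) & res$long$p_value < 0.05, ]
  wide_long <- tidyr::pivot_longer(res$wide, -gene, names_to = "bin",
                                   values_to = "estimate",
                                   values_drop_na = TRUE)
  expect_equal(nrow(wide_long), nrow(long_sig))
  expect_setequal(wide_long$estimate, long_sig$estimate)
  # genes appear once; no column is an intercept
  expect_false(anyDuplicated(res$wide$gene) > 0)
  expect_false(any(grepl("intercept", names(res$wide), ignore.case = TRUE)))

  # lowering alpha never adds entries
  res01 <- fit_bin_regressions(ds, alpha = 0.01)
  keys <- function(r) paste(r$gene, r$bin)[!is.na(r$p_value) &
                                             r$p_value < r$alpha]
  sig05 <- res$long[!is.na(res$long$p_value) & res$long$p_value < 0.05, ]
  sig01 <- res01$long[!is.na(res01$long$p_value) & res01$long$p_value < 0.01, ]
  expect_true(all(paste(sig01$gene, sig01$bin) %in%
                    paste(sig05$gene, sig05$bin)))
})

test_that("small bins are skipped and all-zero genes marked untestable", {
  ds <- binde_fixture(n_per = 30, n_genes = 5, bins = 2, seed = 5)
  # push one bin below the per-genotype floor
  ds$cell_meta$pseudotime[ds$cell_meta$pseudotime > 1][1:45] <- 0.5
  expect_message(res <- fit_bin_regressions(ds, min_cells_per_genotype = 20),
                 "skipping bin")
  expect_true(length(res$skipped_bins) >= 1)

  ds2 <- binde_fixture(n_per = 30, n_genes = 5, bins = 1, seed = 6)
  ds2$counts[3, ] <- 0
  res2 <- fit_bin_regressions(ds2)
  row3 <- res2$long[res2$long$gene == "Gene3", ]
  expect_equal(row3$family, "untestable")
  expect_true(is.na(row3$p_value))
})

test_that("candidate selection is a plain intersection", {
  ds <- binde_fixture(n_per = 100, n_genes = 8, fold = 3, bins = 1, seed = 7)
  res <- fit_bin_regressions(ds)
  expect_equal(select_candidates(res, character(0)), character(0))
  expect_equal(select_candidates(res, res$wide$gene), res$wide$gene)
  expect_equal(select_candidates(res, c("Gene2", "NoSuch")),
               intersect(res$wide$gene, "Gene2"))
})

test_that("tidiers expose the long table and a one-row summary", {
  ds <- binde_fixture(n_per = 60, n_genes = 6, fold = 2, bins = 2, seed = 8)
  res <- fit_bin_regressions(ds)
  expect_identical(tidy(res), res$long)
  gl <- glance(res)
  expect_equal(gl$n_genes_tested, 6)
  expect_equal(gl$alpha, 0.05)
})
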