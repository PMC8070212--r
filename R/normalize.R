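#' Size-factor log-normalization
#'
#' Computes per-cell size factors as library size over the geometric mean of
#' library sizes, then stores a log-normalized layer
#' `ln(count / size_factor + 1)`. Raw counts are retained unmodified; the
#' size factors are reused downstream as offsets in the per-bin
#' negative-binomial regressions.
#'
#' @param ds a [cell_dataset].
#' @return The dataset with `size_factors` and a sparse `norm` layer set.
#' @export
normalize_cells <- function(ds) {
  stopifnot(inherits(ds, "cell_dataset"))
  libsize <- Matrix::colSums(ds$counts)
  if (any(libsize == 0))
    stop("cell(s) with zero total count: ",
         paste(utils::head(ds$cell_meta$barcode[libsize == 0], 5),
               collapse = ", "))
  sf <- libsize / exp(mean(log(libsize)))
  norm <- ds$counts
  # ln(count/sf + 1): zeros stay zero, so sparsity is preserved
  norm@x <- log1p(norm@x / rep.int(sf, diff(norm@p)))
  ds$size_factors <- stats::setNames(as.numeric(sf), ds$cell_meta$barcode)
  ds$norm <- norm
  ds
}

#' Principal component reduction of the normalized layer
#'
#' PCA of the cells x genes log-normalized matrix. Genes are centered and,
#' optionally, unit-scaled. For small problems the decomposition is an exact
#' SVD; above `exact_max` cells a seeded randomized SVD (Gaussian sketch with
#' power iterations) computes the leading components. PC signs follow the
#' convention that each component's largest-magnitude gene loading is
#' positive, so results are reproducible across numerical backends.
#'
#' @param ds a [cell_dataset] with a normalized layer (see [normalize_cells()]).
#' @param n_pc number of components (default 14).
#' @param scale_genes unit-scale genes before decomposition (default FALSE;
#'   genes with zero variance are left unscaled).
#' @param exact_max use exact SVD when `min(cells, genes) <=` this.
#' @param seed seed for the randomized sketch.
#' @return The dataset with `$pca` set: a list of class `fatebin_pca` with
#'   `scores` (cells x n_pc), `loadings` (genes x n_pc, column-orthonormal),
#'   `explained_variance`, `n_pc`.
#' @export
run_pca <- function(ds, n_pc = 14, scale_genes = FALSE, exact_max = 600,
                    seed = 1L) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.null(ds$norm)) stop("run normalize_cells() first")
  x <- t(as.matrix(ds$norm))           # cells x genes
  if (n_pc > min(dim(x)))
    stop("n_pc (", n_pc, ") exceeds min(cells, genes) = ", min(dim(x)))
  center <- colMeans(x)
  x <- sweep(x, 2, center, "-")
  if (scale_genes) {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    x <- sweep(x, 2, s, "/")
  }
  if (min(dim(x)) <= exact_max) {
    sv <- svd(x, nu = n_pc, nv = n_pc)
    d <- sv$d[seq_len(n_pc)]
    u <- sv$u; v <- sv$v
  } else {
    dec <- randomized_svd(x, n_pc, seed = seed)
    d <- dec$d; u <- dec$u; v <- dec$v
  }
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(n_pc)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  scores <- sweep(u, 2, d, "*")
  colnames(scores) <- colnames(v) <- paste0("PC", seq_len(n_pc))
  rownames(scores) <- ds$cell_meta$barcode
  rownames(v) <- ds$gene_meta$gene_id
  ds$pca <- structure(list(
    scores = scores, loadings = v,
    explained_variance = d^2 / (nrow(x) - 1),
    n_pc = n_pc
  ), class = "fatebin_pca")
  ds
}

# Halko-style randomized truncated SVD with power iterations; deterministic
# under `seed`, accurate to ~1e-6 relative for well-separated leading
# singular values at q = 8.
randomized_svd <- function(x, k, oversample = 10, q = 8, seed = 1L) {
  set.seed(seed)
  l <- min(ncol(x), k + oversample)
  omega <- matrix(stats::rnorm(ncol(x) * l), ncol = l)
  y <- x %*% omega
  qy <- qr.Q(qr(y))
  for (i in seq_len(q)) {
    z <- crossprod(x, qy)
    qz <- qr.Q(qr(z))
    y <- x %*% qz
    qy <- qr.Q(qr(y))
  }
  b <- crossprod(qy, x)                # l x p
  sb <- svd(b, nu = k, nv = k)
  list(d = sb$d[seq_len(k)], u = qy %*% sb$u, v = sb$v)
}

#' @exportS3Method base::print
print.fatebin_pca <- function(x, ...) {
  cat("<fatebin_pca> ", nrow(x$scores), " cells x ", x$n_pc, " PCs\n", sep = "")
  cat("  variance: ", paste(signif(x$explained_variance[1:min(5, x$n_pc)], 3),
                            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}
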