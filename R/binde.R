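#' Combine two genotype datasets
#'
#' Concatenates cells of two datasets over their shared gene universe
#' (warning when genes are dropped), preserving each cell's genotype label
#' and any per-cell metadata already computed (annotation, pseudotime,
#' branch). Size factors are recomputed jointly by default so that the
#' pooled negative-binomial fits share one depth scale.
#'
#' @param wt,ko [cell_dataset]s with genotype labels set.
#' @param recompute_size_factors recompute jointly (default TRUE); otherwise
#'   per-dataset factors are retained.
#' @return A combined [cell_dataset].
#' @export
combine_datasets <- function(wt, ko, recompute_size_factors = TRUE) {
  stopifnot(inherits(wt, "cell_dataset"), inherits(ko, "cell_dataset"))
  shared <- intersect(wt$gene_meta$gene_id, ko$gene_meta$gene_id)
  if (length(shared) == 0) stop("no genes in common")
  if (length(shared) < nrow(wt$gene_meta) || length(shared) < nrow(ko$gene_meta))
    warning("gene universes differ; intersecting to ", length(shared), " genes")
  iw <- match(shared, wt$gene_meta$gene_id)
  ik <- match(shared, ko$gene_meta$gene_id)
  bw <- wt$cell_meta$barcode; bk <- ko$cell_meta$barcode
  if (length(intersect(bw, bk)) > 0) {
    bw <- paste0(bw, "_1"); bk <- paste0(bk, "_2")
  }
  counts <- cbind(wt$counts[iw, , drop = FALSE], ko$counts[ik, , drop = FALSE])
  colnames(counts) <- c(bw, bk)
  ds <- cell_dataset(counts, shared, wt$gene_meta$gene_short_name[iw],
                     c(bw, bk))
  meta <- dplyr::bind_rows(
    dplyr::mutate(wt$cell_meta, barcode = bw),
    dplyr::mutate(ko$cell_meta, barcode = bk)
  )
  ds$cell_meta <- meta
  if (recompute_size_factors || is.null(wt$size_factors) ||
      is.null(ko$size_factors)) {
    ds <- normalize_cells(ds)
  } else {
    ds$size_factors <- stats::setNames(
      c(unname(wt$size_factors), unname(ko$size_factors)), c(bw, bk))
    if (!is.null(wt$norm) && !is.null(ko$norm))
      ds$norm <- cbind(wt$norm[iw, , drop = FALSE], ko$norm[ik, , drop = FALSE])
  }
  ds
}

#' Assign cells to pseudotime bins
#'
#' Half-open bins `[b*width, (b+1)*width)` indexed by `floor(pt / width)`.
#'
#' @param pt non-negative finite pseudotime vector.
#' @param width bin width (default 1, "single-unit bins").
#' @return Integer bin index per cell.
#' @export
bin_cells <- function(pt, width = 1.0) {
  if (any(!is.finite(pt))) stop("pseudotime must be finite")
  if (any(pt < 0)) stop("pseudotime must be non-negative")
  stopifnot(width > 0)
  as.integer(floor(pt / width))
}

#' Per-bin negative-binomial regression of expression on genotype
#'
#' The core binned differential-expression procedure: cells are partitioned
#' into pseudotime bins; within each bin with at least
#' `min_cells_per_genotype` cells of both genotypes, every requested gene is
#' fit with a negative-binomial GLM `counts ~ genotype + offset(log
#' size_factor)` (quasi-Poisson fallback on convergence failure). The Wald
#' p-value of the genotype coefficient is recorded; intercepts are always
#' discarded, and entries enter the wide gene x bin table only when
#' `p < alpha`.
#'
#' @param combined a [combine_datasets()] result with `pseudotime` in
#'   `cell_meta`.
#' @param width pseudotime bin width (default 1).
#' @param alpha significance level (default 0.05, uncorrected).
#' @param min_cells_per_genotype minimum cells of each genotype per tested
#'   bin (default 10); smaller bins are skipped and listed in `skipped_bins`.
#' @param genes optional character vector of gene short names to test
#'   (default: all genes).
#' @param bh apply Benjamini-Hochberg correction across genes within bin.
#' @return An object of class `fatebin_binde`: list with `long` (tibble:
#'   gene, bin, estimate, std_error, statistic, p_value, n_wt, n_ko, family),
#'   `wide` (tibble: gene, then one column per bin holding the significant
#'   genotype coefficient or NA), `skipped_bins`, `alpha`, `width`.
#' @export
fit_bin_regressions <- function(combined, width = 1.0, alpha = 0.05,
                                min_cells_per_genotype = 10, genes = NULL,
                                bh = FALSE) {
  stopifnot(inherits(combined, "cell_dataset"))
  pt <- combined$cell_meta$pseudotime
  if (is.null(pt)) stop("combined dataset lacks pseudotime; run order_cells()")
  gt <- combined$cell_meta$genotype
  if (!all(gt %in% c("WT", "TKO"))) stop("genotype must be WT or TKO")
  if (length(unique(gt)) < 2) stop("both genotypes must be present")
  if (is.null(combined$size_factors)) stop("run normalize_cells() first")
  gidx <- if (is.null(genes)) seq_len(n_genes(combined)) else
    match_short_names(combined, genes)
  bins <- bin_cells(pt, width)
  bin_ids <- sort(unique(bins))
  tab <- table(factor(bins, levels = bin_ids), gt)
  testable <- tab[, "WT"] >= min_cells_per_genotype &
    tab[, "TKO"] >= min_cells_per_genotype
  skipped <- bin_ids[!testable]
  if (length(skipped))
    message("skipping bin(s) with < ", min_cells_per_genotype,
            " cells per genotype: ", paste(skipped, collapse = ", "))
  lsf <- log(unname(combined$size_factors))
  # genotype coded WT-reference so the coefficient is the TKO log-fold effect
  gt_f <- factor(gt, levels = c("WT", "TKO"))
  res <- list()
  for (b in bin_ids[testable]) {
    in_bin <- bins == b
    y_all <- as.matrix(combined$counts[gidx, in_bin, drop = FALSE])
    g <- gt_f[in_bin]; off <- lsf[in_bin]
    xb <- stats::model.matrix(~g)
    nwt <- sum(g == "WT"); nko <- sum(g == "TKO")
    fits <- purrr::map_dfr(seq_along(gidx), function(r) {
      y <- y_all[r, ]
      if (all(y == 0)) return(tibble::tibble(
        gene = combined$gene_meta$gene_short_name[gidx[r]], bin = b,
        estimate = NA_real_, std_error = NA_real_, statistic = NA_real_,
        p_value = NA_real_, n_wt = nwt, n_ko = nko, family = "untestable"))
      fit <- nb_genotype_fit(y, g, off, x = xb)
      tibble::tibble(gene = combined$gene_meta$gene_short_name[gidx[r]],
                     bin = b, estimate = fit$estimate,
                     std_error = fit$std_error, statistic = fit$statistic,
                     p_value = fit$p_value, n_wt = nwt, n_ko = nko,
                     family = fit$family)
    })
    if (bh) fits$p_value <- stats::p.adjust(fits$p_value, "BH")
    res[[length(res) + 1]] <- fits
  }
  long <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(gene = character(), bin = integer(), estimate = numeric(),
                   std_error = numeric(), statistic = numeric(),
                   p_value = numeric(), n_wt = integer(), n_ko = integer(),
                   family = character())
  sig <- dplyr::filter(long, !is.na(.data$p_value), .data$p_value < alpha)
  wide <- if (nrow(sig)) {
    sig |>
      dplyr::distinct(.data$gene, .data$bin, .keep_all = TRUE) |>
      dplyr::mutate(bin = paste0("bin_", .data$bin)) |>
      dplyr::select("gene", "bin", "estimate") |>
      tidyr::pivot_wider(names_from = "bin", values_from = "estimate",
                         names_sort = TRUE)
  } else tibble::tibble(gene = character())
  structure(list(long = long, wide = wide, skipped_bins = skipped,
                 alpha = alpha, width = width),
            class = "fatebin_binde")
}

# single-gene NB GLM of counts on genotype with log-size-factor offset;
# Wald test of the genotype coefficient. The fit alternates glm.fit IRLS
# with maximum-likelihood dispersion (MASS::theta.ml), i.e. the same
# alternating scheme as MASS::glm.nb but without per-gene formula/model-frame
# overhead, which matters when fitting thousands of gene x bin models.
# Quasi-Poisson fallback when the NB fit fails or does not converge.
nb_genotype_fit <- function(y, genotype, log_sf, x = NULL) {
  if (is.null(x)) x <- stats::model.matrix(~genotype)
  wald <- function(fit, dispersion = 1) {
    w <- fit$weights
    cov <- tryCatch(solve(crossprod(x, w * x)) * dispersion,
                    error = function(e) NULL)
    if (is.null(cov)) return(NULL)
    se <- sqrt(diag(cov))
    list(estimate = unname(fit$coefficients[2]), std_error = unname(se[2]),
         statistic = unname(fit$coefficients[2] / se[2]))
  }
  th <- NA_real_
  nb <- tryCatch(suppressWarnings({
    f <- stats::glm.fit(x, y, offset = log_sf, family = stats::poisson())
    for (i in 1:10) {
      th_new <- as.numeric(MASS::theta.ml(y, f$fitted.values, limit = 25))
      f <- stats::glm.fit(x, y, offset = log_sf,
                          family = MASS::negative.binomial(theta = th_new))
      done <- is.finite(th_new) && !is.na(th) &&
        abs(th_new - th) < 1e-8 * (abs(th) + 1e-3)
      th <- th_new
      if (done) break
    }
    if (!f$converged || !is.finite(th)) NULL else f
  }), error = function(e) NULL)
  if (!is.null(nb)) {
    wd <- wald(nb)
    if (!is.null(wd))
      return(c(wd, list(p_value = 2 * stats::pnorm(-abs(wd$statistic)),
                        family = "negbin", theta = th)))
  }
  f <- suppressWarnings(stats::glm.fit(x, y, offset = log_sf,
                                       family = stats::poisson()))
  df <- length(y) - ncol(x)
  mu <- f$fitted.values
  disp <- sum((y - mu)^2 / mu) / df
  wd <- wald(f, dispersion = disp)
  if (is.null(wd))
    return(list(estimate = NA_real_, std_error = NA_real_,
                statistic = NA_real_, p_value = NA_real_,
                family = "unfit"))
  c(wd, list(p_value = 2 * stats::pt(-abs(wd$statistic), df),
             family = "quasipoisson"))
}

#' Select candidate genes from a bin-DE table
#'
#' Mechanical stand-in for manual curation: intersects the significant genes
#' of a bin-DE table with a user-supplied gene list (e.g. known
#' transcriptional regulators).
#'
#' @param binde a `fatebin_binde` object.
#' @param gene_filter character vector of gene short names to keep.
#' @return Character vector of selected genes (order of the wide table).
#' @export
select_candidates <- function(binde, gene_filter) {
  stopifnot(inherits(binde, "fatebin_binde"))
  intersect(binde$wide$gene, gene_filter)
}

#' @exportS3Method base::print
print.fatebin_binde <- function(x, ...) {
  nb <- length(setdiff(names(x$wide), "gene"))
  cat("<fatebin_binde> ", nrow(x$wide), " significant genes across ", nb,
      " bins (alpha = ", x$alpha, ", width = ", x$width, ")\n", sep = "")
  if (length(x$skipped_bins))
    cat("  skipped bins: ", paste(x$skipped_bins, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
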