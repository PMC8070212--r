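#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @title Broom-style tidiers for fatebin result objects
#' @description `tidy()` returns per-term / per-gene tibbles; `glance()`
#'   returns one-row summaries.
#' @param x a fatebin result object.
#' @param ... unused.
#' @export
tidy.fatebin_binde <- function(x, ...) x$long

#' @rdname tidiers
#' @export
glance.fatebin_binde <- function(x, ...) {
  sig <- dplyr::filter(x$long, !is.na(.data$p_value), .data$p_value < x$alpha)
  tibble::tibble(
    n_genes_tested = dplyr::n_distinct(x$long$gene),
    n_bins_tested = dplyr::n_distinct(x$long$bin),
    n_bins_skipped = length(x$skipped_bins),
    n_significant_entries = nrow(sig),
    n_significant_genes = dplyr::n_distinct(sig$gene),
    alpha = x$alpha, width = x$width
  )
}

#' @rdname tidiers
#' @export
tidy.fatebin_branchfits <- function(x, ...) x$results

#' @rdname tidiers
#' @param alpha significance level used by the `glance` divergent-gene count.
#' @export
glance.fatebin_branchfits <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_genes = nrow(x$results),
    n_fit = sum(is.na(x$results$error)),
    n_divergent = length(call_divergent_genes(x, alpha)),
    degree = x$degree, alpha = alpha
  )
}

#' @rdname tidiers
#' @export
tidy.branch_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = sqrt(diag(x$vcov))
  )
}

#' @rdname tidiers
#' @export
glance.branch_fit <- function(x, ...) {
  tibble::tibble(gene = x$gene, genotype = x$genotype, n = x$n,
                 degree = x$degree, f_statistic = x$f_statistic,
                 f_p_value = x$f_p_value)
}

#' @rdname tidiers
#' @export
tidy.branch_comparison <- function(x, ...) x$coefficient_tests

#' @rdname tidiers
#' @export
glance.branch_comparison <- function(x, ...) {
  tibble::tibble(gene = x$gene, slope_wt = x$slope_wt, slope_ko = x$slope_ko,
                 slope_difference = x$slope_difference,
                 std_error = x$std_error, t_statistic = x$t_statistic,
                 df = x$df, p_value = x$p_value,
                 support_lo = x$support[1], support_hi = x$support[2])
}

#' @rdname tidiers
#' @export
tidy.fatebin_pca <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_pc),
                 explained_variance = x$explained_variance,
                 proportion = x$explained_variance / sum(x$explained_variance))
}
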