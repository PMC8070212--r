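#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Composition comparison plot
#'
#' Side-by-side cell-type percentages per genotype, significant differences
#' starred.
#'
#' @param object a [compare_compositions()] table.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fatebin_composition <- function(object, ...) {
  d <- object |>
    tidyr::pivot_longer(c("pct_wt", "pct_ko"), names_to = "genotype",
                        values_to = "pct") |>
    dplyr::mutate(genotype = ifelse(.data$genotype == "pct_wt", "WT", "TKO"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_type, y = .data$pct,
                                  fill = .data$genotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = dplyr::filter(object, .data$significant),
      ggplot2::aes(x = .data$cell_type,
                   y = pmax(.data$pct_wt, .data$pct_ko) + 1, label = "*"),
      inherit.aes = FALSE, size = 6) +
    ggplot2::labs(x = NULL, y = "% of cells",
                  title = "Cell-type composition by genotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bin-DE heatmap
#'
#' Gene x pseudotime-bin tile plot of significant genotype coefficients
#' (log-scale TKO effect); non-significant cells are blank.
#'
#' @param object a `fatebin_binde` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fatebin_binde <- function(object, ...) {
  d <- object$long |>
    dplyr::filter(!is.na(.data$p_value), .data$p_value < object$alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$bin), y = .data$gene,
                                  fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "purple4", mid = "grey95",
                                  high = "goldenrod2", midpoint = 0) +
    ggplot2::labs(x = "pseudotime bin", y = NULL,
                  fill = "genotype\ncoefficient",
                  title = "Significant genotype effects by pseudotime bin") +
    ggplot2::theme_minimal()
}

#' Trajectory plot in PC space
#'
#' Cells in the first two PCs coloured by pseudotime (or any cell_meta
#' column), with the principal-graph edges overlaid.
#'
#' @param ds a [cell_dataset] after [order_cells()].
#' @param colour cell_meta column to colour by (default "pseudotime").
#' @return A ggplot.
#' @export
plot_trajectory <- function(ds, colour = "pseudotime") {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.null(ds$trajectory)) stop("run order_cells() first")
  d <- tibble::tibble(PC1 = ds$pca$scores[, 1], PC2 = ds$pca$scores[, 2],
                      value = ds$cell_meta[[colour]])
  g <- ds$trajectory
  seg <- tibble::tibble(
    x = g$nodes[g$edges$from, 1], y = g$nodes[g$edges$from, 2],
    xend = g$nodes[g$edges$to, 1], yend = g$nodes[g$edges$to, 2])
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                  colour = .data$value)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          inherit.aes = FALSE, linewidth = 0.8) +
    ggplot2::labs(colour = colour, title = "Principal graph in PC space") +
    ggplot2::theme_minimal()
}

#' Expression vs pseudotime with per-genotype polynomial fits
#'
#' @param object a `fatebin_branchfits` object.
#' @param gene gene short name (must be among the fitted genes).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fatebin_branchfits <- function(object, gene = NULL, ...) {
  if (is.null(gene)) gene <- names(object$fits)[1]
  f <- object$fits[[gene]]
  if (is.null(f)) stop("gene ", gene, " was not fit")
  pts <- dplyr::bind_rows(
    tibble::tibble(t = f$wt$t, y = f$wt$y, genotype = "WT"),
    tibble::tibble(t = f$ko$t, y = f$ko$y, genotype = "TKO"))
  grid <- function(fit, gt) {
    tt <- seq(fit$t_range[1], fit$t_range[2], length.out = 100)
    tibble::tibble(t = tt, y = predict(fit, tt), genotype = gt)
  }
  lines <- dplyr::bind_rows(grid(f$wt, "WT"), grid(f$ko, "TKO"))
  ggplot2::ggplot(pts, ggplot2::aes(.data$t, .data$y,
                                    colour = .data$genotype)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(data = lines, linewidth = 1) +
    ggplot2::labs(x = "pseudotime", y = "log-normalized expression",
                  title = paste0(gene, ": branch trajectory by genotype"),
                  subtitle = sprintf("slope difference (TKO-WT) = %.3g, p = %.3g",
                                     f$comparison$slope_difference,
                                     f$comparison$p_value)) +
    ggplot2::theme_minimal()
}
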