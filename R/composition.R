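#' Cell-type percentages of an annotated dataset
#'
#' @param ds an annotated [cell_dataset], or a character vector of per-cell
#'   type labels.
#' @return A tibble: cell_type, n, pct (percentages sum to 100).
#' @export
cell_type_percentages <- function(ds) {
  types <- if (inherits(ds, "cell_dataset")) {
    if (is.null(ds$cell_meta$cell_type)) stop("annotate cells first")
    ds$cell_meta$cell_type
  } else as.character(ds)
  if (length(types) == 0) stop("no cells")
  tibble::tibble(cell_type = types) |>
    dplyr::count(.data$cell_type, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n))
}

#' Two-proportion z-tests of cell-type composition between genotypes
#'
#' For each cell type, tests whether its proportion differs between the two
#' genotypes with the classical pooled-variance z-test for independent
#' proportions: `z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
#' `phat` the pooled proportion, two-sided p from the standard normal. No
#' continuity correction; no multiplicity correction unless `bh = TRUE`.
#' Types absent from both genotypes are flagged untestable.
#'
#' @param wt,ko annotated [cell_dataset]s, per-cell type label vectors, or
#'   named count vectors (`cell_type -> n`).
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param bh apply Benjamini-Hochberg correction across types.
#' @return A tibble of class `fatebin_composition`: cell_type, n_wt, n_ko,
#'   pct_wt, pct_ko, delta_pct, z_stat, p_value, significant, note.
#' @export
compare_compositions <- function(wt, ko, alpha = 0.05, bh = FALSE) {
  cw <- composition_counts(wt)
  ck <- composition_counts(ko)
  n1 <- sum(cw); n2 <- sum(ck)
  if (n1 == 0 || n2 == 0) stop("both genotypes must contain cells")
  types <- sort(union(names(cw), names(ck)))
  x1 <- ifelse(types %in% names(cw), cw[types], 0)
  x2 <- ifelse(types %in% names(ck), ck[types], 0)
  p1 <- x1 / n1; p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (p1 - p2) / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  if (bh) p <- stats::p.adjust(p, "BH")
  out <- tibble::tibble(
    cell_type = types,
    n_wt = as.integer(x1), n_ko = as.integer(x2),
    pct_wt = 100 * p1, pct_ko = 100 * p2,
    delta_pct = 100 * (p2 - p1),
    z_stat = z, p_value = p,
    significant = !is.na(p) & p < alpha,
    note = ifelse(is.na(z), "untestable: type absent or universal in pool", "")
  )
  class(out) <- c("fatebin_composition", class(out))
  out
}

composition_counts <- function(x) {
  if (inherits(x, "cell_dataset")) {
    if (is.null(x$cell_meta$cell_type)) stop("annotate cells first")
    x <- x$cell_meta$cell_type
  }
  if (is.numeric(x)) {
    if (is.null(names(x))) stop("count vectors must be named by cell type")
    return(x)
  }
  table(as.character(x))
}
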