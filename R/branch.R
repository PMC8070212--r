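#' Isolate a trajectory branch by marker expression
#'
#' Programmatic replacement for interactive branch picking: tree edges are
#' scored by the mean normalized expression of `marker` over the cells
#' projecting onto them; edges scoring above the across-edge `quantile`
#' threshold are selected, the best-scoring connected run of selected edges
#' is kept, and the selection is extended to every edge downstream of it
#' (away from the root), so the branch runs to its terminal leaves.
#'
#' @param ds a [cell_dataset] that has been through [order_cells()].
#' @param marker gene short name marking the branch entry (default
#'   `"Atoh1"`, the secretory precursor marker).
#' @param quantile across-edge threshold quantile (default 0.75); `0`
#'   selects the whole tree, with a warning.
#' @return A list of class `branch_subset`: `edges` (indices into
#'   `ds$trajectory$edges`), `barcodes`, `marker`, `threshold`,
#'   `edge_scores`.
#' @export
identify_branch <- function(ds, marker = "Atoh1", quantile = 0.75) {
  stopifnot(inherits(ds, "cell_dataset"))
  graph <- ds$trajectory
  if (is.null(graph) || is.null(graph$root))
    stop("run order_cells() first")
  if (is.null(ds$norm)) stop("run normalize_cells() first")
  row <- match_short_names(ds, marker)
  expr <- as.numeric(ds$norm[row, ])
  edge_of_cell <- ds$cell_meta$graph_edge
  ne <- nrow(graph$edges)
  edge_score <- vapply(seq_len(ne), function(e) {
    v <- expr[edge_of_cell == e]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  thr <- stats::quantile(edge_score, quantile, na.rm = TRUE, names = FALSE)
  sel <- if (quantile <= 0) {
    warning("quantile <= 0 selects the whole tree")
    which(!is.na(edge_score))
  } else which(!is.na(edge_score) & edge_score > thr)
  if (length(sel) == 0)
    stop("no edge exceeds the ", quantile,
         " quantile of marker expression; try a lower quantile")
  # connected components of the selected edge set; keep the largest run of
  # above-threshold edges (ties broken by mean marker score)
  sub <- igraph::subgraph_from_edges(graph$tree, sel, delete.vertices = FALSE)
  comp <- igraph::components(sub)$membership
  ecomp <- comp[graph$edges$from[sel]]
  comp_n <- tapply(ecomp, ecomp, length)
  comp_score <- tapply(edge_score[sel], ecomp, mean)
  best <- names(comp_n)[order(comp_n, comp_score, decreasing = TRUE)][1]
  keep <- sel[ecomp == as.integer(best)]
  # extend downstream: every edge whose path from the root crosses `keep`
  parent <- bfs_parents(graph, graph$root)
  edge_key <- paste(pmin(graph$edges$from, graph$edges$to),
                    pmax(graph$edges$from, graph$edges$to))
  in_keep <- logical(ne)
  in_keep[keep] <- TRUE
  downstream <- vapply(seq_len(ne), function(e) {
    v <- child_node(graph, parent, e)
    while (!is.na(parent[v])) {
      pe <- match(paste(min(v, parent[v]), max(v, parent[v])), edge_key)
      if (in_keep[pe]) return(TRUE)
      v <- parent[v]
    }
    FALSE
  }, logical(1))
  edges <- which(in_keep | downstream)
  structure(list(
    edges = edges,
    barcodes = ds$cell_meta$barcode[edge_of_cell %in% edges],
    marker = marker, threshold = thr, edge_scores = edge_score
  ), class = "branch_subset")
}

bfs_parents <- function(graph, root) {
  b <- igraph::bfs(graph$tree, root = root, father = TRUE, unreachable = FALSE)
  as.integer(b$father)
}

# the endpoint of edge e that is farther from the root (its "child" node)
child_node <- function(graph, parent, e) {
  a <- graph$edges$from[e]; b <- graph$edges$to[e]
  if (!is.na(parent[a]) && parent[a] == b) a else b
}

#' Polynomial fit of a gene's expression along a branch
#'
#' Ordinary least squares of log-normalized expression on an orthogonal
#' polynomial basis in pseudotime, for the cells of one genotype on a branch
#' subset. The overall F-test (all non-intercept terms zero) is the
#' within-genotype test of any pseudotime dependence.
#'
#' @param ds a [cell_dataset] (one genotype) with pseudotime.
#' @param branch a `branch_subset` from [identify_branch()], or a character
#'   vector of barcodes.
#' @param gene gene short name.
#' @param degree polynomial degree (default 3).
#' @return A list of class `branch_fit`: coefficients, `vcov`, `poly_coefs`
#'   (basis recipe for prediction), `t_range`, `n`, `f_statistic`,
#'   `f_p_value`, `df_residual`, plus the (t, y) data for plotting.
#' @export
fit_branch_gene <- function(ds, branch, gene, degree = 3) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.null(ds$norm)) stop("run normalize_cells() first")
  bcs <- if (inherits(branch, "branch_subset")) branch$barcodes else branch
  idx <- match(intersect(bcs, ds$cell_meta$barcode), ds$cell_meta$barcode)
  if (length(idx) < degree + 2)
    stop("only ", length(idx), " cells on the branch; need >= ", degree + 2)
  t <- ds$cell_meta$pseudotime[idx]
  if (stats::sd(t) == 0) stop("zero pseudotime variance on the branch")
  y <- as.numeric(ds$norm[match_short_names(ds, gene), idx])
  basis <- stats::poly(t, degree)
  fit <- stats::lm(y ~ basis)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  f_p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(
    gene = gene,
    genotype = ds$cell_meta$genotype[idx][1],
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    poly_coefs = attr(basis, "coefs"),
    degree = degree,
    t_range = range(t),
    n = length(idx),
    f_statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    f_p_value = unname(f_p),
    df_residual = fit$df.residual,
    t = t, y = y
  ), class = "branch_fit")
}

# design row(s) [1, basis(t)] for new pseudotime values
branch_design <- function(fit, t) {
  b <- stats::poly(t, fit$degree, coefs = fit$poly_coefs)
  cbind(1, unclass(b))
}

#' Predicted expression of a branch fit
#'
#' @param object a `branch_fit`.
#' @param t pseudotime values at which to evaluate.
#' @param ... unused.
#' @return Numeric vector of fitted expression values.
#' @export
predict.branch_fit <- function(object, t, ...) {
  as.numeric(branch_design(object, t) %*% object$coefficients)
}

#' Compare two genotypes' branch fits
#'
#' Tests divergence of the fitted trajectories over the genotypes' shared
#' pseudotime support. The headline statistic is the difference between the
#' slopes of the two fits: each genotype's slope is the least-squares linear
#' trend of its fitted curve evaluated over the pooled observed cell
#' pseudotimes inside the shared support (the L2 projection of the
#' polynomial onto a straight line, in expression units per pseudotime
#' unit). This is the "slope of the fit" a practitioner reads off a
#' trajectory plot; summaries that average the raw derivative instead are
#' washed out for saturating trajectories, where a fast decline that
#' reaches the floor early and a slow steady decline can share the same
#' mean derivative. The slope is a linear functional of the coefficients,
#' so its standard error propagates exactly from the coefficient
#' covariance; the genotypes are compared by a Welch t-test with
#' Satterthwaite degrees of freedom. Per-coefficient Welch t-tests are
#' returned as secondary output.
#'
#' @param fit_wt,fit_ko `branch_fit`s of the same gene for each genotype.
#' @return A list of class `branch_comparison`: `gene`, `slope_wt`,
#'   `slope_ko`, `slope_difference` (TKO minus WT), `std_error`,
#'   `t_statistic`, `df`, `p_value`, `support`, and `coefficient_tests`
#'   (tibble).
#' @export
compare_fits <- function(fit_wt, fit_ko) {
  stopifnot(inherits(fit_wt, "branch_fit"), inherits(fit_ko, "branch_fit"))
  lo <- max(fit_wt$t_range[1], fit_ko$t_range[1])
  hi <- min(fit_wt$t_range[2], fit_ko$t_range[2])
  if (hi <= lo) stop("pseudotime supports do not overlap")
  t_eval <- c(fit_wt$t, fit_ko$t)
  t_eval <- t_eval[t_eval >= lo & t_eval <= hi]
  tc <- t_eval - mean(t_eval)
  mean_slope <- function(fit) {
    # least-squares linear trend of the fitted curve over the pooled cell
    # pseudotimes: slope = sum(tc * yhat(t)) / sum(tc^2), linear in beta
    a <- matrix(colSums(tc * branch_design(fit, t_eval)) / sum(tc^2),
                nrow = 1)
    list(est = as.numeric(a %*% fit$coefficients),
         var = as.numeric(a %*% fit$vcov %*% t(a)),
         df = fit$df_residual)
  }
  sw <- mean_slope(fit_wt); sk <- mean_slope(fit_ko)
  v <- sw$var + sk$var
  tstat <- (sk$est - sw$est) / sqrt(v)
  df <- v^2 / (sw$var^2 / sw$df + sk$var^2 / sk$df)
  coef_tests <- purrr::map_dfr(seq_along(fit_wt$coefficients), function(j) {
    vj <- fit_wt$vcov[j, j] + fit_ko$vcov[j, j]
    tj <- (fit_ko$coefficients[j] - fit_wt$coefficients[j]) / sqrt(vj)
    dfj <- vj^2 / (fit_wt$vcov[j, j]^2 / fit_wt$df_residual +
                     fit_ko$vcov[j, j]^2 / fit_ko$df_residual)
    tibble::tibble(term = names(fit_wt$coefficients)[j],
                   difference = fit_ko$coefficients[j] - fit_wt$coefficients[j],
                   t_statistic = tj, df = dfj,
                   p_value = 2 * stats::pt(-abs(tj), dfj))
  })
  structure(list(
    gene = fit_wt$gene,
    slope_wt = sw$est, slope_ko = sk$est,
    slope_difference = sk$est - sw$est,
    std_error = sqrt(v), t_statistic = tstat, df = df,
    p_value = 2 * stats::pt(-abs(tstat), df),
    support = c(lo, hi),
    coefficient_tests = coef_tests
  ), class = "branch_comparison")
}

#' Branch divergence analysis over a gene set
#'
#' Fits each gene's expression-vs-pseudotime polynomial separately per
#' genotype on the genotype's own branch subset, and tests between-genotype
#' divergence with [compare_fits()].
#'
#' @param wt,ko per-genotype [cell_dataset]s with pseudotime.
#' @param branch_wt,branch_ko per-genotype `branch_subset`s (or barcode
#'   vectors).
#' @param genes gene short names to analyse.
#' @param degree polynomial degree (default 3).
#' @return An object of class `fatebin_branchfits`: list with `results`
#'   (tibble: gene, slope_wt, slope_ko, slope_difference, std_error,
#'   t_statistic, df, p_value, f_p_wt, f_p_ko, n_wt, n_ko, error) and
#'   `fits` (named list of per-gene `list(wt, ko, comparison)`).
#' @export
branch_divergence <- function(wt, ko, branch_wt, branch_ko, genes,
                              degree = 3) {
  fits <- list()
  rows <- purrr::map_dfr(genes, function(g) {
    out <- tryCatch({
      fw <- fit_branch_gene(wt, branch_wt, g, degree)
      fk <- fit_branch_gene(ko, branch_ko, g, degree)
      cmp <- compare_fits(fw, fk)
      fits[[g]] <<- list(wt = fw, ko = fk, comparison = cmp)
      tibble::tibble(gene = g, slope_wt = cmp$slope_wt,
                     slope_ko = cmp$slope_ko,
                     slope_difference = cmp$slope_difference,
                     std_error = cmp$std_error,
                     t_statistic = cmp$t_statistic, df = cmp$df,
                     p_value = cmp$p_value,
                     f_p_wt = fw$f_p_value, f_p_ko = fk$f_p_value,
                     n_wt = fw$n, n_ko = fk$n, error = NA_character_)
    }, error = function(e) tibble::tibble(
      gene = g, slope_wt = NA_real_, slope_ko = NA_real_,
      slope_difference = NA_real_, std_error = NA_real_,
      t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
      f_p_wt = NA_real_, f_p_ko = NA_real_, n_wt = NA_integer_,
      n_ko = NA_integer_, error = conditionMessage(e)))
    out
  })
  structure(list(results = rows, fits = fits, degree = degree),
            class = "fatebin_branchfits")
}

#' Call divergent genes from a branch analysis
#'
#' A gene is called divergent when it depends on pseudotime within *both*
#' genotypes (polynomial F-tests) and its fitted trajectories diverge
#' *between* genotypes (mean-slope Welch t), all at level `alpha`.
#'
#' @param branchfits a `fatebin_branchfits` object (or its `results` tibble).
#' @param alpha significance level (default 0.05).
#' @return Character vector of divergent gene short names.
#' @export
call_divergent_genes <- function(branchfits, alpha = 0.05) {
  res <- if (inherits(branchfits, "fatebin_branchfits")) branchfits$results
  else branchfits
  keep <- !is.na(res$p_value) & res$p_value < alpha &
    !is.na(res$f_p_wt) & res$f_p_wt < alpha &
    !is.na(res$f_p_ko) & res$f_p_ko < alpha
  res$gene[keep]
}

#' @exportS3Method base::print
print.fatebin_branchfits <- function(x, ...) {
  cat("<fatebin_branchfits> ", nrow(x$results), " genes, degree ", x$degree,
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.branch_comparison <- function(x, ...) {
  cat("<branch_comparison> ", x$gene, ": slope diff (TKO-WT) = ",
      signif(x$slope_difference, 4), ", t = ", signif(x$t_statistic, 4),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}
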