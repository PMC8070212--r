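#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the analysis this
#' package models: 14 principal components, Leiden k = 40 with resolution
#' 1e-2 (WT) / 4e-2 (TKO), marker fraction-expressing filter 0.10,
#' single-unit pseudotime bins, alpha 0.05, cubic branch fits, Atoh1 branch
#' marker.
#'
#' @param wt_dir,ko_dir 10x-style input directories (NULL to simulate).
#' @param sim a [sim_config()] used when input directories are NULL.
#' @param reference_markers_file TSV with columns cell_type, gene (NULL to
#'   derive from simulated ground truth).
#' @param n_pc,scale_genes PCA parameters.
#' @param k,resolution,top_n,min_frac clustering/annotation parameters;
#'   `resolution` is a named vector with entries WT and TKO.
#' @param nodes_per_cluster,root_type,rescale_max trajectory parameters;
#'   pseudotime of each genotype is rescaled to `rescale_max` units so that
#'   unit bins are comparable across the separately learned trajectories.
#' @param bin_width,alpha,min_cells_per_genotype bin-DE parameters.
#' @param degree,branch_marker,branch_quantile branch-analysis parameters.
#' @param candidate_genes optional gene list restricting the branch analysis
#'   (default: all bin-DE-significant genes).
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(wt_dir = NULL, ko_dir = NULL, sim = sim_config(),
                            reference_markers_file = NULL,
                            n_pc = 14, scale_genes = FALSE,
                            k = 40, resolution = c(WT = 1e-2, TKO = 4e-2),
                            top_n = 25, min_frac = 0.10,
                            nodes_per_cluster = 3, root_type = "Stem",
                            rescale_max = 20,
                            bin_width = 1.0, alpha = 0.05,
                            min_cells_per_genotype = 10,
                            degree = 3, branch_marker = "Atoh1",
                            branch_quantile = 0.75,
                            candidate_genes = NULL, seed = 1L) {
  stopifnot(all(c("WT", "TKO") %in% names(resolution)))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full two-genotype analysis pipeline
#'
#' Executes simulate/load -> normalize -> PCA -> Leiden clustering ->
#' marker-overlap annotation -> composition z-tests -> principal graph +
#' pseudotime -> per-bin genotype regressions -> branch divergence analysis,
#' writing every artifact as TSV plus a manifest into `out_dir`. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (NULL: nothing is written).
#' @return A list of class `fatebin_run` with elements `datasets` (annotated,
#'   ordered per-genotype datasets), `annotation`, `composition`, `binde`,
#'   `branch` (fatebin_branchfits), `divergent_genes`, `config`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- input ----
  sim <- NULL
  if (is.null(config$wt_dir)) {
    sim <- stage("simulate", simulate_dataset(config$sim))
    datasets <- sim$datasets
    message("[simulate] WT ", n_cells(datasets$WT), " cells, TKO ",
            n_cells(datasets$TKO), " cells, ", n_genes(datasets$WT), " genes")
  } else {
    datasets <- stage("load", list(WT = load_tenx(config$wt_dir, "WT"),
                                   TKO = load_tenx(config$ko_dir, "TKO")))
    message("[load] WT ", n_cells(datasets$WT), " cells, TKO ",
            n_cells(datasets$TKO), " cells")
  }
  ref <- stage("reference", {
    if (!is.null(config$reference_markers_file))
      readr::read_tsv(config$reference_markers_file, show_col_types = FALSE)
    else if (!is.null(sim)) reference_markers(sim)
    else stop("no reference marker table and no simulated ground truth")
  })

  ## ---- per-genotype stages ----
  annotation <- list()
  for (g in c("WT", "TKO")) {
    ds <- datasets[[g]]
    ds <- stage("normalize", normalize_cells(ds))
    ds <- stage("pca", run_pca(ds, n_pc = config$n_pc,
                               scale_genes = config$scale_genes,
                               seed = config$seed))
    ds <- stage("cluster", leiden_cluster(ds, k = config$k,
                                          resolution = config$resolution[[g]],
                                          seed = config$seed))
    mk <- stage("markers", top_markers(ds, top_n = config$top_n))
    mk <- stage("filter_markers", filter_markers(mk, config$min_frac))
    ann <- stage("annotate", annotate_clusters(mk, ref))
    ds <- stage("annotate", apply_annotation(ds, ann))
    message("[", g, "] ", max(ds$cell_meta$cluster), " clusters, types: ",
            paste(sort(unique(ann$cell_type)), collapse = ", "))
    graph <- stage("trajectory", learn_graph(
      ds, nodes_per_cluster = config$nodes_per_cluster, seed = config$seed))
    ds <- stage("trajectory", order_cells(ds, graph,
                                          root_type = config$root_type))
    if (!is.null(config$rescale_max))
      ds <- stage("trajectory", rescale_pseudotime(ds, config$rescale_max))
    annotation[[g]] <- list(markers = mk, clusters = ann)
    datasets[[g]] <- ds
  }

  composition <- stage("composition",
                       compare_compositions(datasets$WT, datasets$TKO,
                                            alpha = config$alpha))

  ## ---- combined bin-DE ----
  combined <- stage("combine", combine_datasets(datasets$WT, datasets$TKO))
  binde <- stage("binde", fit_bin_regressions(
    combined, width = config$bin_width, alpha = config$alpha,
    min_cells_per_genotype = config$min_cells_per_genotype))
  message("[binde] ", nrow(binde$wide), " genes significant in >= 1 bin")

  ## ---- branch analysis ----
  genes <- binde$wide$gene
  if (!is.null(config$candidate_genes))
    genes <- intersect(genes, config$candidate_genes)
  branch <- NULL; divergent <- character(); branch_subsets <- NULL
  if (length(genes) > 0) {
    branch_subsets <- stage("branch", list(
      WT = identify_branch(datasets$WT, config$branch_marker,
                           config$branch_quantile),
      TKO = identify_branch(datasets$TKO, config$branch_marker,
                            config$branch_quantile)))
    branch <- stage("branch", branch_divergence(
      datasets$WT, datasets$TKO, branch_subsets$WT, branch_subsets$TKO,
      genes, degree = config$degree))
    divergent <- call_divergent_genes(branch, config$alpha)
    message("[branch] ", length(genes), " genes fit, ", length(divergent),
            " divergent")
  } else message("[branch] skipped: no significant bin-DE genes")

  run <- structure(list(
    datasets = datasets, annotation = annotation, composition = composition,
    binde = binde, branch = branch, branch_subsets = branch_subsets,
    divergent_genes = divergent, sim = sim, config = config,
    manifest = NULL
  ), class = "fatebin_run")

  if (!is.null(out_dir)) run <- write_run(run, out_dir)
  run
}

# write all pipeline artifacts as TSV + manifest + resolved config
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  put <- function(name, df) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path)
    files[[length(files) + 1]] <<- tibble::tibble(file = name, n_rows = nrow(df))
  }
  for (g in c("WT", "TKO")) {
    ds <- run$datasets[[g]]
    put(paste0("cells_", g, ".tsv"), ds$cell_meta)
    put(paste0("markers_", g, ".tsv"), run$annotation[[g]]$markers)
    put(paste0("annotation_", g, ".tsv"), run$annotation[[g]]$clusters)
    if (!is.null(ds$trajectory))
      put(paste0("graph_edges_", g, ".tsv"), ds$trajectory$edges)
  }
  put("composition.tsv", run$composition)
  put("binde_long.tsv", run$binde$long)
  put("binde_wide.tsv", run$binde$wide)
  if (!is.null(run$branch)) {
    put("branch_fits.tsv", run$branch$results)
    put("divergent_genes.tsv", tibble::tibble(gene = run$divergent_genes))
    put("branch_cells.tsv", dplyr::bind_rows(
      tibble::tibble(genotype = "WT", barcode = run$branch_subsets$WT$barcodes),
      tibble::tibble(genotype = "TKO", barcode = run$branch_subsets$TKO$barcodes)))
  }
  cfg <- run$config
  cfg$sim <- unclass(cfg$sim)
  cfg$sim$topology <- NULL
  writeLines(yaml::as.yaml(lapply(unclass(cfg), function(x)
    if (is.null(x)) NULL else x)), file.path(out_dir, "config.yaml"))
  manifest <- dplyr::bind_rows(files)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  run$manifest <- manifest
  run
}

#' @exportS3Method base::print
print.fatebin_run <- function(x, ...) {
  cat("<fatebin_run>\n")
  cat("  composition: ", sum(x$composition$significant),
      " significant type differences\n", sep = "")
  cat("  bin-DE: ", nrow(x$binde$wide), " genes significant in >= 1 bin\n",
      sep = "")
  cat("  branch: ", length(x$divergent_genes), " divergent genes\n", sep = "")
  invisible(x)
}
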