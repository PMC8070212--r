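#' Configuration for the branching two-genotype simulator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: an
#' intestinal-epithelium-like branching lineage (stem -> absorptive;
#' stem -> secretory progenitor -> {goblet, Paneth, tuft, enteroendocrine}),
#' two genotypes with different cell-type composition, per-type marker
#' programs that cross-fade continuously along the tree, library-size
#' variation, negative-binomial noise, and a set of "effect" genes whose
#' log-mean trajectory on the secretory branch diverges between genotypes
#' after a switch time `effect_divergence_time`.
#'
#' @param n_cells_wt,n_cells_ko cells per genotype.
#' @param n_genes total genes simulated.
#' @param markers_per_type marker genes planted per cell type.
#' @param marker_fold fold-elevation of a marker's mean in its own type.
#' @param n_gradient_genes genes whose log-mean drifts linearly with
#'   pseudotime in every cell, genotype-independently. These emulate the
#'   pervasive maturation programs of real differentiating tissue and are
#'   what makes ordering *within* a cell type recoverable.
#' @param gradient_slope_sd sd of the per-gene gradient slope (log-mean
#'   units per pseudotime unit).
#' @param n_effect_genes genes with a planted genotype-divergent secretory
#'   trajectory.
#' @param effect_divergence_time pseudotime t* at which the TKO trajectory
#'   departs from WT; must lie inside the secretory progenitor span.
#' @param effect_slope absolute WT log-mean slope per pseudotime unit on the
#'   secretory branch (signs alternate across effect genes).
#' @param effect_slope_ratio TKO/WT slope ratio after t*.
#' @param nb_dispersion per-gene negative-binomial dispersion (var =
#'   mu + mu^2 * dispersion).
#' @param libsize_lognorm length-2 numeric `(mu, sigma)` of the log-normal
#'   per-cell library-size factor.
#' @param cell_type_props named list with elements `WT` and `TKO`, each a
#'   named probability vector over the seven cell types; must sum to 1.
#' @param base_mean_log mean of the per-gene log-normal baseline expression.
#' @param base_mean_sdlog sd of the per-gene log-normal baseline expression.
#' @param seed integer seed fixing all randomness.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells_wt = 3400,
                       n_cells_ko = 2000,
                       n_genes = 2000,
                       markers_per_type = 20,
                       marker_fold = 8,
                       n_gradient_genes = 150,
                       gradient_slope_sd = 0.08,
                       n_effect_genes = 10,
                       effect_divergence_time = 10,
                       effect_slope = 0.15,
                       effect_slope_ratio = 3,
                       nb_dispersion = 0.5,
                       libsize_lognorm = c(0, 0.3),
                       cell_type_props = NULL,
                       base_mean_log = log(0.2),
                       base_mean_sdlog = 0.6,
                       seed = 1L) {
  topo <- lineage_topology()
  types <- topo$cell_type
  if (is.null(cell_type_props)) {
    cell_type_props <- list(
      WT  = stats::setNames(c(0.15, 0.40, 0.10, 0.12, 0.09, 0.08, 0.06), types),
      TKO = stats::setNames(c(0.22, 0.33, 0.12, 0.17, 0.05, 0.04, 0.07), types)
    )
  }
  for (g in c("WT", "TKO")) {
    p <- cell_type_props[[g]]
    if (is.null(p) || !setequal(names(p), types))
      stop("cell_type_props$", g, " must be named over: ",
           paste(types, collapse = ", "))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("cell_type_props$", g, " is not a probability simplex (sum = ",
           format(sum(p)), ")")
    cell_type_props[[g]] <- p[types]
  }
  sec <- topo[topo$segment == "secretory", ]
  if (effect_divergence_time <= sec$t_min || effect_divergence_time >= sec$t_max)
    stop("effect_divergence_time must lie inside the secretory span (",
         sec$t_min, ", ", sec$t_max, ")")
  stopifnot(n_genes >= markers_per_type * length(types) + n_effect_genes +
              n_gradient_genes,
            length(libsize_lognorm) == 2, nb_dispersion >= 0,
            marker_fold > 0, effect_slope_ratio > 0)
  structure(list(
    n_cells_wt = as.integer(n_cells_wt), n_cells_ko = as.integer(n_cells_ko),
    n_genes = as.integer(n_genes), markers_per_type = as.integer(markers_per_type),
    marker_fold = marker_fold,
    n_gradient_genes = as.integer(n_gradient_genes),
    gradient_slope_sd = gradient_slope_sd,
    n_effect_genes = as.integer(n_effect_genes),
    effect_divergence_time = effect_divergence_time,
    effect_slope = effect_slope, effect_slope_ratio = effect_slope_ratio,
    nb_dispersion = nb_dispersion, libsize_lognorm = as.numeric(libsize_lognorm),
    cell_type_props = cell_type_props, base_mean_log = base_mean_log,
    base_mean_sdlog = base_mean_sdlog, topology = topo, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Branching lineage topology used by the simulator
#'
#' One row per tree segment: the cell type occupying it, its parent type
#' (whose marker program ramps down across the segment), its pseudotime span
#' and its branch label. Spans are half-open on the right except terminal
#' segments.
#'
#' @return A tibble with columns segment, cell_type, parent_type, t_min,
#'   t_max, branch.
#' @export
lineage_topology <- function() {
  tibble::tribble(
    ~segment,     ~cell_type,              ~parent_type,            ~t_min, ~t_max, ~branch,
    "stem",       "Stem",                  NA_character_,           0,      5,      "stem",
    "absorptive", "Enterocyte",            "Stem",                  5,      20,     "absorptive",
    "secretory",  "Secretory progenitor",  "Stem",                  5,      12,     "secretory",
    "goblet",     "Goblet",                "Secretory progenitor",  12,     20,     "goblet",
    "paneth",     "Paneth",                "Secretory progenitor",  12,     20,     "paneth",
    "tuft",       "Tuft",                  "Secretory progenitor",  12,     20,     "tuft",
    "eec",        "Enteroendocrine",       "Secretory progenitor",  12,     20,     "eec"
  )
}

# canonical first marker per type; remaining markers get synthetic names
canonical_markers <- c(
  "Stem" = "Lgr5", "Enterocyte" = "Alpi", "Secretory progenitor" = "Atoh1",
  "Goblet" = "Muc2", "Paneth" = "Lyz1", "Tuft" = "Dclk1",
  "Enteroendocrine" = "Chga"
)

# marker-program activation: a program switches on over the first quarter of
# its own segment and the parent program switches off over the same quarter,
# so the log-mean is continuous across segment boundaries, most of a type's
# cells are own-program dominant, and the average own-type elevation strictly
# exceeds the residual parent-program elevation.
ramp_up <- function(w) pmin(1, 4 * w)
ramp_down <- function(w) pmax(0, 1 - 4 * w)

# log-mean trajectory of an effect gene on the secretory branch:
# common slope b before t*, genotype-specific slope after.
effect_log_mean <- function(t, genotype, log_base, slope, ratio, t_star,
                            t_entry = 5) {
  slope_post <- ifelse(genotype == "TKO", slope * ratio, slope)
  log_base + slope * (pmin(t, t_star) - t_entry) +
    slope_post * pmax(t - t_star, 0)
}

#' Simulate a two-genotype branching scRNA-seq experiment
#'
#' Draws cell types from the per-genotype composition, a true pseudotime
#' uniform within each type's segment, a log-normal library-size factor per
#' cell, and negative-binomial counts around a log-mean that combines a
#' per-gene baseline, cross-fading marker programs, and (for effect genes on
#' the secretory branch) a piecewise-linear genotype-dependent trajectory.
#'
#' @param config a [sim_config()].
#' @return A list of class `fatebin_sim` with elements `datasets` (named list
#'   of [cell_dataset]s, `WT` and `TKO`), `truth_cells` (tibble: barcode,
#'   genotype, true_type, true_pseudotime, true_branch), `truth_genes`
#'   (tibble: gene_id, gene_short_name, role, marker_type, effect_slope_wt,
#'   effect_slope_ko, effect_t_star), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  topo <- config$topology
  types <- topo$cell_type

  ## ---- gene roles ----
  ng <- config$n_genes
  gene_id <- sprintf("SIMG%05d", seq_len(ng))
  short <- sprintf("Gene%04d", seq_len(ng))
  role <- rep("null", ng)
  marker_type <- rep(NA_character_, ng)
  k <- config$markers_per_type
  for (j in seq_along(types)) {
    idx <- (j - 1L) * k + seq_len(k)
    role[idx] <- "marker"
    marker_type[idx] <- types[j]
    short[idx[1]] <- canonical_markers[[types[j]]]
  }
  eff_idx <- length(types) * k + seq_len(config$n_effect_genes)
  role[eff_idx] <- "effect"
  grad_idx <- length(types) * k + config$n_effect_genes +
    seq_len(config$n_gradient_genes)
  role[grad_idx] <- "gradient"

  base <- stats::rlnorm(ng, config$base_mean_log, config$base_mean_sdlog)
  grad_slope <- rep(0, ng)
  if (config$n_gradient_genes > 0)
    grad_slope[grad_idx] <- stats::rnorm(config$n_gradient_genes, 0,
                                         config$gradient_slope_sd)
  eff_sign <- rep_len(c(1, -1), config$n_effect_genes)
  slope_wt <- rep(NA_real_, ng)
  slope_ko <- rep(NA_real_, ng)
  if (config$n_effect_genes > 0) {
    slope_wt[eff_idx] <- eff_sign * config$effect_slope
    slope_ko[eff_idx] <- eff_sign * config$effect_slope * config$effect_slope_ratio
    # moderately expressed at branch entry; declining genes start high
    base[eff_idx] <- ifelse(eff_sign > 0, 0.5, 10)
  }

  truth_genes <- tibble::tibble(
    gene_id = gene_id, gene_short_name = short, role = role,
    marker_type = marker_type,
    gradient_slope = ifelse(role == "gradient", grad_slope, NA_real_),
    effect_slope_wt = slope_wt, effect_slope_ko = slope_ko,
    effect_t_star = ifelse(role == "effect", config$effect_divergence_time,
                           NA_real_)
  )

  ## ---- cells ----
  sec_types <- topo$cell_type[topo$branch %in%
                                c("secretory", "goblet", "paneth", "tuft", "eec")]
  sim_genotype <- function(genotype, n) {
    pr <- config$cell_type_props[[genotype]]
    type <- sample(types, n, replace = TRUE, prob = pr)
    seg <- topo[match(type, topo$cell_type), ]
    t <- stats::runif(n, seg$t_min, seg$t_max)
    sf <- stats::rlnorm(n, config$libsize_lognorm[1], config$libsize_lognorm[2])
    w <- (t - seg$t_min) / (seg$t_max - seg$t_min)

    # log-mean matrix built row-block-wise: null genes are a rank-1 outer
    # product; marker and effect genes get per-cell adjustments.
    logmu <- matrix(log(base), nrow = ng, ncol = n)
    lf <- log(config$marker_fold)
    for (j in seq_along(types)) {
      rows <- which(marker_type == types[j])
      e <- ifelse(type == types[j], ramp_up(w),
                  ifelse(seg$parent_type %in% types[j] &
                           !is.na(seg$parent_type), ramp_down(w), 0))
      # stem cells express the stem program fully throughout their segment
      if (types[j] == "Stem") e[type == "Stem"] <- 1
      logmu[rows, ] <- logmu[rows, , drop = FALSE] +
        matrix(lf * e, nrow = length(rows), ncol = n, byrow = TRUE)
    }
    if (config$n_gradient_genes > 0) {
      # gradient centred mid-lineage so overall expression level is stable
      logmu[grad_idx, ] <- logmu[grad_idx, , drop = FALSE] +
        outer(grad_slope[grad_idx], t - 10)
    }
    if (config$n_effect_genes > 0) {
      on_branch <- type %in% sec_types
      for (g in eff_idx) {
        lm_g <- rep(log(base[g]), n)
        if (any(on_branch))
          lm_g[on_branch] <- effect_log_mean(
            t[on_branch], genotype, log(base[g]), slope_wt[g],
            config$effect_slope_ratio, config$effect_divergence_time)
        logmu[g, ] <- lm_g
      }
    }
    mu <- exp(sweep(logmu, 2, log(sf), "+"))
    size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
    counts <- matrix(
      if (is.finite(size)) stats::rnbinom(length(mu), mu = mu, size = size)
      else stats::rpois(length(mu), mu),
      nrow = ng)
    bc <- sprintf("%s-%06d", genotype, seq_len(n))
    ds <- cell_dataset(counts, gene_id, short, bc, genotype = genotype)
    list(ds = ds,
         truth = tibble::tibble(barcode = bc, genotype = genotype,
                                true_type = type, true_pseudotime = t,
                                true_branch = seg$branch))
  }

  wt <- sim_genotype("WT", config$n_cells_wt)
  ko <- sim_genotype("TKO", config$n_cells_ko)

  structure(list(
    datasets = list(WT = wt$ds, TKO = ko$ds),
    truth_cells = dplyr::bind_rows(wt$truth, ko$truth),
    truth_genes = truth_genes,
    config = config
  ), class = "fatebin_sim")
}

#' @exportS3Method base::print
print.fatebin_sim <- function(x, ...) {
  cat("<fatebin_sim> WT: ", n_cells(x$datasets$WT), " cells, TKO: ",
      n_cells(x$datasets$TKO), " cells, ", n_genes(x$datasets$WT),
      " genes\n", sep = "")
  cat("  gene roles: ",
      paste(names(table(x$truth_genes$role)), table(x$truth_genes$role),
            collapse = ", ", sep = "="), "\n", sep = "")
  invisible(x)
}

#' Reference marker table derived from planted marker programs
#'
#' Returns the cell-type -> marker-gene table (long tibble) that plays the
#' role of a published per-cell-type reference signature set when annotating
#' clusters of simulated data.
#'
#' @param sim a `fatebin_sim` object, or a `truth_genes` tibble.
#' @return A tibble with columns `cell_type`, `gene`.
#' @export
reference_markers <- function(sim) {
  tg <- if (inherits(sim, "fatebin_sim")) sim$truth_genes else sim
  tg |>
    dplyr::filter(.data$role == "marker") |>
    dplyr::transmute(cell_type = .data$marker_type,
                     gene = .data$gene_short_name)
}

#' Write simulator outputs to disk
#'
#' One 10x-style triplet directory per genotype plus `ground_truth.tsv`
#' (per-cell truth), `gene_roles.tsv` (per-gene truth) and
#' `reference_markers.tsv`.
#'
#' @param sim a `fatebin_sim`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "fatebin_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tenx(sim$datasets$WT, file.path(dir, "WT"))
  write_tenx(sim$datasets$TKO, file.path(dir, "TKO"))
  readr::write_tsv(sim$truth_cells, file.path(dir, "ground_truth.tsv"))
  readr::write_tsv(sim$truth_genes, file.path(dir, "gene_roles.tsv"))
  readr::write_tsv(reference_markers(sim), file.path(dir, "reference_markers.tsv"))
  invisible(dir)
}
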