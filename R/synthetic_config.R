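#' Configuration for the synthetic cohort generators
#'
#' Bundles all parameters of the synthetic data generators: reference immune
#' cell profiles, bulk tumor/normal mixtures, coding mutations with transcript
#' models, cancer-cell-fraction (CCF) tables, and survival times. Defaults
#' describe a desk-scale cohort: 10 immune cell types profiled in 5 replicates
#' each, 200 marker genes planted at four-fold linear dominance among 2,000
#' genes, 200 bulk tumors plus 50 normals, and four planted clonal groups.
#'
#' @param seed integer seed; identical configurations yield identical outputs.
#' @param n_cell_types number of immune cell types in the reference compendium.
#' @param n_marker_genes_per_type planted marker genes per cell type.
#' @param n_background_genes genes with no cell-type specificity.
#' @param n_replicates_per_type reference replicates per cell type (>= 3).
#' @param n_tumors,n_normals bulk cohort sizes.
#' @param marker_fold linear-scale dominance of a marker in its own cell type
#'   over every other type (default 4).
#' @param noise_sd log2-scale standard deviation of measurement noise.
#' @param mixture_dirichlet_alpha Dirichlet concentration for bulk mixture
#'   fractions, length `n_cell_types + 1` (last entry is the tumor-intrinsic
#'   component). Default: 0.3 per immune type and 3 for the tumor component.
#' @param n_transcripts number of synthetic transcript models.
#' @param n_mutations number of somatic mutations to generate.
#' @param mutation_class_proportions named simplex over the mutation classes
#'   `missense`, `nonstop`, `frameshift`, `non_frameshift`, `start_codon`,
#'   `splice`, `exon_border`; the last three are decoys that the neo-antigen
#'   filters must remove.
#' @param ccf_components list of planted clonal groups, each a numeric vector
#'   `c(beta_a, beta_b, weight)`: per-mutation CCFs of tumors in that group
#'   are Beta(beta_a, beta_b) draws, `weight` is the group's tumor fraction.
#' @param n_ccf_tumors,n_ccf_per_tumor CCF cohort size and draws per tumor.
#' @param survival_effect list `(marker =, hr =)`: hazard ratio applied to
#'   patients whose planted fraction of `marker` is above the cohort median.
#' @param cell_types optional character vector of cell-type names.
#'
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             n_cell_types = 10L,
                             n_marker_genes_per_type = 20L,
                             n_background_genes = 1800L,
                             n_replicates_per_type = 5L,
                             n_tumors = 200L,
                             n_normals = 50L,
                             marker_fold = 4,
                             noise_sd = 0.1,
                             mixture_dirichlet_alpha = NULL,
                             n_transcripts = 30L,
                             n_mutations = 200L,
                             mutation_class_proportions = c(
                               missense = 0.50, nonstop = 0.05,
                               frameshift = 0.15, non_frameshift = 0.10,
                               start_codon = 0.05, splice = 0.10,
                               exon_border = 0.05),
                             ccf_components = list(
                               c(beta_a = 25,  beta_b = 1.5, weight = 0.25),
                               c(beta_a = 8,   beta_b = 3,   weight = 0.25),
                               c(beta_a = 3,   beta_b = 3,   weight = 0.25),
                               c(beta_a = 1.5, beta_b = 5,   weight = 0.25)),
                             n_ccf_tumors = 100L,
                             n_ccf_per_tumor = 200L,
                             survival_effect = list(marker = NULL, hr = 1),
                             cell_types = NULL) {
  counts <- c(n_cell_types = n_cell_types,
              n_marker_genes_per_type = n_marker_genes_per_type,
              n_background_genes = n_background_genes,
              n_replicates_per_type = n_replicates_per_type,
              n_tumors = n_tumors, n_normals = n_normals,
              n_transcripts = n_transcripts, n_mutations = n_mutations,
              n_ccf_tumors = n_ccf_tumors, n_ccf_per_tumor = n_ccf_per_tumor)
  if (any(counts <= 0)) {
    bad <- names(counts)[counts <= 0][1L]
    stop("count parameter must be positive: ", bad)
  }
  if (marker_fold <= 0 || noise_sd < 0) stop("marker_fold must be > 0 and noise_sd >= 0")

  if (is.null(cell_types)) {
    pool <- c("Tem_CD8", "Tcm_CD8", "Tem_CD4", "Treg", "Th1", "Th17", "Tgd",
              "NK", "aDC", "MDSC", "B_mem", "NKT", "Mast", "Eos", "Neu", "pDC")
    cell_types <- if (n_cell_types <= length(pool)) pool[seq_len(n_cell_types)]
                  else sprintf("CT%02d", seq_len(n_cell_types))
  }
  if (length(cell_types) != n_cell_types || anyDuplicated(cell_types))
    stop("cell_types must give ", n_cell_types, " distinct names")

  if (is.null(mixture_dirichlet_alpha))
    mixture_dirichlet_alpha <- c(rep(0.3, n_cell_types), 3)
  if (length(mixture_dirichlet_alpha) != n_cell_types + 1L ||
      any(mixture_dirichlet_alpha <= 0))
    stop("mixture_dirichlet_alpha must be positive and of length n_cell_types + 1")

  cls <- c("missense", "nonstop", "frameshift", "non_frameshift",
           "start_codon", "splice", "exon_border")
  if (!setequal(names(mutation_class_proportions), cls))
    stop("mutation_class_proportions must be named over the seven mutation classes")
  mutation_class_proportions <- mutation_class_proportions[cls]
  if (any(mutation_class_proportions < 0) ||
      abs(sum(mutation_class_proportions) - 1) > 1e-9)
    stop("mutation_class_proportions must be a simplex (sum to 1 within 1e-9)")

  for (comp in ccf_components) {
    if (length(comp) < 3L || comp[[1L]] <= 0 || comp[[2L]] <= 0)
      stop("ccf_components entries need positive beta_a, beta_b and a weight")
  }
  w <- vapply(ccf_components, function(comp) comp[[3L]], numeric(1))
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-9)
    stop("ccf component weights must be positive and sum to 1")

  if (!is.list(survival_effect) || is.null(survival_effect$hr))
    stop("survival_effect must be a list(marker =, hr =)")
  if (survival_effect$hr <= 0) stop("survival_effect$hr (hazard ratio) must be > 0")
  if (is.null(survival_effect$marker)) survival_effect$marker <- cell_types[1L]

  structure(list(
    seed = as.integer(seed),
    n_cell_types = as.integer(n_cell_types),
    n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
    n_background_genes = as.integer(n_background_genes),
    n_replicates_per_type = as.integer(n_replicates_per_type),
    n_tumors = as.integer(n_tumors),
    n_normals = as.integer(n_normals),
    marker_fold = marker_fold,
    noise_sd = noise_sd,
    mixture_dirichlet_alpha = mixture_dirichlet_alpha,
    n_transcripts = as.integer(n_transcripts),
    n_mutations = as.integer(n_mutations),
    mutation_class_proportions = mutation_class_proportions,
    ccf_components = ccf_components,
    n_ccf_tumors = as.integer(n_ccf_tumors),
    n_ccf_per_tumor = as.integer(n_ccf_per_tumor),
    survival_effect = survival_effect,
    cell_types = cell_types
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:",
      x$n_cell_types, "cell types x", x$n_replicates_per_type, "replicates;",
      x$n_marker_genes_per_type, "markers/type +", x$n_background_genes,
      "background genes;", x$n_tumors, "tumors /", x$n_normals, "normals;",
      x$n_mutations, "mutations;", length(x$ccf_components), "clonal groups\n")
  invisible(x)
}
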