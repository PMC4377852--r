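#' Generate labeled reference expression profiles for purified immune cells
#'
#' Emulates a compendium of microarrays from sorted immune cell populations:
#' each cell type receives a disjoint set of planted marker genes whose median
#' log2 intensity in the own type exceeds every other type's median by at
#' least `marker_fold` on the linear scale; background genes are exchangeable
#' across types. Values are log2 intensities (all positive, microarray-like).
#'
#' @param config a [synthetic_config()].
#' @return list with `expr` (log2-scale genes x samples matrix), `labels`
#'   (named cell-type vector over samples) and `ground_truth` (a list with
#'   `marker_map`, cell type -> planted marker gene IDs).
#' @export
generate_reference_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_replicates_per_type < 3L)
    stop("n_replicates_per_type must be >= 3 (ANOVA needs replication)")
  set.seed(sub_seed(config$seed, 0))

  types <- config$cell_types
  k <- config$n_cell_types
  reps <- config$n_replicates_per_type
  marker_map <- lapply(types, function(t)
    sprintf("M_%s_%02d", t, seq_len(config$n_marker_genes_per_type)))
  names(marker_map) <- types
  genes <- c(unlist(marker_map, use.names = FALSE),
             sprintf("BG_%04d", seq_len(config$n_background_genes)))
  samples <- paste0(rep(types, each = reps), "_r", rep(seq_len(reps), k))
  labels <- stats::setNames(rep(types, each = reps), samples)

  # Baseline log2 intensity per gene; markers get a boost in their own type.
  # The margin of 0.5 log2 units above log2(marker_fold) keeps the dominance
  # invariant intact under replicate-level noise at the default noise_sd.
  base <- pmax(stats::rnorm(length(genes), mean = 6, sd = 0.8), 3)
  names(base) <- genes
  boost <- log2(config$marker_fold) + 0.5

  expr <- matrix(rep(base, length(samples)), nrow = length(genes),
                 dimnames = list(genes, samples))
  for (t in types) {
    expr[marker_map[[t]], labels == t] <-
      expr[marker_map[[t]], labels == t] + boost
  }
  expr <- expr + matrix(stats::rnorm(length(expr), sd = config$noise_sd),
                        nrow = nrow(expr))
  list(expr = expr, labels = labels,
       ground_truth = list(marker_map = marker_map))
}

#' Generate a bulk tumor/normal cohort as mixtures of cell-type profiles
#'
#' Bulk profiles are convex mixtures of the reference cell-type mean profiles
#' (linear scale) plus a tumor-intrinsic (or normal-epithelium) component,
#' under multiplicative log-normal noise. Mixture fractions are Dirichlet
#' draws; hypermutated-like tumors (phenotypes `MSI-H` and `MSS^`) receive a
#' 2.5-fold higher immune concentration, planting the TIL-phenotype
#' association. Normals use a distinct prior with a larger immune share.
#'
#' @param config a [synthetic_config()].
#' @param reference output of [generate_reference_profiles()].
#' @param fractions optional tumors x (cell types + 1) matrix of mixture
#'   weights overriding the Dirichlet draws (rows must be non-negative and
#'   sum to 1).
#' @return list with `expr` (linear-scale TPM-like matrix over tumors and
#'   normals), `sample_type` (named `"tumor"`/`"normal"`), `phenotype`
#'   (named `MSI-H`/`MSS^`/`MSS` for tumors) and `ground_truth` (list with
#'   `mixture_fractions`, tumors x cell-type fraction matrix).
#' @export
generate_tumor_cohort <- function(config, reference, fractions = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, 1))
  expr_ref <- reference$expr
  labels <- reference$labels
  types <- config$cell_types
  genes <- rownames(expr_ref)

  type_means <- vapply(types, function(t)
    rowMeans(2^expr_ref[, labels == t, drop = FALSE]), numeric(length(genes)))

  # Tumor cells do not express immune markers above baseline: intrinsic
  # profiles are fresh baseline-level draws for all genes.
  tumor_prof <- 2^pmax(stats::rnorm(length(genes), 6, 0.8), 3)
  normal_prof <- 2^pmax(stats::rnorm(length(genes), 6, 0.8), 3)

  tumors <- sprintf("T%03d", seq_len(config$n_tumors))
  normals <- sprintf("N%03d", seq_len(config$n_normals))
  phenotype <- stats::setNames(
    sample(c("MSI-H", "MSS^", "MSS"), config$n_tumors, replace = TRUE,
           prob = c(0.13, 0.04, 0.83)), tumors)

  alpha <- config$mixture_dirichlet_alpha
  k <- config$n_cell_types
  if (is.null(fractions)) {
    fractions <- matrix(NA_real_, config$n_tumors, k + 1L,
                        dimnames = list(tumors, c(types, "tumor_intrinsic")))
    hyper <- phenotype %in% c("MSI-H", "MSS^")
    if (any(hyper))
      fractions[hyper, ] <- rdirichlet(sum(hyper), c(alpha[seq_len(k)] * 2.5,
                                                     alpha[k + 1L]))
    if (any(!hyper))
      fractions[!hyper, ] <- rdirichlet(sum(!hyper), alpha)
  } else {
    if (any(fractions < 0)) stop("mixture weights must be non-negative")
    if (nrow(fractions) != config$n_tumors || ncol(fractions) != k + 1L)
      stop("fractions must be n_tumors x (n_cell_types + 1)")
    fractions <- fractions / rowSums(fractions)
    dimnames(fractions) <- list(tumors, c(types, "tumor_intrinsic"))
  }
  normal_fr <- rdirichlet(config$n_normals, c(rep(0.5, k), 8))
  dimnames(normal_fr) <- list(normals, c(types, "tumor_intrinsic"))

  comp <- cbind(type_means, tumor_intrinsic = tumor_prof)
  bulk_t <- comp %*% t(fractions)
  comp_n <- cbind(type_means, tumor_intrinsic = normal_prof)
  bulk_n <- comp_n %*% t(normal_fr)
  bulk <- cbind(bulk_t, bulk_n)
  if (config$noise_sd > 0)
    bulk <- bulk * 2^matrix(stats::rnorm(length(bulk), sd = config$noise_sd),
                            nrow = nrow(bulk))
  dimnames(bulk) <- list(genes, c(tumors, normals))

  list(expr = bulk,
       sample_type = stats::setNames(rep(c("tumor", "normal"),
                                         c(length(tumors), length(normals))),
                                     c(tumors, normals)),
       phenotype = phenotype,
       ground_truth = list(mixture_fractions = fractions[, types, drop = FALSE],
                           normal_fractions = normal_fr[, types, drop = FALSE]))
}
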