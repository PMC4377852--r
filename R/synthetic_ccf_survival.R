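#' Generate per-tumor cancer-cell-fraction tables with planted clonal groups
#'
#' Each tumor is assigned to one planted clonal group and its per-mutation
#' CCFs are drawn from that group's Beta distribution, truncated to (0, 1].
#'
#' @param config a [synthetic_config()]; `ccf_components` defines the groups.
#' @return list with `ccf` (data frame `tumor_id`, `mutation_id`, `ccf`) and
#'   `ground_truth` (list with `clonal_group`, named tumor -> group label).
#' @export
generate_ccf_tables <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  for (comp in config$ccf_components)
    if (comp[[1L]] <= 0 || comp[[2L]] <= 0)
      stop("beta parameters must be positive")
  set.seed(sub_seed(config$seed, 3))

  w <- vapply(config$ccf_components, function(x) x[[3L]], numeric(1))
  counts <- allot_counts(config$n_ccf_tumors,
                         stats::setNames(w, seq_along(w)))
  group <- rep(seq_along(w), counts)
  tumors <- sprintf("H%03d", seq_len(config$n_ccf_tumors))

  tabs <- lapply(seq_along(tumors), function(i) {
    comp <- config$ccf_components[[group[i]]]
    x <- stats::rbeta(config$n_ccf_per_tumor, comp[[1L]], comp[[2L]])
    x <- pmin(pmax(x, 1e-9), 1)
    data.frame(tumor_id = tumors[i],
               mutation_id = sprintf("%s_m%03d", tumors[i],
                                     seq_len(config$n_ccf_per_tumor)),
               ccf = x)
  })
  list(ccf = do.call(rbind, tabs),
       ground_truth = list(clonal_group = stats::setNames(group, tumors)))
}

#' Generate survival times with a planted marker-linked hazard effect
#'
#' Event times are exponential with a baseline median of 24 time units; the
#' hazard of patients whose planted fraction of `config$survival_effect$marker`
#' lies above the cohort median is multiplied by the configured hazard ratio.
#' Censoring is independent uniform over `censor_range`.
#'
#' @param config a [synthetic_config()].
#' @param cohort output of [generate_tumor_cohort()] (the planted mixture
#'   fractions determine the marker-high group).
#' @param censor_range range of the uniform censoring distribution.
#' @return data frame with `patient_id`, `time`, `event` (1 = death
#'   observed), `marker_high`, plus the cohort phenotype label.
#' @export
generate_survival <- function(config, cohort, censor_range = c(6, 60)) {
  stopifnot(inherits(config, "synthetic_config"))
  hr <- config$survival_effect$hr
  if (hr <= 0) stop("hazard ratio must be > 0")
  marker <- config$survival_effect$marker
  fr <- cohort$ground_truth$mixture_fractions
  if (!marker %in% colnames(fr))
    stop("survival_effect$marker not a generated cell type: ", marker)
  set.seed(sub_seed(config$seed, 4))

  f <- fr[, marker]
  high <- f > stats::median(f)
  lambda0 <- log(2) / 24
  t_event <- stats::rexp(length(f), rate = lambda0 * ifelse(high, hr, 1))
  t_cens <- stats::runif(length(f), censor_range[1L], censor_range[2L])
  time <- pmax(pmin(t_event, t_cens), 1e-6)
  data.frame(patient_id = rownames(fr),
             time = time,
             event = as.integer(t_event <= t_cens),
             marker_high = high,
             phenotype = cohort$phenotype[rownames(fr)],
             row.names = NULL)
}

#' Simulate an abundance/expression panel with planted correlations
#'
#' Utility cohort for network-reconstruction experiments: cell-type
#' abundances are independent standard normal scores; each planted gene
#' tracks one cell type with correlation `rho`; decoy genes are independent
#' noise.
#'
#' @param n patients.
#' @param cell_types character vector of cell-type names.
#' @param planted named character vector, gene -> cell type it tracks.
#' @param n_decoys number of independent decoy genes.
#' @param rho planted Pearson correlation.
#' @param seed integer seed.
#' @return list with `abundance` (patients x cell types) and `expr`
#'   (genes x patients, non-negative linear scale).
#' @export
simulate_correlated_panel <- function(n, cell_types, planted, n_decoys = 40L,
                                      rho = 0.8, seed = 1L) {
  set.seed(seed)
  ab <- matrix(stats::rnorm(n * length(cell_types)), n, length(cell_types),
               dimnames = list(sprintf("P%03d", seq_len(n)), cell_types))
  genes <- c(names(planted), sprintf("DECOY%02d", seq_len(n_decoys)))
  expr <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, rownames(ab)))
  for (g in names(planted)) {
    z <- ab[, planted[[g]]]
    expr[g, ] <- rho * scale(z)[, 1L] + sqrt(1 - rho^2) * stats::rnorm(n)
  }
  # shift to a non-negative TPM-like scale without changing correlations
  expr <- 2^(expr + 5)
  ab <- ab - min(ab) + 0.01
  list(abundance = ab, expr = expr)
}

#' Simulate a standardized feature matrix with a planted sparse linear model
#'
#' @param n patients.
#' @param p features.
#' @param beta named coefficient vector over a subset of features (names must
#'   be among `colnames`); remaining features have zero effect.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed.
#' @return list with `X` (n x p standardized matrix), `y` (response) and
#'   `beta` (full-length coefficient vector).
#' @export
simulate_feature_cohort <- function(n = 400L, p = 221L,
                                    beta = c(F001 = 2, F002 = -1),
                                    noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  features <- sprintf("F%03d", seq_len(p))
  X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, features))
  X <- scale(X)[, , drop = FALSE]
  b <- stats::setNames(numeric(p), features)
  b[names(beta)] <- beta
  y <- as.numeric(X %*% b + stats::rnorm(n, sd = noise_sd))
  list(X = X, y = y, beta = b)
}
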