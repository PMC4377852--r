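# Derivation of cell-type-specific immune signature genes and metagenes from
# labeled reference expression profiles. All fold/dominance filters operate on
# linear-scale medians; log2 inputs are exponentiated first ("two-fold change"
# is a linear-scale notion).

group_medians <- function(expr, labels) {
  types <- unique(labels)
  med <- vapply(types, function(t)
    col_medians(t(expr[, labels == t, drop = FALSE])), numeric(nrow(expr)))
  matrix(med, nrow = nrow(expr), dimnames = list(rownames(expr), types))
}

#' One-way ANOVA filter across cell types
#'
#' Keeps genes whose expression differs across cell types (one-way ANOVA
#' p < `alpha`). Genes constant across all samples have undefined F and are
#' assigned p = 1, hence excluded.
#'
#' @param expr genes x samples matrix (any monotone scale).
#' @param labels named cell-type vector over samples.
#' @param alpha significance threshold (default 0.05).
#' @return character vector of retained gene IDs; the per-gene p-values are
#'   attached as attribute `p`.
#' @export
anova_filter <- function(expr, labels, alpha = 0.05) {
  check_expression_matrix(expr)
  labels <- check_labels(expr, labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("need >= 2 cell types")
  if (any(tab < 2L))
    stop("cell type(s) with < 2 replicates: ",
         paste(names(tab)[tab < 2L], collapse = ", "))

  n <- ncol(expr)
  k <- length(tab)
  grand <- rowMeans(expr)
  ssb <- numeric(nrow(expr))
  ssw <- numeric(nrow(expr))
  for (t in names(tab)) {
    sub <- expr[, labels == t, drop = FALSE]
    m <- rowMeans(sub)
    ssb <- ssb + ncol(sub) * (m - grand)^2
    ssw <- ssw + rowSums((sub - m)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[!is.finite(f) | (ssb + ssw) < 1e-24] <- 1  # constant genes
  names(p) <- rownames(expr)
  keep <- rownames(expr)[p < alpha]
  attr(keep, "p") <- p
  keep
}

#' Fold-dominance filter on linear-scale group medians
#'
#' For each gene, computes per-cell-type medians (linear scale), identifies
#' the top and runner-up cell types, and keeps the gene iff the top /
#' runner-up ratio is at least `min_fold` (inclusive). A runner-up median of
#' zero with a positive top median counts as infinite ratio (kept).
#'
#' @param expr genes x samples matrix.
#' @param labels named cell-type vector over samples.
#' @param genes gene IDs to evaluate (subset of rownames).
#' @param min_fold linear fold threshold (default 2).
#' @param log2_scale is `expr` on the log2 scale? If `TRUE` values are
#'   exponentiated before medians are taken.
#' @return data frame of retained genes: `gene_id`, `top_type`,
#'   `runner_up_type`, `fold_ratio` (may be `Inf`).
#' @export
fold_dominance_filter <- function(expr, labels, genes, min_fold = 2,
                                  log2_scale = TRUE) {
  if (min_fold < 1) stop("min_fold must be >= 1")
  if (!all(genes %in% rownames(expr)))
    stop("genes absent from expression matrix")
  labels <- check_labels(expr, labels)
  x <- expr[genes, , drop = FALSE]
  if (log2_scale) x <- 2^x
  med <- group_medians(x, labels)

  top_i <- max.col(med, ties.method = "first")
  top <- med[cbind(seq_along(genes), top_i)]
  med2 <- med
  med2[cbind(seq_along(genes), top_i)] <- -Inf
  ru_i <- max.col(med2, ties.method = "first")
  ru <- med[cbind(seq_along(genes), ru_i)]

  ratio <- ifelse(ru == 0, ifelse(top > 0, Inf, 1), top / ru)
  keep <- ratio >= min_fold
  data.frame(gene_id = genes[keep],
             top_type = colnames(med)[top_i][keep],
             runner_up_type = colnames(med)[ru_i][keep],
             fold_ratio = ratio[keep],
             row.names = NULL)
}

# Shared machinery for the label-permutation specificity test: permuted
# group-median differences with permutation index matrices reused across
# genes.
permutation_specificity_batch <- function(expr, labels, top_type,
                                          runner_up_type, n_perm, seed,
                                          log2_scale = TRUE) {
  if (n_perm <= 0L) stop("n_perm must be >= 1")
  labels <- check_labels(expr, labels)
  x <- if (log2_scale) 2^expr else expr
  set.seed(seed)
  n <- ncol(x)
  types <- unique(labels)
  sizes <- table(labels)[types]

  # one shared set of label permutations; per type, the sample indices that
  # receive that label under each permutation
  perm_idx <- replicate(n_perm, sample.int(n))
  idx_by_type <- lapply(types, function(t)
    perm_idx[which(labels == t), , drop = FALSE])
  names(idx_by_type) <- types

  p <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    v <- x[g, ]
    tt <- top_type[g]; rt <- runner_up_type[g]
    obs <- stats::median(v[labels == tt]) - stats::median(v[labels == rt])
    perm_top <- col_medians(matrix(v[idx_by_type[[tt]]],
                                   nrow = sizes[[tt]], ncol = n_perm))
    perm_ru <- col_medians(matrix(v[idx_by_type[[rt]]],
                                  nrow = sizes[[rt]], ncol = n_perm))
    stat <- perm_top - perm_ru
    p[g] <- (1 + sum(stat >= obs)) / (n_perm + 1)
  }
  stats::setNames(p, rownames(x))
}

#' Label-permutation test of cell-type specificity
#'
#' The observed statistic is the difference between the top cell type's
#' median and the runner-up cell type's median (linear scale). Group labels
#' of all samples are permuted `n_perm` times and the p-value uses the
#' add-one estimator `(1 + b) / (n_perm + 1)`, never exactly zero.
#'
#' @param expr genes x samples matrix.
#' @param labels named cell-type vector.
#' @param gene a single gene ID.
#' @param n_perm number of permutations (default 10000).
#' @param seed permutation seed.
#' @param log2_scale is `expr` log2-scale?
#' @return permutation p-value in (0, 1].
#' @export
permutation_specificity_test <- function(expr, labels, gene, n_perm = 10000L,
                                         seed = 1L, log2_scale = TRUE) {
  if (!gene %in% rownames(expr)) stop("unknown gene: ", gene)
  labels <- check_labels(expr, labels)
  x <- expr[gene, , drop = FALSE]
  med <- group_medians(if (log2_scale) 2^x else x, labels)
  ord <- order(med[1L, ], decreasing = TRUE)
  permutation_specificity_batch(x, labels,
                                top_type = colnames(med)[ord[1L]],
                                runner_up_type = colnames(med)[ord[2L]],
                                n_perm = n_perm, seed = seed,
                                log2_scale = log2_scale)[[1L]]
}

#' Jensen-Shannon divergence (base-2) between two probability vectors
#'
#' @param p,q non-negative vectors of equal length summing to 1 (within
#'   1e-9). `0 * log 0` is taken as 0.
#' @return divergence in bits, in `[0, 1]`.
#' @export
jsd_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  if (any(p < 0) || any(q < 0)) stop("negative entries")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("inputs must sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Specificity score from the Jensen-Shannon divergence
#'
#' `1 - sqrt(JSD)` between a gene's expression pattern across cell types and
#' the one-hot pattern of exclusive expression in one type; 1 means perfectly
#' specific.
#'
#' @inheritParams jsd_divergence
#' @return specificity in `[0, 1]`.
#' @export
jsd_specificity <- function(p, q) {
  1 - sqrt(jsd_divergence(p, q))
}

#' Select metagenes by greedy backward correlation pruning
#'
#' Within each cell type, iteratively drops the candidate gene with the
#' lowest average Pearson correlation to the remaining candidates until every
#' remaining gene has average pairwise r >= `r_min` with correlation-test
#' p < `p_max`. Cell types finishing with fewer than `min_genes` genes are
#' reported as failed (with a warning naming the type) and omitted.
#'
#' @param expr genes x samples matrix (correlations across all samples).
#' @param candidates named list, cell type -> candidate gene IDs.
#' @param r_min minimum average pairwise correlation (default 0.6).
#' @param p_max correlation-test p threshold (default 0.01).
#' @param min_genes minimum metagene size (default 11).
#' @return named list, cell type -> retained gene IDs, with the final mean
#'   pairwise correlation attached as attribute `mean_r` per element; failed
#'   types are recorded in attribute `failed`.
#' @export
select_metagenes <- function(expr, candidates, r_min = 0.6, p_max = 0.01,
                             min_genes = 11L) {
  if (!length(candidates)) stop("candidates must be non-empty")
  if (ncol(expr) < 3L) stop("need >= 3 samples for correlation selection")
  n <- ncol(expr)
  cor_p <- function(r) {
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    stats::pt(t_stat, n - 2, lower.tail = FALSE)  # one-sided: r > 0
  }

  out <- list()
  failed <- character(0)
  for (ct in names(candidates)) {
    genes <- intersect(candidates[[ct]], rownames(expr))
    ok <- FALSE
    while (length(genes) >= max(2L, min_genes)) {
      cm <- stats::cor(t(expr[genes, , drop = FALSE]))
      avg_r <- (rowSums(cm) - 1) / (length(genes) - 1)
      worst <- which.min(avg_r)
      if (avg_r[worst] >= r_min && cor_p(avg_r[worst]) < p_max) {
        ok <- TRUE
        break
      }
      genes <- genes[-worst]
    }
    if (ok && length(genes) >= min_genes) {
      cm <- stats::cor(t(expr[genes, , drop = FALSE]))
      res <- genes
      attr(res, "mean_r") <- mean(cm[lower.tri(cm)])
      out[[ct]] <- res
    } else {
      warning("cell type failed metagene selection (< ", min_genes,
              " genes): ", ct)
      failed <- c(failed, ct)
    }
  }
  attr(out, "failed") <- failed
  out
}

#' Derive the immune metagene compendium from labeled reference profiles
#'
#' Runs the full signature filter chain: one-way ANOVA across cell types,
#' linear two-fold dominance of the top cell type over the runner-up,
#' label-permutation specificity test, Jensen-Shannon specificity scoring,
#' then per-cell-type greedy correlation pruning into metagene sets of at
#' least `min_genes` genes. Metagene weights are the median log2 intensity
#' of the gene in its own cell type.
#'
#' @param expr log2-scale genes x samples reference matrix.
#' @param labels named cell-type vector over samples.
#' @param alpha ANOVA threshold.
#' @param min_fold linear dominance threshold.
#' @param n_perm,perm_alpha permutation-test settings.
#' @param r_min,p_max,min_genes metagene selection settings.
#' @param seed permutation seed.
#' @param extra_sets optional named list of literature-curated gene sets
#'   (e.g. MDSC markers, which cannot be derived from sorted-cell
#'   expression); added as metagenes with weights from their median log2
#'   intensity across all samples.
#' @return list with `metagenes` (data frame `cell_type`, `gene_id`,
#'   `weight`), `records` (per-gene filter statistics), `failed_types`.
#' @export
derive_compendium <- function(expr, labels, alpha = 0.05, min_fold = 2,
                              n_perm = 10000L, perm_alpha = 0.05,
                              r_min = 0.6, p_max = 0.01, min_genes = 11L,
                              seed = 1L, extra_sets = NULL) {
  check_expression_matrix(expr)
  labels <- check_labels(expr, labels)

  keep1 <- anova_filter(expr, labels, alpha = alpha)
  anova_p <- attr(keep1, "p")
  dom <- fold_dominance_filter(expr, labels, keep1, min_fold = min_fold,
                               log2_scale = TRUE)
  perm_p <- permutation_specificity_batch(
    expr[dom$gene_id, , drop = FALSE], labels,
    top_type = dom$top_type, runner_up_type = dom$runner_up_type,
    n_perm = n_perm, seed = seed, log2_scale = TRUE)
  dom$perm_p <- perm_p[dom$gene_id]
  dom <- dom[dom$perm_p < perm_alpha, , drop = FALSE]

  # JSD specificity of the linear mean-expression pattern vs the one-hot
  # pattern of the top type (descriptive record; no additional threshold).
  lin <- 2^expr[dom$gene_id, , drop = FALSE]
  types <- unique(labels)
  mean_by_type <- vapply(types, function(t)
    rowMeans(lin[, labels == t, drop = FALSE]), numeric(nrow(lin)))
  pat <- mean_by_type / rowSums(mean_by_type)
  dom$jsd_specificity <- vapply(seq_len(nrow(dom)), function(i) {
    onehot <- as.numeric(types == dom$top_type[i])
    jsd_specificity(pat[i, ], onehot)
  }, numeric(1))

  candidates <- split(dom$gene_id, dom$top_type)
  sets <- select_metagenes(expr, candidates, r_min = r_min, p_max = p_max,
                           min_genes = min_genes)

  metagene_weight <- function(genes, type_samples)
    apply(expr[genes, type_samples, drop = FALSE], 1, stats::median)

  rows <- lapply(names(sets), function(ct) {
    w <- metagene_weight(sets[[ct]], which(labels == ct))
    data.frame(cell_type = ct, gene_id = sets[[ct]], weight = as.numeric(w),
               row.names = NULL)
  })
  if (!is.null(extra_sets)) {
    rows <- c(rows, lapply(names(extra_sets), function(ct) {
      genes <- intersect(extra_sets[[ct]], rownames(expr))
      w <- apply(expr[genes, , drop = FALSE], 1, stats::median)
      data.frame(cell_type = ct, gene_id = genes, weight = as.numeric(w),
                 row.names = NULL)
    }))
  }
  metagenes <- do.call(rbind, rows)
  if (any(metagenes$weight <= 0))
    stop("metagene weights must be positive; check the expression scale")

  records <- data.frame(gene_id = dom$gene_id,
                        anova_p = as.numeric(anova_p[dom$gene_id]),
                        top_type = dom$top_type,
                        fold_ratio = dom$fold_ratio,
                        perm_p = dom$perm_p,
                        jsd_specificity = dom$jsd_specificity,
                        row.names = NULL)
  list(metagenes = metagenes, records = records,
       failed_types = attr(sets, "failed"))
}

#' Turn a metagene data frame into a named list of gene sets
#'
#' @param metagenes data frame with `cell_type`, `gene_id`.
#' @return named list, cell type -> gene IDs.
#' @export
metagene_sets <- function(metagenes) {
  split(metagenes$gene_id, metagenes$cell_type)
}
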