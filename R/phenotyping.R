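# Per-sample TIL enrichment (ssGSEA), relative immune-cell abundance,
# phenotype association maps, hypermutation classification and tumor-vs-normal
# escape summaries.

#' Z-score normalize each gene across samples
#'
#' Rows are centered and scaled to unit population standard deviation
#' (divisor n, not n - 1). Constant genes are mapped to all-zero rows and
#' recorded in attribute `constant_genes`.
#'
#' @param expr genes x samples matrix with >= 2 samples.
#' @return z-scaled matrix of the same shape.
#' @export
zscore_normalize <- function(expr) {
  check_expression_matrix(expr)
  if (ncol(expr) < 2L) stop("z-score normalization needs >= 2 samples")
  m <- rowMeans(expr)
  s <- sqrt(rowMeans((expr - m)^2))  # population sd
  const <- s == 0
  s[const] <- 1
  z <- (expr - m) / s
  z[const, ] <- 0
  attr(z, "constant_genes") <- rownames(expr)[const]
  z
}

#' Rank genes by descending score for enrichment analysis
#'
#' Ties are broken deterministically: descending score, then ascending gene
#' ID.
#'
#' @param score named numeric vector (gene -> score, e.g. a z-score or a
#'   mean z-score difference).
#' @return a `sample_ranking` list with `genes` (ordered IDs) and `z`
#'   (scores in ranked order).
#' @export
make_ranking <- function(score) {
  if (is.null(names(score))) stop("score must be a named gene vector")
  ord <- order(-score, names(score))
  structure(list(genes = names(score)[ord],
                 z = stats::setNames(score[ord], names(score)[ord])),
            class = "sample_ranking")
}

#' Group-level gene ranking from a z-scaled matrix
#'
#' Genes are ranked by descending mean z-score over the given samples; a
#' singleton group reduces to the per-sample ranking.
#'
#' @param expr_z z-scaled genes x samples matrix.
#' @param sample_ids samples forming the group.
#' @return a `sample_ranking` (see [make_ranking()]).
#' @export
group_ranking <- function(expr_z, sample_ids) {
  if (!length(sample_ids)) stop("sample_ids must be non-empty")
  unknown <- setdiff(sample_ids, colnames(expr_z))
  if (length(unknown))
    stop("unknown sample ID(s): ", paste(unknown, collapse = ", "))
  make_ranking(rowMeans(expr_z[, sample_ids, drop = FALSE]))
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score with |score|^1
# weights on the hits; the ES is the deviation of maximal magnitude.
running_es <- function(ranked_w, member) {
  nh <- sum(member)
  wsum <- sum(ranked_w[member])
  hit <- if (wsum > 0) cumsum(ranked_w * member) / wsum
         else cumsum(member) / nh
  miss <- cumsum(!member) / (length(member) - nh)
  dev <- hit - miss
  dev[which.max(abs(dev))]
}

#' Single-sample gene set enrichment with a gene-set permutation null
#'
#' For each metagene set, computes the weighted running-sum enrichment score
#' on the ranked gene universe (weights `|z|`, exponent 1) and a null from
#' `n_perm` random same-size gene sets. The normalized enrichment score
#' (NES) is ES divided by the mean |ES| of same-sign null scores; the
#' p-value is the same-sign null tail with the add-one estimator;
#' Benjamini-Hochberg q-values are computed across cell types within the
#' sample, and `enriched_flag` marks q <= `q_threshold`.
#'
#' @param ranking a `sample_ranking` (see [make_ranking()], [group_ranking()]).
#' @param sets named list, cell type -> gene IDs (subsets of the universe).
#' @param n_perm number of null sets per set size (>= 100).
#' @param seed permutation seed.
#' @param q_threshold FDR threshold for the enrichment flag (default 0.10).
#' @return data frame with `cell_type`, `es`, `nes`, `p`, `q`,
#'   `enriched_flag`.
#' @export
ssgsea_enrich <- function(ranking, sets, n_perm = 1000L, seed = 1L,
                          q_threshold = 0.10) {
  stopifnot(inherits(ranking, "sample_ranking"))
  if (n_perm < 100L) stop("n_perm must be >= 100")
  universe <- ranking$genes
  n <- length(universe)
  w <- abs(ranking$z)
  for (ct in names(sets)) {
    if (!length(sets[[ct]])) stop("empty gene set: ", ct)
    if (length(sets[[ct]]) > n) stop("gene set larger than universe: ", ct)
    if (!all(sets[[ct]] %in% universe))
      stop("gene set outside the ranked universe: ", ct)
  }

  set.seed(seed)
  sizes <- sort(unique(lengths(sets)))
  null_by_size <- list()
  for (k in sizes) {
    es_null <- numeric(n_perm)
    member <- logical(n)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n, k)
      member[] <- FALSE
      member[idx] <- TRUE
      es_null[b] <- running_es(w, member)
    }
    null_by_size[[as.character(k)]] <- es_null
  }

  res <- lapply(names(sets), function(ct) {
    member <- universe %in% sets[[ct]]
    es <- running_es(w, member)
    nul <- null_by_size[[as.character(sum(member))]]
    same <- nul[sign(nul) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    data.frame(cell_type = ct, es = es, nes = nes, p = p)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, "BH")
  res$enriched_flag <- res$q <= q_threshold
  res
}

#' Relative immune-cell abundance from metagene expression
#'
#' For each cell type c with metagenes i = 1..n_c, computes
#' `I_c = sum_i log10(x_i + 1) / w_i`, where `x_i` is the linear-scale
#' (TPM-like) expression of metagene i in the sample and `w_i` its reference
#' weight (median log2 intensity in the cell type). All-zero expression
#' gives `I_c = 0`.
#'
#' @param expr linear-scale genes x samples matrix (non-negative).
#' @param metagenes data frame with `cell_type`, `gene_id`, `weight` (> 0).
#' @return samples x cell types matrix of abundances.
#' @export
relative_abundance <- function(expr, metagenes) {
  check_expression_matrix(expr, linear = TRUE)
  if (any(metagenes$weight <= 0)) stop("metagene weights must be > 0")
  missing_genes <- setdiff(metagenes$gene_id, rownames(expr))
  if (length(missing_genes))
    stop("metagenes absent from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  types <- unique(metagenes$cell_type)
  out <- vapply(types, function(ct) {
    mg <- metagenes[metagenes$cell_type == ct, ]
    colSums(log10(expr[mg$gene_id, , drop = FALSE] + 1) / mg$weight)
  }, numeric(ncol(expr)))
  matrix(out, nrow = ncol(expr), dimnames = list(colnames(expr), types))
}

#' Classify tumors as hypermutated by coverage-normalized mutation rate
#'
#' @param n_nonsilent number of non-silent coding mutations (vectorized).
#' @param covered_mb sequencing-covered megabases (> 0).
#' @param threshold mutations/Mb separating hypermutated from
#'   non-hypermutated tumors (default 8.24); the boundary is strict
#'   (rate must exceed the threshold).
#' @return data frame with `rate` and `hypermutated`.
#' @export
classify_hypermutation <- function(n_nonsilent, covered_mb, threshold = 8.24) {
  if (any(covered_mb <= 0)) stop("covered_mb must be > 0")
  rate <- n_nonsilent / covered_mb
  data.frame(rate = rate, hypermutated = rate > threshold)
}

#' Phenotype-class vs TIL-enrichment association map
#'
#' For each (phenotype class, cell type) pair, builds the 2x2 table of
#' in-class/out-of-class vs enriched/not-enriched samples, computes the
#' Fisher exact p-value and the sample odds ratio (Haldane-Anscombe 0.5
#' correction when any cell is zero), and clusters the log-OR matrix on
#' both axes (Euclidean distance, average linkage).
#'
#' @param enriched_flags samples x cell types logical matrix.
#' @param phenotype named class vector over samples (>= 2 samples per class).
#' @return list with matrices `log_or`, `or`, `fisher_p` (classes x cell
#'   types) and `row_order`, `col_order` from the clustering.
#' @export
phenotype_association <- function(enriched_flags, phenotype) {
  phenotype <- phenotype[rownames(enriched_flags)]
  if (any(is.na(phenotype))) stop("phenotype missing for some samples")
  tab <- table(phenotype)
  if (any(tab < 2L))
    stop("phenotype class(es) with < 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  classes <- names(tab)
  types <- colnames(enriched_flags)

  or <- p <- matrix(NA_real_, length(classes), length(types),
                    dimnames = list(classes, types))
  for (cl in classes) {
    inc <- phenotype == cl
    for (ct in types) {
      e <- enriched_flags[, ct]
      a <- sum(inc & e); b <- sum(inc & !e)
      c_ <- sum(!inc & e); d <- sum(!inc & !e)
      p[cl, ct] <- stats::fisher.test(matrix(c(a, b, c_, d), 2L,
                                             byrow = TRUE))$p.value
      if (min(a, b, c_, d) == 0L) {
        or[cl, ct] <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
      } else {
        or[cl, ct] <- (a * d) / (b * c_)
      }
    }
  }
  log_or <- log(or)
  row_order <- if (nrow(log_or) >= 2L)
    stats::hclust(stats::dist(log_or), "average")$order else 1L
  col_order <- if (ncol(log_or) >= 2L)
    stats::hclust(stats::dist(t(log_or)), "average")$order
    else 1L
  list(log_or = log_or, or = or, fisher_p = p,
       row_order = row_order, col_order = col_order)
}

#' Tumor-group vs normal enrichment/depletion and fold-change summary
#'
#' Cell-type level: genes are ranked by the difference of mean z-scores
#' (tumor group minus normals) and the enrichment engine is run on that
#' ranking and on its reverse, scoring enrichment and depletion per cell
#' type with BH-adjusted p-values. Gene level: `log2((mean_t + 1) /
#' (mean_n + 1))` with a Wilcoxon rank-sum test and BH adjustment.
#'
#' @param tumor_group,normals sample ID sets (non-empty, disjoint columns of
#'   `expr`).
#' @param expr linear-scale genes x samples matrix containing both groups.
#' @param sets named list of metagene sets.
#' @param n_perm,seed,q_threshold passed to [ssgsea_enrich()].
#' @param genes optional gene subset for the gene-level summary.
#' @return list with `cell_types` (cell_type, direction, es, nes, p, q) and
#'   `genes` (gene_id, log2fc, p, q).
#' @export
group_vs_normal_summary <- function(tumor_group, normals, expr, sets,
                                    n_perm = 1000L, seed = 1L,
                                    q_threshold = 0.10, genes = NULL) {
  if (!length(tumor_group) || !length(normals))
    stop("both sample sets must be non-empty")
  all_s <- unique(c(tumor_group, normals))
  if (!all(all_s %in% colnames(expr)))
    stop("samples absent from expression matrix")
  z <- zscore_normalize(expr[, all_s, drop = FALSE])
  diff <- rowMeans(z[, tumor_group, drop = FALSE]) -
    rowMeans(z[, normals, drop = FALSE])

  enr <- ssgsea_enrich(make_ranking(diff), sets, n_perm = n_perm,
                       seed = seed, q_threshold = q_threshold)
  dep <- ssgsea_enrich(make_ranking(-diff), sets, n_perm = n_perm,
                       seed = seed, q_threshold = q_threshold)
  pick <- ifelse(!is.na(enr$nes) & !is.na(dep$nes) & dep$nes > enr$nes,
                 "depleted", "enriched")
  cell_types <- data.frame(
    cell_type = enr$cell_type,
    direction = pick,
    es = ifelse(pick == "enriched", enr$es, dep$es),
    nes = ifelse(pick == "enriched", enr$nes, dep$nes),
    p = ifelse(pick == "enriched", enr$p, dep$p))
  cell_types$q <- stats::p.adjust(cell_types$p, "BH")
  cell_types$flag <- cell_types$q <= q_threshold

  if (is.null(genes)) genes <- rownames(expr)
  mt <- rowMeans(expr[genes, tumor_group, drop = FALSE])
  mn <- rowMeans(expr[genes, normals, drop = FALSE])
  pg <- vapply(genes, function(g)
    stats::wilcox.test(expr[g, tumor_group], expr[g, normals],
                       exact = FALSE)$p.value, numeric(1))
  gene_tab <- data.frame(gene_id = genes,
                         log2fc = log2((mt + 1) / (mn + 1)),
                         p = pg, q = stats::p.adjust(pg, "BH"),
                         row.names = NULL)
  list(cell_types = cell_types, genes = gene_tab)
}
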