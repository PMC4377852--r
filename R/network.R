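# Reconstruction of the TIL / immunomodulator interaction network: edges
# from Pearson correlation between relative immune-cell abundance and gene
# expression, nodes annotated with survival statistics.

#' Correlation edges between cell-type abundances and panel genes
#'
#' Computes, for every (cell type, gene) pair, the Pearson correlation
#' between the relative abundance and the log2(x + 1)-transformed gene
#' expression over the shared patients, and keeps edges with
#' `r >= r_min` and correlation-test p < `p_max`.
#'
#' @param abundance patients x cell types matrix (see
#'   [relative_abundance()]).
#' @param expr linear-scale genes x patients matrix for the immunomodulator
#'   panel.
#' @param r_min minimum correlation (default 0.6, inclusive).
#' @param p_max correlation-test p threshold (default 0.05).
#' @return data frame with `cell_type`, `gene`, `r`, `p`.
#' @export
network_edges <- function(abundance, expr, r_min = 0.6, p_max = 0.05) {
  patients <- intersect(rownames(abundance), colnames(expr))
  if (length(patients) < 10L) stop("need >= 10 shared patients")
  ab <- abundance[patients, , drop = FALSE]
  ex <- log2(expr[, patients, drop = FALSE] + 1)
  out <- list()
  for (ct in colnames(ab)) {
    for (g in rownames(ex)) {
      ct_test <- stats::cor.test(ab[, ct], ex[g, ])
      if (!is.na(ct_test$estimate) && ct_test$estimate >= r_min &&
          ct_test$p.value < p_max) {
        out[[length(out) + 1L]] <- data.frame(
          cell_type = ct, gene = g,
          r = unname(ct_test$estimate), p = ct_test$p.value)
      }
    }
  }
  if (!length(out))
    return(data.frame(cell_type = character(0), gene = character(0),
                      r = numeric(0), p = numeric(0)))
  do.call(rbind, out)
}

#' Reconstruct the TIL-immunomodulator network with survival annotations
#'
#' Edges come from [network_edges()]. Cell-type nodes are dichotomized at
#' the median abundance; gene nodes at the optimal cutpoint
#' ([optimal_cutpoint()], minimal corrected p). Each node carries the hazard
#' ratio of its high vs low group, the log-rank p-value, a significance flag
#' and a prognosis direction (HR < 1 good, HR > 1 bad). Gene nodes that are
#' not significantly associated with survival are dropped (with their
#' edges); set `filter_genes = FALSE` to keep them.
#'
#' @param abundance patients x cell types abundance matrix.
#' @param expr linear-scale genes x patients panel expression.
#' @param surv data frame with `patient_id`, `time`, `event`.
#' @param r_min,p_max edge thresholds.
#' @param sig_p significance threshold for node survival association
#'   (applied to the corrected p for gene nodes, the plain log-rank p for
#'   median-split cell types).
#' @param filter_genes drop non-significant gene nodes (default TRUE).
#' @return list with `graph` (an `igraph` object), `edges` and `nodes`
#'   data frames.
#' @export
build_network <- function(abundance, expr, surv, r_min = 0.6, p_max = 0.05,
                          sig_p = 0.05, filter_genes = TRUE) {
  patients <- Reduce(intersect, list(rownames(abundance), colnames(expr),
                                     surv$patient_id))
  if (length(patients) < 10L) stop("need >= 10 shared patients")
  surv <- surv[match(patients, surv$patient_id), ]
  ab <- abundance[patients, , drop = FALSE]
  ex <- expr[, patients, drop = FALSE]

  edges <- network_edges(ab, ex, r_min = r_min, p_max = p_max)

  node_stats <- function(values, split_at_median) {
    if (split_at_median) {
      hi <- values > stats::median(values)
      res <- km_logrank(ifelse(hi, "hi", "lo"), surv$time, surv$event)
      data.frame(hr = res$hr, p = res$logrank_p,
                 significant = res$logrank_p < sig_p)
    } else {
      cp <- optimal_cutpoint(values, surv$time, surv$event)
      data.frame(hr = km_logrank(ifelse(values > cp$cutpoint, "hi", "lo"),
                                 surv$time, surv$event)$hr,
                 p = cp$p_corrected,
                 significant = cp$p_corrected < sig_p)
    }
  }

  cell_nodes <- do.call(rbind, lapply(colnames(ab), function(ct)
    cbind(node = ct, type = "cell_type", node_stats(ab[, ct], TRUE))))
  genes_used <- unique(edges$gene)
  gene_nodes <- if (length(genes_used))
    do.call(rbind, lapply(genes_used, function(g)
      cbind(node = g, type = "gene",
            node_stats(log2(ex[g, ] + 1), FALSE))))
  else NULL
  nodes <- rbind(cell_nodes, gene_nodes)
  nodes$prognosis <- ifelse(nodes$hr < 1, "good", "bad")

  if (filter_genes && !is.null(gene_nodes)) {
    drop_genes <- nodes$node[nodes$type == "gene" & !nodes$significant]
    nodes <- nodes[!(nodes$node %in% drop_genes), ]
    edges <- edges[!(edges$gene %in% drop_genes), , drop = FALSE]
  }
  keep_nodes <- nodes$node %in% c(edges$cell_type, edges$gene) |
    nodes$type == "cell_type"
  nodes <- nodes[keep_nodes, ]

  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$cell_type, to = edges$gene,
                   weight = edges$r, p = edges$p),
    directed = FALSE, vertices = nodes)
  list(graph = g, edges = edges, nodes = nodes)
}

#' Write a network to GraphML and an edge-list TSV
#'
#' @param network output of [build_network()].
#' @param graphml_path,edges_path output file paths (either may be `NULL`).
#' @return invisibly, the network.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.table(network$edges, edges_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(network)
}
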