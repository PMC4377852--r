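#!/usr/bin/env Rscript
# Step 6: survival associations of TIL abundances (optimal cutpoints with
# minimal-p correction, KM/log-rank/Cox) and the TIL-immunomodulator network.

suppressMessages(library(immunoscape))
data_dir <- "results/data"
out <- "results"

ab_df <- read_tsv(file.path(out, "relative_abundance.tsv"))
ab <- as.matrix(ab_df[, -1]); rownames(ab) <- ab_df$sample_id
sv <- read_tsv(file.path(data_dir, "survival.tsv"))
expr <- read_expression_tsv(file.path(data_dir, "cohort_expr_tpm.tsv"))
patients <- intersect(rownames(ab), sv$patient_id)
svp <- sv[match(patients, sv$patient_id), ]

## optimal cutpoints per TIL subpopulation
cuts <- do.call(rbind, lapply(colnames(ab), function(ct) {
  oc <- optimal_cutpoint(ab[patients, ct], svp$time, svp$event)
  km <- km_logrank(ifelse(ab[patients, ct] > oc$cutpoint, "hi", "lo"),
                   svp$time, svp$event)
  data.frame(cell_type = ct, cutpoint = oc$cutpoint,
             p_uncorrected = oc$p_uncorrected,
             p_corrected = oc$p_corrected, harrell_c = oc$harrell_c,
             hr_hi_vs_lo = km$hr, n_low = oc$n_low, n_high = oc$n_high)
}))
write_tsv(cuts, file.path(out, "til_survival_cutpoints.tsv"))
sig <- cuts[cuts$p_corrected < 0.05, ]
cat(sprintf("survival: %d/%d TIL subpopulations significant after minimal-p correction\n",
            nrow(sig), nrow(cuts)))
for (i in seq_len(nrow(sig)))
  cat(sprintf("  %s: HR(hi vs lo) %.2f, corrected p %.3g\n",
              sig$cell_type[i], sig$hr_hi_vs_lo[i], sig$p_corrected[i]))

## TIL-immunomodulator network over a marker-gene panel
panel <- unique(read_tsv(file.path(out, "metagenes.tsv"))$gene_id)[1:40]
nw <- build_network(ab[patients, ], expr[panel, patients], svp,
                    filter_genes = TRUE)
write_network(nw, graphml_path = file.path(out, "til_network.graphml"),
              edges_path = file.path(out, "til_network_edges.tsv"))
write_tsv(nw$nodes, file.path(out, "til_network_nodes.tsv"))
cat(sprintf("network: %d nodes (%d survival-significant genes kept), %d edges (r >= 0.6)\n",
            nrow(nw$nodes), sum(nw$nodes$type == "gene"), nrow(nw$edges)))
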