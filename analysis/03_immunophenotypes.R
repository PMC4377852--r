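#!/usr/bin/env Rscript
# Step 3: immunophenotyping of the bulk cohort.
#
# Per-sample ssGSEA enrichment of the TIL metagene sets, relative immune-cell
# abundance (I_c), phenotype x TIL odds-ratio map, and the tumor-vs-normal
# enrichment/depletion (escape) summary per phenotype group.

suppressMessages(library(immunoscape))
data_dir <- "results/data"
out <- "results"

expr <- read_expression_tsv(file.path(data_dir, "cohort_expr_tpm.tsv"))
samples <- read_tsv(file.path(data_dir, "cohort_samples.tsv"))
metagenes <- read_tsv(file.path(out, "metagenes.tsv"))
sets <- metagene_sets(metagenes)
tumors <- samples$sample_id[samples$sample_type == "tumor"]
normals <- samples$sample_id[samples$sample_type == "normal"]

## per-sample enrichment
z <- zscore_normalize(expr[, tumors])
enr <- do.call(rbind, lapply(tumors, function(s) {
  res <- ssgsea_enrich(group_ranking(z, s), sets, n_perm = 200, seed = 1)
  cbind(sample_id = s, res)
}))
write_tsv(enr, file.path(out, "til_enrichment.tsv"))
til_pos <- tapply(enr$enriched_flag, enr$sample_id, any)
cat(sprintf("TILs enriched (q <= 0.10) in %.1f%% of %d tumors\n",
            100 * mean(til_pos), length(tumors)))

## relative abundance
ab <- relative_abundance(expr, metagenes)
write_tsv(data.frame(sample_id = rownames(ab), ab, check.names = FALSE),
          file.path(out, "relative_abundance.tsv"))

## phenotype association map
flags <- matrix(FALSE, length(tumors), length(sets),
                dimnames = list(tumors, names(sets)))
for (i in seq_len(nrow(enr)))
  flags[enr$sample_id[i], enr$cell_type[i]] <- enr$enriched_flag[i]
pheno <- setNames(samples$phenotype[match(tumors, samples$sample_id)], tumors)
assoc <- phenotype_association(flags, pheno)
write_tsv(data.frame(phenotype = rownames(assoc$log_or), assoc$log_or,
                     check.names = FALSE),
          file.path(out, "phenotype_log_odds.tsv"))

## escape summary per phenotype group vs normals
escape <- do.call(rbind, lapply(unique(pheno), function(g) {
  res <- group_vs_normal_summary(names(pheno)[pheno == g], normals, expr,
                                 sets, n_perm = 500, seed = 1)
  cbind(group = g, res$cell_types)
}))
write_tsv(escape, file.path(out, "escape_cell_types.tsv"))
sig <- escape[escape$flag, ]
cat(sprintf("escape summary: %d significant (q <= 0.10) group x cell-type shifts\n",
            nrow(sig)))
for (g in unique(sig$group))
  cat(sprintf("  %s: %s\n", g,
              paste(sprintf("%s(%s)", sig$cell_type[sig$group == g],
                            substr(sig$direction[sig$group == g], 1, 3)),
                    collapse = " ")))
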