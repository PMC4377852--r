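#!/usr/bin/env Rscript
# Step 1: simulate the study inputs with planted ground truth.
#
# Emits, under results/data/: the labeled reference expression compendium
# (sorted immune cells), the bulk tumor/normal cohort, somatic mutations with
# transcript models / proteome / HLA types, per-tumor CCF tables and the
# survival table. Every downstream step reads only these files.

suppressMessages(library(immunoscape))
seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# high effector-memory CD8 infiltration is planted as protective (HR 0.25)
cfg <- synthetic_config(seed = seed,
                        survival_effect = list(marker = "Tem_CD8", hr = 0.25))

ref <- generate_reference_profiles(cfg)
write_expression_tsv(ref$expr, file.path(out, "reference_expr_log2.tsv"))
write_tsv(data.frame(sample_id = names(ref$labels), cell_type = ref$labels),
          file.path(out, "reference_labels.tsv"))

coh <- generate_tumor_cohort(cfg, ref)
write_expression_tsv(coh$expr, file.path(out, "cohort_expr_tpm.tsv"))
write_tsv(data.frame(sample_id = names(coh$sample_type),
                     sample_type = coh$sample_type,
                     phenotype = coh$phenotype[names(coh$sample_type)]),
          file.path(out, "cohort_samples.tsv"))

ms <- generate_mutation_set(cfg)
write_tsv(ms$mutations, file.path(out, "mutations.tsv"))
write_transcripts_json(ms$transcripts, file.path(out, "transcripts.json"))
Biostrings::writeXStringSet(ms$proteome, file.path(out, "proteome.fasta"))
write_tsv(ms$hla, file.path(out, "hla_alleles.tsv"))

cc <- generate_ccf_tables(cfg)
write_tsv(cc$ccf, file.path(out, "ccf.tsv"))

sv <- generate_survival(cfg, coh)
write_tsv(sv, file.path(out, "survival.tsv"))

truth <- list(
  marker_map = ref$ground_truth$marker_map,
  mixture_fractions = as.data.frame(coh$ground_truth$mixture_fractions),
  planted_binders = ms$ground_truth$planted_binders,
  clonal_group = as.list(cc$ground_truth$clonal_group))
jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "simulated: %d reference arrays (%d cell types), %d tumors + %d normals,\n",
  ncol(ref$expr), cfg$n_cell_types, cfg$n_tumors, cfg$n_normals))
cat(sprintf("  %d mutations on %d transcripts, %d CCF tumors, %d survival records\n",
            nrow(ms$mutations), cfg$n_transcripts, cfg$n_ccf_tumors, nrow(sv)))
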