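#!/usr/bin/env Rscript
# Step 4: the antigenome.
#
# Neo-antigens: filter mutations, translate to mutant proteins, enumerate
# 8-11-mer windows over altered regions, score against patient HLA alleles
# with the (mock) binding predictor, keep rank <= 2 peptides absent from the
# reference proteome. Cancer-germline antigens: normal-tissue baseline
# (median + 3 SD) with downregulation and zero-SD filters.

suppressMessages(library(immunoscape))
data_dir <- "results/data"
out <- "results"

muts <- read_tsv(file.path(data_dir, "mutations.tsv"))
muts$ref[is.na(muts$ref)] <- ""; muts$alt[is.na(muts$alt)] <- ""
transcripts <- read_transcripts_json(file.path(data_dir, "transcripts.json"))
proteome <- Biostrings::readAAStringSet(file.path(data_dir, "proteome.fasta"))
hla <- read_tsv(file.path(data_dir, "hla_alleles.tsv"))
truth <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"),
                             simplifyVector = TRUE)

flt <- filter_mutations(muts, transcripts)
write_tsv(flt$excluded, file.path(out, "mutations_excluded.tsv"))
cat(sprintf("mutation filter: %d kept, %d excluded (%s)\n",
            nrow(flt$kept), nrow(flt$excluded),
            paste(names(table(flt$excluded$exclusion_reason)),
                  table(flt$excluded$exclusion_reason), collapse = " ",
                  sep = ":")))

peps <- list()
for (i in seq_len(nrow(flt$kept))) {
  m <- flt$kept[i, ]
  tm <- suppressWarnings(translate_mutation(transcripts[[m$transcript_id]], m))
  if (is.null(tm$altered_span)) next
  w <- enumerate_windows(tm$protein, tm$altered_span)
  if (!nrow(w)) next
  peps[[length(peps) + 1L]] <- data.frame(
    patient_id = m$patient_id, mutation_id = m$mutation_id,
    transcript_id = m$transcript_id, peptide = w$peptide)
}
peps <- do.call(rbind, peps)
cat(sprintf("enumerated %d candidate mutant peptides from %d mutations\n",
            nrow(peps), length(unique(peps$mutation_id))))

pred <- make_binding_predictor(seed = 1, planted = truth$planted_binders,
                               background = "nonbinding")
neo <- call_neoantigens(peps, hla, pred, proteome)
write_tsv(neo, file.path(out, "neoantigens.tsv"))
freq <- neoantigen_frequency(flt$kept, neo)
write_tsv(freq, file.path(out, "neoantigen_frequency.tsv"))
cat(sprintf("called %d neo-antigens; mean neo-antigen frequency %.2f\n",
            nrow(neo), mean(freq$frequency, na.rm = TRUE)))
shared <- shared_neoantigens(neo)
write_tsv(shared$shared, file.path(out, "shared_neoantigens.tsv"))
cat(sprintf("%d peptides shared by >= 2 patients (%.1f%% of called)\n",
            nrow(shared$shared),
            100 * nrow(shared$shared) / max(1, length(unique(neo$peptide)))))

## cancer-germline antigens on a literature-style candidate panel:
## background genes of the synthetic cohort stand in for the candidate list
expr <- read_expression_tsv(file.path(data_dir, "cohort_expr_tpm.tsv"))
samples <- read_tsv(file.path(data_dir, "cohort_samples.tsv"))
tumors <- samples$sample_id[samples$sample_type == "tumor"]
normals <- samples$sample_id[samples$sample_type == "normal"]
cga_panel <- grep("^BG_00", rownames(expr), value = TRUE)[1:60]
cga <- call_cga(expr[, tumors], expr[, normals], cga_panel, k = 3, seed = 1)
write_tsv(cga$records, file.path(out, "cga_records.tsv"))
cat(sprintf("CGA baseline: %d/%d candidates retained; %d genes positive in >= 1 tumor\n",
            nrow(cga$records), length(cga_panel),
            sum(cga$records$n_positive > 0)))
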