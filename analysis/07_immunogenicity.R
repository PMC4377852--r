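#!/usr/bin/env Rscript
# Step 7: determinants of tumor immunogenicity.
#
# Assembles per-patient feature blocks (immunosuppressive TIL abundances,
# immunomodulator-panel expression, neo-antigen frequency), standardizes
# them, and fits the lasso model of the cytotoxicity score (mean of the
# CD8/NK/Tgd abundances) with post-selection OLS refit and outer 10-fold CV.

suppressMessages(library(immunoscape))
data_dir <- "results/data"
out <- "results"

ab_df <- read_tsv(file.path(out, "relative_abundance.tsv"))
ab <- as.matrix(ab_df[, -1]); rownames(ab) <- ab_df$sample_id
expr <- read_expression_tsv(file.path(data_dir, "cohort_expr_tpm.tsv"))
samples <- read_tsv(file.path(data_dir, "cohort_samples.tsv"))
tumors <- samples$sample_id[samples$sample_type == "tumor"]
freq <- read_tsv(file.path(out, "neoantigen_frequency.tsv"))

cyto_components <- intersect(c("Tem_CD8", "NK", "Tgd"), colnames(ab))
y_all <- cytotoxicity_score(ab[tumors, ], components = cyto_components)

suppress <- ab[tumors, setdiff(colnames(ab), cyto_components), drop = FALSE]
panel_genes <- setdiff(rownames(expr),
                       read_tsv(file.path(out, "metagenes.tsv"))$gene_id)[1:180]
panel <- t(log2(expr[panel_genes, tumors] + 1))
neo_block <- matrix(NA_real_, length(tumors), 1,
                    dimnames = list(tumors, "neoantigen_frequency"))
neo_block[freq$patient_id[freq$patient_id %in% tumors], 1] <-
  freq$frequency[freq$patient_id %in% tumors]
neo_block[is.na(neo_block)] <- 0  # patients without scored mutations

fa <- suppressWarnings(assemble_features(list(
  immunosuppressive_tils = suppress,
  immunomodulator_panel = panel,
  neoantigen_frequency = neo_block)))
y <- y_all[rownames(fa$X)]
cat(sprintf("feature matrix: %d patients x %d standardized features\n",
            nrow(fa$X), ncol(fa$X)))

fit <- fit_lasso_model(fa$X, y, n_folds = 10, seed = 1)
coefs <- fit$refit[order(-abs(fit$refit$estimate)), ]
write_tsv(coefs, file.path(out, "immunogenicity_coefficients.tsv"))
write_tsv(data.frame(fold = seq_along(fit$cv$fold_r2), r2 = fit$cv$fold_r2,
                     mse = fit$cv$fold_mse),
          file.path(out, "immunogenicity_cv.tsv"))

cat(sprintf("lasso: %d nonzero features at lambda %.4g, %d kept at adjusted p < 0.005\n",
            sum(fit$coefficients != 0), fit$lambda, length(fit$selected)))
cat(sprintf("outer 10-fold CV: mean R2 %.3f, mean MSE %.4f\n",
            fit$cv$mean_r2, fit$cv$mean_mse))
top <- coefs[coefs$feature %in% fit$selected, ]
cat("determinants ranked by |coefficient|:",
    paste(head(top$feature, 8), collapse = ", "), "\n")
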