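# Synthetic-data generators: determinism, planted structure, degenerate
# inputs.

test_that("generators are deterministic and validate their configuration", {
  cfg <- synthetic_config(seed = 42, n_cell_types = 3,
                          n_marker_genes_per_type = 5,
                          n_background_genes = 30, n_tumors = 20,
                          n_normals = 5, n_mutations = 40, n_transcripts = 8,
                          n_ccf_tumors = 12, n_ccf_per_tumor = 50)
  expect_identical(generate_reference_profiles(cfg),
                   generate_reference_profiles(cfg))
  ref <- generate_reference_profiles(cfg)
  expect_identical(generate_tumor_cohort(cfg, ref),
                   generate_tumor_cohort(cfg, ref))
  expect_identical(generate_mutation_set(cfg), generate_mutation_set(cfg))
  expect_identical(generate_ccf_tables(cfg), generate_ccf_tables(cfg))

  expect_error(synthetic_config(n_tumors = 0), "positive")
  expect_error(synthetic_config(mutation_class_proportions = c(
    missense = 0.6, nonstop = 0.1, frameshift = 0.1, non_frameshift = 0.1,
    start_codon = 0.1, splice = 0.05, exon_border = 0.05)), "simplex")
  expect_error(generate_reference_profiles(
    synthetic_config(n_replicates_per_type = 2)), "replication|>= 3")
  expect_error(synthetic_config(survival_effect = list(marker = "x", hr = 0)),
               "hazard ratio")
})

test_that("planted markers dominate their own cell type by the configured fold", {
  sr <- small_reference()
  ref <- sr$ref
  lin <- 2^ref$expr
  for (ct in names(ref$ground_truth$marker_map)) {
    for (g in ref$ground_truth$marker_map[[ct]]) {
      med <- tapply(lin[g, ], ref$labels, median)
      own <- med[[ct]]
      other <- max(med[names(med) != ct])
      expect_gte(own / other, sr$cfg$marker_fold)
    }
  }
})

test_that("zero-noise bulk profiles equal the exact mixture of type means", {
  cfg <- synthetic_config(seed = 5, n_cell_types = 3,
                          n_marker_genes_per_type = 5,
                          n_background_genes = 20, n_tumors = 10,
                          n_normals = 3, noise_sd = 0)
  ref <- generate_reference_profiles(cfg)
  coh <- generate_tumor_cohort(cfg, ref)
  type_means <- sapply(cfg$cell_types, function(t)
    rowMeans(2^ref$expr[, ref$labels == t, drop = FALSE]))
  fr <- coh$ground_truth$mixture_fractions
  # tumor-intrinsic share completes the mixture
  resid <- 1 - rowSums(fr)
  for (s in rownames(fr)) {
    immune_part <- as.numeric(type_means %*% fr[s, ])
    intrinsic <- coh$expr[, s] - immune_part
    # residual is a non-negative tumor-intrinsic contribution
    expect_true(all(intrinsic > -1e-8))
  }
  # the residual, rescaled by the intrinsic fraction, is one shared profile
  s1 <- rownames(fr)[1]; s2 <- rownames(fr)[2]
  prof1 <- (coh$expr[, s1] - type_means %*% fr[s1, ]) / resid[s1]
  prof2 <- (coh$expr[, s2] - type_means %*% fr[s2, ]) / resid[s2]
  expect_equal(as.numeric(prof1), as.numeric(prof2), tolerance = 1e-8)
})

test_that("negative mixture weights are rejected", {
  cfg <- synthetic_config(seed = 5, n_cell_types = 3,
                          n_marker_genes_per_type = 5,
                          n_background_genes = 20, n_tumors = 4, n_normals = 2)
  ref <- generate_reference_profiles(cfg)
  bad <- matrix(1, 4, 4); bad[1, 1] <- -0.1
  expect_error(generate_tumor_cohort(cfg, ref, fractions = bad),
               "non-negative")
})

test_that("planted TIL fractions are recovered by relative abundance", {
  cfg <- synthetic_config(seed = 3)
  ref <- generate_reference_profiles(cfg)
  coh <- generate_tumor_cohort(cfg, ref)
  comp <- derive_compendium(ref$expr, ref$labels, n_perm = 500)
  ab <- relative_abundance(coh$expr, comp$metagenes)
  fr <- coh$ground_truth$mixture_fractions
  for (ct in intersect(colnames(ab), colnames(fr))) {
    rho <- cor(ab[rownames(fr), ct], fr[, ct], method = "spearman")
    expect_gte(rho, 0.8)
  }
  # monotonicity on the extremes
  ct <- colnames(fr)[1]
  hi <- rownames(fr)[which.max(fr[, ct])]
  lo <- rownames(fr)[which.min(fr[, ct])]
  expect_gt(ab[hi, ct], ab[lo, ct])
})

test_that("generated coding sequences translate cleanly and match an oracle", {
  cfg <- synthetic_config(seed = 9, n_transcripts = 12, n_mutations = 30)
  ms <- generate_mutation_set(cfg)
  for (tr in ms$transcripts) {
    expect_identical(substr(tr$cds_sequence, 1, 3), "ATG")
    expect_identical(nchar(tr$cds_sequence) %% 3L, 0L)
    prot <- oracle_translate(tr$cds_sequence)
    expect_false(grepl("*", prot, fixed = TRUE))
    # package translation equals the table-driven oracle
    expect_identical(
      as.character(Biostrings::translate(
        Biostrings::DNAString(substr(tr$cds_sequence, 1,
                                     nchar(tr$cds_sequence) - 3)),
        no.init.codon = TRUE)),
      prot)
    # exon spans cover the CDS exactly
    expect_identical(sum(tr$exons$end - tr$exons$start + 1L),
                     nchar(tr$cds_sequence))
  }
})

test_that("mutation classes appear at configured proportions within one count", {
  cfg <- synthetic_config(seed = 13, n_mutations = 200)
  ms <- generate_mutation_set(cfg)
  got <- table(ms$mutations$class)
  want <- cfg$mutation_class_proportions * cfg$n_mutations
  for (cls in names(want))
    expect_lte(abs(got[[cls]] - want[[cls]]), 1)
  expect_error(generate_mutation_set(cfg, cds_codon_range = c(5, 8)),
               "33 coding nt")
})

test_that("mock binding predictor is deterministic, validated and uniform", {
  expect_identical(mock_binding_predictor("SIINFEKLL", "HLA-A*02:01", seed = 1),
                   mock_binding_predictor("SIINFEKLL", "HLA-A*02:01", seed = 1))
  planted <- data.frame(peptide = "SIINFEKLL", allele = "HLA-A*02:01")
  r <- mock_binding_predictor("SIINFEKLL", "HLA-A*02:01", planted = planted)
  expect_lte(r, 2)
  expect_error(mock_binding_predictor("SIINFEKL1", "A"), "invalid residue")
  expect_error(mock_binding_predictor("SHORT", "A"), "8-11")

  set.seed(20)
  peps <- random_peptide(10000)
  ranks <- mock_binding_predictor(peps, "HLA-A*02:01", seed = 4)
  expect_true(all(ranks > 0 & ranks <= 100))
  ks <- suppressWarnings(ks.test(ranks / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
  # nonbinding background never yields a chance binder
  rnb <- mock_binding_predictor(peps[1:1000], "HLA-A*02:01", seed = 4,
                                background = "nonbinding")
  expect_true(all(rnb > 2))
})

test_that("CCF tables respect planted clonal architecture", {
  cfg <- synthetic_config(seed = 2,
                          ccf_components = list(c(200, 1, 1)),
                          n_ccf_tumors = 1, n_ccf_per_tumor = 100)
  cc <- generate_ccf_tables(cfg)
  expect_lt(heterogeneity_score(cc$ccf$ccf), 0.05)

  cfg2 <- synthetic_config(seed = 2, ccf_components = list(c(5, 2, 1)),
                           n_ccf_tumors = 2, n_ccf_per_tumor = 1000)
  cc2 <- generate_ccf_tables(cfg2)
  D <- pairwise_ks(cc2$ccf)
  expect_lt(D[1, 2], 0.1)

  expect_error(synthetic_config(ccf_components = list(c(-1, 2, 1))),
               "positive")
})

test_that("planted survival effects are recovered and the null is calibrated", {
  cfg <- synthetic_config(seed = 17, n_tumors = 300,
                          survival_effect = list(marker = "Tem_CD8", hr = 4))
  ref <- generate_reference_profiles(cfg)
  coh <- generate_tumor_cohort(cfg, ref)
  sv <- generate_survival(cfg, coh)
  expect_true(all(sv$time > 0))
  fit <- survival::coxph(survival::Surv(time, event) ~ marker_high, data = sv)
  expect_lt(abs(coef(fit) - log(4)) / log(4), 0.30)

  # null hazard ratio: log-rank at the planted split rejects at ~5%
  cfg0 <- synthetic_config(seed = 1, n_tumors = 150,
                           survival_effect = list(marker = "Tem_CD8", hr = 1))
  ref0 <- generate_reference_profiles(cfg0)
  coh0 <- generate_tumor_cohort(cfg0, ref0)
  rej <- 0
  n_rep <- 500
  for (r in seq_len(n_rep)) {
    cfg0$seed <- 1000L + r
    sv0 <- generate_survival(cfg0, coh0)
    p <- km_logrank(ifelse(sv0$marker_high, "hi", "lo"),
                    sv0$time, sv0$event)$logrank_p
    rej <- rej + (p < 0.05)
  }
  expect_gt(rej / n_rep, 0.02)
  expect_lt(rej / n_rep, 0.08)

  # full censoring: survival comparison errors out informatively
  sv_c <- generate_survival(cfg, coh, censor_range = c(1e-4, 2e-4))
  expect_identical(sum(sv_c$event), 0L)
  expect_error(km_logrank(ifelse(sv_c$marker_high, "hi", "lo"),
                          sv_c$time, sv_c$event), "censored|no events")
})
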