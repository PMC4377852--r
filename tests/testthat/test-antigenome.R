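# Mutation filtering, mutant translation, window enumeration, neo-antigen
# and cancer-germline antigen calling.

# A hand-built two-exon transcript: CDS "ATG GGT AAA TGC CCA GAT TAC ... TAA"
toy_transcript <- function() {
  cds <- paste0("ATG", "GGTAAATGCCCAGATTACGAAGTTCTGAGG",
                "GGTAAATGCCCAGATTACGAAGTTCTGAGG", "TAA")
  list(transcript_id = "TOY1", gene_id = "TOYG1", strand = "+",
       exons = data.frame(start = c(1001, 2001),
                          end = c(1001 + 30 - 1, 2001 + nchar(cds) - 30 - 1)),
       cds_sequence = cds,
       downstream_utr_sequence = "CCCCCCCCCCCCTAGAAAA")
}

mut_row <- function(class, pos, ref, alt, id = "m1", patient = "P1",
                    transcript = "TOY1", expressed = TRUE) {
  data.frame(patient_id = patient, mutation_id = id,
             transcript_id = transcript, class = class, cds_pos = pos,
             ref = ref, alt = alt, expressed_flag = expressed)
}

test_that("mutation filtering excludes decoys with logged reasons", {
  tr <- toy_transcript()
  trs <- list(TOY1 = tr)
  muts <- rbind(
    mut_row("missense", 20, substr(tr$cds_sequence, 20, 20), "A", id = "keep"),
    mut_row("start_codon", 2, "T", "C", id = "start"),
    mut_row("splice", 30, substr(tr$cds_sequence, 30, 30), "A", id = "spl"),
    mut_row("non_frameshift", 29, substr(tr$cds_sequence, 29, 31), "",
            id = "border"),
    mut_row("silent", 21, substr(tr$cds_sequence, 21, 21), "G", id = "sil"))
  muts$alt[muts$mutation_id == "keep"] <-
    setdiff(c("A", "C", "G", "T"), muts$ref[muts$mutation_id == "keep"])[1]
  res <- filter_mutations(muts, trs)
  expect_identical(res$kept$mutation_id, "keep")
  reasons <- setNames(res$excluded$exclusion_reason, res$excluded$mutation_id)
  expect_identical(reasons[["start"]], "start_codon")
  expect_identical(reasons[["spl"]], "splice")
  expect_identical(reasons[["border"]], "exon_border")
  expect_identical(reasons[["sil"]], "not_protein_altering")
  expect_error(filter_mutations(mut_row("missense", 5, "G", "A",
                                        transcript = "NOPE"), trs),
               "unknown transcript")
})

test_that("missense translation substitutes one residue at the right place", {
  tr <- toy_transcript()
  # codon 2 is GGT (Gly); GGT -> GAT is Gly -> Asp at protein position 2
  m <- mut_row("missense", 5, "G", "A")
  res <- translate_mutation(tr, m)
  expect_identical(res$altered_span, c(2L, 2L))
  expect_identical(substr(res$protein, 2, 2), "D")
  expect_identical(substr(res$wt_protein, 2, 2), "G")
  expect_identical(nchar(res$protein), nchar(res$wt_protein))
  # ref mismatch is caught
  expect_error(translate_mutation(tr, mut_row("missense", 5, "C", "A")),
               "ref allele")
})

test_that("indel and nonstop translations match a table-driven oracle", {
  set.seed(50)
  cfg <- synthetic_config(seed = 50, n_mutations = 300, n_transcripts = 25)
  ms <- generate_mutation_set(cfg)
  flt <- filter_mutations(ms$mutations, ms$transcripts)
  n_checked <- 0
  for (i in seq_len(nrow(flt$kept))) {
    m <- flt$kept[i, ]
    tr <- ms$transcripts[[m$transcript_id]]
    res <- suppressWarnings(translate_mutation(tr, m))
    # oracle: edit the CDS independently and translate with the codon table
    cds <- tr$cds_sequence
    mut_cds <- if (nchar(m$ref) == 0) {
      paste0(substr(cds, 1, m$cds_pos - 1), m$alt,
             substr(cds, m$cds_pos, nchar(cds)))
    } else {
      paste0(substr(cds, 1, m$cds_pos - 1), m$alt,
             substr(cds, m$cds_pos + nchar(m$ref), nchar(cds)))
    }
    expect_identical(res$protein,
                     oracle_translate(paste0(mut_cds,
                                             tr$downstream_utr_sequence)))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 200)
})

test_that("nonstop read-through ends exactly at the next downstream stop", {
  tr <- toy_transcript()
  L <- nchar(tr$cds_sequence)
  # TAA -> CAA abolishes the stop; downstream UTR holds an in-frame TAG
  m <- mut_row("nonstop", L - 2L, "T", "C")
  res <- translate_mutation(tr, m)
  wt_len <- nchar(res$wt_protein)
  expect_gt(nchar(res$protein), wt_len)
  expect_identical(res$altered_span, c(wt_len + 1L, nchar(res$protein)))
  # appended tail equals oracle translation of CDS+UTR
  expect_identical(res$protein,
                   oracle_translate(paste0(substr(tr$cds_sequence, 1, L - 3),
                                           "CAA",
                                           tr$downstream_utr_sequence)))
})

test_that("frameshift without a downstream stop truncates with a warning", {
  # poly-GGA CDS: no stop codon appears in the shifted frame
  cds <- paste0("ATG", strrep("GGA", 20), "TAA")
  tr <- list(transcript_id = "FS1", gene_id = "FSG1", strand = "+",
             exons = data.frame(start = 1, end = nchar(cds)),
             cds_sequence = cds,
             downstream_utr_sequence = "CCCCCCCCCCCC")
  m <- mut_row("frameshift", 5, substr(cds, 5, 5), "", transcript = "FS1")
  expect_warning(res <- translate_mutation(tr, m), "truncated")
  expect_identical(res$altered_span[2], nchar(res$protein))
})

test_that("window enumeration equals brute force on synthetic mutations", {
  # interior single altered residue: 8+9+10+11 = 38 windows
  set.seed(51)
  prot <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                       replace = TRUE), collapse = "")
  w <- enumerate_windows(prot, c(30L, 30L))
  expect_identical(sum(w$multiplicity), 38L)

  # altered residue at position 2: only 2 windows fit per length
  w2 <- enumerate_windows(prot, c(2L, 2L))
  expect_identical(sum(w2$multiplicity), 8L)

  expect_error(enumerate_windows(prot, NULL), "altered_span")
  expect_error(enumerate_windows(prot, c(0L, 5L)), "bounds")

  # every mutation class agrees with the brute-force substring oracle
  cfg <- synthetic_config(seed = 52, n_mutations = 300, n_transcripts = 25)
  ms <- generate_mutation_set(cfg)
  flt <- filter_mutations(ms$mutations, ms$transcripts)
  n_checked <- 0
  for (i in seq_len(nrow(flt$kept))) {
    m <- flt$kept[i, ]
    res <- suppressWarnings(
      translate_mutation(ms$transcripts[[m$transcript_id]], m))
    if (is.null(res$altered_span)) next
    w <- enumerate_windows(res$protein, res$altered_span)
    got <- sort(rep(w$peptide, w$multiplicity))
    want <- sort(oracle_windows(res$protein, res$altered_span))
    expect_identical(got, want)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 200)
})

test_that("neo-antigen calling respects the inclusive rank-2 boundary and novelty", {
  proteome <- c(P1 = "MAAAAAAAAAAAKLMNPQRSTVW")
  peps <- data.frame(patient_id = "P1",
                     peptide = c("SIINFEKLL", "AAAAAAAAA", "WWWWWWWWW"),
                     mutation_id = c("m1", "m2", "m3"),
                     transcript_id = "t1")
  hla <- data.frame(patient_id = "P1", allele = "HLA-A*02:01")
  ranks <- c(SIINFEKLL = 2.0, AAAAAAAAA = 0.5, WWWWWWWWW = 2.0001)
  pred <- function(p, a) unname(ranks[p])
  res <- call_neoantigens(peps, hla, pred, proteome)
  # rank exactly 2.0 is called; 2.0 + eps is not; proteome substring is not
  expect_setequal(res$peptide, "SIINFEKLL")
  expect_error(call_neoantigens(
    data.frame(patient_id = "P2", peptide = "SIINFEKLL", mutation_id = "m",
               transcript_id = "t"), hla, pred, proteome), "without HLA")

  # raising the threshold never removes a called neo-antigen
  res3 <- call_neoantigens(peps, hla, pred, proteome, rank_threshold = 3)
  expect_true(all(res$peptide %in% res3$peptide))
})

test_that("planted binders are recovered exactly end-to-end", {
  cfg <- synthetic_config(seed = 53, n_mutations = 150, n_transcripts = 20)
  ms <- generate_mutation_set(cfg)
  flt <- filter_mutations(ms$mutations, ms$transcripts)
  peps <- list()
  for (i in seq_len(nrow(flt$kept))) {
    m <- flt$kept[i, ]
    tm <- suppressWarnings(
      translate_mutation(ms$transcripts[[m$transcript_id]], m))
    if (is.null(tm$altered_span)) next
    w <- enumerate_windows(tm$protein, tm$altered_span)
    if (!nrow(w)) next
    peps[[length(peps) + 1]] <- data.frame(
      patient_id = m$patient_id, mutation_id = m$mutation_id,
      transcript_id = m$transcript_id, peptide = w$peptide)
  }
  peps <- do.call(rbind, peps)
  pred <- make_binding_predictor(seed = 53,
                                 planted = ms$ground_truth$planted_binders,
                                 background = "nonbinding")
  neo <- call_neoantigens(peps, ms$hla, pred, ms$proteome)
  pb <- ms$ground_truth$planted_binders
  # planted binders are (peptide, allele) pairs; the same peptide arising in
  # another patient carrying that allele is a legitimate call
  expect_setequal(paste(neo$peptide, neo$hla_allele),
                  paste(pb$peptide, pb$allele))
  expect_true(all(paste(pb$patient_id, pb$peptide, pb$allele) %in%
                    paste(neo$patient_id, neo$peptide, neo$hla_allele)))
  # self-filter soundness: no called peptide occurs in the proteome
  prot <- as.character(ms$proteome)
  for (p in unique(neo$peptide))
    expect_false(any(grepl(p, prot, fixed = TRUE)))
  # silent mutations never produce peptides
  expect_false(any(ms$mutations$class[match(neo$mutation_id,
                                            ms$mutations$mutation_id)] ==
                     "silent"))
})

test_that("neo-antigen frequencies follow the implemented definition", {
  muts <- do.call(rbind, lapply(1:10, function(i)
    mut_row("missense", 10, "A", "G", id = paste0("m", i), patient = "P1")))
  neo <- data.frame(patient_id = "P1",
                    peptide = sprintf("PEPTIDE%02dA", 1:4),
                    mutation_id = paste0("m", 1:4),
                    hla_allele = "X", rank = 1)
  fr <- neoantigen_frequency(muts, neo)
  expect_equal(fr$frequency, 0.4)

  neo_all <- data.frame(patient_id = "P1",
                        peptide = sprintf("PEPTIDE%02dA", 1:10),
                        mutation_id = paste0("m", 1:10),
                        hla_allele = "X", rank = 1)
  expect_equal(neoantigen_frequency(muts, neo_all)$frequency, 1.0)
  expect_equal(neoantigen_frequency(muts, neo_all[0, ])$frequency, 0.0)

  muts0 <- muts; muts0$expressed_flag <- FALSE
  expect_true(is.na(neoantigen_frequency(muts0, neo)$frequency))

  # per-mutation mode counts all neo-antigens
  fr2 <- neoantigen_frequency(muts, rbind(neo, neo[1, ]), mode = "per_mutation")
  expect_equal(fr2$frequency, 0.5)
})

test_that("shared neo-antigens are grouped across patients", {
  neo <- data.frame(
    patient_id = c("P1", "P2", "P1", "P3"),
    peptide = c("AAAAAAAA", "AAAAAAAA", "CCCCCCCC", "DDDDDDDD"),
    mutation_id = paste0("m", 1:4),
    transcript_id = c("g1", "g2", "g3", "g4"),
    hla_allele = "X", rank = 1)
  res <- shared_neoantigens(neo)
  expect_identical(res$shared$peptide, "AAAAAAAA")
  expect_identical(res$shared$n_patients, 2L)
  expect_match(res$shared$transcripts, "g1;g2")

  # all-unique cohort: empty shared table
  res0 <- shared_neoantigens(neo[3:4, ])
  expect_identical(nrow(res0$shared), 0L)

  # planted hotspot peptide in 30 of 100 patients
  set.seed(54)
  cohort <- data.frame(
    patient_id = sprintf("P%03d", 1:100),
    peptide = replicate(100, paste(sample(LETTERS[c(1, 3:5)], 9,
                                          replace = TRUE), collapse = "")),
    mutation_id = sprintf("m%03d", 1:100), transcript_id = "g",
    hla_allele = "X", rank = 1)
  cohort$peptide[1:30] <- "EEEEEEEEE"
  res30 <- shared_neoantigens(cohort)
  expect_identical(res30$shared$n_patients[res30$shared$peptide ==
                                             "EEEEEEEEE"], 30L)
})

test_that("cancer-germline antigen baselines follow the median + 3 SD rule", {
  set.seed(55)
  normals <- matrix(rnorm(5 * 10, 5, 1), 5, 10,
                    dimnames = list(paste0("g", 1:5), paste0("n", 1:10)))
  tumors <- matrix(5, 5, 6,
                   dimnames = list(paste0("g", 1:5), paste0("t", 1:6)))
  # fix g1 to a known baseline: median 5, sd 1 -> baseline 8
  normals["g1", ] <- c(4, 4.5, 5, 5, 5, 5, 5, 5.5, 6, 6)
  s <- sd(normals["g1", ]); normals["g1", ] <- 5 + (normals["g1", ] - 5) / s
  tumors["g1", 1] <- 8.5   # above baseline
  tumors["g1", 2] <- 8.0   # exactly at baseline -> negative
  normals["g2", ] <- 3     # zero sd -> excluded
  de <- data.frame(gene_id = paste0("g", 1:5), log2fc = 0, q = 1)
  de$log2fc[3] <- -2; de$q[3] <- 0.001  # g3 downregulated -> removed
  res <- call_cga(tumors, normals, paste0("g", 1:5), de = de, k = 0)
  expect_setequal(res$records$gene_id, c("g1", "g4", "g5"))
  expect_equal(res$records$baseline[res$records$gene_id == "g1"], 8)
  expect_true(res$positive["g1", "t1"])
  expect_false(res$positive["g1", "t2"])
  expect_identical(res$dropped$reason[res$dropped$gene_id == "g2"],
                   "zero_normal_sd")
  expect_identical(res$dropped$reason[res$dropped$gene_id == "g3"],
                   "downregulated_in_tumor")
  expect_error(call_cga(tumors, normals[, 1, drop = FALSE],
                        paste0("g", 1:5)), "2 normal")
})
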