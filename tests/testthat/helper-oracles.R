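# Independent brute-force oracles used to verify the package's statistics.
# Each re-derives its quantity from first principles, without touching the
# implementation under test.

# --- translation: explicit standard genetic code table -----------------------
codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3
  aa <- character(0)
  for (i in seq(1, n - 2, by = 3)) {
    a <- codon_table[[substr(nt, i, i + 2)]]
    if (a == "*") return(paste(aa, collapse = ""))
    aa <- c(aa, a)
  }
  paste(aa, collapse = "")
}

# --- enrichment: direct running-sum recomputation ----------------------------
oracle_es <- function(ranked_genes, ranked_weights, set) {
  hits <- ranked_genes %in% set
  wsum <- sum(ranked_weights[hits])
  n_miss <- length(ranked_genes) - sum(hits)
  run <- 0; best <- 0
  for (i in seq_along(ranked_genes)) {
    run <- if (hits[i]) run + ranked_weights[i] / wsum else run - 1 / n_miss
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# --- peptide windows: full substring enumeration -----------------------------
oracle_windows <- function(protein, span, lengths = 8:11) {
  out <- character(0)
  for (L in lengths) {
    if (nchar(protein) < L) next
    for (s in seq_len(nchar(protein) - L + 1)) {
      e <- s + L - 1
      if (s <= span[2] && e >= span[1]) out <- c(out, substr(protein, s, e))
    }
  }
  out
}

# --- concordance: O(n^2) pair counting ---------------------------------------
oracle_harrell_c <- function(score, time, event) {
  conc <- ties <- comp <- 0
  n <- length(score)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        comp <- comp + 1
        if (score[i] > score[j]) conc <- conc + 1
        else if (score[i] == score[j]) ties <- ties + 1
      }
    }
  }
  (conc + 0.5 * ties) / comp
}

# --- misc --------------------------------------------------------------------
random_peptide <- function(n, len = 9) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
}

# Small test cohort reused by several files.
small_reference <- function(seed = 11) {
  cfg <- synthetic_config(seed = seed, n_cell_types = 4,
                          n_marker_genes_per_type = 12,
                          n_background_genes = 120,
                          n_replicates_per_type = 5,
                          n_tumors = 40, n_normals = 10)
  list(cfg = cfg, ref = generate_reference_profiles(cfg))
}
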