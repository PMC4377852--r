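# Seeded string hash on (0, 1]: polynomial rolling hash modulo 2^31 - 1.
# Exact in double arithmetic (intermediate values stay below 2^46).
hash_unit <- function(x, seed = 0L) {
  p <- 2147483647
  vapply(x, function(s) {
    h <- (as.numeric(seed) %% p)
    for (b in utf8ToInt(s)) h <- (h * 131 + b) %% p
    # Lehmer scrambling rounds decorrelate the low-order structure
    h <- (h * 48271) %% p
    h <- (h * 69621) %% p
    (h + 1) / (p + 1)
  }, numeric(1), USE.NAMES = FALSE)
}

aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Deterministic mock MHC binding predictor
#'
#' Stands in for an MHC class I binding predictor: maps each (peptide,
#' allele) pair to a percentile rank via a seeded hash, so predictions are
#' reproducible without network calls. Pairs listed in `planted` always
#' receive a rank in (0, 2]. Background behavior is configurable:
#' `"uniform"` draws ranks uniformly over (0, 100] (realistic percentile
#' ranks); `"nonbinding"` maps non-planted pairs to (2, 100], so planted
#' binders are recovered exactly.
#'
#' @param peptide,allele character vectors (recycled to equal length).
#'   Peptides must be 8-11 uppercase residues over the 20-letter amino-acid
#'   alphabet.
#' @param seed integer hash seed.
#' @param planted optional data frame with `peptide`, `allele` columns of
#'   planted strong binders.
#' @param background `"uniform"` or `"nonbinding"` (see above).
#' @return numeric percentile ranks in (0, 100].
#' @export
mock_binding_predictor <- function(peptide, allele, seed = 0L, planted = NULL,
                                   background = c("uniform", "nonbinding")) {
  background <- match.arg(background)
  n <- max(length(peptide), length(allele))
  peptide <- rep_len(peptide, n)
  allele <- rep_len(allele, n)
  if (any(nchar(peptide) < 8L | nchar(peptide) > 11L))
    stop("peptides must be 8-11 residues long")
  bad <- grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), peptide)
  if (any(bad))
    stop("invalid residue character in peptide(s): ",
         paste(unique(peptide[bad]), collapse = ", "))
  u <- hash_unit(paste(peptide, allele, sep = "|"), seed = seed)
  rank <- switch(background,
                 uniform = u * 100,
                 nonbinding = 2 + u * 98)
  if (!is.null(planted) && nrow(planted)) {
    key <- paste(peptide, allele, sep = "|")
    planted_key <- paste(planted$peptide, planted$allele, sep = "|")
    hit <- key %in% planted_key
    rank[hit] <- 0.1 + u[hit] * 1.9
  }
  rank
}

#' Build a binding-predictor closure for [call_neoantigens()]
#'
#' @inheritParams mock_binding_predictor
#' @return function `(peptide, allele) -> rank`.
#' @export
make_binding_predictor <- function(seed = 0L, planted = NULL,
                                   background = c("uniform", "nonbinding")) {
  background <- match.arg(background)
  force(seed); force(planted)
  function(peptide, allele)
    mock_binding_predictor(peptide, allele, seed = seed, planted = planted,
                           background = background)
}

random_cds <- function(n_codons) {
  codons <- expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                        b3 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  codons <- apply(codons, 1, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(codons, stops)
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(stops, 1L))
}

# Deterministic multinomial allotment: class counts match proportions within
# one count.
allot_counts <- function(n, prop) {
  cum <- round(cumsum(prop) * n)
  counts <- diff(c(0L, cum))
  names(counts) <- names(prop)
  counts
}

#' Generate transcript models, somatic mutations, proteome and HLA types
#'
#' Builds random multi-exon coding transcripts (start codon, no internal
#' stops, one terminal stop), somatic mutations of the configured classes --
#' including decoys (start-codon changes, splice-site mutations,
#' exon-border-spanning deletions) that the neo-antigen filters must remove
#' -- the wild-type reference proteome, per-patient HLA class I allele
#' lists, and a set of planted strong binders drawn from the mutant peptide
#' windows.
#'
#' @param config a [synthetic_config()].
#' @param cds_codon_range range of CDS lengths in codons (including start
#'   and stop).
#' @param expressed_rate fraction of mutations flagged as expressed.
#' @param planted_rate fraction of filter-passing mutations contributing one
#'   planted binder peptide.
#' @return list with `transcripts` (named list of transcript models:
#'   `transcript_id`, `strand`, `exons` (1-based inclusive genomic spans),
#'   `cds_sequence`, `downstream_utr_sequence`), `mutations` (data frame),
#'   `proteome` (`AAStringSet` of wild-type translations plus decoy
#'   proteins), `hla` (data frame `patient_id`, `allele`) and
#'   `ground_truth` (list with `planted_binders`).
#' @export
generate_mutation_set <- function(config, cds_codon_range = c(60L, 150L),
                                  expressed_rate = 0.8, planted_rate = 0.4) {
  stopifnot(inherits(config, "synthetic_config"))
  if (min(cds_codon_range) * 3L < 33L)
    stop("transcripts must have >= 33 coding nt to host an 11-mer window")
  set.seed(sub_seed(config$seed, 2))

  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  tr_ids <- sprintf("TX%03d", seq_len(config$n_transcripts))
  transcripts <- vector("list", config$n_transcripts)
  names(transcripts) <- tr_ids
  for (i in seq_len(config$n_transcripts)) {
    n_codons <- sample(cds_codon_range[1L]:cds_codon_range[2L], 1L)
    cds <- random_cds(n_codons)
    utr <- paste(sample(bases, 90L, replace = TRUE), collapse = "")
    n_ex <- sample(2:4, 1L)
    cuts <- sort(sample(seq_len(nchar(cds) - 1L), n_ex - 1L))
    lens <- diff(c(0L, cuts, nchar(cds)))
    gstart <- sample(1e4:1e6, 1L)
    exon_start <- integer(n_ex); exon_end <- integer(n_ex)
    pos <- gstart
    for (e in seq_len(n_ex)) {
      exon_start[e] <- pos
      exon_end[e] <- pos + lens[e] - 1L
      pos <- exon_end[e] + sample(50:500, 1L)
    }
    transcripts[[i]] <- list(
      transcript_id = tr_ids[i],
      gene_id = sub("TX", "GENE", tr_ids[i]),
      strand = sample(c("+", "-"), 1L),
      exons = data.frame(start = exon_start, end = exon_end),
      cds_sequence = cds,
      downstream_utr_sequence = utr)
  }

  counts <- allot_counts(config$n_mutations, config$mutation_class_proportions)
  classes <- rep(names(counts), counts)
  patients <- sprintf("T%03d", seq_len(config$n_tumors))

  snv_alt <- function(ref) sample(setdiff(bases, ref), 1L)
  rows <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cls <- classes[i]
    tr <- transcripts[[sample(tr_ids, 1L)]]
    cds <- tr$cds_sequence
    L <- nchar(cds)
    junc <- exon_junctions(tr)
    pos <- NA_integer_; ref <- ""; alt <- ""
    if (cls == "missense") {
      repeat {
        codon_i <- sample(2:(L %/% 3L - 1L), 1L)
        off <- sample(0:2, 1L)
        pos <- (codon_i - 1L) * 3L + 1L + off
        ref <- substr(cds, pos, pos)
        alt <- snv_alt(ref)
        codon <- substr(cds, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
        mut_codon <- codon
        substr(mut_codon, off + 1L, off + 1L) <- alt
        aa_wt <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                                    no.init.codon = TRUE))
        aa_mt <- as.character(Biostrings::translate(Biostrings::DNAString(mut_codon),
                                                    no.init.codon = TRUE))
        if (aa_mt != aa_wt && aa_mt != "*") break
      }
    } else if (cls == "nonstop") {
      repeat {
        off <- sample(0:2, 1L)
        pos <- L - 2L + off
        ref <- substr(cds, pos, pos)
        alt <- snv_alt(ref)
        stop_codon <- substr(cds, L - 2L, L)
        mut_codon <- stop_codon
        substr(mut_codon, off + 1L, off + 1L) <- alt
        if (!mut_codon %in% stops) break
      }
    } else if (cls %in% c("frameshift", "non_frameshift")) {
      len <- if (cls == "frameshift") sample(c(1L, 2L, 4L), 1L) else 3L
      # keep the edit inside one exon so the border filter keeps it
      repeat {
        pos <- sample(4:(L - 6L - len), 1L)
        if (!any(junc >= pos & junc < pos + len)) break
      }
      if (stats::runif(1) < 0.5) { # deletion
        ref <- substr(cds, pos, pos + len - 1L)
        alt <- ""
      } else {                     # insertion
        ref <- ""
        alt <- paste(sample(bases, len, replace = TRUE), collapse = "")
      }
    } else if (cls == "start_codon") {
      pos <- sample(1:3, 1L)
      ref <- substr(cds, pos, pos)
      alt <- snv_alt(ref)
    } else if (cls == "splice") {
      pos <- if (length(junc)) junc[sample.int(length(junc), 1L)] else 4L
      ref <- substr(cds, pos, pos)
      alt <- snv_alt(ref)
    } else if (cls == "exon_border") {
      if (!length(junc)) junc <- L %/% 2L
      j <- junc[sample.int(length(junc), 1L)]
      pos <- j - 1L
      ref <- substr(cds, pos, pos + 2L)  # deletion spanning the junction
      alt <- ""
    }
    rows[[i]] <- data.frame(
      patient_id = sample(patients, 1L),
      mutation_id = sprintf("mut%04d", i),
      transcript_id = tr$transcript_id,
      class = cls, cds_pos = pos, ref = ref, alt = alt,
      expressed_flag = stats::runif(1) < expressed_rate)
  }
  mutations <- do.call(rbind, rows)

  wt_proteins <- vapply(transcripts, function(tr)
    translate_until_stop(tr$cds_sequence)$protein, character(1))
  decoys <- vapply(seq_len(20L), function(i)
    paste(sample(aa_alphabet(), 120L, replace = TRUE), collapse = ""),
    character(1))
  proteome <- Biostrings::AAStringSet(c(wt_proteins,
                                        stats::setNames(decoys,
                                                        sprintf("DECOY%02d",
                                                                seq_along(decoys)))))

  allele_pool <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*11:01", "HLA-A*24:02",
                   "HLA-B*07:02", "HLA-B*08:01", "HLA-B*35:01", "HLA-C*07:01",
                   "HLA-C*04:01")
  hla <- do.call(rbind, lapply(patients, function(p)
    data.frame(patient_id = p,
               allele = sample(allele_pool, sample(4:6, 1L)))))

  # Plant strong binders among the mutant peptide windows of filter-passing,
  # expressed mutations.
  flt <- filter_mutations(mutations, transcripts)
  planted <- list()
  cand <- flt$kept[as.logical(flt$kept$expressed_flag), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    if (stats::runif(1) > planted_rate) next
    m <- cand[i, ]
    tm <- suppressWarnings(translate_mutation(transcripts[[m$transcript_id]], m))
    if (is.null(tm$altered_span)) next
    win <- enumerate_windows(tm$protein, tm$altered_span)
    win <- win[peptide_is_novel(win$peptide, proteome), , drop = FALSE]
    if (!nrow(win)) next
    pep <- sample(win$peptide, 1L)
    alleles <- hla$allele[hla$patient_id == m$patient_id]
    planted[[length(planted) + 1L]] <- data.frame(
      peptide = pep, allele = sample(alleles, 1L),
      patient_id = m$patient_id, mutation_id = m$mutation_id)
  }
  planted <- if (length(planted)) do.call(rbind, planted)
             else data.frame(peptide = character(0), allele = character(0),
                             patient_id = character(0),
                             mutation_id = character(0))

  list(transcripts = transcripts, mutations = mutations, proteome = proteome,
       hla = hla, ground_truth = list(planted_binders = planted))
}
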