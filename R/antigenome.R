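#' @import Biostrings
NULL

# Translate a nucleotide string in frame 1 until the first stop codon.
# Returns list(protein, stopped); trailing bases short of a codon are ignored.
translate_until_stop <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return(list(protein = "", stopped = FALSE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)), no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) list(protein = substr(aa, 1L, stop_at - 1L), stopped = TRUE)
  else list(protein = aa, stopped = FALSE)
}

# CDS-coordinate positions of exon-exon junctions (after the last base of
# each non-terminal exon).
exon_junctions <- function(transcript) {
  lens <- transcript$exons$end - transcript$exons$start + 1L
  if (length(lens) < 2L) return(integer(0))
  cumsum(lens)[-length(lens)]
}

#' Filter somatic mutations to the protein-altering, cleanly exonic set
#'
#' Retains missense, nonstop, frameshift and non-frameshift mutations that
#' lie within the coding sequence, do not touch the start codon, are not
#' splice-site mutations, and (for indels) do not span an exon junction.
#' Every exclusion is recorded with its reason.
#'
#' @param mutations data frame with columns `patient_id`, `mutation_id`,
#'   `transcript_id`, `class`, `cds_pos` (1-based), `ref`, `alt` (empty
#'   string for pure insertions/deletions).
#' @param transcripts named list of transcript models (see
#'   [generate_mutation_set()] for the schema).
#' @return list with `kept` (retained mutations) and `excluded` (mutations
#'   with an `exclusion_reason` column).
#' @export
filter_mutations <- function(mutations, transcripts) {
  unknown <- setdiff(unique(mutations$transcript_id), names(transcripts))
  if (length(unknown))
    stop("unknown transcript(s): ", paste(unknown, collapse = ", "))

  reason <- character(nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    tr <- transcripts[[m$transcript_id]]
    cds_len <- nchar(tr$cds_sequence)
    ref_len <- nchar(m$ref)
    span_len <- max(ref_len, 1L)
    span <- c(m$cds_pos, m$cds_pos + span_len - 1L)
    if (m$class %in% c("silent", "other")) {
      reason[i] <- "not_protein_altering"
    } else if (m$class == "splice") {
      reason[i] <- "splice"
    } else if (span[1L] < 1L || span[2L] > cds_len) {
      reason[i] <- "not_exonic"
    } else if (m$class == "start_codon" || span[1L] <= 3L) {
      reason[i] <- "start_codon"
    } else if (ref_len != nchar(m$alt) &&
               any(exon_junctions(tr) >= span[1L] &
                   exon_junctions(tr) < span[2L])) {
      reason[i] <- "exon_border"
    } else if (!m$class %in% c("missense", "nonstop", "frameshift",
                               "non_frameshift")) {
      reason[i] <- "unsupported_class"
    }
  }
  kept <- mutations[reason == "", , drop = FALSE]
  excluded <- mutations[reason != "", , drop = FALSE]
  if (nrow(excluded)) excluded$exclusion_reason <- reason[reason != ""]
  list(kept = kept, excluded = excluded)
}

#' Translate a coding mutation to the mutant protein and its altered span
#'
#' Applies the DNA change to the coding sequence and translates with the
#' standard genetic code. Missense changes substitute one residue;
#' non-frameshift indels change a local in-frame block; frameshifts are
#' translated in the shifted frame until the first stop (reading into the
#' downstream UTR if needed); nonstop mutations read through the abolished
#' stop into the downstream UTR until the next in-frame stop. When no stop
#' is reached before the end of the available sequence, translation is
#' truncated there with a warning.
#'
#' Insertions (`ref == ""`) place `alt` immediately before the base at
#' `cds_pos`; deletions (`alt == ""`) remove `nchar(ref)` bases starting at
#' `cds_pos`.
#'
#' @param transcript a transcript model (list with `cds_sequence` and
#'   `downstream_utr_sequence`).
#' @param mutation one row of a mutation table (see [filter_mutations()]).
#' @return list with `protein` (mutant protein string), `altered_span`
#'   (integer c(first, last) residue of the altered region, or `NULL` when
#'   the change yields no altered residues) and `wt_protein`.
#' @export
translate_mutation <- function(transcript, mutation) {
  cds <- transcript$cds_sequence
  utr <- transcript$downstream_utr_sequence %||% ""
  pos <- mutation$cds_pos
  ref <- mutation$ref
  alt <- mutation$alt

  if (nchar(ref) > 0L &&
      substr(cds, pos, pos + nchar(ref) - 1L) != ref)
    stop("ref allele does not match transcript ", transcript$transcript_id,
         " at CDS position ", pos)

  mut_cds <- if (nchar(ref) == 0L) {
    paste0(substr(cds, 1L, pos - 1L), alt, substr(cds, pos, nchar(cds)))
  } else {
    paste0(substr(cds, 1L, pos - 1L), alt,
           substr(cds, pos + nchar(ref), nchar(cds)))
  }

  wt <- translate_until_stop(cds)
  mt <- translate_until_stop(paste0(mut_cds, utr))
  if (!mt$stopped)
    warning("no downstream stop codon for ", mutation$mutation_id %||% "mutation",
            " on ", transcript$transcript_id, "; truncated at sequence end")

  wt_p <- wt$protein
  mt_p <- mt$protein
  len_wt <- nchar(wt_p)
  len_mt <- nchar(mt_p)

  # Longest common prefix of wild-type and mutant proteins.
  l <- 0L
  max_l <- min(len_wt, len_mt)
  while (l < max_l &&
         substr(wt_p, l + 1L, l + 1L) == substr(mt_p, l + 1L, l + 1L))
    l <- l + 1L

  cls <- mutation$class
  if (cls == "missense") {
    span <- if (l < len_mt) c(l + 1L, l + 1L) else NULL
  } else if (cls == "non_frameshift") {
    r <- 0L
    max_r <- min(len_wt, len_mt) - l
    while (r < max_r &&
           substr(wt_p, len_wt - r, len_wt - r) ==
           substr(mt_p, len_mt - r, len_mt - r))
      r <- r + 1L
    if (l + 1L <= len_mt - r) {
      span <- c(l + 1L, len_mt - r)
    } else {
      # clean in-frame deletion: flag the junction residues
      span <- c(max(1L, l), min(len_mt, l + 1L))
      if (span[1L] > span[2L]) span <- NULL
    }
  } else { # frameshift, nonstop: everything from the first novel residue
    span <- if (l < len_mt) c(l + 1L, len_mt) else NULL
  }
  if (!is.null(span) && (span[1L] > span[2L] || span[1L] < 1L)) span <- NULL
  list(protein = mt_p, altered_span = span, wt_protein = wt_p)
}

#' Enumerate candidate peptide windows over the altered protein region
#'
#' Slides windows of the given lengths over the mutant protein and keeps
#' every window that overlaps at least one altered residue and lies fully
#' within the protein. Duplicate peptide strings are collapsed with their
#' multiplicity recorded.
#'
#' @param mutant_protein mutant protein string.
#' @param altered_span integer `c(first, last)` altered residues.
#' @param lengths window lengths (default 8:11).
#' @return data frame with `peptide` and `multiplicity`.
#' @export
enumerate_windows <- function(mutant_protein, altered_span, lengths = 8:11) {
  if (is.null(altered_span) || length(altered_span) != 2L)
    stop("altered_span must be a non-empty c(first, last) residue interval")
  len <- nchar(mutant_protein)
  if (altered_span[1L] < 1L || altered_span[2L] > len ||
      altered_span[1L] > altered_span[2L])
    stop("altered_span out of protein bounds")
  peps <- character(0)
  for (L in lengths) {
    s0 <- max(1L, altered_span[1L] - L + 1L)
    s1 <- min(altered_span[2L], len - L + 1L)
    if (s0 > s1) next
    starts <- s0:s1
    peps <- c(peps, substring(mutant_protein, starts, starts + L - 1L))
  }
  if (!length(peps))
    return(data.frame(peptide = character(0), multiplicity = integer(0)))
  tab <- table(peps)
  data.frame(peptide = names(tab), multiplicity = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Exact-substring novelty check against a reference proteome.
peptide_is_novel <- function(peptides, proteome) {
  prot <- as.character(proteome)
  vapply(peptides, function(p) !any(grepl(p, prot, fixed = TRUE)),
         logical(1), USE.NAMES = FALSE)
}

#' Call neo-antigens from mutant peptides, patient HLA alleles and a predictor
#'
#' Scores every (peptide, allele) pair of a patient with the binding
#' predictor and keeps pairs with percentile rank at or below
#' `rank_threshold` (inclusive, default 2) whose peptide is not an exact
#' substring of any reference protein.
#'
#' @param peptides data frame with `patient_id`, `peptide` and optionally
#'   `mutation_id`, `transcript_id`.
#' @param hla data frame with `patient_id`, `allele`.
#' @param predictor function `(peptide, allele) -> percentile rank in (0,100]`,
#'   vectorized over both arguments; see [make_binding_predictor()].
#' @param proteome reference proteome (character vector or `AAStringSet`).
#' @param rank_threshold inclusive percentile-rank cutoff (default 2).
#' @return data frame of called neo-antigens: `patient_id`, `peptide`,
#'   `mutation_id`, `transcript_id`, `hla_allele`, `rank`, `novel_flag`.
#' @export
call_neoantigens <- function(peptides, hla, predictor, proteome,
                             rank_threshold = 2) {
  patients <- unique(peptides$patient_id)
  missing_hla <- setdiff(patients, unique(hla$patient_id))
  if (length(missing_hla))
    stop("patient(s) without HLA alleles: ", paste(missing_hla, collapse = ", "))

  out <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    p <- patients[i]
    pep <- peptides[peptides$patient_id == p, , drop = FALSE]
    alleles <- unique(hla$allele[hla$patient_id == p])
    idx <- rep(seq_len(nrow(pep)), times = length(alleles))
    cand <- pep[idx, , drop = FALSE]
    cand$hla_allele <- rep(alleles, each = nrow(pep))
    cand$rank <- predictor(cand$peptide, cand$hla_allele)
    cand <- cand[cand$rank <= rank_threshold, , drop = FALSE]
    out[[i]] <- cand
  }
  called <- do.call(rbind, out)
  if (is.null(called) || !nrow(called)) {
    return(data.frame(patient_id = character(0), peptide = character(0),
                      hla_allele = character(0), rank = numeric(0),
                      novel_flag = logical(0)))
  }
  novel_by_pep <- peptide_is_novel(unique(called$peptide), proteome)
  names(novel_by_pep) <- unique(called$peptide)
  called$novel_flag <- novel_by_pep[called$peptide]
  called <- called[called$novel_flag, , drop = FALSE]
  rownames(called) <- NULL
  called
}

#' Per-patient neo-antigen frequency
#'
#' The fraction of a patient's expressed protein-altering mutations that
#' yield at least one called neo-antigen (`mode = "fraction"`, default), or
#' the number of called neo-antigens per expressed protein-altering mutation
#' (`mode = "per_mutation"`). Patients with zero expressed protein-altering
#' mutations get `NA` (undefined, not 0).
#'
#' @param mutations filtered mutation table (output `kept` of
#'   [filter_mutations()]) with an `expressed_flag` column.
#' @param neoantigens output of [call_neoantigens()].
#' @param mode frequency definition, see above.
#' @return data frame with `patient_id`, `n_expressed`, `n_immunogenic`,
#'   `frequency`.
#' @export
neoantigen_frequency <- function(mutations, neoantigens,
                                 mode = c("fraction", "per_mutation")) {
  mode <- match.arg(mode)
  expressed <- mutations[as.logical(mutations$expressed_flag), , drop = FALSE]
  patients <- unique(mutations$patient_id)
  n_exp <- vapply(patients, function(p)
    sum(expressed$patient_id == p), integer(1))
  neo_exp <- neoantigens[neoantigens$mutation_id %in% expressed$mutation_id, ,
                         drop = FALSE]
  if (mode == "fraction") {
    n_imm <- vapply(patients, function(p)
      length(unique(neo_exp$mutation_id[neo_exp$patient_id == p])), integer(1))
  } else {
    n_imm <- vapply(patients, function(p)
      sum(neo_exp$patient_id == p), integer(1))
  }
  freq <- ifelse(n_exp > 0L, n_imm / n_exp, NA_real_)
  data.frame(patient_id = patients, n_expressed = n_exp,
             n_immunogenic = n_imm, frequency = freq, row.names = NULL)
}

#' Shared neo-antigens across a cohort
#'
#' Groups identical peptide strings across patients and reports peptides seen
#' in two or more patients, with the source transcripts collapsed. Also
#' two-way clusters the binary peptide x patient incidence matrix
#' (Euclidean distance, average linkage).
#'
#' @param neoantigens output of [call_neoantigens()] for a cohort.
#' @return list with `shared` (data frame `peptide`, `n_patients`,
#'   `patients`, `transcripts`), `incidence` (binary matrix), and, when at
#'   least two shared peptides/patients exist, `peptide_order` and
#'   `patient_order` from hierarchical clustering.
#' @export
shared_neoantigens <- function(neoantigens) {
  if (!nrow(neoantigens))
    return(list(shared = data.frame(peptide = character(0),
                                    n_patients = integer(0)),
                incidence = NULL))
  by_pep <- split(neoantigens, neoantigens$peptide)
  n_pat <- vapply(by_pep, function(d) length(unique(d$patient_id)), integer(1))
  shared_peps <- names(by_pep)[n_pat >= 2L]
  shared <- data.frame(
    peptide = shared_peps,
    n_patients = n_pat[shared_peps],
    patients = vapply(by_pep[shared_peps], function(d)
      paste(sort(unique(d$patient_id)), collapse = ";"), character(1)),
    transcripts = vapply(by_pep[shared_peps], function(d)
      paste(sort(unique(as.character(d$transcript_id %||% ""))),
            collapse = ";"), character(1)),
    row.names = NULL)
  res <- list(shared = shared, incidence = NULL)
  if (length(shared_peps)) {
    pats <- sort(unique(neoantigens$patient_id))
    inc <- matrix(0L, length(shared_peps), length(pats),
                  dimnames = list(shared_peps, pats))
    for (p in shared_peps)
      inc[p, unique(by_pep[[p]]$patient_id)] <- 1L
    res$incidence <- inc
    if (nrow(inc) >= 2L)
      res$peptide_order <- stats::hclust(stats::dist(inc), "average")$order
    if (ncol(inc) >= 2L)
      res$patient_order <- stats::hclust(stats::dist(t(inc)), "average")$order
  }
  res
}

# k-means++ style seeding: spread initial centers by squared-distance sampling.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1L, prob = prob)
    dj <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  x[centers, , drop = FALSE]
}

#' Call cancer-germline antigens against a normal-tissue baseline
#'
#' Removes candidate genes significantly downregulated in tumors (per
#' supplied differential-expression results, or a built-in rank-sum test),
#' removes genes whose normal-tissue standard deviation is zero, sets the
#' per-gene baseline at `median(normal) + 3 * sd(normal)`, and calls a gene
#' positive in a tumor when its expression is strictly above the baseline.
#' Genes are then k-means clustered (k-means++ seeding) on the
#' positive-expression matrix.
#'
#' @param tumor_expr,normal_expr linear-scale expression matrices
#'   (genes x samples) sharing the gene universe.
#' @param cga_genes candidate cancer-germline antigen gene IDs.
#' @param de optional data frame `gene_id`, `log2fc`, `q` from an external
#'   differential-expression analysis; when `NULL` a Wilcoxon rank-sum test
#'   with BH adjustment is used.
#' @param de_q_threshold FDR threshold for the downregulation filter.
#' @param k number of k-means clusters (set to 0 to skip clustering).
#' @param seed seed for the k-means initialization.
#' @return list with `records` (per retained gene: `gene_id`,
#'   `normal_median`, `normal_sd`, `baseline`, `n_positive`), `positive`
#'   (genes x tumor-samples logical matrix), `clusters` (named gene ->
#'   cluster), `dropped` (gene, reason).
#' @export
call_cga <- function(tumor_expr, normal_expr, cga_genes, de = NULL,
                     de_q_threshold = 0.05, k = 3L, seed = 1L) {
  if (ncol(normal_expr) < 2L) stop("need >= 2 normal samples (sd undefined)")
  missing_genes <- setdiff(cga_genes, intersect(rownames(tumor_expr),
                                                rownames(normal_expr)))
  if (length(missing_genes))
    stop("cga genes absent from expression: ",
         paste(missing_genes, collapse = ", "))

  if (is.null(de)) {
    p <- vapply(cga_genes, function(g)
      stats::wilcox.test(tumor_expr[g, ], normal_expr[g, ],
                         exact = FALSE)$p.value, numeric(1))
    q <- stats::p.adjust(p, "BH")
    lfc <- log2((rowMeans(tumor_expr[cga_genes, , drop = FALSE]) + 1) /
                (rowMeans(normal_expr[cga_genes, , drop = FALSE]) + 1))
    de <- data.frame(gene_id = cga_genes, log2fc = lfc, q = q)
  }
  de <- de[match(cga_genes, de$gene_id), ]
  down <- !is.na(de$q) & de$q < de_q_threshold & de$log2fc < 0

  nmed <- apply(normal_expr[cga_genes, , drop = FALSE], 1, stats::median)
  nsd <- apply(normal_expr[cga_genes, , drop = FALSE], 1, stats::sd)
  zero_sd <- nsd == 0

  dropped <- data.frame(
    gene_id = c(cga_genes[down], cga_genes[!down & zero_sd]),
    reason = c(rep("downregulated_in_tumor", sum(down)),
               rep("zero_normal_sd", sum(!down & zero_sd))))
  keep <- cga_genes[!down & !zero_sd]

  baseline <- nmed[keep] + 3 * nsd[keep]
  pos <- sweep(tumor_expr[keep, , drop = FALSE], 1, baseline, ">")
  records <- data.frame(gene_id = keep, normal_median = nmed[keep],
                        normal_sd = nsd[keep], baseline = baseline,
                        n_positive = rowSums(pos), row.names = NULL)

  clusters <- NULL
  if (k > 0L && length(keep) > k) {
    set.seed(seed)
    m <- tumor_expr[keep, , drop = FALSE] * pos
    centers <- kmeanspp_centers(m, k)
    km <- stats::kmeans(m, centers = centers)
    clusters <- stats::setNames(km$cluster, keep)
  }
  list(records = records, positive = pos, clusters = clusters,
       dropped = dropped)
}
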