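---
title: "Methods: immunophenotype and antigenome characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immunophenotype and antigenome characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

immunoscape characterizes the immune contexture and the antigen repertoire of
a tumor cohort from bulk expression and somatic mutation data. This vignette
describes the statistical machinery, the assumptions behind it, the choices
made where the methods literature leaves the design open, and what the
synthetic cohort used in the tests does and does not establish.

## Immune metagene compendium

Cell-type-specific signature genes are derived from expression profiles of
sorted immune cell populations in four filter stages:

1. **One-way ANOVA** across cell types (default p < 0.05). Genes constant
   across all samples have an undefined F statistic; they are assigned p = 1
   and excluded.
2. **Two-fold dominance**: per-type medians are compared on the *linear*
   scale (log2 input is exponentiated first, since "two-fold" is a
   linear-scale notion); a gene is kept when the top type's median is at
   least twice the runner-up's. The boundary is inclusive — a ratio of
   exactly 2 passes — so behavior at the threshold is deterministic. A zero
   runner-up median with a positive top median counts as an infinite ratio.
3. **Label-permutation specificity**: the statistic is the difference
   between the top-type and runner-up-type medians; all sample labels are
   permuted (default 10,000 times) and the p-value uses the add-one
   estimator (1 + b)/(n + 1), which can never be zero. Note a structural
   consequence: permutations can recreate the observed partition, so the
   attainable minimum is slightly above the 1/(n + 1) floor.
4. **Jensen-Shannon specificity** (descriptive, not thresholded): the
   divergence, in bits, between a gene's mean-expression pattern across
   types and the one-hot pattern of exclusive expression, reported as
   1 − sqrt(JSD).

Metagenes are then selected per cell type by greedy backward elimination:
the candidate with the lowest average Pearson correlation to the others is
dropped until all remaining genes have average r ≥ 0.6 with correlation-test
p < 0.01. The search procedure is not fixed by the methods literature;
greedy elimination was chosen because it is deterministic and matches how
correlation-pruned signatures are built in practice. Types that finish below
11 genes are reported as failed and omitted — a gene-set statistic over
fewer genes is too unstable. Each metagene carries a weight, its median
log2 intensity in its own cell type; myeloid-derived suppressor cells have
no sorted-cell profiles and their literature-curated set enters through the
`extra_sets` argument.

## Enrichment and abundance

Per sample (or group), genes are ranked by descending z-score (population
standard deviation; constant genes map to zero and are flagged), with ties
broken by gene identifier so rankings are reproducible. The enrichment score
is the weighted Kolmogorov-Smirnov running sum with |z| weights at exponent
1. Because a single sample admits no phenotype permutation, the null is a
gene-set permutation: random same-size sets drawn from the ranked universe.
NES divides the ES by the mean |ES| of same-sign null scores, the p-value is
the same-sign null tail (add-one form), and q-values are Benjamini-Hochberg
*within a sample across cell types* — the alternative, a global adjustment
across samples, mixes samples of different quality and was rejected. A cell
type is called enriched at q ≤ 0.10.

The relative abundance of cell type *c* is

$$I_c = \sum_{i=1}^{n_c} \frac{\log_{10}(x_i + 1)}{w_i},$$

with `x_i` the TPM-like linear expression of metagene *i* and `w_i` its
reference weight. The +1 pseudocount makes the statistic zero for an
all-zero sample and strictly increasing in every metagene's expression.
Tumors are called hypermutated when the coverage-normalized non-silent
mutation rate strictly exceeds 8.24 per megabase; the boundary is strict so
that a tumor at exactly the published threshold is non-hypermutated.

Tumor-vs-normal "escape" summaries rank genes by the difference in mean
z-scores and run the enrichment engine on the ranking and its reverse, so
depletion is scored symmetrically with enrichment. Gene-level fold changes
use log2((mean + 1)/(mean + 1)) pseudocount form — consistent with the
log10(x + 1) convention of I~c~ — with a Wilcoxon rank-sum test and BH
adjustment as the built-in differential test; externally computed results
(e.g. from a negative-binomial model) can be supplied instead.

## Antigenome

**Neo-antigens.** Mutations are filtered to the cleanly exonic,
protein-altering set: start-codon changes, splice-site mutations, indels
spanning an exon junction, and silent changes are excluded, each with a
logged reason. Surviving mutations are applied to the coding sequence and
translated with the standard genetic code: missense substitutes one
residue; in-frame indels change a local block (for a clean deletion the
junction residues are flagged as altered); frameshifts translate in the
shifted frame until the first stop, reading into the transcript's stored
downstream UTR if necessary (translation truncates at the sequence end,
with a warning, when no stop appears — no genome walking); nonstop
mutations read through the abolished stop until the next in-frame stop.
All 8-11-mer windows overlapping at least one altered residue are
enumerated; a peptide is called a neo-antigen when its predicted binding
percentile rank for a patient allele is ≤ 2 (inclusive, so a rank of
exactly 2 is kept) and it is not an exact substring of the reference
proteome. Near-matches to the proteome are deliberately kept: only exact
matches are non-novel.

Binding prediction is a pluggable interface — any function
`(peptide, allele) -> rank`. The shipped mock maps a seeded string hash to
a percentile rank so results are reproducible without external tools. Its
background is configurable: `"uniform"` spreads ranks over (0, 100] like
real percentile ranks, while `"nonbinding"` confines non-planted pairs to
(2, 100]; the synthetic cohort uses the latter so that planted-binder
recovery is exact rather than contaminated by ~2% chance binders. Planted
binders are keyed by (peptide, allele), so an identical peptide arising in
another patient carrying the allele is a genuine call.

The per-patient neo-antigen frequency is not uniquely fixed by its usual
presentation; two definitions are implemented, and the default — the
fraction of expressed protein-altering mutations yielding at least one
called neo-antigen — is used throughout, with neo-antigens per expressed
mutation behind `mode = "per_mutation"`. A patient with zero expressed
protein-altering mutations gets a missing value, not zero. "Expressed" is
taken at the gene level (> 1 TPM, configurable); allele-level expression of
the mutant copy is not resolved by bulk data.

**Cancer-germline antigens.** Candidates significantly downregulated in
tumors are removed first (supplied DE results or the built-in rank-sum
test), then genes with zero normal-tissue standard deviation (no usable
baseline). The baseline is median + 3 SD of normal expression; a tumor is
positive strictly above it, so a value exactly at the baseline is negative.
Positive-expression matrices are k-means clustered with a k-means++-style
seeding (D² sampling), which stabilizes the clusters against bad random
starts.

## Heterogeneity

The heterogeneity of a tumor is the exact area under the right-continuous
empirical CDF of its cancer-cell fractions over [0, 1], computed as the sum
of rectangles between consecutive sorted values (no quadrature). Fully
clonal tumors score 0; the statistic equals 1 − mean(CCF), which the tests
use as an independent closed form. Pairwise tumor similarity is the
two-sample Kolmogorov-Smirnov D evaluated exactly over the pooled
breakpoints. "Hierarchical clustering with a Euclidean measure and Ward
agglomeration" on a KS-D matrix is ambiguous — D is itself a distance — so
the default treats D-matrix rows as feature vectors under Euclidean Ward
clustering (honoring both printed choices), and `method = "direct"` uses D
directly with average linkage. The default of four clonal groups is
configurable.

## Survival machinery and the TIL network

Candidate cutpoints for a marker are midpoints between consecutive distinct
values whose low-side fraction lies in the inner 80% (10th-90th
percentiles). The minimal two-group log-rank p over that scan is corrected
with the Miller-Siegmund approximation

$$p_{cor} = \varphi(z)\,(z - 1/z)\,\log\frac{(1-\varepsilon)^2}{\varepsilon^2} + \frac{4\varphi(z)}{z},$$

with ε = 0.1, clamped to [p_min, 1], so the corrected value is never
smaller than the uncorrected one. An alternative criterion maximizes
Harrell's C of the dichotomized marker; C counts a tied score as half a
concordance and a pair as comparable when the earlier time is an observed
event. The log-rank scan is a vectorized in-package implementation (one
O(n) pass per candidate after a single sort), verified against
`survival::survdiff`; Cox fits and Kaplan-Meier curves delegate to the
survival package, with the hazard ratio reported for the high vs the low
group.

Network edges connect a cell type and a panel gene when the Pearson
correlation between I~c~ and log2(TPM + 1) is at least 0.6 with
correlation-test p < 0.05. Cell-type nodes are dichotomized at the median
abundance, gene nodes at their optimal cutpoint; each node carries the
hazard ratio, log-rank p, significance flag and prognosis direction.
Following the convention that only survival-relevant candidate genes are
displayed, non-significant gene nodes are dropped (with their edges) by
default, while cell-type nodes are always retained; `filter_genes = FALSE`
keeps everything.

## Immunogenicity model

The response is the cytotoxicity score, the mean of the CD8, NK and Tgd
abundance summaries. Feature blocks (immunosuppressive TIL abundances,
immunomodulator panel expression, neo-antigen frequencies, antigen counts,
…) are column-bound over their shared patients — complete-case, since
imputation would manufacture signal in a model meant to rank determinants —
standardized to mean 0 / SD 1 (a full cohort-scale assembly runs to a few
hundred features — the recovery tests use 221 — while the workflow uses
what its blocks provide), and zero-variance columns are
dropped with a warning. The lasso penalty is chosen by inner
cross-validation on MSE; nonzero-coefficient features are refit by ordinary
least squares and kept at BH-adjusted p < 0.005. This post-selection
inference is deliberately naive (it ignores the selection event), matching
the practice of the era in which the approach was described; the caveat
matters when interpreting the adjusted p-values. Where sources disagree on
the significance threshold (0.001 vs an adjusted 0.005), the adjusted 0.005
is the default and both are reachable through `p_threshold`. Model
performance is an outer seeded 10-fold cross-validation, nested so the
penalty is re-chosen within each training fold.

## The synthetic cohort

The generators produce every input with planted ground truth: reference
profiles with disjoint marker sets at four-fold linear dominance (plus a
0.5-log2 margin so the dominance invariant survives replicate noise at the
default noise SD of 0.1 log2 units); bulk tumors as Dirichlet mixtures of
cell-type mean profiles plus a tumor-intrinsic component under
multiplicative log-normal noise (log-normal is the standard choice for RNA
abundance noise; the sources are silent on a simulation model);
hypermutated-like tumors with 2.5× the immune concentration, planting the
phenotype association; multi-exon transcripts with decoy mutation classes
generated explicitly so every filter path is exercised; four Beta clonal
groups; and exponential survival with a marker-linked hazard ratio and
independent uniform censoring. Default sizes — 10 cell types × 5
replicates, 2,000 genes, 200 tumors + 50 normals, 200 mutations, 100 CCF
tumors at 200 CCFs each — keep the full pipeline at desk scale (the whole
test suite runs in a few minutes on one core).

What the synthetic cohort does **not** emulate: probe-level microarray
artifacts and batch effects, gene-gene correlation structure beyond the
planted mixtures, copy-number and purity distortions of CCF estimates,
allele-level expression of mutations, linkage between mutation burden and
the expression phenotype, and real HLA-peptide binding chemistry. Passing
tests therefore demonstrate that the statistical machinery is implemented
correctly and recovers planted structure under its stated model — not that
the pipeline's biological conclusions transfer to any particular real
cohort.

## Numerical conventions

Genomic intervals in files are 1-based inclusive; CDS positions are
1-based; insertions place the alternate allele immediately before the
stated position. Rankings break ties by gene identifier. Fisher odds ratios
use the Haldane-Anscombe 0.5 correction only when a 2×2 cell is zero, so
log odds ratios are always finite. All stochastic steps (generators,
permutation nulls, k-means seeding, CV folds) take explicit seeds, and
identical configurations reproduce byte-identical outputs.
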