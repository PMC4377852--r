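# immunoscape

Characterization of tumor immunophenotypes and the cancer antigenome from
bulk expression and somatic mutation data, for computational immunologists
and tumor-genomics analysts. The package implements, as tested R functions,
the full analytical chain used to dissect tumor-immune interactions in
colorectal-cancer-style cohorts:

- **Immune metagene compendium** — cell-type-specific signature genes from
  sorted-cell reference profiles (ANOVA, linear two-fold dominance of the
  top cell type, label-permutation specificity, Jensen-Shannon specificity,
  correlation-pruned metagene sets of ≥ 11 genes with average pairwise
  r ≥ 0.6).
- **TIL enrichment and quantification** — single-sample GSEA (weighted
  Kolmogorov-Smirnov running sum, gene-set permutation null, NES, BH
  q ≤ 0.10 flags) and the relative immune-cell abundance
  *I*<sub>c</sub> = Σ<sub>i</sub> log₁₀(x<sub>i</sub> + 1)/w<sub>i</sub>
  over each cell type's metagenes, plus phenotype×TIL Fisher odds-ratio
  maps and tumor-vs-normal enrichment/depletion summaries.
- **Antigenome** — neo-antigens (mutation filtering, mutant-protein
  translation for missense/indel/frameshift/nonstop classes, 8-11-mer
  window enumeration, HLA binding rank ≤ 2, reference-proteome novelty) and
  cancer-germline antigens (normal baseline = median + 3 SD, zero-SD and
  downregulation filters, k-means clustering).
- **Clonal heterogeneity** — the area under the empirical CDF of per-tumor
  cancer-cell fractions, pairwise Kolmogorov-Smirnov D similarity and Ward
  clustering into clonal groups.
- **Survival machinery and the TIL-immunomodulator network** — optimal
  cutpoints in the inner 80% with the Miller-Siegmund minimal-p correction,
  Harrell's C, KM/log-rank/Cox wrappers, and correlation networks
  (r ≥ 0.6, p < 0.05) annotated with per-node hazard ratios.
- **Immunogenicity model** — lasso-regularized regression of the
  cytotoxicity score (mean CD8/NK/Tgd abundance) on tumor-intrinsic and
  -extrinsic feature blocks, post-selection OLS refit with BH-adjusted
  p < 0.005, nested 10-fold cross-validation.

A seeded synthetic-cohort generator (`synthetic_config()` and the
`generate_*()` family) produces every input with planted ground truth, so
the complete pipeline runs and is verified at desk scale without external
data.

## Worked example: the analysis workflow

The `analysis/` scripts run the whole study on a synthetic cohort and write
their tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

Output of a run (seed 1):

```
simulated: 50 reference arrays (10 cell types), 200 tumors + 50 normals,
  200 mutations on 30 transcripts, 100 CCF tumors, 200 survival records
compendium: 200 signature genes -> 200 metagenes over 10 cell types
  planted-marker recovery 100.0%, background false positives 0.00%
TILs enriched (q <= 0.10) in 96.0% of 200 tumors
mutation filter: 160 kept, 40 excluded (exon_border:10 splice:20 start_codon:10)
enumerated 6774 candidate mutant peptides from 157 mutations
called 47 neo-antigens; mean neo-antigen frequency 0.38
heterogeneity: scores in [0.052, 0.790]; 4 clonal groups, ARI vs planted 1.00
survival: 2/10 TIL subpopulations significant after minimal-p correction
  Tem_CD8: HR(hi vs lo) 0.12, corrected p 8.37e-11
lasso: 69 nonzero features at lambda 0.002032, 7 kept at adjusted p < 0.005
outer 10-fold CV: mean R2 0.670, mean MSE 0.0048
```

Reading the numbers: all 200 planted marker genes pass the four-stage
signature filter with no background gene leaking through; 96% of tumors
show at least one enriched TIL subpopulation at q ≤ 0.10; the mutation
filter removes exactly the planted decoy classes (start-codon, splice-site,
exon-border); the four planted clonal architectures are recovered perfectly
(adjusted Rand index 1.0); the planted protective effect of effector-memory
CD8 infiltration is found by the corrected cutpoint scan (HR 0.12); and the
lasso names the TIL abundances as the dominant determinants of the
cytotoxicity score.

The same machinery is available directly, e.g.:

```r
library(immunoscape)
cfg <- synthetic_config(seed = 1)
ref <- generate_reference_profiles(cfg)
comp <- derive_compendium(ref$expr, ref$labels, n_perm = 10000)
cohort <- generate_tumor_cohort(cfg, ref)
abundance <- relative_abundance(cohort$expr, comp$metagenes)
```

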