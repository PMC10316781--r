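# panelomics

Multi-omic functional characterization of disease gene panels, built around
the diagnostic question raised by hereditary ataxia: gene panels are
partitioned by typical age of onset (adult, childhood, or both), but is that
partition visible in functional genomic annotation — and does it cost
diagnoses? The package provides the full statistical machinery to ask this
of any panel set, together with a synthetic-data module that generates every
input with planted effects, so each stage is testable and calibratable
without access-controlled cohort data.

## What it computes

* **Per-gene features** by interval arithmetic over gene models (GTF):
  gene length, transcript and exon–exon junction counts, GC content; short
  tandem repeat (STR) densities per period and genic context from a
  HipSTR-dialect catalog; expression-associated STR (eSTR) counts;
  repetitive-element (LINE/L1, SINE/Alu, SVA) densities; and the covered
  fraction of constrained non-conserved regions (CNCR density).
* **Expression specificity**: the 5-fold tissue-specific expression rule,
  the 3.5-fold module-membership rule, and row-normalized cell-type
  specificity matrices (each gene's row sums to 1).
* **Expression-weighted cell-type enrichment (EWCE)**: for a gene set and
  cell type, the bootstrap p-value

  `p = (1 + #{replicates with mean specificity >= target mean}) / (B + 1)`

  with replicates matched to the target on transcript length and GC content
  via joint quantile bins, and effect size reported in bootstrap standard
  deviations.
* **Panel comparison**: pairwise Wilcoxon rank-sum (numeric) or chi-squared
  (categorical, Yates-corrected) over all six panel pairs, with
  Benjamini–Hochberg adjustment per feature family.
* **Balanced recursive feature elimination**: correlation pruning at
  r > 0.9, then repeated class-balanced resampling with a logistic-model
  RFE scored by cross-validated Cohen's kappa; features selected in >= 80%
  of 50 repeats are retained and embedded in 2-D by UMAP.
* **Rare-variant burden testing**: per gene and scenario (LoF, pathogenic
  score > 0.8, pathogenic-in-CCR, de novo), one-sided Fisher's exact test
  on case/control carrier counts under MAF thresholds of 0.1% (dominant)
  and 1% (recessive), a 4-carrier minimum, and one joint FDR correction
  across all tests.
* **STR allele-size tails**: per locus, the mean of the top 1% of
  per-individual maximum repeat sizes, contrasted case minus control, split
  by known-pathogenic vs naturally occurring loci.

## Worked example

Simulate a 150-gene panel set with the default planted 2x STR density in
disease-class genes, annotate, and compare the STR count across panels:

```r
library(panelomics)

cfg     <- sim_config(seed = 42, n_genes = 150)
ann     <- gen_annotation(cfg)
catalog <- gen_str_catalog(ann, cfg)
feats   <- gene_features(ann, catalog = catalog)
compare_feature(feats, "n_strs")[, c("group_x", "group_y", "p", "p_adj",
                                     "summary_x", "summary_y")]
#>     group_x   group_y        p    p_adj summary_x summary_y
#> 1     adult childhood 5.57e-01 7.82e-01      14.5        16
#> 2     adult   control 1.07e-05 2.13e-05      14.5         8
#> 3     adult   overlap 6.52e-01 7.82e-01      14.5        17
#> 4 childhood   control 3.56e-19 2.14e-18      16.0         8
#> 5 childhood   overlap 9.96e-01 9.96e-01      16.0        17
#> 6   control   overlap 1.45e-10 4.36e-10       8.0        17
```

Every disease panel carries about twice the control STR density (medians
14.5–17 vs 8 STRs per gene), the disease-vs-control pairs are strongly
significant after the within-feature FDR correction, and — as planted —
the disease panels are indistinguishable from one another.

Burden testing at realistic cohort sizes (816 adult-onset cases vs 6658
controls, carrier rates 6/816 vs 7/6658 planted in one childhood-onset
gene):

```r
v <- gen_variants(cfg, data.frame(gene_id = "G0001", rate_case = 6/816,
                                  rate_control = 7/6658))
run_burden(v$variants, data.frame(gene_id = "G0001", panel = "childhood"),
           v$cohorts, scenarios = "pathogenic")
#>   gene_id   scenario  a c_ odds_ratio        p    p_adj
#> 1   G0001 pathogenic 13 10      10.76 1.15e-07 1.15e-07
```

Thirteen of 816 adult-onset cases versus ten of 6658 controls carry a
qualifying variant in this typically childhood-onset gene: an odds ratio of
10.8 with a one-sided Fisher p of 1.1e-07, the signature the framework is
designed to detect.

`run_pipeline(cfg, "out/")` chains all stages (simulate, annotate,
expression features, comparisons, EWCE, selection/embedding, burden, STR
tails) and writes TSV outputs plus a checksummed `manifest.json`.

## Vignette

`vignettes/panel-annotation-methods.Rmd` documents the models and rules,
every tunable threshold with its default and rationale, what the synthetic
generators emulate (and what they deliberately do not), numerical and
tie-breaking conventions, and known limitations.
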