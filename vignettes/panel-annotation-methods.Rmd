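---
title: "Methods: multi-omic characterization of disease gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic characterization of disease gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelomics)
```

## The problem

Hereditary ataxias are diagnosed against gene panels partitioned by typical
age of onset (adult, childhood, or both), yet most patients remain
molecularly undiagnosed after whole-genome sequencing. `panelomics`
implements an analysis framework that asks whether that partition is visible
in functional genomic annotation: it builds per-gene multi-omic features,
compares them across onset panels, tests cell-type expression enrichment,
selects the most discriminating features, and validates hypotheses with
gene-based rare-variant burden tests and short tandem repeat (STR)
allele-size comparisons in case/control cohorts. Because the cohort data
such analyses run on are access-controlled, the package ships a synthetic
data module that generates every pipeline input with planted, tunable
effects, so each stage can be exercised and statistically calibrated.

## Synthetic study conditions

`sim_config()` fixes the conditions every generator works under. Cohort
sizes default to the study design the framework mirrors: 816 adult-onset
cases, 306 childhood-onset cases and 6658 non-neurological controls. Panel
fractions (5% adult, 45% childhood, 15% overlap, 35% control at the default
200 genes) keep the real panels' ordering — few adult-onset genes, many
childhood-onset, an intermediate overlap set — while reserving enough
control genes for balanced feature selection. Planted effect defaults: a 2x
STR density ratio in disease-class genes (the observed per-gene medians,
roughly 34.5 vs 16, motivate a twofold planted contrast), a 3-fold
expression specificity, carrier rates of 6/816 vs 7/6658 (the scale at
which the burden analysis reports an odds ratio near 7), and +10 repeat
units planted in 1% of case alleles.

All randomness flows from a single root seed: each stage hashes its name
together with the root via `stage_seed()`, so `gen_str_catalog()` output,
for instance, is reproducible without re-running `gen_annotation()`.
Identical configurations give byte-identical outputs; this is asserted in
the tests and recorded as checksums in the pipeline manifest.

What the generators emulate — and what they do not. Gene models have master
exon sets with transcripts dropping exons at random, exact per-gene GC
content, and UTR/CDS partitions in transcript orientation; genes are
non-overlapping on one synthetic chromosome. Allele sizes use a discretized
negative-binomial jitter around the catalog reference count, floored at one
repeat unit, giving the right-skewed tails empirical STR distributions show;
the real cohorts' allele-size distribution is not published, so this noise
model is a stand-in and results about tail *shape* should not be
over-read. There is no linkage disequilibrium, population structure,
read-level error or genotyping saturation: passing tests demonstrate that
the statistical machinery is correct and calibrated, not that effect sizes
transfer to real cohorts.

## Per-gene features

Internal coordinates are 0-based half-open; GTF is read/written as 1-based
inclusive, and the HipSTR-dialect STR BED (chrom, start, end, period,
reference repeat count, name) is read as a 0-based start with an inclusive
end, with a `one_based` flag for catalogs in fully 1-based coordinates.

* `structure_features()`: gene length, transcript count, unique
  (donor, acceptor) junction pairs over all transcripts, and GC content over
  the gene span with ambiguous bases excluded from the denominator.
* `str_features()`: STR counts per gene, per period (2–6) and per genic
  context. An STR overlapping several gene spans counts toward every one of
  them — density is treated as a per-gene property, and whether shared loci
  should instead be assigned to a single primary gene is not specified
  upstream; the both-genes rule is the documented choice. Context follows
  the precedence `coding_exon > 5'UTR > 3'UTR > intron` over the union of
  transcripts, since coding and 5'UTR STRs are the actionable classes for
  repeat-expansion screening.
* `estr_features()`: expression-associated STR counts and the union of
  affected tissues, de-duplicated by locus.
* `cncr_density()`: the fraction of the gene span covered by the base-level
  union of constrained non-conserved regions — invariant under segment
  order and splitting, verified against a per-base scan oracle.

## Expression specificity rules

The tissue rule flags a gene in a tissue when expression there is at least
5-fold the mean across *all* tissues (the focal tissue included — the
literal reading). A consequence worth guarding rather than silently
reinterpreting: with T tissues and fold f, a flag requires
`x >= f/T * (x + rest)`, impossible when `T <= f`; hence
`tissue_specific_flags()` refuses fewer than `fold + 1` tissues with an
explanatory error, and `sim_config()` requires at least 10 tissues. At most
`floor(T/fold)` tissues can ever be flagged per gene, which the tests assert
as a property.

The module-membership rule compares against the *other* tissues
(3.5-fold), flooring negative memberships at zero because a fold change
over a negative baseline is undefined; a negative focal value never flags.
Whether the original rule used the mean or the maximum over other tissues
is not published; the mean is the default and `baseline = "max"` is the
switch.

Cell-type specificity is the row-normalized mean-expression matrix: each
retained gene's row sums to one, all-zero rows are dropped with a message,
and the result is invariant under uniform rescaling of a gene's row.

## Expression-weighted cell-type enrichment

`ewce_test()` asks whether a gene set's mean specificity in a cell type
exceeds that of matched random sets. Matching controls transcript length
and GC content by joint quantile bins (5 per covariate by default; the
original method's exact matching scheme is not restated in its description,
so granularity is configurable). Per replicate, each target gene is
replaced by a uniform draw from its own joint bin, with replacement —
per-gene replacement rather than whole-set matching, since the alternative
is not specified. The p-value uses the add-one estimator
`(1 + #{boot >= target}) / (B + 1)`, which can never return 0 from a finite
bootstrap; `sd_from_mean` reports effect size in bootstrap standard
deviations. Correction scope is explicit: `"all"` (cell types x gene sets
jointly) or `"per_gene_set"` for granular cell-type levels where
correcting across sets only is appropriate.

Under the null (targets drawn by the matched sampler itself) the p-values
are uniform — the acceptance suite checks this by Kolmogorov–Smirnov over
200 replicate seeds and observes a type-I rate near 5% — and a 3-fold
planted specificity in 50 of 2000 genes is detected essentially always.

## Pairwise panel comparison

Numeric features are compared between every pair of panels by Wilcoxon
rank-sum (exact enumeration when the combined sample is at most 12 without
ties, otherwise the tie- and continuity-corrected normal approximation);
categorical features by chi-squared. The Yates continuity correction is on
by default for 2x2 tables: reconstructing the repeat-expansion mechanism
table from the published panel sizes and percentages (8 of 23 adult-onset
vs 1 of 213 childhood-onset genes) reproduces the published
p = 3.205e-14 only with the correction applied, which pins down the
convention; `continuity = FALSE` is available. Within each feature, the six
pairwise p-values are Benjamini–Hochberg adjusted as one family.

## Balanced recursive feature elimination

Features correlated above 0.9 are greedily pruned first (the member of the
worst pair with the larger mean absolute correlation goes; ties break by
name; constant columns are removed up front because their correlation is
undefined). Each of 50 repeats then draws 50% of the disease genes and an
equal-sized bootstrap sample of controls, z-scores the features, and runs
recursive elimination with a logistic-link linear model, ranking by
absolute standardized coefficient — the model family is stated upstream,
the ranking criterion is not, so it is the documented default. Candidate
subset sizes are the powers of two down from the full set (the original
grid is unpublished). One elimination path is computed per repeat and
cross-validation scores the candidate sizes on shared folds: pairing the
size comparisons this way stops fold-to-fold path noise from dominating the
size choice. The full-size model involves no feature selection, so its
cross-validated Cohen's kappa is an unbiased skill estimate; a repeat whose
full model does not reach kappa 0.2 (the conventional floor of "fair"
agreement) contributes no selections, since a chance-level model's "best
subset" is noise. Features selected in at least 80% of repeats (more than
40 of 50) are retained.

With five 1.5-SD informative features among 60 (200 genes per class), all
five are recovered at frequency 0.8 in nearly every seed, while permuted
labels select nothing. The 2-D embedding of the selected features calls
UMAP as an external routine on z-scored columns, shrinking the
neighbourhood parameter with a warning when genes are few.

## Rare-variant burden testing

Variants qualify when rarer than 0.1% (dominant) or 1% (recessive) and
matching one of four scenarios: predicted LoF, predicted pathogenic
(score > 0.8), pathogenic in a constrained coding region, or de novo —
the last restricted to probands where de novo calling was possible, in
both numerator and denominator. A proband carries a gene with one
qualifying dominant variant or two qualifying recessive alleles (homozygous
counts as two). The four-way design crosses childhood genes with adult
cases, adult genes with childhood cases, and overlap genes with both. Tests
with fewer than four carriers are dropped before a single joint
Benjamini–Hochberg correction across all scenarios; the realized family
size is recorded, since the surviving grid depends on the cohort at hand.

The one-sided p is the hypergeometric upper tail; the odds ratio is the
sample cross-product with the Haldane–Anscombe 0.5 correction on zero
cells (the conditional MLE is a switch, as the upstream convention is
unstated). When summarizing replicate odds ratios across simulated cohorts
the package uses the geometric mean: at carrier rates of 6/816 vs 7/6658
the arithmetic mean of per-cohort cross-product ratios is inflated about
20% by the heavy right tail of small-count ratios, whereas the log-scale
summary — the standard way to average odds ratios — recovers the planted
7.04 scale within a few percent.

## STR allele-size tails

Screenable loci are the tri- to hexanucleotide STRs in coding exons or
5'UTRs of panel genes; known pathogenic expansion loci are tagged but kept.
Per locus and group, individuals are ranked by their maximum allele and the
top `ceiling(0.01 * n)` form the tail; ties at the boundary are included by
rank and trimmed in individual-id order, making membership invariant to row
order. The published description ranks maxima per STR, so per-locus
comparison is the default and pooling across loci sits behind
`mode = "pooled"`; individuals missing a genotype are excluded at that
locus only. No hypothesis test is attached by default — the comparison
reports a trend — but `tail_permutation_test()` offers a label-shuffling
test for synthetic validation. Binning of repeat sizes, where wanted, is in
integer repeat units.

A +10-repeat inflation of 1% of case alleles (500 cases, 2000 controls)
produces a positive pooled difference in essentially every seed; with no
inflation the difference is centred at zero.

## Orchestration and problem sizes

`run_pipeline()` executes the stages in dependency order from one
configuration, writes every output as TSV/GTF/FASTA/BED, and emits a
manifest with MD5 checksums; identical configurations reproduce identical
checksums. The spec-level command-line surface maps onto the exported
functions plus `scripts/acceptance.R`; each stage is equally usable on
ingested files via the readers (`read_gtf()`, `read_str_bed()`,
`read_matrix_tsv()`, `read_tsv()`).

The shipped validation uses desk-scale problem sizes chosen to estimate
each quantity stably: 500 simulated cohorts for the odds-ratio summary, 200
seeds for enrichment calibration and 50 for power, 10–20 seeds for feature
selection and tails, and bootstrap counts of 200–1000 in simulation loops
(the analysis default remains 10000). These sizes are the package's own
validation design; all of them are arguments.

## Known limitations

* The synthetic allele-size model is a stand-in for unpublished cohort
  distributions (above).
* Pedigree-based segregation filtering, covariate-adjusted burden
  regression and kinship/ancestry adjustment are out of scope; segregation
  arrives as an upstream boolean.
* Upstream residualization (batch correction, covariate regression) and
  co-expression network construction are assumed done; the package ingests
  their matrices.
* The embedding is plumbing around an external UMAP implementation; only
  seed-level determinism is guaranteed.
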