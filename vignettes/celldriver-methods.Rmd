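---
title: "Scoring critical cell types and candidate driver genes from bulk organoid RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring critical cell types and candidate driver genes from bulk organoid RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldriver)
```

## The problem

Bulk RNA-seq of donor-derived organoids averages expression over a mixture of
cell types. When comparing case donors (for example, carriers of a
copy-number variant such as a 16p11.2 deletion or a 15q11–13 duplication)
against control donors, two questions arise that the bulk signal alone does
not answer: *which cell types* carry the perturbation, and *which genes in
the locus* drive it. `celldriver` answers both with enrichment statistics
built on top of per-gene differential expression, using externally derived
single-cell cluster gene lists and a reference co-expression compendium as
side information.

## Quality control

The QC funnel is fixed in order and each step is a separate function:

1. **Representative transcripts** (`select_representative_transcripts`):
   one transcript per gene, the one with the highest mean FPKM across *all*
   samples; ties go to the lexicographically smallest transcript id.
2. **Expression filter** (`filter_expressed`): genes with mean FPKM across
   all samples strictly below 2 are removed; a gene exactly at the
   threshold is kept.
3. **Variability filter** (`flag_variable_genes`): computed on *control
   samples only*, so that genuine case signal is never discarded as noise.
   Per gene we take the maximum across control donors of the SD over that
   donor's replicates (intra-individual) and the SD across control-donor
   means (inter-individual). Each statistic is z-scored across genes and
   flagged above z = 2 (intra) or z = 1.5 (inter). The z-score reading
   makes "more than k standard deviations of variability" a population-level
   cutoff; both cutoffs are exposed in `analysis_config()`.
4. **Inverse normal transform** (`inverse_normal_transform`): per gene,
   values become standard-normal quantiles of Blom fractional ranks,
   `qnorm((rank - 3/8)/(n + 1/4))`, with ties averaged. Blom's offset is the
   standard convention for rank-based inverse normal scores. A constant row
   maps to zeros. Note that rows containing ties do not center exactly at
   zero (averaged ranks pass through a nonlinear quantile map); tie-free
   rows do.

Fold changes are always computed on the *pre-normalization* FPKM scale
(`compute_fold_changes`), because copy-number dosage should read out
directly: a hemizygous deletion is expected near 0.5 and a duplication near
1.5, which is impossible on rank-normalized values.

## Differential expression

`fit_differential_expression` runs per-gene ordinary least squares of
normalized expression on the case/control indicator, treating every
replicate as an independent sample, with the first principal component of
the expression matrix as the default covariate. In cohorts of this kind a
single dominant component carries most of the expression variance and acts
as a surrogate for sample-level technical covariates; including it removes
that axis without modeling each covariate separately. Two-sided p-values
come from the group coefficient's t statistic; genes with zero residual
variance get p = 1 (rather than being dropped) so that gene universes stay
aligned across stages. Benjamini–Hochberg adjustment is delegated to
`stats::p.adjust`.

## CellScore: which cell types are perturbed

Each single-cell cluster contributes a gene list. Genes appearing in exactly
one cluster are *cell-type-specific*; genes shared by two or more clusters
are *non-specific* (`partition_cluster_genes`). The cluster score is

> CellScore = mean of −log10 p over the cluster's specific genes −
> mean of −log10 p over its non-specific genes,

with denominators counting only genes present in the differential-expression
table. Subtracting the non-specific mean cancels signal common to many cell
types (library effects, global inflation), leaving the cell-type-specific
excess.

Significance comes from a **pseudo-case permutation null**: each permutation
draws `n_case` pseudo-cases uniformly *from the actual control samples
only*; all real cases plus the remaining controls form the pseudo-controls.
The per-gene regressions are refit for each permutation (the PC1 covariate
is computed once from the observed matrix, since relabelling does not change
the expression values) and the cluster score is recomputed. All clusters
share the same label draws, so their p-values are comparable. The empirical
p-value is the one-sided exceedance proportion `#{null >= observed}/N`; when
no null score reaches the observation, the p-value is reported as the bound
`< 1/N`. When `choose(n_control, n_case)` does not exceed the requested
permutation count, the null switches to exhaustive enumeration.
Family-wise control across clusters is Bonferroni: 10 clusters at level 0.05
give a per-cluster threshold of 0.005.

Two cohorts measuring the same contrast (say, organoids and post-mortem
tissue) are combined by `combine_dataset_pvalues`: a weighted average of the
two −log10 p-values with weights proportional to the absolute cluster
scores. Both the −log10 value and its back-transform are returned, labeled,
since either scale may be wanted downstream.

### Calibration of the empirical p-values

A property worth stating plainly: these empirical p-values are *valid but
conservative*, not exactly uniform under the null. Because the real case
samples are excluded from the pseudo-case pool, every null score shares with
the observed score whatever structure sits in the fixed case block; across
exchangeable synthetic cohorts the observed score and the null mean
correlate strongly, which pushes empirical p-values away from both tails
(the fraction below 0.05 is well under 0.05). This is a property of the
sampling scheme itself — we verified it is unchanged by removing the PC1
covariate, deepening the permutations, or enlarging the cohort, and a
minimal re-implementation of the scheme on a plain t statistic deviates from
uniformity as well. Conservatism means reported discoveries are not
inflated; it also means the scheme loses some power relative to an exactly
calibrated null. The test suite asserts validity (mean p near 0.5, lower
tail at most nominal) and additionally records the strict
uniformity check, which this scheme cannot meet.

### Fine-mapping cluster identities

`pairwise_overlap_matrix` computes directional percentage overlaps
(entry (A, B) is the share of A's genes found in B — the denominator is the
first set's size, and "mean overlap" averages the two directions; the
convention is exposed rather than hidden because no single convention is
canonical). `deduplicate_clusters` joins clusters when either direction
reaches 50% and returns connected components, collapsing redundant clusters
from multi-protocol studies into unique groups. `atlas_overlap_profile` and
`profile_correlation` then fingerprint each cluster against a reference
cell-type atlas and correlate fingerprints between cluster systems.

## GeneScore: which locus genes drive the signal

For each locus gene *x*, `compute_connectivity` computes the squared Pearson
correlation of *x*'s profile with every gene in a large reference
compendium (self-correlations excluded; zero-variance genes dropped from the
denominator). The score is

> GeneScore(x) = (1 / log10 λ) · Σ_y (−log10 p_y · r²_{x,y}) / Num_y,

a connectivity-weighted average of differential-expression evidence over
reference genes, optionally restricted to one cluster's specific plus
non-specific genes for a cell-type-specific score. λ is the genomic-control
inflation factor of *that run's* full p-value vector (p-values mapped to
1-df chi-square statistics; λ is the ratio of the observed to expected
median). Each permutation run is normalized by its own λ because every
relabelling yields a different overall inflation; dividing by log10 λ puts
runs on a common scale. Permutation p-values reuse the pseudo-case scheme.

Two guarded edges deserve mention. First, when λ ≤ 1 the prefactor is
undefined or negative, and a negative prefactor would invert the ranking;
the implementation returns the unnormalized score with `normalized = FALSE`
and a warning instead. Second, λ-normalization is only stable when runs are
genuinely inflated (λ meaningfully above 1), which is the regime this
statistic is designed for: cohorts with replicate structure analyzed by OLS
that treats replicates as independent are inflated in every run. `Num_y`
counts the genes actually entering each sum (reference genes with a defined
correlation that appear in the run's differential-expression table, and in
the scope subset if one is given).

False-discovery control for the cell-type-specific scores is
percentile-based (`percentile_fdr_thresholds`): the p-values pooled across
all clusters of a locus are sorted and the 5th / 10th percentile values
(nearest-rank, rounding down; undefined when fewer than `100/percentile`
values are pooled) become the FDR 0.05 / 0.1 thresholds.

## Overlap enrichment and power

`overlap_enrichment` compares replication rates between two companion model
systems as a 2×2 table: the point estimate is the sample cross-product odds
ratio, with Fisher's exact test providing the confidence interval and
p-value (a Woolf log-normal interval is the recorded fallback if the exact
network algorithm fails). `simulate_setd_power` estimates the power of a
two-group comparison at a Bonferroni family-wise threshold over a grid of
base means and fold changes, drawing Normal(mean, sd) values and testing
with the pipeline's OLS group test without covariates (simulated data carry
no principal-component structure, so this is an equal-variance t test).
Negative draws are kept: truncation would silently change the sampling
model. The default Bonferroni denominator is 9978, a typical post-QC gene
universe for this assay, and is a parameter.

## The synthetic cohort generator

`generate_cohort` draws log2 expression as gene baseline + per-(gene, donor)
random effect + replicate noise + a global sample factor, exponentiated to
the FPKM scale. The pieces map onto the features of real organoid cohorts
that the pipeline must cope with:

- **Donor effects** (SD 0.35 log2 units) make replicates of a donor more
  alike than samples of different donors — the intra- over inter-individual
  concordance that replicate QC measures — and, because the per-gene tests
  treat replicates as independent, they produce the genuine test-statistic
  inflation (λ > 1) that genomic-control normalization absorbs.
- **The global factor** (per-sample score, SD 0.5; per-gene loadings around
  1) creates a dominant principal component carrying roughly half the
  expression variance, emulating the single technical axis real cohorts
  show; without it, a planted perturbation would itself become PC1 and be
  regressed away, which is not how these data behave.
- **Dosage** multiplies locus genes by a fold change in case donors only
  (0.5 for deletions, 1.5 for duplications); because the model is
  multiplicative, arithmetic-mean fold changes recover the planted dosage.
- **Cluster perturbations** add a log2 shift to designated genes in case
  samples, emulating a perturbed cell-type program.

Default cohort shape is 13 case and 12 control donors with 1–3 replicates
each. `generate_cluster_sets` plants an exactly known specific/shared
partition (specific genes per cluster drawn from 47–266, shared from 12–49,
mirroring curated organoid cluster lists); any shared-pool gene drawn by
only one cluster is promoted into a second, so "shared" is true by
construction. `generate_reference_compendium` builds block-exchangeable
correlation (single-factor construction, within-block correlation ρ ∈ [0,1))
so a planted driver gene can sit in a block overlapping a perturbed
cluster's genes.

What the generator does **not** emulate: count noise (values are log-normal,
not negative binomial), varying library sizes, batch structure beyond one
global factor, correlated gene-gene structure in the cohort itself, or
realistic single-cell composition shifts. Passing tests therefore
demonstrate the statistical machinery on data with the right first- and
second-order structure, not performance on any particular real dataset.

## Numerical choices and problem sizes

- One-sided tests (large score = perturbation) by default.
- Empirical p uses the raw exceedance proportion with an explicit `< 1/N`
  floor rather than the (k+1)/(N+1) convention, so a result beyond the
  null's resolution is reported as a bound, never as an exact value.
- Enumeration replaces sampling automatically when the design allows.
- Gene symbols are matched verbatim and case-sensitively; no alias
  resolution.
- The test suite exercises the permutation machinery at reduced but
  representative sizes — cohorts of 12–30 samples, 150–400 genes, 200–1000
  permutations, 50 generator seeds for recovery properties — chosen so the
  suite completes in minutes while keeping every statistical check
  meaningful at its stated tolerance.

## Limitations

Cluster gene lists are inputs; the package does not cluster single-cell
data. Deconvolution of cell-type proportions is out of scope. The empirical
p-values are conservative (see the calibration note above), and the
λ-normalized driver score is unstable when applied to cohorts without
genuine inflation. Replicates are modeled as independent samples by design,
matching the analysis the statistics were built around, not as a general
recommendation for clustered designs.
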