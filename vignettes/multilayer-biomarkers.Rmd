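---
title: "Multi-layer microbiome biomarker discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-layer microbiome biomarker discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdmicro)
```

## The problem

Graves' disease (GD) is an organ-specific autoimmune disorder whose gut
microbiome carries compositional and genetic signatures of disease state.
`gdmicro` implements the downstream statistics of a three-group cohort
design — healthy controls, mild patients (GD1) and severe patients (GD2) —
in which shotgun metagenomes are summarised into four feature layers
(species relative abundances, metagenome-assembled-genome (MAG)
abundances, gene-family abundances, and per-species SNP frequencies),
alongside predicted metabolite profiles and clinical indexes. The package
covers: per-layer differential testing, a monotonic-trend filter for SNP
markers, gene-consensus MAG taxonomy, compositional statistics and
ordination, association tests between data layers, a combined-layer
random-forest marker search, and cross-cohort specificity screens of a
marker panel.

Raw sequence processing (assembly, binning, annotation, SNP calling) is
out of scope: the package consumes the tabular products of those
pipelines. A synthetic cohort generator emulates exactly those products,
with planted ground truth, so every stage is testable end to end.

## Statistical building blocks

**Rank-sum testing.** All differential calls use the two-tailed
Wilcoxon/Mann-Whitney rank-sum test with midranks for ties. The p-value
is exact (from the null rank-sum distribution) when the pooled sample
size is at most 12 and no ties are present, and otherwise uses the normal
approximation with tie correction and continuity correction. A
comparison whose tie-corrected variance is zero (all values identical) is
assigned p = 1: such data carry no evidence either way, and the
convention avoids a 0/0. Selection criteria operate on raw p-values —
matching how rank-sum screens of this design are usually reported —
while Benjamini–Hochberg q-values are always computed alongside for
transparency.

**The monotonic-trend SNP filter.** A SNP locus is called a marker iff
(i) the healthy-vs-severe and mild-vs-severe comparisons both reach
p < α (strictly; default α = 0.05) and (ii) the three group mean
frequencies are strictly ordered, healthy > mild > severe or healthy <
mild < severe. Ties between two group means reject the locus, mirroring
the strict inequalities of the rule. The healthy-vs-mild p-value is
computed and reported but deliberately not part of the criterion. The
conjunction of two tests plus an ordering constraint makes the null
false-selection rate far below α (about 0.5% empirically at α = 0.05),
which the acceptance suite verifies on 2000 null loci.

**Gene-consensus MAG taxonomy.** Each gene of a MAG is assigned to the
genome of its best alignment hit among hits with percent identity ≥ 95
and query coverage ≥ 90 (coverage = alignment length / gene length × 100,
capped at 100). "At a threshold of" is read as boundary-passing, so both
cutoffs are inclusive. Hits are ranked by identity, then coverage, then
lexicographic genome ID — a total order, so results are invariant to hit
order. A MAG is assigned iff strictly more than 80% of **all** its genes
(including genes with no qualifying hit, which is why the caller needs
the per-MAG gene totals) agree on one genome; exactly 80% is unassigned.
Two genomes cannot each exceed 80%, so the rule is unambiguous; exact
splits below the threshold are simply unassigned.

**Compositional statistics.** Abundance layers are compositions; they
are analysed after a centered log-ratio (CLR) transform. Zeros are
replaced multiplicatively: each zero becomes δ = half the smallest
non-zero relative abundance in the table (scale-aware, configurable) and
the non-zero parts are shrunk so the row still closes to 1. The
Aitchison distance is the Euclidean distance between CLR rows, PCoA is
the eigendecomposition of the Gower-centered squared-distance matrix
(negative eigenvalues are reported untouched and excluded from the
proportion-explained denominator rather than "corrected" away), the
Mantel statistic is the Pearson correlation of upper-triangle distance
vectors with a joint row/column permutation null, and PERMANOVA is
one-way (disease status), delegated to `vegan::adonis2` and checked in
the tests against the direct sum-of-squares decomposition. Both
permutation tests use the (1+B)/(1+N) p-value estimator, so p is never
exactly zero.

**The classifier.** The four fused layers are species, MAG and gene CLR
values plus SNP presence/absence (frequency > 0 → 1); the trend filter
works on frequencies while the classifier uses presence patterns — both
representations are kept. Random forests use `ranger` with default
hyperparameters except `num.trees = 5000`, single-threaded for exact
reproducibility, with impurity (Gini) importance by default and
permutation importance as an option. AUC is computed rank-based
(Mann–Whitney concordance with midranks), and three-class performance is
macro-averaged one-vs-rest AUC from class probabilities.

## The feature-count sweep and selection bias

The marker search refits the forest on the top-*n* features for
*n* ∈ {2, 4, 8, 16, 32, 64, 128, 256}, scoring each *n* by stratified
fivefold cross-validation and by a stratified 50–50 train/test split; the
chosen *n* maximises the pooled out-of-fold CV AUC, with ties broken to
the smallest *n*.

One design decision deserves emphasis: features are **re-ranked inside
every cross-validation training fold** (and inside the training half of
the 50–50 split). Ranking once on the full data and then
cross-validating the top-*n* subsets leaks the test folds into the
selection step; with hundreds of candidate features this classic
selection bias can push the null CV AUC of a label-permuted data set well
above 0.5. Nested re-ranking keeps permuted-label AUCs centred at 0.5 —
a property the acceptance suite checks — at the cost of five extra
forest fits per sweep. The full-data ranking is still computed, and is
what the reported marker set is drawn from, since that is how a final
marker panel would be published. Both the pooled out-of-fold AUC and the
per-fold mean ± sd are reported; the 50–50 holdout AUC is reported
per *n* as well, so readers can compare the two validation styles.

Folds are stratified by class. With a smallest class of 36 samples,
unstratified fivefold CV can produce folds nearly empty of one class;
stratification costs nothing and stabilises the per-fold AUCs.

## What the synthetic generator emulates

`generate_cohort()` produces every input table from a single integer
seed (sub-stream seeds are derived per layer, so layers are
independently reproducible):

* **Abundance layers** (species / MAG / gene): log-normal latent
  abundances — a feature-specific base drawn from N(0, 2²) gives a
  realistic rank-abundance spread, with per-sample variation of
  σ = 1 (configurable) — multiplied by planted per-group fold effects,
  then multinomially resampled at a sequencing-depth proxy (default 10⁵)
  and closed to relative abundances. The resampling produces the zeros
  that exercise the pseudocount machinery.
* **Metabolite layer**: a fixed non-negative random linear map of the
  gene layer plus multiplicative log-normal noise (sd 0.25), closed to 1.
  This stands in for the output table of a trained metabolite-prediction
  model and preserves the gene-metabolite coupling that the Mantel
  analysis relies on.
* **SNP layer**: zero-inflated Beta frequencies. A locus with target
  group mean *m* is detected with probability √*m*; detected
  frequencies follow Beta(κ√*m*, κ(1−√*m*)) with concentration κ = 20,
  so the marginal mean is exactly *m*. The zero inflation matters: the
  classifier consumes presence/absence, and a model in which every locus
  is always present would make binary SNP features constant and
  unlearnable. The √*m* detection link makes both the presence pattern
  and the conditional frequency increase with the planted mean, which is
  how read-depth-limited SNP calling behaves qualitatively.
* **Clinical indexes**: Gaussian with monotone disease shifts (default
  1 sd per severity step) on a named 11-index panel; thyroid and liver
  indexes shift in both patient groups, immune indexes only in severe
  disease, and TSH shifts downward (suppressed in hyperthyroidism).
  Demographics carry no group effect.
* **Gene-hit tables**: BLAST-tabular fixtures with a configurable
  fraction of genes hitting the true genome above both thresholds, plus
  decoy and sub-threshold hits at stated rates.

Default group sizes are 62 / 36 / 64 (healthy / mild / severe; 162
subjects). The default planted truth is 32 markers — 8 per fused layer,
half increasing and half decreasing, with severe-group fold 4 (mild at
the geometric midpoint 2) for abundances and group mean frequencies
(0.2, 0.45, 0.7) for SNPs.

What the generator does **not** emulate: phylogenetic correlation among
features, compositional interactions beyond closure, batch effects,
overdispersed (non-log-normal) count noise, linkage between SNP loci,
and cohort-level confounding. Passing tests therefore demonstrate that
the algorithms recover the structure they claim to recover under a
clean, known generative model — not that any particular real data set
contains such structure.

## Numerical choices and degenerate inputs

* Write → parse → write of every TSV is byte-identical (`%.12g`
  formatting, which is idempotent at this precision).
* All-zero samples are an error for CLR; all-zero *pairs* in
  Bray–Curtis are defined as distance 0 with a warning.
* Constant features are skipped (with a warning) in the Spearman
  network, since rank correlation is undefined for them.
* A single-group PERMANOVA returns R² = 0, p = 1 rather than erroring,
  so screens over metadata columns degrade gracefully.
* Random-forest runs are single-threaded with explicit seeds; the whole
  pipeline, including the command-line interface, is byte-reproducible,
  and provenance records deliberately contain no wall-clock fields.

## Problem sizes used in the test and acceptance runs

The shipped acceptance checks run the full study design: the 162-sample
default cohort with 440 fused features and 5000-tree forests for the
marker sweep; 2000 null and 200 planted loci at 30 samples per group for
trend-filter calibration and power; 1000 random instances against the
brute-force consensus oracle; and an 8 × 50-sample cohort panel for the
specificity screen. Unit tests use smaller cohorts and forests; the
kernels they exercise are size-independent.

## Known limitations

* The monotonic-trend rule is the published selection heuristic, not an
  ordered-alternative test (e.g. Jonckheere–Terpstra); its operating
  characteristics are documented empirically by the calibration tests.
* PERMANOVA is one-way; marginal multi-variable variance partitioning is
  not implemented.
* The per-layer quota of a published combined panel (how many species /
  MAGs / genes / SNPs end up in a fixed-size marker set) emerges from the
  importance ranking alone; no quota mechanism is provided.
* Cross-cohort harmonisation is namespace intersection with zero-fill
  and per-cohort CLR; no batch correction is attempted, by design.

## A worked example

```{r example, eval = FALSE}
library(gdmicro)

bundle <- generate_cohort(cohort_config(seed = 1))

# SNP markers with a monotone severity trend
markers <- monotonic_trend_filter(bundle$snps, bundle$metadata)

# combined-layer marker search on the healthy-vs-severe task
fused <- fuse_layers(bundle$tables[c("species", "mag", "gene")], bundle$snps)
grp <- bundle$metadata$group
keep <- grp %in% c("Healthy", "GD2")
report <- sweep_feature_counts(fused[keep, ], grp[keep], seed = 1)
report$chosen_n
```

The same analyses are exposed as a command line
(`inst/scripts/gdmicro.R`): `simulate`, `diff`, `snp-markers`,
`assign-mags`, `ordinate`, `mantel`, `permanova`, `network`, `train`,
`evaluate`, `specificity`, driven by a flat YAML configuration whose
defaults `gdmicro config --defaults` prints.
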