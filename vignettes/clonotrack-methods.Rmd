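---
title: "Tracking antigen-specific TCR clonotypes between single cells and bulk repertoires"
author: "clonotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking antigen-specific TCR clonotypes between single cells and bulk repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrack)
library(dplyr)
```

## The problem

Autoreactive CD4+ T cells recognising islet antigens such as GAD65 exist in
both healthy donors (HD) and people with type 1 diabetes (T1D), so the
interesting question is not whether such cells exist but where their
receptors live in the peripheral immune system. `clonotrack` implements a
tandem analysis for that question: antigen-specific single cells are
identified (activation-induced CD154+CD69+ markers after antigen
stimulation), their TCR beta-chain CDR3 sequences are read out per cell,
and each clonotype is then *tracked back* into deep-sequenced bulk TCRB
repertoires of sorted peripheral subsets from the same and other donors —
true naive (TN), central memory (CM), regulatory (Treg) and stem-cell-like
memory (Tscm) CD4+ cells.

Tracking is done at two resolutions:

* **Nucleotide level** — a bulk clone matches when its CDR3 nucleotide
  sequence is identical to the query. A cross-donor nucleotide match is
  strong evidence of convergent recombination, because the junctional
  machinery rarely produces the same nucleotide sequence twice.
* **Amino-acid level** — all distinct bulk nucleotide sequences translating
  to the query's amino-acid CDR3 form its *convergent set*. Its size is the
  clonotype's **convergence** in that repertoire, and the clonotype
  frequency is the arithmetic mean of the per-nucleotide-variant
  frequencies (the mean, not the sum: each variant is an independent
  rearrangement whose abundance estimates the same amino-acid clonotype).

Per clonotype and subset, the share of searched repertoires containing it
defines **publicity**: extremely public (found in at least 75% of
individuals), public (25–74.9%), private (less than 25%), and ultraprivate
(found only in the donor in which the single cell was sorted — one hit out
of 31 TN or CM repertoires is 3.23% of individuals; with only 16 Treg or
Tscm repertoires the same single hit is 6.25%). The denominator is always
taken from the repertoire set being searched, never hard-coded, so the
subset-specific ultraprivate thresholds arise naturally.

## Matching rules and their edge cases

Matching is CDR3-only: V and J calls are carried as opaque labels and are
not part of clonotype identity during tracking, because the search is
defined on the CDR3 sequence itself. A strict mode (`strict_v = TRUE` in
`track_clonotypes()`) additionally requires V-gene equality for
sensitivity analyses. Within a bulk repertoire, clone records are keyed by
(CDR3 nucleotide, V, J); records sharing a nucleotide sequence under
different V/J annotations have their frequencies summed before matching.
"Found" means at least one read — no abundance threshold is applied.
Duplicate single cells carrying the same clonotype collapse to one query
per source donor before tracking, so all publicity and tracking-rate
statistics are unique-clonotype statistics.

The per-donor **tracking rate** is the percentage of a donor's unique
clonotypes found in at least one repertoire of the whole set, summarised
as unweighted mean ± sample standard deviation across donors. Averaging
per donor (rather than pooling clonotypes) weights each individual
equally; that is the reading implemented here.

**Clonal expansion** is a within-donor notion: two or more cells of one
donor with an identical beta-chain CDR3 nucleotide sequence (and, at the
paired level, an identical alpha chain). An identical sequence in two
donors is publicity, not expansion. The group-size threshold defaults to
2 cells and is exposed (`min_size`); any repeated sequence counts as an
expansion, and stricter thresholds are one argument away.

**Cohort-exclusive sets**: within one subset, a clonotype found in at
least one HD repertoire and no T1D repertoire is HD-only; symmetrically
for T1D-only; clonotypes found in both cohorts or in neither belong to
neither set.

## The expression arm

Single-cell qPCR Ct values (48-gene panel, duplicate wells) become
expression values by the transform used for BioMark-style data: per (cell,
gene) the minimum Ct over available duplicates is taken, missing readings
are set to the detection ceiling of 32 cycles, and Et = 32 − min(Ct, 32),
so Et lives on [0, 32] with 0 meaning undetected and the scale log2-like
(each PCR cycle is a doubling). Cells with zero expression in every gene
are removed. Readings above 40 cycles are physically implausible and are
treated as missing with a warning.

Cells are clustered by scaling genes to zero mean and unit variance,
projecting onto 10 principal components, building a shared-nearest-
neighbour graph (k = 20 neighbours, Jaccard edge weights pruned below
1/15) and running Louvain community detection at resolution 1 with a fixed
seed. The number of PCs (10) and the resolution (1) are the analysis
conditions this package models; the neighbour count and pruning cutoff
are conventional defaults exposed as arguments. Labels are ordered by decreasing cluster size, so the
partition — not the numbering — is the reproducible object.

Marker genes per cluster are found with a two-part **hurdle test** of the
cluster against all other cells: a discrete likelihood-ratio component on
the detection rate (Et > 0; group-wise Bernoulli maximum likelihood, 1 df)
and a continuous component on the expression level among detected cells
(common-variance Gaussian, 1 df), combined by summing the chi-square
deviances (2 df overall; 1 df when one group has no detected cells so the
continuous part cannot be fit). This is a deliberate plain-likelihood
version of the hurdle model; Bayesian shrinkage as in MAST is out of
scope. The average log fold change is the difference of group mean Et
(already a log2-like scale); markers require Bonferroni-adjusted overall
p ≤ 0.05 and |avg logFC| > 0.25. Cohort differences in cluster occupancy
use per-donor cell fractions (summing to 1 per donor) compared by
two-sided Wilcoxon rank-sum tests per cluster, Bonferroni corrected over
clusters; when every fraction ties, the rank test has zero variance and
the result is reported as p = 1 rather than NaN.

Batch correction across qPCR runs is not performed by default: the
simulated data are single-batch, and no specific correction method is
assumed for real multi-run data. This is a known limitation; the
housekeeping gene (SRP14) is carried in the panel so a per-run centering
can be applied upstream if needed.

## Assay scores

The ELISPOT stimulation index is SI = mean(antigen spots) / mean(diluent
spots) over triplicates, positive at SI ≥ 3 (the boundary is inclusive).
Wells with zero mean background would give an infinite SI; instead the
denominator falls back to a pseudocount of 1 and the record carries an
explicit `zero_background` flag, so borderline positives are visible
rather than silent. Index-sort phenotypes are gated post hoc from CD45RO,
CD27 and CD95 against sample-specific cutoffs (CM: RO+27+; EM: RO+27−;
NTEM: RO−27−; TN: RO−27+95−; Tscm: RO−27+95+); positivity means strictly
above the cutoff, so a value exactly at the gate reads negative — a
boundary has to be chosen and ties are measure-zero for real
intensities. AIM frequencies are n(CD154+CD69+)/n(CD4+) per condition
with no background subtraction; conditions are compared directly.

## What the simulator plants, and what it does not emulate

`sim_config()` encodes the emulated study conditions: 17 HD and 14 T1D
donors with TN and CM repertoires, 8 + 8 of them with Treg and Tscm
repertoires (94 repertoires in total), and 12 single-cell donors (5 HD,
7 T1D) carrying 10 unique antigen-specific clonotypes each. Background
clones are random in-frame, stop-free CDR3s of 36–48 nt framed by the
conserved C...F anchors, globally unique by construction with translations
kept disjoint from every planted amino-acid clonotype — so planted sharing
is the *only* sharing and every recovery check can demand exactness.
Clone sizes follow a power law (Pareto exponent 2.5) and counts are drawn
multinomially to an exact depth of 1e5 reads per repertoire.

The plant catalogue seeds, per subset, clonotypes at chosen publicity
levels (e.g. 24/31 TN → 77.4% extremely public; 1/16 Treg → 6.25%
ultraprivate), with chosen convergence realised as verified synonymous
third-position codon variants at equal per-variant counts. Eight
correlation clonotypes are seeded into the *same* five TN repertoires
with convergence i = 1..8 and per-variant count 20·i: because every
repertoire has exactly the same total depth and the variant counts are
equal within a clonotype, the mean amino-acid frequency is exactly
proportional to i, so the planted convergence→frequency relation is
strictly monotone and its Spearman correlation is exactly 1 — a sharp
oracle for the correlation machinery. Exclusive clonotypes are seeded
into single-cohort repertoire sets; ratio clonotypes into both Treg and
CM of their source donor. Expansion groups (default ten, sizes 2–4, four
of them alpha-paired, three confined to one expression cluster) are
emitted as repeated cells. The truth manifest is derived from the
generator's own seeding tables — never from the analysis functions — and
records publicity, convergence, achieved frequencies, exclusivity,
expansion structure and per-donor tracking rates.

What the generator does **not** emulate: V(D)J generation probabilities
(sequences are structurally valid placeholders with no biological
generation model), background convergence and background sharing between
donors (real repertoires share public clonotypes by chance), sequencing
error, and multi-batch qPCR structure. Passing the recovery suite
therefore demonstrates that the statistics are computed correctly, not
that they are robust to the messiness of real repertoires. Cohort-scale
sequencing depth (tens of millions of reads) is represented at a desk
scale of 1e5 reads per repertoire, which preserves every definitional
property while keeping a full run under half a minute.

## Numerical choices

* Publicity category order: extremely public → public → ultraprivate →
  private; boundaries at 25% and 75% are inclusive upwards. A single hit
  outside the source donor is private, not ultraprivate.
* Spearman correlations use the normal approximation (`exact = FALSE`),
  so tied convergence values are handled uniformly; when all convergence
  values coincide the correlation is undefined and reported as `NA`.
* The hurdle continuous component guards the degenerate residual cases:
  zero residual variance under the null gives a zero statistic, zero
  residual variance only under the alternative gives p → 0.
* Louvain runs under a fixed seed; cluster labels are size-ordered, and
  invariance tests compare partitions (Rand index), not label vectors.
* All stage seeds derive from one root seed (root + small offsets), so
  stages are independently re-runnable yet jointly reproducible.

## Problem sizes used in validation

The packaged checks run the default simulation (94 repertoires × 600
background clones, 1e5 reads each, 135 single cells), a brute-force
tracking oracle on 50 queries × 20 repertoires (≤ 1000 clones each), and
a null-calibration study of the hurdle test with 1000 permuted genes at
200 cells, in which the fraction of overall p-values below 0.05 is
expected within 0.05 ± 0.02.
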