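---
title: "Methods: chemical-gene signature enrichment"
author: "chemsig maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-gene signature enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemsig)
```

## The problem

Curated toxicogenomics databases record, chemical by chemical, which genes
respond to an exposure and how many publications support each relation.
Pooled per chemical, these relations form a *chemical signature*: a gene set
with per-gene citation support. Given a two-class expression experiment
(disease vs control, or exposed vs unexposed), asking which signatures are
over-represented among the differentially expressed (DE) genes yields a
ranked list of candidate environmental exposures for that phenotype --
hypothesis generation from existing data, not a substitute for toxicology or
epidemiology.

`chemsig` implements that pipeline end to end: signature construction from
interaction tables, cross-species gene pooling, permutation-based DE
selection, hypergeometric enrichment with resampling q-values, validation
against curated disease-chemical maps, and bioactivity-similarity clustering
of the predictions.

## Signature construction

Interaction records are pooled per chemical after mapping every gene into an
ortholog-group namespace (see below). A gene's support is the number of
*distinct* citation identifiers across all of that chemical-gene pair's
records, summed over organisms, so duplicate table rows never double-count.
Signatures with fewer than `minGenes = 5` genes are discarded: sets of one
or two genes make the hypergeometric test uninformative and dominate curated
databases (the set-size distribution is heavily right-skewed, with a median
near 2). The filter is applied *after* cross-species pooling, so relations
observed only in different organisms can jointly push a chemical over the
threshold; the alternative (filtering per organism first) silently discards
exactly the cross-species evidence the pooling exists to use.

`removeRelationsBySource()` subtracts citation sets and drops relations left
without support. Its purpose is circularity control: when the interaction
database itself cites the expression dataset being queried, those relations
are removed before building the database.

## Cross-species pooling

Genes enter all set arithmetic as ortholog-group ids from a
Homologene-layout table. Symbol matching is case-insensitive (mouse `Cyp1a1`
vs human `CYP1A1`); a gene present in two groups keeps its first assignment,
and the conflict is counted. Genes absent from the table receive a synthetic
singleton group keyed by `(taxon, symbol)` rather than being dropped: they
can still match within-species relations, and the unmapped set is reported
so the loss is visible. Mapping is idempotent -- group ids map to themselves
-- so pipelines may mix pre-mapped and raw gene lists.

## Differential expression

The DE stage is a two-class, unpaired moderated statistic:

$$ d_i = \frac{\bar{x}_{i,\mathrm{case}} - \bar{x}_{i,\mathrm{control}}}
{s_i + s_0}, \qquad
s_i = \sqrt{\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)
\frac{SS_{i,1} + SS_{i,2}}{n_1 + n_2 - 2}} $$

with an exchangeability constant $s_0$ damping genes whose tiny sample
variance would otherwise dominate the rankings. The default $s_0$ is the 5th
percentile (order statistic) of the $s_i$; it is deliberately simple,
recorded in every result, and overridable -- the original
coefficient-of-variation tuning is a possible extension, though on data with
roughly homogeneous variance the choice moves results very little.

Ordered observed statistics $d_{(i)}$ are compared with expected order
statistics $\bar{d}_{(i)}$ averaged over label permutations (complete
enumeration whenever at most 1000 assignments exist -- e.g. all 252 for a
5 vs 5 design -- otherwise seeded Monte-Carlo draws). The first deviation
larger than `delta` on each side of the center fixes asymmetric cutoffs, and
all genes beyond them are called. The *median FDR* is the median over
permutations of the number of permuted statistics beyond the same cutoffs,
divided by the number of called genes, with $\pi_0$ fixed conservatively
at 1. `selectDelta()` scans an increasing grid (40 points spanning the
observed deviations by default) and returns the smallest `delta` whose
median FDR meets the target.

Two FDR targets appear in the package. `selectDelta()` defaults to 0.05;
the pipeline (`predictChemicals()`, `runPipeline()`) defaults to 0.07, the
upper end of the 5-7% band the gene lists are controlled to. On small
two-class designs the DE stage, not the enrichment stage, is the power
bottleneck, so the pipeline prefers the most permissive threshold inside
that band. Precomputed DE lists bypass the stage entirely and are accepted
everywhere downstream.

## Enrichment, universe, and ranking

Each signature is scored with the upper-tail hypergeometric probability of
observing at least $k$ of its $K$ genes in an $n$-gene DE list drawn from an
$N$-gene universe (evaluated through `phyper`, which works in log space).
The universe is the intersection of the platform's genes (group space) with
the union of signature genes, by default: genes that can never overlap any
signature would otherwise inflate $N$ and flatter every p-value. A
`"platform"` policy is available for sensitivity analysis. Signatures are
*not* re-filtered after universe intersection, keeping the tested set count
constant across datasets.

Results are sorted by ascending p with stable ties broken by chemical id,
and labelled with the percentile convention
`floor(100 * (1 - (rank - 1)/total))`, chosen because it reproduces more of
the conventional report-table labels than rounding variants; rank 1 of
1,338 is "100", rank 40 is "97".

## Resampling q-values

Multiplicity over ~1,300 correlated, discrete tests is handled by a
resampling estimate rather than an analytic correction: `B = 100` random
gene draws of the observed DE-list size (without replacement, from the same
universe -- mirroring the sampling model of the test itself) are each scored
against every signature. For an observed p-value $p_c$,

$$ \hat q(p_c) = \frac{\tfrac{1}{B}\,\#\{\text{null } p \le p_c\}}
{\max(1, \#\{\text{observed } p \le p_c\})}, $$

clamped to $[0,1]$ and made monotone non-decreasing in $p$ by a cumulative
minimum from the largest p downward (standard step-up hygiene; the raw
estimator can invert on discrete support). A chemical is a *positive
prediction* when $p \le \alpha$ and $q < 0.1$.

## Disease-chemical validation

To validate a prediction list against curated disease-chemical knowledge,
chemicals with $p \le \alpha$ are selected (the sweep defaults to
$\alpha \in \{10^{-4}, 10^{-3}, 10^{-2}, 0.05\}$) and tested for enrichment
in a disease's curated chemical set with the same hypergeometric machinery,
over the chemical universe of *tested* chemicals -- only they could have
been selected, so the draw model conditions on them (a map-wide universe
switch exists). The false-positive sweep repeats the test for every disease
with at least 5 curated chemicals and counts competitors with *strictly*
lower p than the true disease; ties do not count against, matching the
strict-comparison convention.

## Bioactivity clustering

Where a chemical-by-assay score matrix is available, pairwise similarity is
the Pearson correlation over co-assayed entries, with pairs sharing fewer
than `minShared = 2` assays zeroed and masked; precomputed similarity
matrices are accepted verbatim (server-side bioactivity tools do not
publish their metric, so the package treats similarity as an input in the
primary path). Chemicals are ordered by average-linkage agglomerative
clustering on $1 - $ similarity, and the report table carries
$-\log_{10} p$ per chemical and dataset with absences masked, never zeroed.

## The synthetic-data generator

Every stage is testable without downloads through seeded generators that
emulate the real inputs:

* **Interactions** -- per-chemical set sizes follow a discretized log-normal
  (`meanlog = log 2`, `sdlog = 1.747`) calibrated so the median, 70th and
  75th percentiles land at 2, 5 and 7 genes, reproducing the heavy right
  tail of curated databases; about 30% of chemicals survive the 5-gene
  filter. Citation counts are `1 + Geometric(0.35)` -- cosmetic, but they
  exercise the report columns.
* **Homology** -- one group per pool gene with members in human, mouse and
  rat, using the field's symbol-casing conventions.
* **Expression** -- background `Normal(0, noiseSd)` in both classes; a fixed
  fraction (default 0.75) of a planted chemical's signature genes is shifted
  by `effect` (default `2 * noiseSd`) in cases. The default study shape is
  1,338 signatures over a 5,000-gene pool (the platform covers the pool),
  5 vs 5 samples, and a 20-gene planted signature.
* **Disease map** -- 141 diseases, all meeting the 5-chemical eligibility
  floor, with the planted disease's curated set containing the planted
  chemical plus decoys.

A scenario's manifest records every parameter and the seed; regeneration is
bit-identical. What the generator does *not* emulate: expression covariance
between genes, batch effects, heteroscedastic platform noise, dose-response
structure, and the literature biases of curated databases (well-studied
genes appear in many signatures). Passing tests therefore demonstrate the
statistical machinery, not performance on any real dataset.

## Power at the default conditions

One property of the default scenario deserves emphasis. A 2-sigma shift
with 5 samples per class gives a per-gene noncentrality of
$2/\sqrt{2/5} \approx 3.2$; among ~5,000 null genes, a handful always
exceed the typical spiked statistic, so *any* FDR-controlled selector at
5-7% recovers only a few of the 15 shifted genes. The planted chemical
still usually tops the ranking -- enrichment aggregates over the signature
-- but exact q = 0 (which requires the observed p to undercut every one of
the $B \times 1338$ resampled p-values) is not a near-certain event at
these sample sizes. Recovery becomes essentially deterministic with either
a stronger effect (3 sigma), more samples, or a precomputed DE list, and
the test suite uses those regimes where it needs determinism.

## Numerical and design notes

* Hypergeometric tails come from `phyper` (log-space); bounds are validated
  and violations name the offending argument; $k = 0$ returns exactly 1.
* All randomness (permutations, resamples, generators) flows through a
  single seed argument per entry point; seeded runs are byte-reproducible,
  and the temporary RNG state never leaks into the caller's session.
* Ties in p rank by chemical id; ties in the disease sweep never count as
  false positives.
* `floor(fraction * |signature|)` genes are shifted, so `fraction = 0.75`
  of 20 genes is exactly 15.
* Degenerate inputs: empty interaction tables and empty DE lists produce
  warnings or instructive errors rather than silent empties; zero variance
  with $s_0 = 0$ is an error instructing a nonzero $s_0$.
* Problem sizes in the test suite: statistical properties run at the
  default study shape (1,338 signatures, 5,000 genes) with tens to a
  hundred seeded replicates; structural and IO tests use 120-200 signature
  scenarios over 500-700 gene pools.

## Limitations

Direction of expression change is parsed but ignored throughout (curated
directions conflict often enough that sign-aware signatures lose
sensitivity); consequently the method cannot say whether a predicted
chemical would raise or suppress the observed profile. Paired and
time-course designs are out of scope for the DE stage -- supply a
precomputed DE list instead. The disease validation inherits the biases of
its curated map, and closely related diseases (other neoplasms, for a
cancer query) surface as apparent false positives.
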