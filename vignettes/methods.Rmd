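---
title: "Methods: quantifying GWAS/EWAS overlap and what it implies about trait architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying GWAS/EWAS overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epioverlap)
```

## The model

A trait's genetic and epigenetic signal is summarised by two gene pools.
*Causal genes* influence the trait; GWAS associations, being anchored in
germline variation, are taken to tag them. *Associated genes* correlate
with the trait through any mechanism — causation, confounding, or the trait
altering methylation — and EWAS associations tag them. The scientific
question is the size of, and overlap between, these pools. Everything in
this package is a way of interrogating that overlap from summary
statistics: sites passing the study thresholds are reduced to gene lists,
gene lists to overlap statistics, and the statistics are calibrated against
resampling nulls or interpreted through simulation.

Assumptions worth keeping in view: (i) nearest-gene assignment is treated
as correct, although a site may act on a distal gene; (ii) sites are
treated as exchangeable within a study — no weighting by effect size or
allele frequency; (iii) the z-test against a resampled null assumes the
null distribution of the statistic is roughly normal; and (iv) the
simulations operate at gene level — a study "detects" genes, and site-level
data exist only to exercise the mapping machinery.

## Coordinates, mapping and regions

All coordinates are 0-based half-open internally; 1-based gene tables are
converted on read (`read_genome(..., one_based = TRUE)`). A site inside one
or more gene bodies maps to *all* of them; otherwise to the gene(s) at
minimum distance to the nearer gene edge, with equidistant ties mapping to
all tied genes. Ties-to-all is the deterministic completion of the
many-to-many stance for contained sites; distance-to-edge (zero inside) is
the standard convention. Strand is ignored throughout. Mapping never
crosses a chromosome; a site on a gene-free chromosome is counted as
unmapped and reported.

The region analysis tiles each chromosome into `region_width` blocks
(default 500 kb, the scale at which methylation and genetic signals can
plausibly share a locus), drops blocks without a measured probe (an EWAS
cannot identify a region its array does not cover), and classifies each
remaining block as neither / GWAS-only / EWAS-only / both at a lenient
threshold: `min(1e-5, max reported EWAS p)`. The resolved threshold is
logged per trait.

## Overlap statistics

The gene-overlap odds ratio is the cross-product `(a*d)/(b*c)` of the 2×2
table of the two gene lists over the declared universe, with `OR = 0`
whenever the intersection is empty and `OR = +Inf` when a complement cell
is empty; no continuity correction is applied, so empty intersections
report exactly 0. The p-value is the conventional two-sided exact test
(minimum-likelihood tail); the conditional-MLE odds ratio is recorded
alongside for comparison, since the cross-product and the exact-test
estimate can differ noticeably in small tables.

Enrichment profiles use the same 2×2 construction per geneset. Zero scores
(geneset shares no hit gene) and infinite scores are preserved — no
pseudo-count by default, because the downstream comparison is Spearman's
rank correlation, where a monotone transform changes nothing:
`enrichment_correlation` therefore ranks raw scores (equal to ranks of log
scores) with average ranks for ties. A Haldane–Anscombe 0.5 option exists
(`enrichment_profile(..., pseudo_count = 0.5)`) for users who want finite
scores. Profiles with fewer than three genesets or zero rank variance are
errors, not NA results.

The gene universe for all 2×2 tables is explicit and configurable
(`run_config(universe_mode = )`): all genes in the loaded annotation by
default, or protein-coding only. Reported odds ratios scale with the
universe size (through the `d` cell), so results are only comparable at a
fixed universe — one reason this choice is surfaced rather than buried.

## Resampling nulls

Both nulls recompute the *entire* observed pipeline — positions to genes to
statistics — per replicate. Random positions are uniform over the
concatenated genome (length-weighted per chromosome). The shifted null
advances every observed DMP by `max(G) × I` for iteration `I`, where
`max(G)` is the maximum gene length in the loaded annotation — the only
reading that gives a single fixed shift per iteration — wrapping from the
last chromosome to the first; it preserves the multiset of inter-site gaps
exactly (asserted in the tests), and thereby the local correlation
structure of the observed sites. Shifts of a genome length or more are
reduced modulo the total length with a note. A replicate whose statistic
cannot be evaluated (e.g. no resampled gene lands in the annotation
universe) contributes NA and is excluded from the null's moments, with the
dropped count recorded; a degenerate null (zero variance) makes the z-test
an error rather than a silent 0 or 1.

The "expected" overlap reported in the summary tables is the null mean, and
`p_diff` is the two-sided z-test of observed versus that null. On the
synthetic data the two null schemes give overlapping 95% intervals for
every statistic (stage 3 of the analysis and the acceptance suite), so
preserving the correlation structure does not change expected overlap —
the random-position null is an adequate default.

## The synthetic-data generator

The generator is first-class, tested code: it is the ground truth against
which every downstream claim is checked. It emulates (a) a genome layout of
equal chromosomes; (b) non-overlapping gene bodies, placed uniformly by
stick-breaking (overlap-free placement makes exact-recovery tests
assertable as equalities; infeasible packing is an error); (c) a geneset
annotation with a configurable broad/narrow split — by default 30–50% of
sets exceed 100 members, echoing the breadth of curated functional terms —
and log-uniform sizes in between; (d) a trait architecture with exact
causal/associated overlap (`round(p × n_associated)` genes); and (e)
site-level summary statistics: each signal gene carries `n_sites_per_gene`
sites in its body, is detected with probability `power` (its lead site's
p-value then drawn log-uniformly between 1e-30 and the study threshold —
the spread exercises sorting and formatting paths), and background sites at
`panel_density` per Mb (default 10) carry Uniform(0,1] p-values, emulating
a sparse probe panel without modelling probe chemistry. Effects are the
signed z-scores implied by the p-values. About a third of genes are
labelled protein-coding, roughly the share in human annotation.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium and co-methylation
between sites (no correlation structure within a study's sites), distal
regulation (signal sites always lie inside their gene), unequal chromosome
lengths, population structure, and any distinction between confounded and
reverse-causal associated genes (both pools' members behave identically; a
label field is reserved).

## Power simulation

Study sample size is operationalised purely as the number of genes a study
detects: "EWAS power" is the fraction of the associated pool the EWAS
captures. The default grid crosses detected-gene counts {50, 100, 500},
power {0.2, 0.5, 1} and causal proportions {0, 0.05, 1}, over disjoint
default pools of 1000 causal and 1000 associated genes in a 20,000-gene
universe (scaled to 4000 genes with 800–1000-gene pools in the shipped
analyses and tests; the AUC ordering is insensitive to this scaling). Every
non-null cell is scored against its matched causal-proportion-zero twin by
the AUC of the metric across 2×reps replicates, with a DeLong 95% CI. The
replicate engine is a batched sparse matrix product over all replicates of
a scenario; it is tested for exact agreement with the one-replicate-at-a-
time API.

## Architecture simulation

Given known gene lists KGG and KEG (N~KTG~ = N~KGG~ + N~KEG~), each grid
scenario builds causal and associated pools of size N~KTG~ × multiplier
containing the known lists, padded with novel genes drawn outside them. The
pools' overlap interpolates linearly between the two quoted endpoints: at
proportion 0 the only overlap is the known one (KGG ∩ KEG); at 1 the
maximum feasible extra overlap `min(S − |KGG|, S − |KEG|)` is added, which
(when |KGG| ≤ |KEG|) makes the associated-only genes exactly the known EWAS
genes not found by GWAS; with |KGG| > |KEG| the symmetric condition holds
for the causal side. Infeasible cells (pool smaller than a known list, or
more novel genes than the universe holds) fail loudly: they are reported
with their error and excluded from the FDR adjustment, never silently
dropped. Each scenario is scored by a two-sided z-test of the observed
enrichment correlation against its simulated distribution,
Benjamini–Hochberg-adjusted across the grid (and across traits when traits
are pooled).

A caution established during validation: with very small known lists
(around 8 genes per study) the simulated correlation distribution is
coarse and skewed enough that the z-test over-rejects the true scenario
(roughly 10% at a nominal 5%). Calibration is good from about 20 known
genes per study upward, which covers the realistic range; for smaller lists
an empirical (rank-based) p-value against the simulated draws would be the
appropriate refinement.

## Cross-study comparison

Pairwise Spearman correlations between many studies' enrichment profiles
form a symmetric matrix; each pair is then tested one-sided against the
grand mean of all pairwise correlations, scaled by their empirical standard
deviation, with BH-FDR across pairs. The variance choice (pooled empirical
SD rather than a per-group SD) is deliberate and recorded in the output
metadata; it makes the test conservative when genuine within-group signal
inflates the spread.

## Numerical choices and reproducibility

One master seed governs everything; each stochastic stage derives an
independent child stream from `(seed, stage, scenario, iteration)`
(`child_seed`), so a single replicate can be replayed in isolation — the
test suite replays null replicates by hand to assert this. Pipeline runs
are byte-identical under a fixed seed. Default simulation sizes in the
shipped analyses: 500 resampling replicates per null, 300–500 replicates
per simulation scenario, 20 seed replicates for trend assertions, 100–200
replicate traits for calibration checks; criteria that are exact
arithmetic (draw composition, pool-size ratios, tiling) are asserted
exactly at full size.

## Known limitations

Nearest-gene assignment, the absence of within-study site correlation, and
the normality assumption of the z-test are the three places where this
implementation's answers could diverge from an analysis with richer data.
The enrichment correlation also varies remarkably little across candidate
architectures (visible in stage 5 of the analysis): many architectures are
compatible with one observed correlation, so the architecture grid should
be read as excluding corners of parameter space, not as estimating a
point.
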