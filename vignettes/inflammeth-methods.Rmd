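---
title: "Methods: paired somatic variant and bisulfite methylome analysis"
author: "inflammeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired somatic variant and bisulfite methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis this package implements

The package models a paired-tissue inflammation study. On the genetic
side, the mucosa and the muscularis mucosae of the same animal are
exome-sequenced; because both tissues share the animal's germline, any
variant present in both is treated as germline and removed, leaving the
mucosa-specific somatic set. On the epigenetic side, whole-genome
bisulfite sequencing of an inflamed and a control methylome is compared
per cytosine context (CG, CHG, CHH) and summarized into differentially
methylated regions (DMRs), which are then mapped to gene zones and tested
for pathway over-representation. Every stage is exercised against a
synthetic scenario with planted ground truth, so the statistical behaviour
of the chain is verifiable.

# Methylome model

## Site calling

A cytosine with `m` methylated of `n` total reads is called methylated
when `m` is incompatible with pure bisulfite non-conversion error `e`:

$$p = P(X \ge m), \quad X \sim \mathrm{Binomial}(n, e)$$

with Benjamini–Hochberg control across all tested sites at
`alpha = 0.05`. Sites with coverage below 4 are never tested. The
non-conversion rate defaults to `e = 0.005`; conversion efficiency is
instrument- and kit-dependent and is deliberately a parameter, not a
constant. Non-conversion is modelled only as false methylation on
unmethylated cytosines — the dominant artifact in real bisulfite data;
the converse error (failure to read true methylation) is not modelled.

## Summaries

mC-type ratios count called sites per context (site counts, not reads and
not strand-merged CpGs; a symmetric-merge variant was considered and
rejected because the totals being emulated are strand-unaware). Chromosome
densities tile half-open fixed windows left to right. The 9-bp context
matrix takes reference flanks at offsets −4..+4, reverse-complemented for
minus-strand sites so the center column is always C; sites within 4 bp of
a chromosome end are skipped and counted.

## Metagene profiles

Gene flanks of 2 kb are binned at 100 bp (20 bins per side) and gene
bodies into 20 equal fractions, all in 5'→3' gene orientation: the first
upstream bin is the farthest from the TSS, and for a minus-strand gene the
upstream flank lies to the right of its body. A bin's value is the mean of
site-level methylation within the bin for a gene, averaged across genes;
bins empty in a gene are excluded from that average rather than
zero-filled, since zero-filling biases profile means downward at low
coverage. Genes shorter than the number of body bins are skipped with a
warning.

# The DMR caller

Between two samples and per context, seed sites are cytosines called
methylated in at least one sample that additionally pass the coverage
screens: total reads >= 10 in *both* samples, and >= 4 methylated reads in
each sample where the site is called. Consecutive seeds closer than 200 bp
are chained; a maximal chain becomes a candidate region if its span lies
within 40 bp–10 kb. A candidate is a DMR iff it has >= 5 called cytosines
in at least one sample, pooled-level fold change > 2, and Pearson
chi-square p <= 0.05.

Numerical and policy choices, all configurable via `dmr_config()`:

* **Threshold strictness.** The count thresholds are inclusive
  (>= 5 sites, >= 10 reads, >= 4 methylated reads), the conventional
  reading; the fold and p criteria are strict (> 2, <= 0.05).
* **Pooled levels.** A region's level per sample is
  `sum(meth) / sum(total)` over member sites (read-weighted), consistent
  with feeding the same pooled counts into the chi-square table; the
  unweighted mean of site levels would test a different quantity than the
  criterion it gates.
* **Fold change** is orientation-free, `max(level)/min(level)`, with a
  direction label (`hyper` = higher in sample B). A zero denominator with
  a positive numerator passes the criterion (fold `Inf`); two zero levels
  give fold 1 and fail.
* **Chi-square** is Pearson's on the pooled 2x2 table, 1 df, no
  continuity correction; degenerate margins yield statistic 0, p 1 (a
  rejection, not an error). Expected counts below 5 are tallied and
  reported but do not trigger a Fisher substitution — the region
  definition specifies the chi-square.
* **Over-long chains are dropped, not split.** The length window is a
  bound on regions, and no principled split point exists without
  additional smoothing assumptions; this is recorded as a limitation.
* **No multiple-testing correction across regions** by default (raw
  p <= 0.05, matching the region definition); `bh_correct = TRUE` is
  available.
* Coverage failures exclude the site from seeding rather than voiding the
  region, maximizing usable signal under the per-cytosine phrasing of the
  screens.

Because all criteria are evaluated without short-circuiting, rejection
reasons are tallied per run and the null behaviour of the chi-square
criterion alone is observable: on simulated null data (identical true
levels) the pass fraction among evaluated candidates is close to alpha,
which the test suite checks against a 3-standard-error bound.

# Somatic variant accounting

Filters keep MQ > 20 and DP > 4, strict inequalities. Germline
subtraction is an exact key match on `(chrom, pos, ref, alt)`; no
position-tolerance window is applied for alternative InDel
representations, so input VCFs are expected left-normalized (a documented
limitation). The **frequency SUM** statistic is the sum of per-variant
allele fractions over the somatic set — reading "frequency" as allele
fraction; the statistic is then a burden measure weighted by clonality.
Gene assignment uses whole-gene interval containment (functional
consequence classes are out of scope), and the multi-sample intersection
is an exact set intersection.

# Enrichment

DMRs map to strand-aware zones (up2k / body / down2k) by >= 1 bp overlap;
a DMR may hit several genes and zones, and the three zones can also be
analysed separately. The hypergeometric upper tail is computed against
the whole annotated gene universe as background — not just tested genes —
and corrected by Benjamini–Hochberg (the correction method is
configurable); significance is Q < 0.05.

# The synthetic scenario

`sim_config()` defaults define the reference conditions used by the test
suite and the acceptance script: 2 chromosomes of 300 kb at GC 0.42, 40
non-overlapping genes of 2–8 kb placed >= 2 kb from chromosome ends and
> 4 kb apart, 20 planted DMRs per context of 300–1000 bp, mean coverage 30
with negative-binomial dispersion 0.2 (Poisson at 0), non-conversion
0.005, and per mouse 500 germline plus 100 somatic variants (allele
fractions {0.5, 1} and U(0.05, 0.5) respectively), 10% of the somatic
records written deliberately below the MQ/DP thresholds.

Two generator choices deserve justification:

* **Bimodal background methylation.** Real methylomes are strongly
  bimodal: most cytosines of a context are essentially unmethylated and a
  minority are methylated at a characteristic level. The generator draws
  each background cytosine as methylated with a per-context probability
  (`methylated_fraction_*`, defaults 0.05/0.02/0.01) at the context
  baseline (defaults 0.2/0.15/0.1), and unmethylated otherwise; planted
  DMRs are uniformly methylated at the baseline (control) versus
  baseline + 0.4 (treated), i.e. 0.2 vs 0.6, fold 3. This matters
  structurally: under a *uniform* baseline of 0.2 at coverage 30,
  essentially every CG site is called methylated, the < 200 bp chaining
  rule then produces chromosome-length chains, and the length window
  discards them — the caller would return nothing on any input. The
  methylated-site density set by `methylated_fraction_*` is what breaks
  background chains (mean seed gap above 200 bp) while planted regions
  chain internally, which is exactly the regime the caller was designed
  for. Consequently, convergence of observed levels to the configured
  baseline holds over the methylated-site stratum (the test suite verifies
  it with `methylated_fraction = 1`).
* **A host-gene subset for planted DMRs.** Planted DMRs are concentrated
  on a configurable fraction of genes (default 0.35) rather than spread
  over all genes; pathway over-representation is only definable when
  DMR-hosting genes are a proper subset of the universe, and focal
  differential methylation is also what real comparisons show. The
  designated pathway receives 90% of the host genes plus a 10% background
  sample; gene placement keeps neighbouring genes more than 4 kb apart so
  no position belongs to two genes' zones and a planted DMR hits exactly
  its host.

Planted intervals keep >= 800 bp separation so background seeds cannot
fuse two planted regions into one over-long chain. Germline variants
share DP/MQ across both tissues of a mouse, so filter-induced germline
leakage cannot contaminate the subtraction; sub-threshold injection
applies to somatic records only, keeping the recovery oracle exact
(recovered = planted minus deliberately-failing).

What the generator does **not** emulate: read-level errors and mapping
artifacts, M-bias, PCR duplicates, CpG islands or any sequence-driven
methylation structure, replicate-to-replicate biological dispersion (one
methylome per condition, as in the comparison being modelled), and InDel
representation ambiguity. Passing tests therefore demonstrate the
correctness and calibration of the algorithms under the stated sampling
model, not robustness to upstream artifacts.

# Problem sizes and determinism

The reference scenario (~600 kb of genome, ≈ 270k cytosine records per
sample, 600 variants per mouse across 3 mice) runs the full pipeline in
seconds on one CPU; these sizes were chosen so that binomial sampling
error is small relative to the planted effects (coverage 30 over dozens
of sites per region) while property tests over many replicates stay
cheap. All generators are seeded (`seed`, with fixed per-stage offsets),
and the pipeline writes an md5 manifest; identical configurations
reproduce byte-identical outputs.

# Known limitations

* The DMR caller assumes one methylome per condition; it tests read
  sampling, not biological replication — effect sizes, not population
  generality.
* Chains longer than 10 kb are lost entirely; dense differential blocks
  larger than the window are invisible.
* Exact-key germline matching misses representation-shifted InDels.
* The mC ratio interpretation (site counts) and the allele-fraction
  reading of the frequency SUM are modelling choices; both are
  parameterized at the surface where alternatives would plug in.
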