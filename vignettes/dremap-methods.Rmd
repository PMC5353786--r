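---
title: "Mapping differential regulatory elements from methylation profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping differential regulatory elements from methylation profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dremap)
```

## The model

`dremap` treats DNA methylation as a readout of regulatory element activity.
A regulatory element that is active in a cell population shows a contiguous
span of de-methylated CpGs; an inactive one is densely methylated. Comparing
a cancer sample class with a control class therefore partitions the
regulatory landscape into elements *gained* in cancer (hypomethylated in the
cancer class only), *lost* (hypomethylated in control only), *shared*
(active in both; the baseline for enrichment statistics) and highly
methylated regions (inactive in both; the background for permutation
statistics).

### Read-weighted class consensus

Samples differ widely in sequencing depth, so per-sample read counts are not
directly comparable. At each CpG `k`, the combined read count over the
samples contributing a measurement at that site is

$$R(k) = \frac{\sum_i w_i\, r_{ik}}{\sum_i w_i}, \qquad
  w_i = \frac{1}{\text{total aligned reads of sample } i},$$

with the same combination applied to methylated read counts to give
$MR(k)$, and the consensus methylation level $MR(k)/R(k)$. Down-weighting
deep samples prevents one heavily sequenced sample from dominating the class
consensus. Two conventions are deliberate:

* **Per-site normaliser.** The weight sum runs over the samples that still
  cover the site after the coverage filter, not over all samples. Including
  non-covered samples would deflate $R(k)$ at sites missing in some samples
  and make the consensus depend on the assay panel rather than the signal.
* **Filter before combining.** Sites seen by fewer than five reads in a
  sample are removed from that sample first; a site survives overall if any
  sample retains it.

Strand is retained as a column but sites are keyed by position: the two
strands of one CpG dinucleotide are distinct positions in the input tables
and are not merged.

### Segmentation

The consensus profile is segmented by a run rule: a region is a maximal run
of consecutive assayed CpGs on one side of the methylation cutoff (0.5),
broken wherever two consecutive CpGs are more than `max_gap_bp` apart, and
reported when it holds at least `n_cpg_cutoff` (3) CpGs. A site exactly at
0.5 counts as methylated (hypermethylated state); the tie convention is
fixed and tested. Region coordinates span the first member CpG through the
last plus the dinucleotide (end = last CpG + 2, half-open).

Two parameters matter in practice:

* `meth_cutoff = 0.5`, `n_cpg_cutoff = 3` — the published operating point;
  both exposed.
* `max_gap_bp = 500` — RRBS covers CpGs sparsely, so ungapped runs would
  connect CpGs separated by megabases into meaningless regions. 500 bp is of
  the order of the inter-CpG spacing within regulatory elements and is
  exposed as a flag. The published analysis delegated segmentation to an HMM
  tool whose internals also bound the span; the run rule implemented here is
  the declared computation, and region length statistics of the original
  data are not reproduction targets.

### Classification

A case hypomethylated region overlapping (≥ 1 bp by default) a control
hypomethylated region is *shared*: overlap chains are merged transitively
and take union coordinates, since the activity evidence covers the union.
Case regions without overlap are *gained*; control regions without overlap
are *lost*. hiMRs are the interval intersections of the two hypermethylated
maps, re-checked against the ≥ 3-CpG rule on the consensus profiles. The
contrast is exactly antisymmetric: swapping the class maps swaps gained and
lost and fixes shared and hiMR — a property the test suite asserts on the
synthetic fixture.

Genomic categories are assigned with precedence promoter > exonic >
intronic > intergenic; the promoter window is −1,000/+500 bp around the TSS,
strand-aware (both flags exposed; the published analysis used an external
annotator's defaults).

## Downstream statistics

**Gene linkage.** Each region is credited to the single gene with the
nearest TSS (distance zero when the TSS falls inside the region; ties broken
by gene identifier for determinism). Expression fold change is the ratio of
class means on the natural scale, computed only for genes with mean ≥ 0.1 in
both classes; ranking percentiles are taken over this filtered universe,
since only reliably measured genes can be ranked. Enrichment of a dRE class
near a gene set G is $fract(R,G)/fract(S,G)$ with the shared elements S as
baseline, and its significance the one-sided binomial tail with
$fract(S,G)$ as success probability; both tails are reported with the
direction flagged.

**Spatial statistics.** Distances are edge-to-edge (overlap = 0);
cross-chromosome neighbours are disallowed. The background shuffles class
labels over the fixed region coordinates 1,000 times; the observed
distribution is compared against the pooled permutation distances by
one-sided Wilcoxon rank-sum (clustering direction for within-class,
dispersion direction for cross-class), and the averaged background ECDF is
also returned. Testing against pooled distances rather than the averaged
distribution is a choice: the pooled set preserves permutation-level
variance; the averaged distribution is reported for display.

**GWAS enrichment.** Tag SNPs expand through tight LD (r² > 0.8, distance
< 500 kb, strict inequalities) over however many phased panels are supplied,
joining a trait when linked in at least one panel. Traits agglomerate by
editable keyword rules with precedence CLL > lymphoma > cancer > irrelevant,
enforced at the SNP level so category sets are disjoint. The permutation
p-value is reported both raw (the exceedance probability, as published) and
with the add-one correction, which never returns zero. SNP-in-region
membership is half-open: a SNP at a region's `end` coordinate is outside.

**SNP association.** The strict upper-tail binomial
$\Pr(X > n_{k,c})$ takes the control-class allele frequency as a known
constant. Two consequences are documented rather than patched: (i) an
allele or genotype state unobserved in controls has tail 0, so any case
observation is trivially "significant" — such SNPs carry a
`zero_control_freq` flag so users can require minimum control depth;
(ii) with a shallow control pool the null flag rate is anti-conservative
(about a third of null SNPs at 40 + 40 reads), and the ten-sample
genotype-state comparison inflates further; the calibration test fixes a
deep control pool where the rate stays under 20%. No multiple-testing
correction is applied by default, matching the raw 0.05 rule; a
Benjamini–Hochberg column is available. All alleles are tested and the
minimum taken; the cancer-associated allele is the one with the largest
positive case-minus-control frequency excess.

**Haplotype association.** Chromosome counts over the pooled panel give
$OR = D_{11}D_{22}/(D_{12}D_{21})$ with an infinite sentinel when only the
denominator vanishes; significance is Fisher's exact test, two-sided by the
point-probability method (one-sided also reported), which the test suite
checks against exhaustive hypergeometric enumeration.

**TFBS change.** PWMs get a 0.01 pseudocount, uniform background unless one
is supplied, and a hit threshold calibrated so that a background window
scores above it with probability ≤ 1e-4. The calibration is exact, not
sampled: scores are discretized to a lattice (1/1,000 of the score range)
and the null distribution computed by convolution across positions, making
scanning deterministic and oracle-checkable. A hit is attributed to a SNP
when its window overlaps the substituted base; hits elsewhere in the flank
are ignored. Background positions (30 per SNP, matching the WT base within
the host region) are pooled across SNPs to estimate the background change
fraction $p_t$; per-SNP breakdowns are recoverable from the counts. The
binomial significance uses trial counts $N(t|\mathrm{WT})$ for loss and
$N(t|\mathrm{MU})$ for gain — the published formulas print an exponent
inconsistent with these trial counts, which we read as a typographical slip
and implement as the standard binomial. When no background hit exists for a
motif the background fraction is taken as 0 and flagged by its zero
denominator columns.

## The synthetic-data generator

`simulate_dre_dataset()` generates every input under one master seed with
deterministic per-stage sub-seeds, so all outputs are byte-reproducible.
Its defaults are the study conditions: 32 cancer vs 10 control samples,
mean coverage 30 reads/CpG (per-site totals Poisson, truncated at one read,
with per-sample depth factors spanning 0.8–1.25 to exercise the weights),
hypomethylated level 0.05 and background level 0.9, planted regions of 8–15
CpGs spaced 25 bp apart. The layout plants ten regions of each truth class
plus a three-element lost cluster sharing one gene locus (the
multiple-lost-elements pattern), companion genes 1.5 kb upstream of each
region, and expression fold changes near 3× (up), ⅓× (down) or 1 (neutral),
with a 30% admixture of differential expression among shared-element hosts
so the baseline fraction is non-degenerate, and five genes below the 0.1
expression filter. Planted SNPs carry 0.8 vs 0.2 alt-allele frequencies
(associated), 0.5/0.5 (null), and monomorphic positions at 8 and 25 reads
to exercise the assay-status rules; SNP read depth matches the CpG
coverage. LD pairs are built by correlation mixture at equal frequencies to
hit target r² (0.95 by default; one tag placed 600 kb away to exercise the
distance rule), over a 1,000-chromosome panel that also carries 60
independent background SNPs. Motifs are high-information PWMs of width 8–9:
at the 1e-4 threshold these admit only exact-consensus windows, so a
planted single-base substitution always creates or destroys its site —
which is what makes motif-level ground truth recoverable.

What the generator does *not* emulate: bisulfite conversion error,
alignment artifacts, copy-number variation, correlated methylation noise
between neighbouring CpGs, population structure in the haplotype panel, or
any coupling between the synthetic genome sequence and CpG coordinates
(CpG sites are abstract positions, not CG dinucleotides). Passing the
recovery tests therefore shows the pipeline implements its rules correctly
at realistic noise levels, not that it is robust to every artifact of real
RRBS data.

## Numerical choices and degenerate inputs

* Binomial tails use `pbinom` upper tails (strict, `X > n` as written);
  the suite checks them against explicit log-space summation to 1e-12 up to
  n = 10,000.
* Zero denominators return documented sentinels (`Inf` enrichment with
  exact p from the zero-probability null; `NaN` when both sides are empty)
  rather than errors, with warnings where a quantity is undefined (empty
  region sets, monomorphic SNPs, classes without panel SNPs).
* Permutation seeds are derived from the global seed per stage through a
  Lehmer step (always within the 31-bit range R requires); shuffling is
  keyed on sorted coordinates so input order cannot change results.
* Matched-control sampling is rejection sampling with a bounded budget
  (1,000 attempts per control by default); exhaustion returns fewer
  controls with a warning rather than looping forever.
* The interval engine is a sorted sweep over tibbles; every overlap
  computation is checked against a per-base painting oracle in the tests.

## Problem sizes in the test suite

The suite regenerates its fixtures at test time: the default synthetic
dataset (about 4,400 CpG sites × 42 samples), 500 random profiles of up to
1,000 CpGs for the segmentation oracle, 200 simulated traits at 1,000
permutations and 200 spatial datasets at 50 permutations for the null
calibrations, and exhaustive Fisher enumeration over small tables plus a
500-table random sweep up to total 40. These sizes keep the full suite in
the tens of minutes on a single core while leaving each statistical check
enough resolution to fail if the implementation drifts.

## Known limitations

* The association test ignores sampling noise in the control frequencies
  (see above); treat associated-SNP lists from shallow panels as candidate
  sets.
* The run-rule segmentation has no FDR calibration and does not detect
  partially methylated domains; cutoffs are operating points, not estimates.
* Shared-element coordinates are unions of overlapping case and control
  regions; analyses sensitive to exact sRE boundaries inherit this
  convention.
* The GWAS density denominator is panel SNPs in the class (per 1,000); if a
  class contains no panel SNPs the density is undefined and flagged.
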