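---
title: "Surrogate-TOH regions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-TOH regions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tohkit)
```

## The problem

A tract of homozygosity (TOH) is a run of consecutive SNPs at which one
subject carries two identical alleles. Long tracts mark chromosomal
segments that are identical by descent or swept by selection, and are
candidate carriers of rare recessive risk variants. Single tracts are
noisy, subject-specific objects; what is informative for case-control
work is a *region* where many subjects' tracts pile up. `tohkit`
implements a three-level aggregation of per-subject tracts into
surrogate regions and tests each region's presence/absence against
disease status:

* **cTOH** (common TOH): a maximal stretch of consecutive SNPs, each
  covered by tract calls from at least `n` subjects (default 10), at
  least `L` SNPs long (default 100).
* **gTOH**: within one cTOH, a cluster of tracts whose pairwise spans
  overlap by a high fraction of each member's length (proximal
  boundaries), found by a repeated binary spectral clustering tree with
  a positional similarity kernel.
* **aTOH**: the same construction under an allelic kernel, so that
  members additionally carry the *same* homozygous allele across their
  overlap. A locus where two ancestral haplotypes both drift to
  homozygosity is one gTOH but two aTOHs; only the allelic view can see
  the difference.

## Tract scanning

`scan_toh()` reports, per subject and chromosome, every maximal run of
homozygous calls satisfying `scan_params()`:

* `min_snps` (`L`, default 100): minimum run length in SNPs.
  Alternatively `min_kb` switches to a physical-length criterion with a
  reduced SNP floor `min_snps_if_kb` (default 25, a conservative guard
  against calling long sparse windows on a handful of SNPs).
* `max_het` (default 0) and `max_missing` (default 2): interior
  heterozygous and missing calls tolerated per run. Genotyping error
  breaks true long tracts, so a small missing allowance is standard
  practice; the het allowance defaults to zero because a genuine
  heterozygote is direct evidence against autozygosity. Neither
  allowance may sit at a run boundary: endpoints are always homozygous
  non-missing calls, which stops allowances from padding boundaries
  outward.
* `max_gap_kb` (off by default): a density guard capping the physical
  gap between adjacent in-run SNPs.

"Maximal" means a run cannot be extended by one SNP in either
direction without violating a constraint; overlapping sub-runs are never
reported. Per-SNP coverage — all the downstream accumulation needs — is
identical between this convention and conventions that enumerate every
qualifying window, but maximal runs keep the output linear in the data.
The suite verifies the scanner against an exhaustive
all-windows oracle on random chromosomes.

## cTOH accumulation

`toh_call_counts()` counts, for every SNP, the tracts covering it;
`call_ctoh()` extracts maximal runs of SNPs with count `>= n` and keeps
those at least `L` SNPs long. The count threshold is inclusive
(`>= 10` under the defaults). A subject is *present* for a cTOH when at
least one of its tracts overlaps the region by one or more SNPs; no
minimum overlap fraction applies at this level.

## The TOH cluster tree

Within one cTOH the member tracts form the root node. A node is split
into two by normalized spectral clustering:
with similarity matrix $S$ and degree matrix
$D = \mathrm{diag}(d_i)$, $d_i = \sum_j s_{ij}$, we eigendecompose the
symmetric normalized Laplacian
$L_{sym} = I - D^{-1/2} S D^{-1/2}$, take the eigenvectors of the two
smallest eigenvalues as columns, normalize each row to unit Euclidean
norm, and run k-means with $k = 2$ (10 restarts, best within-cluster sum
of squares, deterministic under the supplied seed). Row normalization
plus the symmetric Laplacian is the Ng–Jordan–Weiss construction, which
is what the row-normalization step in the original algorithm identifies.
Splitting recurses until a stop rule fires:

1. depth reaches `max_depth` (default 100);
2. the node has fewer than `min_node_size` members (default 5);
3. the summary statistic of the node's pairwise similarities exceeds
   `threshold` — strict `>` when stopping, `>=` when deciding whether a
   leaf is reported.

The statistic is the lower quartile by default (`minimum` and `mean` are
available); the default threshold is 0.75. The lower quartile tolerates
a minority of weak pairs (broken tracts, boundary outliers) while still
demanding that three quarters of pairs be tight; the minimum is very
stringent and the mean very loose, and both remain available for
sensitivity analysis. Leaves always partition the root set, which the
suite asserts.

Two numerical degeneracies are handled explicitly. Members with zero
off-diagonal similarity are disconnected from everything in the node;
they are separated as one side of the split before the
eigendecomposition (a node of mutually non-overlapping tracts
degenerates to singletons, which the reporting gate then drops). A node
whose spectral embedding collapses to a single point (all-ones
similarity) splits deterministically as first member versus the rest —
its children immediately stop on the similarity rule, so the choice
cannot affect reported regions. Two-member nodes take their only
bipartition directly.

### Similarity kernels

* Positional (gTOH): $s_{ij} = \min(o/l_i,\, o/l_j)$, where $o$ is the
  overlap length and $l_i, l_j$ the member lengths, all in SNPs by
  default (bp mode by flag). This is exactly the pairwise criterion in
  the gTOH definition — the overlap must be a large fraction of *each*
  member — which is why `min` is the shipped kernel; a geometric variant
  $o^2/(l_i l_j)$ is available as configuration, since the choice is a
  reconstruction rather than a formula the source states. Tracts on
  different chromosomes have similarity 0.
* Allelic (aTOH): pairs whose overlap fraction
  $\min(o/l_i, o/l_j)$ falls below `gamma` (default 0.5) get similarity
  0; otherwise the similarity is the proportion of overlap SNPs at which
  both subjects are homozygous for the same allele. Heterozygous or
  missing calls never count as matches, and the computation uses
  unordered allele pairs, so token order in the ped file is irrelevant
  (asserted as a property test).

### Region boundaries

Reported leaves (at least `min_report_size = 2` members, statistic at or
above the threshold) become regions. Member boundaries jitter, so the
region span avoids the extremes: by default the start is the 0.75
interpolated quantile of member starts and the end the 0.25 quantile of
member ends, each snapped to the first actual member boundary at or
above the interpolated value so that reported coordinates are real SNPs.
A literal mode using the lower quartile of both boundary sets is
available (`boundary_mode = "literal"`); the interior default was chosen
because a lower quartile of the *starts* sits left of most members,
which contradicts the stated goal of trimming extreme boundaries. If the
two quantiles invert (possible for very heterogeneous leaves), the
envelope of member spans is used instead. All quantiles in the package —
similarity lower quartile, boundary quantiles, tract-length quantiles —
use linear interpolation between order statistics (R type 7).

## Association testing

Presence of each region is cross-tabulated against case-control status.
When every cell of the 2x2 table is at least 5 — the dispatch uses
observed cells, for determinism — a logistic model
`status ~ presence + covariates` is fitted and the presence coefficient
is tested by Wald; categorical covariates such as smoking enter as
indicator contrasts against the reference level. Otherwise Fisher's
exact test is used: two-sided p by the point-probability rule (the sum
of probabilities of all tables, at fixed margins, no more probable than
the observed one), the odds ratio as the conditional MLE of the
noncentral hypergeometric parameter — reported as 0 or infinity for
zero cells, with the corresponding one-sided-style exact confidence
bound — and a 95% CI from inverting the exact conditional tails. These
conventions are the ones under which the package reproduces published
exact results to printed precision; the suite additionally checks the
p-value and the conditional MLE against brute-force hypergeometric
enumeration. Separation or non-convergence in the logistic fit falls
back to Fisher with a warning; a rank-deficient design is an error.
Raw p-values against a fixed threshold (default 0.01) are the primary
read-out; a Benjamini–Hochberg column is optional and off by default.

## Calibration utilities

`chance_run_length(p, n_subjects, n_snps, alpha)` returns the smallest
integer $L$ with $n_{subjects} \cdot n_{snps} \cdot p^L < \alpha$: the
expected number of chance length-$L$ homozygous runs across the whole
study, under SNP independence, falls below $\alpha$. The product form
(per subject *and* per SNP) is adopted because it is the only reading
that reproduces the published choice of 58 from the published marginal
statistics (homozygosity 0.665, 1618 subjects, 514,355 SNPs). SNPs are
not independent, so `ld_adjusted_length(L, tag_fraction)` deflates by
the fraction of separable LD tag groups among all SNPs, rounding half
up (58 with tag fraction 0.63 gives 92). Haplotype-block and tag-group
discovery are deliberately not reimplemented: their summary numbers are
inputs, typically from PLINK. `toh_length_quantiles()` supports the
empirical route: rescan with a permissive length just above the local-LD
block scale, then read off upper quantiles of the observed tract-length
distribution.

## The synthetic generator

`simulate_toh_data()` draws background genotypes per SNP from
Hardy–Weinberg proportions at a fixed minor-allele frequency, solved
from a target homozygosity rate ($1 - 2m(1-m) = r$, so $r = 0.665$
gives $m \approx 0.213$), emulating the marginal statistics of a real
SNP-array study. Planted tracts overwrite chosen carriers' spans with
homozygous calls; each carrier's boundaries are jittered independently
by a rounded centered Gaussian, producing the proximal-but-not-identical
boundaries gTOH is designed for. Allele patterns: `matched` (one shared
haplotype), `allele_groups` (two groups carrying complementary
haplotypes — invisible to the positional kernel, separated by the
allelic one) and `random`. Het/missing noise can be injected inside
tracts, and a logistic phenotype model adds per-tract presence effects
on top of a baseline case probability, with age/sex/smoking covariates.
Everything is reproducible from one seed.

What the generator does *not* emulate: linkage disequilibrium between
neighbouring SNPs (no haplotype-copying model), recombination maps,
allele-frequency ascertainment, or population structure. Passing the
planted-recovery tests therefore shows the machinery is correct under
the stated model, not that the default parameters are optimal for any
particular real cohort — on real data the calibration utilities exist
precisely because chance and LD produce short runs the generator does
not.

## Problem sizes used by the test suite

The oracle and recovery suites run at deliberately chosen scales: the
scanner is checked against exhaustive window enumeration on 200 random
500-SNP chromosomes; Fisher statistics against full hypergeometric
enumeration for every table with total count up to 20 plus 300 random
tables with margins up to 50; spectral splits against connected
components and exhaustive minimum normalized cut on instances of up to
14 members; planted-structure recovery on 200 subjects by 5,000 SNPs
with two 150-SNP tract groups at boundary jitter sd 3; the permutation
null on 2,000 replicates at 500 cases / 500 controls with 300 present.
These sizes make the whole suite run in a few minutes while leaving
every check statistically meaningful.

## Known limitations

* Genome-scale allelic clustering is quadratic in the members of each
  cTOH; very large cTOHs (thousands of tracts) will be slow in pure R.
* The logistic path requires complete covariate data; rows with missing
  covariates are not imputed.
* Binary PLINK (.bed) and VCF input are out of scope; convert with
  PLINK first.
* Tract calling is rule-based, not likelihood-based: no
  genotype-quality or HMM smoothing.
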