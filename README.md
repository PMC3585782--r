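# tohkit

Detection of tracts of homozygosity (TOH) from SNP-array genotypes,
aggregation into **surrogate-TOH** regions, and case–control association
testing of region presence.

Long runs of consecutive homozygous SNP calls mark chromosomal segments
that are identical by descent and are candidate carriers of rare
recessive risk variants. Individual tracts are noisy per-subject
objects; `tohkit` aggregates them into three kinds of region suitable
for association work:

* **cTOH** — a maximal stretch of consecutive SNPs each covered by
  tract calls from ≥ *n* subjects (default 10) and ≥ *L* SNPs long
  (default 100);
* **gTOH** — within a cTOH, a cluster of tracts whose pairwise spans
  overlap by a large fraction of each member's length, found by a
  repeated binary spectral clustering tree (Ng–Jordan–Weiss: symmetric
  normalized Laplacian `L = I − D^{−1/2} S D^{−1/2}`, eigenvectors of
  the two smallest eigenvalues, row normalization, k-means with k = 2),
  with similarity kernel `s_ij = min(o/l_i, o/l_j)`;
* **aTOH** — the same tree under an allelic kernel: the proportion of
  overlap SNPs at which both subjects carry the *same* homozygous
  allele (0 when the overlap fraction is below γ = 0.5).

Splitting stops when a node's pairwise-similarity summary statistic
(lower quartile by default) exceeds a threshold (0.75), the node drops
below 5 members, or the tree reaches depth 100. Each region's
presence/absence per subject is tested against case–control status:
covariate-adjusted logistic regression with a Wald test when all 2×2
cells are ≥ 5, otherwise Fisher's exact test (point-probability
two-sided p, conditional-MLE odds ratio, exact CI). Calibration
utilities pick the minimum run length: the smallest *L* with
`n_subjects · n_snps · p_hom^L < α`, optionally deflated by an LD
tag-group fraction.

The package reads PLINK-style text `.ped`/`.map` files, is
tidyverse-native (tibbles in and out, `ggplot2` `autoplot()`,
broom-style `tidy()`/`glance()` for cluster trees), and ships a
synthetic genotype generator with planted homozygous tracts so every
stage can be validated against known ground truth.

## Worked example

Simulate a 120-subject, 2,000-SNP study with two planted tract groups —
one disease-associated (carriers have 5× odds), one split into two
allele groups — then run the full pipeline:

```r
library(tohkit)

spec <- sim_spec(
  n_subjects = 120, n_snps = 2000,
  tracts = plant_tracts(list(
    list(start = 600, end = 799, carriers = 1:30, jitter_sd = 3),
    list(start = 1400, end = 1549, carriers = 31:54,
         pattern = "allele_groups", jitter_sd = 3))),
  baseline_case_prob = 0.4,
  effects = c(tract1 = log(5)),
  seed = 42)
sim <- simulate_toh_data(spec)

res <- run_toh_pipeline(sim$geno, phenotypes = sim$phenotypes,
                        alpha = 0.05, seed = 42)
#> scan: 54 TOHs in 120 subjects
#> ctoh: 2 regions (n >= 10, L >= 100)
#> cluster: 2 gTOHs, 3 aTOHs
#> assoc: 7 regions tested, 4 significant at p < 0.05
```

The scanner finds the 54 planted tracts; both loci become cTOHs and
gTOHs, and the allele-split locus yields an extra aTOH (3 aTOHs from 2
loci) because the two allele groups are invisible to the positional
kernel but separate under the allelic one. The association table picks
out the planted effect:

```r
res$assoc[, c("region_id", "test", "p_value", "odds_ratio",
              "n_cases_present", "n_controls_present")]
#> # A tibble: 7 × 6
#>   region_id test          p_value odds_ratio n_cases_present n_controls_present
#> 1 ctoh_1    logistic_wald 0.00109       5.71              25                  5
#> 2 gtoh_1    logistic_wald 0.00109       5.71              25                  5
#> 3 atoh_1    logistic_wald 0.00109       5.71              25                  5
#> # ... 4 more rows
```

The fitted odds ratio 5.71 recovers the planted log(5) effect; 25 of the
30 carriers are cases. Recovery against the planted truth is exact:

```r
truth_compare(sim$truth, res$gtoh)
#> # A tibble: 2 × 5
#>   cluster detected reciprocal_overlap matched_region rand_index
#> 1 tract1  TRUE                  0.99  gtoh_1                  1
#> 2 tract2  TRUE                  0.987 gtoh_2                  1
```

`rand_index = 1` means the detected region memberships agree perfectly
with the planted carrier sets; reciprocal overlap just under 1 reflects
the interior boundary convention (region bounds are quantiles of the
jittered member boundaries).

A thin command-line front-end over the same functions is installed at
`inst/cli/tohkit.R`
(`Rscript tohkit.R <scan|ctoh|cluster|assoc|calibrate|simulate|run-all>`).

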