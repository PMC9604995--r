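---
title: "Tracking homozygosity buildup in selfed families with SNP genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking homozygosity buildup in selfed families with SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfpath)
library(dplyr)
```

## The problem

Inbred lines are the raw material of uniform hybrid breeding, but in
long-generation outcrossing tree crops such as cacao, developing them by
repeated self-pollination is slow: each generation takes years and large
trial areas, and the breeder advancing a random offspring has no idea
whether it happens to sit above or below its family's expected level of
inbreeding. Genome-wide SNP genotypes give a direct readout: count, per
individual, how many of its genotyped SNPs are homozygous. Offspring whose
homozygosity sits furthest above the family mean can be advanced
preferentially, accelerating fixation by one or more generations.

`selfpath` implements that workflow end to end: genotype and pedigree IO
with panel-style quality control, per-individual genotypic counts and
observed homozygosity, a Mendelian expectation model for selfing with
per-offspring deviation tests, within-family standardization and ranking,
parent–offspring compatibility checks, cohort summaries (Hardy–Weinberg
tests, MAF spectrum, inbreeding coefficient *F*), and cross-prioritization
via Smouse–Peakall codominant distances, UPGMA dendrograms and expected F1
heterozygosity. A synthetic-data module simulates the whole design so every
stage is testable without any external files.

## The Mendelian selfing model

All calls are Illumina AB-coded (`AA`, `AB`, `BB`). Under selfing, a locus
homozygous in the parent is fixed in every offspring; a heterozygous locus
segregates 1 AA : 2 AB : 1 BB. From the parent's genotypic counts
$(n_{AA}, n_{AB}, n_{BB})$ the offspring expectation is therefore

$$\left(n_{AA} + \tfrac{n_{AB}}{4},\; \tfrac{n_{AB}}{2},\;
  n_{BB} + \tfrac{n_{AB}}{4}\right),$$

each homozygous class gaining 25% of the parental heterozygous calls and
the heterozygous class halving. At the fraction level, homozygosity after
$g$ generations from baseline $h_0$ is $h_g = 1 - (1 - h_0)/2^g$. The two
formulations agree exactly, which the test suite asserts.

Each offspring is tested against its parent-derived expectation with a
Pearson chi-square on the three genotypic classes (df = 2, fully specified
null, $\alpha = 0.05$ by default). Two conventions matter and both are
deliberate:

* **No rescaling of the expectation to the offspring's genotyped total**
  (default). Parent and offspring totals differ only through call-rate
  differences, and the unscaled statistic is the field's reporting
  convention; `rescale = TRUE` is available and shifts the statistic only
  in the second decimal for realistic call rates.
* **Full-precision homozygosities everywhere.** Family means, standard
  deviations, z-scores and RMSD are computed from the raw counts, never
  from 3-decimal rounded values; rounding first visibly distorts z-scores
  (a -1.879 becomes -1.93).

Within each family (≥ 2 offspring of one selfed parent) homozygosities are
standardized, $z_i = (h_i - \mu)/\sigma$ with the sample (n−1) standard
deviation, and ranked; `select_candidates()` picks the top-*k* per family
with ties broken by individual id for reproducibility. The family summary
reports the expected mean (one-step propagation of the parent's observed
homozygosity), observed mean, sd, range, the RMSD between observed and
predicted homozygosity (population, i.e. *n*, denominator), and a
one-sample t-test of per-offspring observed-minus-expected homozygous-call
counts against zero. The t-test formulation is ours: reported family-level
t statistics in comparable published tables could not be reproduced under
any standard one- or two-sample formulation we tried, so the package
documents its own and the test suite asserts only non-significance on the
reference data, which holds under every formulation considered.

When a family's selfed parent was never genotyped, the class-wise mean of
its genotyped siblings substitutes for it (`surrogate_parent_counts()`);
siblings share the grandparent, so their Mendelian expectation matches the
missing parent's in expectation. `surrogate_overrides` can pin a specific
single sibling instead — the reference family-C chi-squares reproduce
exactly only under a single-sibling surrogate, so both routes are
first-class.

## Quality control and cohort statistics

`qc_genotypes()` filters in a fixed, documented order: samples by call
rate (computed across all markers present before any marker filtering),
then markers by call frequency, then markers by MAF computed on the
retained samples. Defaults (call frequency ≥ 95%, MAF ≥ 0.01, sample call
rate ≥ 87%) follow standard Infinium-panel practice. The order matters
because MAF is defined on the post-sample-filter cohort; the operation is
idempotent.

The cohort inbreeding coefficient is $F = 1 - H_o/H_e$ with observed and
expected (2pq) heterozygosities averaged over polymorphic markers
(ratio-of-means by default; a mean-of-ratios variant is available because
the estimator behind published cohort-level *F* values is rarely fully
specified). Monomorphic markers are excluded from *F*, from the HWE
denominators and from the expected-homozygosity average. The HWE test uses
1 df (one estimated allele frequency, three classes), no continuity
correction; markers with any expected class below 1 are flagged.

## Parentage screening

A selfed offspring can carry only parental alleles, so a homozygous parent
call is compatible only with the identical offspring call; heterozygous
parent calls are compatible with everything. `verify_parentage()` counts
incompatible loci over loci non-missing in both members; the default
exclusion threshold (rate > 0.02 with ≥ 500 compared loci) allows roughly
1% per-call genotyping error in either member while unrelated substitutes
on an informative panel show incompatibility rates an order of magnitude
higher. Both thresholds are explicit parameters because published
exclusion rules are typically qualitative ("several hundred mismatches").

## Divergence and cross prioritization

The Smouse–Peakall codominant distance scores each comparable locus 0
(identical genotypes), 1 (homozygote vs heterozygote sharing an allele) or
4 (opposite homozygotes) — equivalently the squared difference in B-allele
dosage — and sums over loci. The four-fold weight on AA × BB mirrors F1
heterozygosity: such a cross is heterozygous with probability 1, against
0.5 for any cross involving a heterozygote, which is exactly
`expected_f1_heterozygosity()`; for fully homozygous parents the per-locus
distance divided by 4 equals the F1 heterozygosity (asserted in tests).
Missing data are handled by per-pair deletion, and because per-pair locus
counts then differ, `normalize = TRUE` averages per comparable locus; the
default reports raw sums, the convention of the common desktop tools.
UPGMA trees are built by average-linkage agglomeration (node height = half
the merge distance, so cophenetic distances reproduce merge distances),
with input rows sorted by id so the Newick output is reproducible.

## The synthetic-data generator

`simulate_founders()` draws per-marker allele frequencies and genotypes
from inbreeding-adjusted proportions $(p^2 + Fpq,\, 2pq(1-F),\, q^2 +
Fpq)$. The default MAF model is $0.5\,\mathrm{Beta}(4, 2)$ with the minor
allele assigned at random, giving mean MAF ≈ 0.33 and median ≈ 0.34 — the
left-skewed, high-MAF spectrum typical of fixed-content panels ascertained
for informativeness (reported cohort values for such panels are mean
≈ 0.325, median ≈ 0.347). A uniform model is provided for calibration
studies. `simulate_selfing_offspring()` segregates heterozygous loci
1:2:1 independently (free recombination); `apply_genotyping_noise()` adds
symmetric class-swap errors and missingness. `simulate_selfing_series()`
composes these into founder + multi-generation families of 6–10 offspring
with full truth bookkeeping, emitting exactly the file dialects the IO
layer consumes.

What the generator deliberately does **not** model: linkage between
markers (the analysis treats markers as exchangeable counts, so unlinked
loci are consistent with the model being tested, but real panels have
correlated loci and the effective number of independent markers is
smaller — simulated sampling variances are therefore optimistic),
allele-dropout-biased error, locus-specific missingness, and any
fitness/selection effect such as purging of genetic load. Passing tests on
synthetic data show the statistics are computed correctly under the stated
model, not that real families obey it.

Two simulators cover the advancement experiment. `simulate_program()` is
genotype-level and can emit every intermediate matrix and pedigree.
`selfing_trajectory_mc()` is counts-level: with unlinked loci an
offspring's heterozygous-call count is Binomial(parent het count, 1/2) and
ranking by homozygosity is ranking by that count, so the homozygosity
trajectory needs no genotype matrix at all. The two agree in distribution
(asserted in the suite), and the counts-level route makes 500-replicate
comparisons instantaneous. Replicates share a seed across strategies so
strategy contrasts are paired.

## Numerical choices and degenerate inputs

* Zero genotyped calls: counts are returned, statistics are `NA` with a
  warning; an all-equal family has undefined z (flagged `NA`), zero RMSD.
* A zero expected class with a nonzero observed count yields an infinite
  chi-square flag rather than an error.
* Ties in ranking and UPGMA input order are broken lexicographically.
* Missing tokens `--`, `NC` and the empty string are accepted on read;
  `--` is always emitted on write, making write→read the identity.
* Bonferroni thresholds are computed (`alpha/n_tests`), never copied from
  truncated printed values.

## Problem sizes in the test suite

The suite regresses the full published six-family table (49 offspring,
3,380 SNPs, exact at print precision), calibrates the deviation test with
10,000 multinomial null replicates, recovers founder *F* over
{0, 0.15, 0.3, 0.6} from 500 × 3,000-marker cohorts within ±0.02, checks
distances/UPGMA against brute-force oracles, and compares advancement
strategies over 500 paired replicates of 30-offspring families for three
generations (baseline homozygosity 0.48). These sizes were chosen to keep
Monte-Carlo error well below the tolerances being asserted while the whole
suite runs in seconds.

## A worked example

```{r}
counts <- cacao_selfing_counts()
pedigree <- cacao_selfing_pedigree()
fit <- analyze_selfing(counts, pedigree)
glance(fit)[, c("family", "n_offspring", "expected_mean_hom",
                "observed_mean_hom", "sd_hom", "rmsd")]
select_candidates(fit, 1)[, c("family", "individual", "obs_hom", "z")]
```

And the headline simulation — marker-assisted vs random advancement:

```{r}
mc <- selfing_trajectory_mc(h0 = 0.48, family_size = 30, n_generations = 3,
                            reps = 200, seed = 1)
mc %>%
  group_by(strategy, generation) %>%
  summarise(mean_hom = mean(hom), .groups = "drop")
```

## Known limitations

Counts-based expectations ignore linkage and selection; the parentage test
addresses only selfing (no two-parent or likelihood-based inference); the
*F* estimator is one documented choice among several in use; and the UPGMA
implementation targets reproducibility, not large-cohort performance.
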