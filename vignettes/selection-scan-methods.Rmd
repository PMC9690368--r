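---
title: "Detecting selective sweeps with haploSweep: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with haploSweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploSweep)
```

# The problem

When two subpopulations of one species have been bred toward opposite
phenotypes — short versus long guard hair on a fur animal, large versus
small pelts, divergent coat colors — loci underlying the selected traits
leave three complementary footprints in the genome:

* **allele-frequency differentiation** between the groups, measured per SNP
  by the Weir–Cockerham fixation index (Fst);
* **extended haplotype homozygosity**: a recently swept allele rises so fast
  that recombination cannot break up its haplotype, so the selected group
  carries unusually long stretches of identical haplotypes, which the
  cross-population XP-EHH statistic detects;
* **loss of nucleotide diversity** in the selected group, measured per site
  by the ratio of theta-pi between the groups.

No single statistic is reliable on its own: Fst is inflated by drift in
small groups, XP-EHH by local recombination cold spots, and diversity
ratios by low-recombination regions. `haploSweep` therefore takes the
conservative route of intersecting the empirical top tails of all three
and reporting only SNPs extreme in every one, expanded into small
candidate regions and annotated with overlapping genes.

# Data model

The central container is the `HaplotypeMatrix`: phased biallelic SNP
alleles coded 0/1/NA, one row per haplotype (two consecutive rows per
diploid sample) and one column per variant, with variants sorted by
position within chromosome. Phasing is a hard requirement for the
haplotype statistics; the package does not phase or impute, and the VCF
reader rejects unphased genotypes by default so that silently treating
genotype pairs as haplotypes is impossible. Coordinates are 1-based
inclusive everywhere inside the package (the VCF/GFF convention); BED
output is converted to 0-based half-open only at the writer, which keeps
every off-by-one conversion in one place.

A `GroupContrast` fixes the orientation of the scan. The *test* group is
the one hypothesised to carry the sweep; XP-EHH is
$\ln(\mathrm{iHH}_{test}/\mathrm{iHH}_{control})$ and the diversity ratio
is $\log_2(\pi_{control}/\pi_{test})$, so **positive values of both point
at the test group** and the three upper tails can be intersected directly.

# Quality control

`applyQc()` reproduces a standard WGS hard-filter set with an exact
Hardy–Weinberg test written from the conditional distribution of
heterozygote counts given allele counts: all attainable heterozygote
counts with probability no larger than the observed one are summed
(two-sided exact test, not mid-p). Defaults: MAF $\ge 0.05$ (a site at
exactly 0.05 is kept), no missing genotypes (`maxMissing = 0`, the
`--max-missing 1.0` idiom of VCF tooling), HWE $p \ge 10^{-6}$ on the
pooled sample, and an autosome whitelist (empty = accept all labels,
since chromosome naming schemes differ between assemblies).

Two open choices were resolved as follows. HWE is tested on the *pooled*
sample because QC precedes any group-specific analysis; this means strong
between-group differentiation (the Wahlund effect) can in principle
remove a real sweep site, which is the conservative direction. Each
removed variant is attributed to the *first* failing filter in the fixed
order multiallelic → non-autosomal → missingness → MAF → HWE, making the
`QcReport` deterministic and exactly conservative of the input count.

# The three statistics

## Weir–Cockerham Fst

For two populations with per-site diploid sample sizes $n_1, n_2$,
alt-allele frequencies $p_1, p_2$ and observed heterozygote proportions
$h_1, h_2$, `fstComponents()` evaluates the variance components $a$
(among populations), $b$ (among individuals within populations) and $c$
(within individuals) of the 1984 estimator, and
$F_{st} = a/(a+b+c)$. Observed heterozygosity comes from genotype calls,
not from allele frequencies — the estimator requires it. Negative
estimates are clamped to zero after computation (`fst` column; the
unclamped `fst_raw` is kept for diagnostics), and sites where either
group has fewer than two complete genotypes, or where $a+b+c = 0$
(monomorphic in both groups), are reported `NA` and excluded from the
empirical quantiles.

## EHH, iHH and XP-EHH

EHH at distance $x$ from a core SNP is the probability that two randomly
drawn haplotypes of the group are identical over every variant between
the core and $x$:
$\mathrm{EHH}(x) = \sum_g \binom{e_g}{2} / \binom{n}{2}$ over the groups
of haplotypes identical on that interval. Two conventions are pinned
down here. First, all haplotypes of a population are pooled (no partition
by core allele), the XP-EHH variant of the statistic; the curve value at
offset 0 is 1 by definition, and identity from the first offset onward
includes the core site. Second, missing alleles match nothing, including
each other, so missingness can only shorten homozygosity, never fake it.

iHH is the trapezoidal integral of EHH over *physical* distance (no
genetic map is assumed; this matches the physical-distance mode of the
standard scan software). Integration of an arm stops where EHH falls
below the cutoff (default 0.05, the common program default), with the
crossing point linearly interpolated, or where two consecutive sites are
more than `maxGap` apart (default 200 kb) — the arm then ends at the last
site before the gap rather than being penalized, the simpler of the
documented program behaviors.

For XP-EHH both groups must be integrated over the *same* extent, else
the log-ratio conflates haplotype length with marker geometry. The extent
per arm is determined by the EHH of the pooled sample (test plus control
haplotypes) falling below the cutoff; test and control curves are then
integrated over exactly that extent. This makes
`xpehh_raw` antisymmetric under swapping the groups, which the test suite
checks. Raw values are z-normalized genome-wide (sample standard
deviation, $n-1$) into `xpehh_norm`. The per-site scan is implemented in
C++ with incremental haplotype-group refinement, so a genome-scale scan
is linear in (sites × haplotypes × extent).

## Diversity ratio

Per-site theta-pi is the fraction of haplotype pairs differing at the
site, $2j(n-j)/(n(n-1))$ for $j$ alt alleles among $n$ non-missing
haplotypes. The reported statistic is $\log_2(\pi_{control}/\pi_{test})$.
Sites with zero diversity in either group yield a *missing* ratio rather
than a pseudocount value: the log is undefined there, and pseudocounts
would distort exactly the empirical tail the scan depends on. The count
of such sites is logged because silently shrinking the quantile universe
would bias the thresholds.

# Outliers, regions, genes

`topQuantile()` takes the empirical top 1% (configurable `q`): the
threshold is the value at rank $\lceil qN \rceil$ from the top among
eligible values, and all ties at the threshold are kept — a superset of
exactly 1% is preferable to dropping arbitrary SNPs, and the rule is
deterministic. Eligibility differs by statistic: Fst and the diversity
ratio use all non-missing values; XP-EHH uses *positive* values only,
because only positive values indicate selection in the test group.

Two tiers are intersected: `2way` (Fst ∩ XP-EHH) and `3way` (adding the
diversity ratio), mirroring the two levels of stringency commonly
reported. Intersected SNPs are expanded by ±5 kb flanks, clipped at
chromosome bounds, and overlapping or book-ended windows are merged
(isolated SNPs hence give `end - start = 10000` regions; clusters give
longer merged regions). Genes are assigned on ≥1 bp closed-interval
overlap — the default semantics of interval-intersection tools — via
`GenomicRanges::findOverlaps`, with a brute-force all-pairs oracle in the
test suite.

# The synthetic-data generator

Real selection-scan data (deep WGS of phenotyped populations) is rarely
redistributable, so the package ships a generator that makes the entire
pipeline testable end to end with known truth.

*Background.* Each chromosome has a pool of 8 founder haplotypes with
site frequencies uniform on [0.1, 0.9]; every sample haplotype is a
mosaic of founders with a per-site switch probability of 0.05, i.e.
expected blocks of 20 SNPs (about 200 kb at benchmark SNP density). This
gives genuine block-wise LD with directly controllable scale while both
groups draw from one founder pool, so the neutral between-group Fst is
pure drift/sampling noise (mean ≈ 0.02 at 15 + 15 individuals, checked
in the tests).

*Sweep.* A hard sweep is modeled as haplotype replacement: a fraction
(`carrierFreq`, default 0.9) of test-group haplotypes have the interval
`pos ± span/2` (default span 500 kb) overwritten by one fixed carrier
haplotype. This creates exactly the power case of XP-EHH — long shared
homozygosity at high frequency in one group, polymorphism in the other —
plus frequency differentiation and diversity loss at the same locus.

*Planted QC violations* are singleton (low-MAF) columns, columns with one
missing genotype, and all-homozygote half/half columns that any exact
HWE test rejects. A deterministic repair pass then nudges every
*non-planted* site to clear the default QC thresholds (raising realized
MAF by flipping majority alleles on non-carrier haplotypes; restoring
HWE by allele swaps between individuals, which preserve allele counts
and therefore frequencies), never touching carrier haplotypes inside the
sweep span. QC on a generated fixture therefore removes exactly the
planted sites — the bookkeeping test the QC module must pass.

*What the generator does not emulate:* coalescent genealogies,
recombination-map structure, demography (bottlenecks, migration), soft
sweeps and allele ages. Passing the recovery benchmark shows the
pipeline detects a strong hard sweep against block-LD background at
desk scale; it does not certify power on real demographies — for that,
a coalescent simulator would have to replace the background model.

# Benchmark scenario and expectations

The default `simConfig()` is the package's benchmark: two 25-Mb
chromosomes with 2,500 SNPs each, 15 test + 15 control diploids, one
hard sweep (carrier frequency 0.9, 500-kb span) mid-chromosome 1 —
sample sizes on the scale of real phenotype-contrast subgroups, and a
problem size a laptop core scans in a couple of seconds.
`sweepBenchmark()` runs this across seeds; in the shipped validation the
three-way intersection localizes the sweep to within ±1 Mb in at least
80% of seeds (observed: 20/20 with median distance ≈ 50 kb), and neutral
genomes produce no concentrated three-way region (no region built from
more than 3 merged windows) in at least 95% of seeds. These two rates,
plus the neutral mean Fst, are what `scripts/acceptance.R` recomputes.

# Numerical and degenerate-input choices

* HWE test in log-space with a $(1+10^{-9})$ relative tolerance on the
  "no more probable than observed" comparison, so floating-point ties are
  included as intended.
* Monomorphic or undefined sites propagate as `NA` and are excluded from
  quantiles; zero retained variants after QC is a warning with an empty
  matrix, not an error, so batch runs survive degenerate inputs.
* Normalization refuses constant input (zero variance) instead of
  returning NaN.
* Group-refinement keys in the C++ EHH core are remapped to 1..k at every
  step, so key growth cannot overflow regardless of walk length.
* Pipeline TSVs format numerics with `%.6g`, making reruns byte-identical
  and locale-independent.

# Known limitations

* Two populations only (the r = 2 estimator); no multi-population Fst,
  no Hudson/Nei variants, no windowed statistics.
* Physical distance only for iHH; a genetic map is not supported.
* Phasing is required and trusted; phase errors shorten haplotype
  homozygosity and deflate XP-EHH.
* The empirical top-1% rule is per-SNP, not windowed or smoothed; at few
  eligible SNPs the threshold is noisy (the code warns below 100/q
  eligible values).
* GO/KEGG enrichment of candidate genes is out of scope (external
  databases); the gene lists are the hand-off point.
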