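---
title: "Allele-sharing genome scans: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-sharing genome scans: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the methods it implements: the
estimators and their assumptions, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices made where a definition left room.

## The matching framework

Everything starts from the allele-sharing (matching) proportion. For two
diploid individuals with alternate-allele dosages $x_i, x_j \in \{0,1,2\}$
at a biallelic site,

$$m_{ij} = \frac{x_i x_j + (2-x_i)(2-x_j)}{4}$$

is the probability that two alleles, one drawn at random from each
individual, are identical. $M_{ij}$ averages $m_{ij}$ over the sites at
which both genotypes are observed — a *ratio of sums* (sum of per-site
matchings over the count of jointly observed sites), which is unbiased
when genotypes are missing at random and is the standard treatment for
matching estimators. Pairs are then averaged unweighted (each pair counts
once regardless of how many sites it used), provided each pair meets a
`min_snps` floor. The self-matching $M_{ii}$ — 1 at homozygous sites, 0 at
heterozygous ones — plays the same role for inbreeding coefficients.

From $M$ the package derives, as moment estimators:

* $\beta_{ij} = (M_{ij} - \bar M_B)/(1 - \bar M_B)$, relatedness relative
  to the mean matching $\bar M_B$ over all distinct pairs in the analysed
  panel. The panel-wide baseline (rather than a between-population one) is
  deliberate: relatedness is a panel-level notion here, whereas group
  contrasts define their own baselines below.
* group-specific $F_{ST} = (\bar M_w - \bar M_b)/(1 - \bar M_b)$ with
  $\bar M_w$ over unordered pairs of distinct target individuals and
  $\bar M_b$ over target × reference pairs. The target group is treated as
  a single unit: for an islands-vs-mainland contrast, cross-population
  pairs *within* the island group (EC × WC) count toward $\bar M_w$. That
  is exactly what makes the statistic sensitive to ancestry shared by the
  whole target group and robust to substructure, since no F-model
  independence between populations is assumed.
* pairwise $F_{ST}$ with $\bar M_w$ the unweighted mean of the two
  within-population averages.
* $F_{IT,i}$ and $F_{IS,i}$: self-matching measured against the panel-wide
  and within-population pair baselines respectively; overall $F_{ST}$
  contrasts within- against between-population pair matching.

These are method-of-moments quantities: no likelihood, no MCMC, no
assumption that populations are independent draws from a common ancestral
pool. The cost is estimator noise at few SNPs — which is why windows carry
a minimum SNP count (below).

## Window statistics

Windows are fixed-size (default 100 kb) and stepped (default 20 kb) along
each contig from coordinate 0; trailing windows that would not fit are not
emitted. Within each window:

* the matching matrix of the in-window SNPs feeds the configured
  group-specific and pairwise $F_{ST}$ statistics;
* $\pi = \sum_s 2 p_s (1-p_s)\,n_s/(n_s-1) / L$ per group, and
  $d_{xy} = \sum_s [p_A(1-p_B) + p_B(1-p_A)] / L$ per group pair, both per
  base pair with $L$ the window length. The denominator is the *window
  length*, not the SNP count: the input is a genome-wide SNP set, so
  positions absent from it are treated as invariant. This puts π and dxy
  on an absolute per-bp scale comparable across windows.
* blocked LD: within a sample group, SNPs above a minor-allele-frequency
  floor (strictly > 0.05 by default, computed within the analysed group)
  are grouped per scaffold into consecutive blocks of 100; each block pair
  gets the mean squared Pearson correlation of dosages over its SNP pairs
  (distinct pairs only within a block). Correlations use pairwise-complete
  samples; with ≤ 5% missingness imputation would add nothing.

`min_snps` defaults to 10 per window. Windows below it are emitted with
missing statistics and excluded from threshold estimation — a variance
control, since a 100-kb window with a handful of SNPs yields an $F_{ST}$
estimate noisy enough to dominate the outlier tail.

## Calling outlier regions

The threshold is genome-wide mean + 5 sample standard deviations of the
windowed statistic, computed once per run over non-missing windows (not
per scaffold). Under normality the one-sided tail beyond 5 SD is
$2.87\times10^{-7}$ — about one window in 3.5 million — so with hundreds
of thousands of windows the expected false-positive count stays well below
one. Windows *strictly* above the threshold are clustered by genomic-span
overlap on the same scaffold; a cluster needs at least two supporting
windows to become a region (with 20-kb steps and 100-kb windows,
consecutive outlier windows always overlap; merely abutting spans do not
cluster). Ties at the threshold are measure-zero, and strictness matches
the "higher than" reading of the rule.

The island-vs-island design uses a conjunction: a window supports a region
only if the *pairwise* statistic clears its five-sigma threshold **and**
the focal island's own specific $F_{ST}$ clears that statistic's
genome-wide 99th quantile (linear interpolation between order statistics,
R's default type 7 — stated so results are reproducible bit for bit). The
two thresholds actually applied are attached to the result. Genes overlap
a region if their half-open intervals share at least 1 bp; no containment
is required.

Coordinates are 0-based half-open internally everywhere; VCF and GFF3 are
converted on read, BED is written natively, and human-facing TSVs use
1-based positions. One unambiguous internal convention avoids the classic
off-by-one family of bugs.

## Genotype QC

Input VCFs are reduced to biallelic SNPs; records on excluded scaffolds
(e.g. sex-linked super-scaffolds) are dropped; phase is discarded (no
analysis here uses it) and genotypes become alt-allele dosages. The
missingness rule is strict: sites with a missing fraction ≥ 5% are
removed. The exact Hardy–Weinberg screen (Levene's conditional
distribution of the heterozygote count given the allele counts; p sums the
probabilities of outcomes no more probable than the observed one) is
applied over all samples pooled, and is *off by default*: it serves
analyses of neutral structure, and whether a scan should use the screened
set is a judgement call the caller makes via `apply_hwe`. LD pruning is a
PLINK-style greedy pass (50-SNP windows, 10-SNP steps, r² > 0.1 removes
the later-positioned SNP); windows run over the currently retained SNP
list and passes repeat until stable, so the output genuinely contains no
co-windowed pair above the cutoff.

## The synthetic-data generator

`simulate_neutral()` draws, per site, an ancestral frequency uniform on
(0.05, 0.95) — the input being emulated is a SNP set, so rare monomorphic
draws are avoided and realized-monomorphic sites are dropped — then
population frequencies from the Balding–Nichols beta distribution
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ and genotypes as Binomial(2, p)
per individual. The default configuration mirrors the archipelago design:
EC (n = 10) and WC (n = 9) as islands, MA (n = 3), PT (n = 9) and IS
(n = 9) as mainland — the MA group deliberately stresses small-sample code
paths — with drift coefficients 0.11, 0.10, 0.02, 0.02, 0.05 chosen to
put genome-wide differentiation on the 0.05–0.10 scale typical of
long-isolated island populations, islands more drifted than mainland.
30,000 SNPs on ten 5-Mb contigs give ≈ 60 SNPs per 100-kb window.

`plant_sweep()` installs a swept haplotype: one allele per site (drawn
once from the ancestral frequencies), copied into each target individual
on 2 / 1 / 0 chromosomes with probabilities $f^2 / 2f(1-f) / (1-f)^2$
(default $f = 0.97$), remaining chromosomes redrawn from the individual's
population frequency. Because the copy number is drawn once per individual
for the whole region, carriers of background chromosomes are the *same*
individuals at every site — which is precisely what produces region-wide
LD, depressed within-group π and depressed between-island dxy. For
$f < 1$ the copy-number draw is conditioned on at least two non-swept
chromosomes among the targets: a sweep emulated at 97% frequency should be
near-fixed *but still polymorphic* among carriers — with 19 island
individuals an unconditional draw leaves the region completely monomorphic
in roughly a third of realizations, where LD (and the figure-style
signature) is simply undefined, and residual variation of a single
chromosome would sit below the 5% MAF floor of the LD analysis. The
conditioning keeps the planted region in the regime the signature
describes at every seed, at the cost of a slightly lower realized
haplotype frequency. Setting $f = 1$ bypasses it and gives the fully fixed
limit (π = 0, dxy = 0 within the region).

The neutral background has *no linkage at all* — sites are independent
draws — so LD exists only where planted. That is a feature for testing
(the LD contrast is a clean signature with a known truth) and a limitation
for realism: real genomes have background LD, recombination-rate
variation, and sweeps on standing variation whose residual haplotype
structure is richer than two haplotype classes. Passing tests on these
fixtures therefore demonstrates that the estimators and the calling rules
do what they claim under the assumed structure, not that the pipeline's
power/false-positive trade-off transfers quantitatively to any real
genome.

The two-island configuration (`dual_island_config()`) plants one 240-kb
region private to each island on a 25-Mb genome at higher SNP density
(≈ 120 SNPs per window). Those sizes are deliberate: the dual rule's
99th-quantile criterion is only meaningful when outlier windows are a
small fraction of the genome, and the pairwise EC–WC signal of a
population-private sweep is weaker than the islands-vs-mainland one, so
windows need more SNPs for the five-sigma threshold to separate signal
from window noise.

`simulate_niche()` draws standard-normal site environments; the specialist
samples sites with probability $\propto \exp(z \cdot \mathrm{offset})$ —
a displaced, narrow niche along the offset direction (default: magnitude
2 on the first variable, the "hot-arid" axis) — while the generalist
samples uniformly.

## OMI

The environment table is standardized to weighted mean 0 and variance 1
per variable under the site weights (uniform by default; exposed for
raster-cell area weighting), so the origin of the niche space is the mean
habitat of the sampling area — the niche of a hypothetical ubiquitous
species. Each species' centroid is the occurrence-weighted mean of the
standardized site rows; OMI is its squared norm. Ordination axes come from
the eigen-decomposition of the species-total-weighted cross-product of the
centroid matrix, with each axis carrying its eigenvalue's share of the
total marginality. Per species, total occurrence-weighted inertia
decomposes exactly into OMI + tolerance (weighted variance of the
species' site scores along its own centroid direction) + residual
tolerance; the decomposition is asserted to 1e-9 in the tests.
Presence records are aggregated to counts per site before analysis, so
either raster cells or raw records can serve as the site unit. Eigenvector
signs are fixed by forcing each axis's largest-magnitude loading positive
(the sign is otherwise arbitrary and must be deterministic). A
seeded permutation test of OMI (random shifts of occurrence rows) is
available but off by default in the workflow.

## Degenerate inputs and tie-breaking

* A pair with zero jointly observed sites gets a missing matching entry;
  $\bar M_b = 1$ makes the FST ratio undefined and returns missing with a
  warning rather than ±Inf.
* Monomorphic sites contribute 0 to π and dxy; a group unobserved at every
  window site yields a missing window value.
* Zero-variance environment variables abort standardization by name;
  exactly duplicated variables can be dropped beforehand.
* The LD pruner removes the *later-positioned* SNP of an offending pair —
  deterministic and order-stable.
* All generators and resampling steps (rarefaction, permutation test) are
  seeded; identical configurations give byte-identical outputs.

## Problem sizes used by the tests and the acceptance script

The test fixtures are sized for tight feedback while keeping every
estimator in its intended regime: parameter recovery uses 20,000 SNPs at
10 individuals per population (recovering the configured F within ±0.02);
the planted-sweep scan uses the default 30,000-SNP / 50-Mb configuration
(2,460 windows); the false-positive control runs 100 replicate pipelines
on a 10-Mb genome at the same per-window SNP density; and the rarefaction
oracle enumerates subsamples exhaustively only on toy panels. These are
the package's own choices of study condition, stated here so that anyone
scaling the workflow up to a real dataset knows which knobs were held
where during validation.

## Known limitations

* The neutral simulator's independent-sites design cannot generate
  background LD or recombination maps; LD-based conclusions on real data
  need the usual caution about low-recombination regions (the package's
  own mainland-contrast check is the intended guard).
* The islands-vs-mainland pairwise FST (`fst_island_mainland`) is computed on
  pooled groups with the same matching estimator as everything else; it is
  provided descriptively, and the group-specific statistic is the
  recommended scan statistic precisely because pooled pairwise scans are
  confounded by substructure.
* Window statistics assume the SNP set is genome-wide and uniformly
  ascertained; π and dxy denominators count unlisted positions as
  invariant, so a filtered or exome-like SNP set would bias them low.
* The HWE screen pools all samples; in strongly structured panels the
  Wahlund effect makes it conservative toward removing differentiated
  sites, which is why it is optional and off for scans.
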