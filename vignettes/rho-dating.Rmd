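---
title: "Dating Y-chromosome divergences with the rho statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating Y-chromosome divergences with the rho statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodate)
```

## The problem and the model

The male-specific part of the Y chromosome does not recombine, so a set of Y
chromosomes is related by a single genealogy and point mutations accumulate
along its branches like ticks of a clock. Given haploid genotype calls at the
sites of the chromosome accessible to short-read sequencing (~10 million
sites), the age of the common ancestor of two clades can be read off the
mutation counts on the lineages descending from it.

`rhodate` implements this programme end to end:

1. **Ingest** haploid genotypes (VCF) with per-sample callable masks (BED)
   into a missing-data-aware genotype matrix.
2. **Build** a phylogeny from pairwise-deletion distances by neighbor
   joining, root it with an outgroup, and **map** every variant site onto a
   branch by Fitch parsimony.
3. **Date** clade divergences with the rho statistic and attach three nested
   confidence intervals.
4. **Contrast** the sequence-based clock with the short-tandem-repeat (STR)
   clock it supersedes, reproducing the saturation mechanism that makes STR
   dates collapse at deep time scales.
5. **Simulate** all of the above with known ground truth, so every stage is
   testable without restricted-access data.

## The rho statistic with pooled low-coverage aggregation

For a clade $C$ with designated ancestor node $a$ (usually the MRCA of the
union of the two clades being dated), each member $s$ contributes the number
of mapped mutations $k_s$ on its path to $a$, restricted to sites callable in
$s$, and its callable-site total $L_s$. The pooled estimate is

$$\hat\rho_C = \frac{\sum_{s \in C} k_s}{\sum_{s \in C} L_s},$$

mutations per site per lineage. Division by a per-site per-year rate $\mu$
converts to years, and a two-clade divergence time averages the two sides:

$$\hat T = \frac{(\hat\rho_A + \hat\rho_B)/2}{\mu}.$$

The pooled (count-sum over callable-sum) form is what makes very-low-coverage
samples usable: a sample that can see 40% of the chromosome contributes about
40% as many mutations and exactly 40% as much denominator, so it neither
biases the estimate nor is discarded. We chose pooling over averaging
per-sample rescaled ratios because the ratio of sums has lower variance when
some $L_s$ are small; the two coincide for fully callable samples. Under
missingness that is independent of genotype, pooling is unbiased — this is
verified by simulation at callable fractions 0.3, 0.5 and 1.0 in the test
suite.

The default rate is $\mu = 0.76 \times 10^{-9}$ mutations/site/year, the
value obtained by ancient-sample calibration (below), with 95% bounds
$(0.67, 0.86) \times 10^{-9}$. The bounds are configuration constants: they
reproduce, via the interval arithmetic below, the published interval
endpoints for the divergence times this calibration was used for, but the
calibration study's own unrounded interval is not available, so they should
be treated as reasonable defaults rather than authoritative.

## Rate calibration by ancient-sample branch shortening

A radiocarbon-dated ancient sample stopped accumulating mutations at its
death, so measured to a shared ancestor its lineage is short by
$\mathrm{age} \times \mu$ mutations per site relative to modern lineages:

$$\hat\mu = \frac{\hat\rho_{\text{modern}} - \hat\rho_{\text{ancient}}}{\text{age}}.$$

`calibrate_rate()` implements this inversion, with both rho pooled (the
modern side over all calibration samples). A non-positive numerator is an
error rather than a rate of zero: it signals mis-rooting or a wrong age. On
simulated 45-ky ancient tips the calibration recovers the generating rate to
within a few percent (mean over 30 replicates in the acceptance script).

## Three nested confidence intervals

* **Rate propagation** (`rate_ci_propagate`): $T$ is inversely proportional
  to $\mu$, so the 95% rate interval maps to
  $(T\mu/\mu_{hi},\; T\mu/\mu_{lo})$. The width relative to $T$ is constant.
* **Site bootstrap** (`site_bootstrap_ci`): resample the callable site
  universe with replacement, recompute the mapping, rho and $T$ on the fixed
  topology, and take the 2.5/97.5 percentiles (linear interpolation, R
  quantile type 7) of the replicate times.
* **Combined** (`combine_ci`): apply the rate bounds multiplicatively to the
  bootstrap endpoints — deliberately conservative, as the two uncertainty
  sources are treated as if they stacked in the worst direction.

Reported times are rounded to 0.1 ky in reports; the functions themselves
return unrounded years.

Two implementation choices deserve explanation.

**The bootstrap resamples the whole site universe, not just variant
columns.** The statistic is a count of rare events spread over ~$10^7$
sites. Resampling only the $M$ observed variant columns with a fixed
multinomial total constrains the replicate totals and provably understates
the variance of a near-linear count statistic (the shortfall is
$(\sum_i c_i)^2 / (M \sum_i c_i^2)$ for site contributions $c_i$, about half
under our study design), which in simulation drives coverage of the 95%
interval down to ~83%. Drawing an $L$-sized multinomial and keeping the
variant categories — realised exactly as a Binomial total distributed
uniformly over the variant columns — makes each column's weight
approximately Poisson(1), matches the Poisson sampling variance of the
mutation process, and restores near-nominal coverage (93/100 in the
acceptance run). The callable denominators $L_s$ are held fixed across
replicates; their resampling variability is relative order $10^{-3}$ and
negligible. A corollary: a matrix whose columns are all identical still has
a non-degenerate (narrow) bootstrap interval, because the resampled variant
total varies.

**Replicates reuse the per-site mapping.** Fitch assignment of a site does
not depend on other sites, so remapping a resampled matrix is exactly the
original per-site assignments weighted by the resampling counts. The
implementation exploits this (one matrix product per replicate) without
changing the procedure's definition.

## Phylogeny construction and mutation mapping

Distances are pairwise-deletion difference rates: discordant non-missing
calls over the mutually callable site count (variant plus invariant). Using
the shared-callable denominator keeps low-coverage samples from collapsing
toward the tree's center. Neighbor joining is delegated to `ape::nj()`;
negative branch lengths are clamped to zero with the deficit moved to the
sibling branch, preserving path lengths through the parent. Outgroup rooting
places the root at the midpoint of the branch separating a (required
monophyletic) outgroup. Tree inference here is deliberately distance-based:
the quantities this package estimates need the deep topology and branch
mutation counts, not maximum-likelihood branch lengths, and the site
bootstrap provides clade support.

Mutation mapping is binary Fitch parsimony with the root constrained to the
ancestral allele (REF, or the `AA` INFO tag when present) and missing calls
treated as compatible with either state. The down-pass prefers the parent
state, so an ambiguous placement resolves toward the older branch. Sites
whose resolution needs more than one state flip are homoplasic and excluded
from dating (logged for audit); under the infinite-sites simulator they do
not occur, and in real data their count is a useful data-quality signal. One
known limitation: if *every* member of a clade is missing at a site as well
as all samples outside it, an ambiguous stem mutation can resolve above the
dating ancestor and be lost to the clade's rho. This requires the
simultaneous masking of all clade members, so it is negligible whenever each
clade contains at least one high-coverage genome (as in the emulated study
design, and as verified by the parameter-recovery tests at mixed coverage).

Haplogroup assignment is hierarchical: the deepest marker with a derived
call wins, missing intermediate markers are tolerated, and derived calls on
incompatible branches raise an error, because on a true tree they cannot
both be right.

## The synthetic-data generator

The generator emulates the study design the pipeline is meant for: two
deeply diverged clades (default split 54 ky, within-clade coalescence
laddered below 40 ky), an outgroup at 70 ky, ~$10^7$ callable sites, mutation
rate $0.76 \times 10^{-9}$/site/year, a mix of fully callable and 40%-callable
samples, an optional 45-ky ancient tip, and a matched 10-locus STR panel.
Mutations are Poisson per branch ($\mu L t$) at distinct uniform sites
(infinite sites; exceeding $L$ is an error, not a silent multi-hit).
Missingness is per site per sample, missing-completely-at-random — the
paper-scale datasets this emulates do not document their low-coverage
missingness mechanism, so the simplest mechanism is used and stated.
Genotypes can be written as haploid or homozygous-diploid VCF (both dialects
occur in public Y data), masks as per-sample BED, and the ground truth as
Newick plus a JSON sidecar.

For $L \le$ `mask_limit` ($2\times10^5$ by default) per-site masks are
materialised exactly, enabling BED output and exact shared-callable counts.
Above that, the identical stochastic process is drawn marginally:
Bernoulli missingness at variant sites plus a Binomial($L - M$, $c_s$)
callable remainder, with shared-callable counts $L_i L_j / L$ (relative
error ~$3\times10^{-4}$ at $10^7$ sites). A single seeded RNG stream with a
fixed draw order (branch counts, site placement, per-sample masks in tip
order) makes every dataset byte-reproducible from its seed.

What the generator does *not* model — sequencing error, ancient-DNA damage,
reference bias, coalescent topology variation within clades, recombination
(absent on the Y) — bounds what passing tests show: they validate the
estimators under their own assumptions, not the upstream genotyping.

## The STR clock and its saturation

Y-STR dating rests on the single-step mutation model: the squared difference
in repeat counts between two lineages separated $t$ generations has
expectation $2\nu t$ for mutation rate $\nu$ per locus per generation, so
`str_tmrca()` inverts the cross-group average squared distance (ASD). With a
*bounded* allele range — reflecting boundaries at $\pm 10$ repeat units
around the ancestral allele, a typical Y-STR spread — the walk forgets its
starting point after the mixing time (order bound² mutation events, roughly
45 for a ±10 range) and ASD plateaus at twice the stationary variance,
$2 \times (21^2 - 1)/12 \approx 73$, capping the estimator near
$73 / (2\nu) \times 25 \approx 440$ ky for the genealogical rate
$\nu = 2.08\times10^{-3}$ per 25-year generation.

`saturation_experiment()` makes this quantitative: on matched genealogies it
dates each split with the STR clock and with the sequence pipeline. The
sequence estimator tracks the truth at every time scale tested; the STR
clock is near-unbiased in the linear regime and collapses far below the
truth once $2\nu t / 25$ approaches the plateau. A caveat worth stating
plainly: at a 50-ky split with $\nu = 2.08\times10^{-3}$ each lineage takes
only ~4 mutational steps per locus, far from the $\pm10$ boundary, so under
these exact parameters saturation is mild (bias ratio ~0.95); the collapse
becomes dramatic for splits beyond a few hundred thousand years or for
faster rates/tighter bounds. Historical STR-based underestimates of deep
divergences therefore plausibly combine saturation with an assumed rate that
is too fast and a generation time that is too short — the mechanism is
implemented and configurable here, but saturation alone does not halve a
50-ky estimate at the genealogical rate.

## Numerical and design choices

* Ties everywhere (neighbor joining Q-criterion via `ape`, marker depth,
  sibling choice when clamping) resolve by lowest index/lexicographic order;
  reruns are bit-identical given the seed.
* Percentile bootstrap, not BCa: with 100 replicates the plain 2.5/97.5
  percentiles are the most defensible reading of a 95% interval.
* Heterozygous diploid calls on the haploid Y are set missing and counted —
  a cheap genotype-quality proxy.
* Reference-implied ancestral calls during cohort merging are made only
  inside a sample's callable mask, so low-coverage absence is never read as
  the ancestral state.
* Divergence clades may be given as leaf lists or haplogroup labels; both
  are validated for monophyly on the inferred tree before dating.

## Problem sizes

The test suite and acceptance script run entirely on simulated data at the
study's design scale where cheap ($L = 10^7$ for point estimation, mutation
counts are what matter and number in the thousands) and scaled to $L = 10^6$
for the 100-outer-replicate bootstrap-coverage study (10,000 tree/bootstrap
recomputations). Parameter-recovery experiments use 25–50 replicates;
Monte-Carlo assertions use 3-standard-error tolerances computed from the
replicates themselves.

## A worked call

```{r}
tree <- two_clade_tree(t_split = 54000, t_within = 40000, t_outgroup = 70000)
cfg <- sim_config(tree, coverage = 1.0, seed = 7)
sim <- simulate_snv_dataset(cfg)
gm <- sim$matrix
rt <- root_by_outgroup(neighbor_joining(pairwise_distances(gm)), "OUT")
ht <- map_mutations_parsimony(rt, gm)
est <- divergence_time(ht, gm, sprintf("AUS%d", 1:5), sprintf("ASN%d", 1:5),
                       rate = mutation_rate(), n_boot = 100, seed = 7)
tidy(est)
```
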