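# rhodate

Divergence dating for the human Y chromosome (and any non-recombining
haploid locus) from complete sequence data, built around the **ρ statistic
with pooled low-coverage aggregation**.

Deep population splits — such as the divergence of Aboriginal Australian and
Papuan Y lineages from their closest mainland-Asian relatives — can be dated
directly from the mutations accumulated on a non-recombining chromosome. For
a clade \(C\) with ancestor node \(a\), each member \(s\) contributes its
mapped mutation count \(k_s\) on the path to \(a\) (restricted to sites
callable in \(s\)) and its callable total \(L_s\):

    ρ̂_C = Σ k_s / Σ L_s          (mutations per site per lineage)
    T̂   = ((ρ̂_A + ρ̂_B) / 2) / μ  (years, with μ per site per year)

with μ = 0.76 × 10⁻⁹/site/year calibrated from the branch shortening of a
radiocarbon-dated ancient genome, μ̂ = (ρ̂_modern − ρ̂_ancient)/age. Three
nested 95% confidence intervals accompany every date: rate propagation
(T·μ/μ_hi, T·μ/μ_lo), a site bootstrap over the full callable universe, and
their conservative multiplicative combination. The package also implements
the Y-STR dating approach this methodology supersedes (average squared
distance under the stepwise mutation model, E[ASD] = 2νt) together with a
saturation experiment showing why bounded STR alleles cannot date deep
splits.

Everything runs on a known-truth synthetic generator — infinite-sites SNVs
on a user-specified genealogy with per-sample callable masks, optional
ancient tips, and a matched STR panel — so the whole pipeline is testable
without restricted-access genomes, while accepting standard VCF/BED/TSV for
real data.

## Worked example

Simulate the emulated study design — two five-genome clades splitting 54 ky
ago (three high-coverage and two 40%-callable genomes each), an outgroup at
70 ky, 10⁷ callable sites — then build the tree, map mutations, and date the
split:

```r
library(rhodate)

tree <- two_clade_tree(t_split = 54000, t_within = 40000, t_outgroup = 70000)
cv   <- setNames(c(rep(c(1, 1, 1, .4, .4), 2), 1), tree$tip.label)
sim  <- simulate_snv_dataset(sim_config(tree, coverage = cv, seed = 7))
gm   <- sim$matrix
gm
#> <geno_matrix> 11 samples x 2876 variant sites (universe L = 1e+07)
#>   missing calls: 21.5%; per-sample callable L_s in [3,997,328, 1e+07]

rt  <- root_by_outgroup(neighbor_joining(pairwise_distances(gm)), "OUT")
ht  <- map_mutations_parsimony(rt, gm)
est <- divergence_time(ht, gm, sprintf("AUS%d", 1:5), sprintf("ASN%d", 1:5),
                       rate = mutation_rate(), n_boot = 100, seed = 7)
est
#> <time_estimate> T = 56.5 ky (rate CI 50.0-64.1 ky)
#>   bootstrap CI 54.0-59.6 ky; combined 47.7-67.6 ky (100 reps)
```

The point estimate reads 56.5 ky against a true split of 54 ky — single
replicates scatter a few percent because the mutation counts are Poisson —
and the combined interval (47.7–67.6 ky) comfortably covers the truth. Over
50 replicate simulations the mean estimate is within 0.1% of 54 ky (the
acceptance script below recomputes this). `tidy(est)` returns the same
numbers as a one-row tibble, and `make_report()` renders a markdown table:

```
| clade pair | T (ky) | rate CI | bootstrap CI | combined CI |
|---|---|---|---|---|
| AUS vs ASN | 56.5 | 50.0-64.1 | 54.0-59.6 | 47.7-67.6 |
```

The same flow runs from files and a single YAML config through
`run_pipeline()` (VCF + per-sample BED masks + panel TSV in; Newick tree,
support/haplogroup/dating TSVs and JSON out), with clades specified as leaf
lists or as haplogroup labels resolved through a marker table
(`assign_haplogroups()`, e.g. C-M347, M-M186). For the STR contrast, see
`saturation_experiment()` and its `autoplot()` method.

## Layout

- `R/` — simulator, ingestion, phylogeny/parsimony, ρ dating and CIs, STR
  dating, pipeline orchestration, tidy/plot methods.
- `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
- `vignettes/rho-dating.Rmd` — the methods vignette: model, assumptions,
  design choices, limitations.
- `inst/extdata/demo_markers.tsv` — a small demonstration haplogroup marker
  table (marker names and hierarchy as used in the field; positions are
  synthetic demo coordinates).
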