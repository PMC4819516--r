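Package: rhodate
Title: Rho-Statistic Divergence Dating for Non-Recombining Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Divergence dating for haploid, non-recombining sequence data
    (the human Y chromosome in particular) using the rho statistic with
    pooled aggregation across low-coverage samples. Includes a
    known-truth synthetic-data generator (infinite-sites single-nucleotide
    variants with per-sample callable masks, optional ancient tips, and a
    matched stepwise-mutation-model STR panel), VCF/BED ingestion into a
    missing-data-aware genotype matrix, neighbor-joining phylogeny
    construction with pairwise-deletion distances and outgroup rooting,
    Fitch parsimony mutation mapping, site-bootstrap clade support,
    marker-based haplogroup assignment, mutation-rate calibration from
    ancient-sample branch shortening, three nested confidence-interval
    procedures (rate propagation, site bootstrap, multiplicative
    combination), and an STR average-squared-distance TMRCA estimator
    with a saturation-bias experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
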