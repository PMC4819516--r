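#' Mutation rate with 95% bounds
#'
#' Per-site per-year point rate and its 95% interval. The defaults are the
#' calibration used throughout the package: a point rate of 0.76e-9 derived
#' from ancient-sample branch shortening, with multiplicative 95% bounds
#' (0.67e-9, 0.86e-9).
#'
#' @param point per-site per-year rate.
#' @param lo,hi 95% bounds, same units, `0 < lo <= point <= hi`.
#' @return an object of class `mutation_rate`.
#' @export
mutation_rate <- function(point = 0.76e-9, lo = 0.67e-9, hi = 0.86e-9) {
  if (!(0 < lo && lo <= point && point <= hi)) {
    stop("rate bounds must satisfy 0 < lo <= point <= hi")
  }
  structure(list(point = point, lo = lo, hi = hi), class = "mutation_rate")
}

#' @export
print.mutation_rate <- function(x, ...) {
  cat(sprintf("<mutation_rate> %.3g /site/yr (95%%: %.3g - %.3g)\n",
              x$point, x$lo, x$hi))
  invisible(x)
}

#' The rho statistic with pooled low-coverage aggregation
#'
#' For each leaf `s` of the clade, counts the mapped mutations on the path
#' from `s` up to `ancestor`, restricted to sites callable (non-missing) in
#' `s`; the pooled estimate is the summed count divided by the summed
#' per-sample callable totals, `rho = sum(count_s) / sum(L_s)`. The pooled
#' (count-sum over callable-sum) form is what makes very-low-coverage
#' samples usable: each sample contributes mutations in proportion to the
#' fraction of the chromosome it can see.
#'
#' @param ht a [map_mutations_parsimony()] result.
#' @param gm the [geno_matrix()] the mapping was computed from.
#' @param clade character vector of tip labels.
#' @param ancestor internal node number; defaults to the clade's MRCA.
#' @return an object of class `rho_estimate`: list with `clade`, `ancestor`,
#'   `count` (pooled), `total` (pooled callable sites), `rho_per_site`, and
#'   the per-sample counts.
#' @export
rho <- function(ht, gm, clade, ancestor = NULL) {
  stopifnot(inherits(ht, "haplo_tree"))
  tree <- ht$tree
  if (!all(clade %in% tree$tip.label)) {
    stop("unknown clade leaves: ",
         paste(setdiff(clade, tree$tip.label), collapse = ", "))
  }
  if (!length(clade)) stop("empty clade")
  tips <- match(clade, tree$tip.label)
  if (is.null(ancestor)) {
    ancestor <- if (length(tips) == 1L) tree$edge[match(tips, tree$edge[, 2L]), 1L] else
      ape::getMRCA(tree, clade)
  }
  counts <- stats::setNames(numeric(length(clade)), clade)
  for (k in seq_along(clade)) {
    sites <- unlist(ht$edge_sites[path_edges(tree, tips[k], ancestor)])
    counts[k] <- if (length(sites)) {
      sum(!is.na(gm$calls[clade[k], sites]))
    } else 0
  }
  total <- sum(gm$L_s[clade])
  if (total <= 0) stop("pooled callable total is zero for clade")
  structure(
    list(clade = clade, ancestor = ancestor,
         count = sum(counts), total = total,
         rho_per_site = sum(counts) / total,
         sample_counts = counts),
    class = "rho_estimate"
  )
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("<rho_estimate> %d leaves to node %d: %g mutations / %s callable = %.4g per site\n",
              length(x$clade), x$ancestor, x$count,
              format(x$total, big.mark = ","), x$rho_per_site))
  invisible(x)
}

#' Divergence time between two clades from the rho statistic
#'
#' Both clades' rho are measured to the MRCA of their union and averaged;
#' division by the point rate converts to years:
#' `T = ((rho_A + rho_B) / 2) / rate`. Optionally attaches all three
#' confidence intervals: rate propagation ([rate_ci_propagate()]), site
#' bootstrap ([site_bootstrap_ci()]), and the conservative multiplicative
#' combination ([combine_ci()]).
#'
#' @param ht a [map_mutations_parsimony()] result.
#' @param gm the matching [geno_matrix()].
#' @param clade_a,clade_b character vectors of tip labels (disjoint,
#'   non-empty).
#' @param rate a [mutation_rate()].
#' @param n_boot number of site-bootstrap replicates (0 to skip the
#'   bootstrap CIs).
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `time_estimate`: `T_years`, `rho_a`, `rho_b`,
#'   `rate`, `ci_rate`, and when bootstrapped `ci_boot`, `ci_combined`,
#'   `replicates`.
#' @export
divergence_time <- function(ht, gm, clade_a, clade_b, rate = mutation_rate(),
                            n_boot = 0L, seed = 1L) {
  if (!length(clade_a) || !length(clade_b)) stop("empty clade")
  if (length(intersect(clade_a, clade_b))) stop("clades must be disjoint")
  mrca <- ape::getMRCA(ht$tree, c(clade_a, clade_b))
  ra <- rho(ht, gm, clade_a, ancestor = mrca)
  rb <- rho(ht, gm, clade_b, ancestor = mrca)
  T_years <- (ra$rho_per_site + rb$rho_per_site) / 2 / rate$point
  out <- structure(
    list(clade_a = clade_a, clade_b = clade_b, mrca = mrca,
         rho_a = ra, rho_b = rb, rate = rate,
         T_years = T_years,
         ci_rate = rate_ci_propagate(T_years, rate)),
    class = "time_estimate"
  )
  if (n_boot >= 2L) {
    bs <- site_bootstrap_ci(ht, gm, clade_a, clade_b, rate,
                            n_reps = n_boot, seed = seed)
    out$ci_boot <- bs$ci
    out$replicates <- bs$replicates
    out$ci_combined <- combine_ci(bs$ci, rate)
  }
  out
}

#' @export
print.time_estimate <- function(x, ...) {
  cat(sprintf("<time_estimate> T = %.1f ky (rate CI %.1f-%.1f ky)\n",
              x$T_years / 1000, x$ci_rate[1] / 1000, x$ci_rate[2] / 1000))
  if (!is.null(x$ci_boot)) {
    cat(sprintf("  bootstrap CI %.1f-%.1f ky; combined %.1f-%.1f ky (%d reps)\n",
                x$ci_boot[1] / 1000, x$ci_boot[2] / 1000,
                x$ci_combined[1] / 1000, x$ci_combined[2] / 1000,
                length(x$replicates)))
  }
  invisible(x)
}

#' Propagate mutation-rate uncertainty into a time interval
#'
#' `lo = T * point / hi`, `hi = T * point / lo`: a faster rate shrinks the
#' inferred time, a slower rate stretches it. Returned in years, unrounded;
#' reports round to 0.1 ky.
#'
#' @param T_years point divergence time in years.
#' @param rate a [mutation_rate()].
#' @return numeric `c(lo, hi)` in years.
#' @export
rate_ci_propagate <- function(T_years, rate) {
  c(T_years * rate$point / rate$hi, T_years * rate$point / rate$lo)
}

#' Conservative multiplicative combination of bootstrap and rate CIs
#'
#' Applies the rate uncertainty multiplicatively to the bootstrap interval
#' endpoints: `lo = boot_lo * point / hi`, `hi = boot_hi * point / lo`.
#'
#' @param boot_ci numeric `c(lo, hi)` in years (a site-bootstrap CI).
#' @param rate a [mutation_rate()].
#' @return numeric `c(lo, hi)` in years.
#' @export
combine_ci <- function(boot_ci, rate) {
  c(boot_ci[1] * rate$point / rate$hi, boot_ci[2] * rate$point / rate$lo)
}

#' Site-bootstrap confidence interval for a divergence time
#'
#' Resamples the callable site universe with replacement and recomputes the
#' pooled-rho divergence time on the fixed topology for each replicate; the
#' CI is the 2.5/97.5 percentile pair (linear interpolation). Because the
#' parsimony assignment of a site does not depend on the other sites, a
#' replicate's remapped branch counts equal the original per-site
#' assignments weighted by the resampling counts, which is how the
#' replicates are computed (see the vignette). Deterministic given `seed`.
#'
#' @param ht a [map_mutations_parsimony()] result (fixed topology).
#' @param gm the matching [geno_matrix()].
#' @param clade_a,clade_b tip-label vectors; must be clades on the fixed
#'   topology.
#' @param rate a [mutation_rate()].
#' @param n_reps bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @return list with `ci` (years, `c(lo, hi)`) and `replicates` (years).
#' @export
site_bootstrap_ci <- function(ht, gm, clade_a, clade_b, rate = mutation_rate(),
                              n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 2L)
  tree <- ht$tree
  for (cl in list(clade_a, clade_b)) {
    if (length(cl) > 1L && !has_clade(tree, cl)) {
      stop("clade {", paste(cl, collapse = ","),
           "} is not monophyletic on the fixed topology")
    }
  }
  set.seed(seed)
  mrca <- ape::getMRCA(tree, c(clade_a, clade_b))
  M <- ncol(gm$calls)
  path_ind <- function(clade) {
    tips <- match(clade, tree$tip.label)
    t(vapply(seq_along(clade), function(k) {
      on_path <- logical(M)
      sites <- unlist(ht$edge_sites[path_edges(tree, tips[k], mrca)])
      on_path[sites] <- TRUE
      on_path & !is.na(gm$calls[clade[k], ])
    }, logical(M)))
  }
  A <- path_ind(clade_a) * 1
  B <- path_ind(clade_b) * 1
  tot_a <- sum(gm$L_s[clade_a]); tot_b <- sum(gm$L_s[clade_b])
  reps <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    w <- boot_site_weights(M, gm$L)
    rho_a <- sum(A %*% w) / tot_a
    rho_b <- sum(B %*% w) / tot_b
    reps[r] <- (rho_a + rho_b) / 2 / rate$point
  }
  ci <- unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
  list(ci = ci, replicates = reps)
}

#' Calibrate the point mutation rate from an ancient tip's branch shortening
#'
#' An ancient sample's lineage stops accumulating mutations at its death, so
#' relative to modern lineages measured to the same shared ancestor it is
#' short by `age * rate` mutations per site. Inverting:
#' `rate = (rho_modern - rho_ancient) / age`, with both rho measured to the
#' shared ancestor and rho_modern pooled over the modern tips.
#'
#' @param ht a [map_mutations_parsimony()] result.
#' @param gm the matching [geno_matrix()].
#' @param ancient_tip tip label of the dated ancient sample.
#' @param age_years the sample's age (> 0).
#' @param modern_tips modern tips sharing the calibration ancestor; defaults
#'   to all other tips descending from the MRCA of the whole tree minus
#'   outgroup handling — pass explicitly for anything non-trivial.
#' @return a [mutation_rate()] with degenerate bounds at the point estimate.
#' @export
calibrate_rate <- function(ht, gm, ancient_tip, age_years,
                           modern_tips = setdiff(ht$tree$tip.label, ancient_tip)) {
  if (age_years <= 0) stop("age must be > 0")
  anc <- ape::getMRCA(ht$tree, c(ancient_tip, modern_tips))
  r_mod <- rho(ht, gm, modern_tips, ancestor = anc)
  r_anc <- rho(ht, gm, ancient_tip, ancestor = anc)
  num <- r_mod$rho_per_site - r_anc$rho_per_site
  if (num <= 0) {
    stop("modern rho (", signif(r_mod$rho_per_site, 4),
         ") does not exceed ancient rho (", signif(r_anc$rho_per_site, 4),
         "); negative rate — check rooting and the sample age")
  }
  pt <- num / age_years
  mutation_rate(pt, pt, pt)
}
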