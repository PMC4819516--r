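#' Simulation configuration
#'
#' Bundles everything the synthetic-data generators need: a rooted genealogy
#' with branch lengths in years, a per-site per-year point mutation rate, the
#' size of the callable site universe, per-sample callable fractions, the STR
#' panel settings, and optional ancient tips.
#'
#' Defaults are the study conditions the pipeline is meant to emulate:
#' mu = 0.76e-9 mutations/site/year, L = 1e7 callable sites, a 10-locus STR
#' panel mutating at 2.08e-3 per locus per 25-year generation, and allele
#' excursions bounded at +-10 repeat steps from the root allele.
#'
#' @param tree a rooted `ape::phylo` with `edge.length` in years. Modern tips
#'   must be contemporaneous (age 0); tips listed in `ancient_tips` sit above
#'   the present by their stated age.
#' @param mu per-site per-year mutation rate (>= 0; 0 gives a variant-free
#'   dataset).
#' @param L callable site count (integer >= 1).
#' @param coverage named vector of per-sample callable fractions c_s in
#'   (0, 1]; names must cover all tips. A single unnamed value is recycled.
#' @param populations optional named character vector tip -> population label
#'   for the emitted sample panel.
#' @param str_loci number of STR loci.
#' @param str_rate per-locus per-generation stepwise mutation rate (> 0).
#' @param generation_years years per generation for the STR clock.
#' @param str_bound reflecting boundary, in repeat steps either side of the
#'   root allele (`Inf` for an unbounded walk).
#' @param str_root_allele repeat length at the root.
#' @param ancient_tips named numeric vector tip -> age in years (may be empty).
#' @param seed integer RNG seed; the generators are deterministic given it.
#' @param mask_limit largest `L` for which exact per-site masks are
#'   materialised (enables BED output and exact shared-callable counts);
#'   above it, missingness is drawn marginally (same process, see vignette).
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(tree, mu = 0.76e-9, L = 1e7, coverage = 1.0,
                       populations = NULL,
                       str_loci = 10L, str_rate = 2.08e-3,
                       generation_years = 25, str_bound = 10,
                       str_root_allele = 20L,
                       ancient_tips = numeric(0), seed = 1L,
                       mask_limit = 2e5) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (mu < 0) stop("mu must be >= 0")
  if (L < 1) stop("L must be >= 1")
  if (str_rate <= 0) stop("str_rate must be > 0")
  tips <- tree$tip.label
  if (length(coverage) == 1L && is.null(names(coverage))) {
    coverage <- stats::setNames(rep(coverage, length(tips)), tips)
  }
  if (!all(tips %in% names(coverage))) stop("coverage must name every tip")
  coverage <- coverage[tips]
  if (any(coverage <= 0 | coverage > 1)) stop("coverage fractions must be in (0, 1]")
  ages <- node_ages(tree)
  tip_ages <- ages[seq_along(tips)]
  declared <- stats::setNames(rep(0, length(tips)), tips)
  if (length(ancient_tips)) declared[names(ancient_tips)] <- ancient_tips
  if (any(abs(tip_ages - declared[tips]) > 1e-6 * max(ages, 1))) {
    stop("tip depths inconsistent with declared ancient-tip ages ",
         "(modern tips must be contemporaneous)")
  }
  structure(
    list(tree = tree, mu = mu, L = as.double(L), coverage = coverage,
         populations = populations,
         str_loci = as.integer(str_loci), str_rate = str_rate,
         generation_years = generation_years, str_bound = str_bound,
         str_root_allele = as.integer(str_root_allele),
         ancient_tips = ancient_tips, seed = as.integer(seed),
         mask_limit = mask_limit),
    class = "sim_config"
  )
}

#' Node ages in years from a rooted tree with year-scaled branch lengths
#'
#' Ages are measured back from the youngest tip (age 0).
#' @param tree rooted `ape::phylo` with `edge.length` in years.
#' @return numeric vector of ages indexed by ape node number.
#' @export
node_ages <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_node)
  eo <- rev(ape::postorder(tree))  # parents before children
  for (e in eo) {
    depth[tree$edge[e, 2L]] <- depth[tree$edge[e, 1L]] + tree$edge.length[e]
  }
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Two-clade demonstration genealogy
#'
#' Builds the design the package's synthetic experiments use throughout: two
#' monophyletic clades (think Sahul C chromosomes versus their closest
#' mainland-Asian relatives) splitting `t_split` years ago, each coalescing
#' internally in a ladder starting at `t_within`, plus an optional outgroup
#' diverging at `t_outgroup` and an optional ancient tip "ANC" branching off
#' at the split.
#'
#' @param n_a,n_b tips per clade (>= 1).
#' @param t_split split time of the two clades, years.
#' @param t_within within-clade MRCA age, years (< `t_split`); internal node
#'   ages are evenly spaced below it.
#' @param t_outgroup outgroup divergence, years (> `t_split`); `NULL` for none.
#' @param ancient_age if non-`NULL`, adds a tip "ANC" of this age branching
#'   off at `t_split` (used for rate calibration).
#' @param labels_a,labels_b,label_out tip label prefixes.
#' @return a rooted `ape::phylo` with branch lengths in years, ultrametric up
#'   to declared ancient tips.
#' @export
two_clade_tree <- function(n_a = 5, n_b = 5, t_split = 54000,
                           t_within = 40000, t_outgroup = 70000,
                           ancient_age = NULL,
                           labels_a = "AUS", labels_b = "ASN",
                           label_out = "OUT") {
  stopifnot(t_within < t_split, is.null(t_outgroup) || t_outgroup > t_split)
  a_lab <- sprintf("%s%d", labels_a, seq_len(n_a))
  b_lab <- sprintf("%s%d", labels_b, seq_len(n_b))
  clade_part <- function(labels) {
    if (length(labels) == 1L) return(sprintf("%s:%s", labels, fmt_yr(t_split)))
    sprintf("%s:%s", ladder_newick(labels, t_within), fmt_yr(t_split - t_within))
  }
  core <- sprintf("(%s,%s)", clade_part(a_lab), clade_part(b_lab))
  if (!is.null(ancient_age)) {
    stopifnot(ancient_age < t_split)
    core <- sprintf("(%s:0,ANC:%s)", core, fmt_yr(t_split - ancient_age))
  }
  if (!is.null(t_outgroup)) {
    core <- sprintf("(%s:%s,%s:%s)", core, fmt_yr(t_outgroup - t_split),
                    label_out, fmt_yr(t_outgroup))
  }
  ape::read.tree(text = paste0(core, ";"))
}

fmt_yr <- function(x) format(x, scientific = FALSE, trim = TRUE)

# Newick for a clade whose MRCA sits at height t_top, without the stem branch.
# Internal nodes laddered at heights t_top * (n-1):1 / (n-1).
ladder_newick <- function(labels, t_top) {
  n <- length(labels)
  if (n == 1L) return(sprintf("%s:%s", labels[1], fmt_yr(t_top)))
  hts <- t_top * ((n - 1L):1L) / (n - 1L)
  nwk <- sprintf("(%s:%s,%s:%s)", labels[n - 1L], fmt_yr(hts[n - 1L]),
                 labels[n], fmt_yr(hts[n - 1L]))
  h_prev <- hts[n - 1L]
  if (n >= 3L) {
    for (k in (n - 2L):1L) {
      nwk <- sprintf("(%s:%s,%s:%s)", labels[k], fmt_yr(hts[k]), nwk,
                     fmt_yr(hts[k] - h_prev))
      h_prev <- hts[k]
    }
  }
  nwk
}
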