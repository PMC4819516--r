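#' Simulate a Y-STR panel on a genealogy under the stepwise mutation model
#'
#' Each locus evolves independently along the tree: mutation events on a
#' branch are Poisson with mean `rate * branch_years / generation_years`, and
#' each event moves the repeat length by +1 or -1 with equal probability.
#' Excursions are reflected at `str_root_allele +- str_bound` (a bounded
#' allele range is what makes STR distances saturate at deep time scales);
#' set `str_bound = Inf` for the unbounded walk.
#'
#' @param config a [sim_config()] (uses `tree`, `str_loci`, `str_rate`,
#'   `generation_years`, `str_bound`, `str_root_allele`, `seed`).
#' @param seed optional override of `config$seed` (so an SNV and an STR panel
#'   can be drawn independently from one configuration).
#' @return an object of class `str_panel`: list with `lengths` (samples x
#'   loci integer matrix), `loci`, `rate_per_gen`, `generation_years`,
#'   `bound`, `root_allele`, and `truth` (per-edge per-locus event counts).
#' @export
simulate_str_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$str_rate <= 0) stop("STR mutation rate must be > 0")
  set.seed(seed)
  tree <- config$tree
  tips <- tree$tip.label
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  n_loci <- config$str_loci
  gens <- tree$edge.length / config$generation_years
  bounded <- is.finite(config$str_bound)
  lb <- config$str_root_allele - config$str_bound
  ub <- config$str_root_allele + config$str_bound

  alleles <- matrix(NA_integer_, nrow = n_node, ncol = n_loci)
  alleles[n_tip + 1L, ] <- config$str_root_allele
  eo <- rev(ape::postorder(tree))  # parents before children
  event_counts <- matrix(0L, nrow = nrow(tree$edge), ncol = n_loci)
  for (e in eo) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    n_ev <- stats::rpois(n_loci, config$str_rate * gens[e])
    event_counts[e, ] <- n_ev
    x <- alleles[p, ]
    for (l in which(n_ev > 0L)) {
      xi <- x[l]
      for (s in sample(c(-1L, 1L), n_ev[l], replace = TRUE)) {
        xi <- xi + s
        if (bounded) {
          if (xi > ub) xi <- 2L * as.integer(ub) - xi
          if (xi < lb) xi <- 2L * as.integer(lb) - xi
        }
      }
      x[l] <- xi
    }
    alleles[ch, ] <- x
  }
  lengths <- alleles[seq_len(n_tip), , drop = FALSE]
  dimnames(lengths) <- list(tips, sprintf("STR%02d", seq_len(n_loci)))
  structure(
    list(lengths = lengths, loci = colnames(lengths),
         rate_per_gen = config$str_rate,
         generation_years = config$generation_years,
         bound = config$str_bound, root_allele = config$str_root_allele,
         truth = list(tree = tree, event_counts = event_counts)),
    class = "str_panel"
  )
}

#' @export
print.str_panel <- function(x, ...) {
  cat(sprintf("<str_panel> %d samples x %d loci, rate %.3g/locus/generation (%g y), bound +-%s\n",
              nrow(x$lengths), ncol(x$lengths), x$rate_per_gen,
              x$generation_years, format(x$bound)))
  invisible(x)
}
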