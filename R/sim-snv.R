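#' Simulate an infinite-sites haploid SNV dataset with known ground truth
#'
#' Mutations fall on each branch as Poisson(mu * L * branch_years) events,
#' each at a distinct uniformly chosen site in `1:L` (infinite sites; a
#' request for more mutations than sites is an error advising a larger `L`).
#' A tip carries the derived allele at a site exactly when the mutation's
#' branch lies on its path to the root. Each sample's callable mask drops
#' every site independently with probability `1 - c_s`; masked genotypes are
#' missing. Everything is deterministic given `config$seed`.
#'
#' For `L <= config$mask_limit` the per-site masks are materialised exactly
#' (required for BED output via [write_sim_dataset()]); above that, the same
#' missingness process is drawn marginally: Bernoulli at the variant sites
#' and a Binomial(L - M, c_s) callable count for the invariant remainder.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_dataset`: a list with the analysis-ready
#'   [geno_matrix()] (`$matrix`, variant-filtered; `$matrix_full` keeps sites
#'   with no observed derived call), the ground truth (`$truth`: the tree,
#'   per-edge mutation positions and counts), the per-sample panel tibble,
#'   and the exact masks when materialised.
#' @export
simulate_snv_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  tips <- tree$tip.label
  S <- length(tips)
  L <- config$L
  n_edge <- nrow(tree$edge)

  # 1) mutation counts per edge (edge order as stored in tree$edge)
  edge_mu <- config$mu * L * tree$edge.length
  edge_n <- stats::rpois(n_edge, edge_mu)
  M <- sum(edge_n)
  if (M > L) {
    stop("infinite-sites violation: ", M, " mutations requested for L = ", L,
         " sites; increase L")
  }

  # 2) distinct sites, assigned to edges in edge order
  sites <- if (M > 0) sort(sample.int(L, M)) else integer(0)
  # shuffle so edge assignment is independent of coordinate
  perm <- if (M > 0) sample.int(M) else integer(0)
  edge_of_site <- integer(M)       # index into tree$edge rows, by site order
  idx <- 0L
  edge_sites <- vector("list", n_edge)
  for (e in seq_len(n_edge)) {
    if (edge_n[e] == 0L) { edge_sites[[e]] <- integer(0); next }
    take <- perm[(idx + 1L):(idx + edge_n[e])]
    edge_sites[[e]] <- sites[take]
    edge_of_site[take] <- e
    idx <- idx + edge_n[e]
  }

  # 3) tip genotypes: derived iff mutation edge on tip's root path
  desc <- edge_descendant_tips(tree)          # list per edge of tip indices
  calls <- matrix(0L, nrow = S, ncol = M, dimnames = list(tips, NULL))
  for (e in seq_len(n_edge)) {
    if (edge_n[e] > 0L) calls[desc[[e]], match(edge_sites[[e]], sites)] <- 1L
  }

  # 4) masks / missingness, per sample in tip order
  cvg <- config$coverage
  masks <- NULL
  if (L <= config$mask_limit) {
    masks <- matrix(FALSE, nrow = S, ncol = L, dimnames = list(tips, NULL))
    for (s in seq_len(S)) masks[s, ] <- stats::runif(L) < cvg[s]
    L_s <- stats::setNames(rowSums(masks), tips)
    if (M > 0) calls[!masks[, sites, drop = FALSE]] <- NA_integer_
    mm <- masks * 1
    shared <- mm %*% t(mm)
  } else {
    for (s in seq_len(S)) {
      if (cvg[s] < 1 && M > 0) {
        calls[s, stats::runif(M) >= cvg[s]] <- NA_integer_
      }
    }
    inv_call <- stats::rbinom(S, L - M, cvg)
    L_s <- stats::setNames(inv_call + rowSums(!is.na(calls)), tips)
    shared <- round(outer(L_s, L_s) / L)
    diag(shared) <- L_s
  }

  panel <- tibble::tibble(
    sample_id = tips,
    population = if (!is.null(config$populations)) {
      unname(config$populations[tips])
    } else sub("[0-9]+$", "", tips),
    coverage_class = ifelse(cvg >= 0.8, "high", "low"),
    haplogroup_truth = NA_character_
  )

  gm_full <- geno_matrix(calls, positions = sites, L = L, L_s = L_s,
                         shared_callable = shared, panel = panel)
  truth <- list(tree = tree, edge_sites = edge_sites, edge_counts = edge_n,
                edge_of_site = edge_of_site, sites = sites,
                mu = config$mu, L = L)
  structure(
    list(matrix = drop_uninformative_sites(gm_full), matrix_full = gm_full,
         truth = truth, panel = panel,
         masks = masks, config = config),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d samples, %d true mutations (%d observable), L = %s\n",
              nrow(x$matrix_full$calls), length(x$truth$sites),
              ncol(x$matrix$calls), format(x$truth$L, big.mark = ",")))
  invisible(x)
}

# tip indices descending from each edge's child node
edge_descendant_tips <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  below <- vector("list", n_node)
  for (i in seq_len(n_tip)) below[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below[[tree$edge[e, 2L]]])
}

#' True divergence time between two clades under a simulated genealogy
#'
#' Reads the age of the MRCA of the union of the two leaf sets off the
#' ground-truth tree.
#' @param truth the `$truth` element of a [simulate_snv_dataset()] result, or
#'   any rooted tree with year-scaled branch lengths.
#' @param clade_a,clade_b character vectors of tip labels.
#' @return age in years.
#' @export
true_divergence_time <- function(truth, clade_a, clade_b) {
  tree <- if (inherits(truth, "phylo")) truth else truth$tree
  mrca <- ape::getMRCA(tree, c(clade_a, clade_b))
  node_ages(tree)[mrca]
}
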