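#' Pairwise-deletion per-site distance between two samples
#'
#' The number of sites with discordant non-missing calls, divided by the
#' number of sites callable in both samples — the variant matrix plus the
#' shared callable invariant remainder. Using the shared-callable denominator
#' keeps low-coverage samples from being pulled toward artificially short
#' branches.
#'
#' @param gm a [geno_matrix()].
#' @param i,j sample ids or indices.
#' @return per-site difference rate (scalar).
#' @export
pairwise_distance <- function(gm, i, j) {
  D <- pairwise_distances(gm)
  D[i, j]
}

#' All pairwise-deletion distances
#'
#' @param gm a [geno_matrix()].
#' @return a symmetric samples x samples matrix of per-site difference rates.
#' @export
pairwise_distances <- function(gm) {
  A <- (gm$calls == 1L) & !is.na(gm$calls)
  P <- !is.na(gm$calls)
  storage.mode(A) <- "double"; storage.mode(P) <- "double"
  B <- P - A                                   # callable & ancestral
  discord <- A %*% t(B) + B %*% t(A)
  denom <- gm$shared_callable
  if (any(denom[upper.tri(denom)] <= 0)) {
    bad <- which(denom <= 0 & upper.tri(denom), arr.ind = TRUE)
    stop("no mutually callable sites for pair(s): ",
         paste(rownames(denom)[bad[, 1]], colnames(denom)[bad[, 2]],
               sep = "/", collapse = ", "))
  }
  d <- discord / denom
  diag(d) <- 0
  d
}

#' Neighbor-joining tree with deterministic post-processing
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]) followed by the
#' package's deterministic clean-up: any negative branch length is clamped to
#' zero and its deficit moved to the sibling branch (preserving tip-to-tip
#' path lengths through the parent node), with residual negatives clamped.
#'
#' @param d symmetric distance matrix (>= 3 taxa, finite entries).
#' @return an unrooted `ape::phylo`.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs >= 3 taxa")
  if (any(!is.finite(d))) stop("distances must be finite")
  if (max(abs(d - t(d))) > 1e-12 * max(1, max(abs(d)))) {
    stop("distance matrix is not symmetric")
  }
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sibs)) {
      sib <- sibs[order(tr$edge[sibs, 2L])][1L]
      tr$edge.length[sib] <- tr$edge.length[sib] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Root a tree on the branch separating an outgroup from the ingroup
#'
#' The outgroup must be monophyletic in the unrooted tree; the root is placed
#' at the midpoint of the separating branch. Re-rooting with the same
#' outgroup is idempotent.
#'
#' @param tree an `ape::phylo` (rooted or not).
#' @param outgroup character vector of outgroup tip labels.
#' @return a rooted `ape::phylo`.
#' @export
root_by_outgroup <- function(tree, outgroup) {
  stopifnot(all(outgroup %in% tree$tip.label))
  if (!has_clade(tree, outgroup)) {
    stop("outgroup is not monophyletic; violating leaves: ",
         paste(outgroup, collapse = ", "))
  }
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  root <- ape::Ntip(tr) + 1L
  kids <- which(tr$edge[, 1L] == root)
  if (length(kids) == 2L) {
    tot <- sum(tr$edge.length[kids])
    tr$edge.length[kids] <- tot / 2
  }
  tr
}

#' Does a tree contain a given clade/bipartition?
#'
#' For rooted trees this is clade membership; for unrooted trees the leaf set
#' counts as present if either it or its complement appears as a split.
#' @param tree an `ape::phylo`.
#' @param tips character vector of tip labels.
#' @return logical scalar.
#' @export
has_clade <- function(tree, tips) {
  n <- ape::Ntip(tree)
  if (length(tips) %in% c(1L, n)) return(TRUE)
  want <- sort(match(tips, tree$tip.label))
  if (anyNA(want)) stop("unknown tip labels: ",
                        paste(tips[is.na(match(tips, tree$tip.label))],
                              collapse = ", "))
  rooted <- ape::is.rooted(tree)
  # on an unrooted tree any single-tip side is a trivial split
  if (!rooted && length(tips) == n - 1L) return(TRUE)
  pp <- ape::prop.part(tree)
  comp <- setdiff(seq_len(n), want)
  for (cl in pp) {
    cl <- sort(cl)
    if (identical(cl, want)) return(TRUE)
    if (!rooted && identical(cl, sort(comp))) return(TRUE)
  }
  FALSE
}

#' Map variant sites onto branches by Fitch parsimony
#'
#' Each variant site is assigned to the single branch on which it changes
#' state, under Fitch parsimony with the root constrained to the ancestral
#' allele and missing calls treated as unknown (compatible with either
#' state). Sites needing more than one change are flagged homoplasic and
#' excluded from dating; sites whose observed derived calls vanish entirely
#' under the resolution (no state flip anywhere) are flagged unassigned and
#' excluded likewise.
#'
#' @param tree a rooted `ape::phylo` whose tips are the matrix samples.
#' @param gm a [geno_matrix()].
#' @return an object of class `haplo_tree`: list with `tree`, `edge_sites`
#'   (column indices per edge), `edge_counts`, `edge_positions`,
#'   `edge_of_site` (NA for excluded sites), `homoplasic` and `unassigned`
#'   site column indices.
#' @export
map_mutations_parsimony <- function(tree, gm) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!setequal(tree$tip.label, sample_ids(gm))) {
    stop("tree leaf set must equal the matrix sample set")
  }
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  M <- ncol(gm$calls)
  # state sets as 2-bit masks: 1 = ancestral, 2 = derived, 3 = either
  sets <- matrix(0L, nrow = n_node, ncol = M)
  tipX <- gm$calls[tree$tip.label, , drop = FALSE]
  sets[seq_len(n_tip), ] <- ifelse(is.na(tipX), 3L, tipX + 1L)
  changes <- integer(M)
  po <- ape::postorder(tree)
  seen <- logical(n_node)
  for (e in po) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    child_set <- sets[ch, ]
    if (!seen[p]) {
      sets[p, ] <- child_set
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(sets[p, ], child_set)
      hit <- inter > 0L
      changes <- changes + as.integer(!hit)
      sets[p, ] <- ifelse(hit, inter, bitwOr(sets[p, ], child_set))
    }
  }
  root <- n_tip + 1L
  root_set <- sets[root, ]
  # the root is constrained to the ancestral allele: a pure-derived root set
  # (possible only through missing data) costs one extra change and resolves
  # in the down-pass
  changes <- changes + as.integer(root_set == 2L)

  # top-down state resolution preferring the parent state (root = ancestral)
  state <- matrix(0L, nrow = n_node, ncol = M)
  state[root, ] <- 1L
  edge_of_site <- rep(NA_integer_, M)
  flips <- integer(M)
  for (e in rev(po)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    ps <- state[p, ]
    cs <- ifelse(bitwAnd(sets[ch, ], ps) > 0L, ps, sets[ch, ])
    state[ch, ] <- cs
    flip <- which(cs != ps)
    edge_of_site[flip] <- e
    flips[flip] <- flips[flip] + 1L
  }
  homoplasic <- which(flips > 1L)
  unassigned <- which(flips == 0L)   # no observed derived call resolves
  excluded <- union(homoplasic, unassigned)
  edge_of_site[excluded] <- NA_integer_
  edge_sites <- lapply(seq_len(nrow(tree$edge)),
                       function(e) which(edge_of_site == e))
  structure(
    list(tree = tree,
         edge_sites = edge_sites,
         edge_counts = lengths(edge_sites),
         edge_positions = lapply(edge_sites, function(i) gm$positions[i]),
         edge_of_site = edge_of_site,
         homoplasic = homoplasic,
         unassigned = unassigned),
    class = "haplo_tree"
  )
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat(sprintf("<haplo_tree> %d tips, %d mapped sites (%d homoplasic, %d unassignable excluded)\n",
              ape::Ntip(x$tree), sum(x$edge_counts), length(x$homoplasic),
              length(x$unassigned)))
  invisible(x)
}

# edge indices on the path from a tip up to (not beyond) an ancestor node
path_edges <- function(tree, tip, ancestor) {
  edge_above <- match(seq_len(ape::Ntip(tree) + tree$Nnode), tree$edge[, 2L])
  out <- integer(0)
  node <- tip
  while (node != ancestor) {
    e <- edge_above[node]
    if (is.na(e)) stop("node ", ancestor, " is not an ancestor of tip ", tip)
    out <- c(out, e)
    node <- tree$edge[e, 1L]
  }
  out
}

#' Site-bootstrap clade support
#'
#' Resamples the callable site universe with replacement (realised as
#' multinomial weights on the variant columns; see the vignette), rebuilds
#' the neighbor-joining tree for each replicate, and reports for each focal
#' clade the percentage of replicates in which it appears. Deterministic
#' given `seed`.
#'
#' @param gm a [geno_matrix()].
#' @param clades named list of tip-label vectors.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return a tibble with `clade`, `support` (percent), `n_reps`. Support is
#'   split-based, so it is invariant to how each replicate tree is rooted.
#' @export
bootstrap_support <- function(gm, clades, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  set.seed(seed)
  A <- (gm$calls == 1L) & !is.na(gm$calls)
  P <- !is.na(gm$calls)
  storage.mode(A) <- "double"; storage.mode(P) <- "double"
  B <- P - A
  M <- ncol(gm$calls)
  hits <- stats::setNames(numeric(length(clades)), names(clades))
  for (r in seq_len(n_reps)) {
    w <- boot_site_weights(M, gm$L)
    Aw <- sweep(A, 2L, w, `*`); Bw <- sweep(B, 2L, w, `*`)
    discord <- Aw %*% t(B) + Bw %*% t(A)
    d <- discord / gm$shared_callable
    diag(d) <- 0
    tr <- neighbor_joining(d)
    for (k in seq_along(clades)) {
      if (has_clade(tr, clades[[k]])) hits[k] <- hits[k] + 1
    }
  }
  tibble::tibble(clade = names(clades), support = 100 * hits / n_reps,
                 n_reps = as.integer(n_reps))
}

# Bootstrap weights for the M variant columns under resampling of the full
# L-site universe with replacement: the variant categories of an L-draw
# multinomial, sampled exactly as Binomial total + uniform multinomial.
boot_site_weights <- function(M, L) {
  if (M == 0L) return(numeric(0))
  n_var <- stats::rbinom(1L, size = L, prob = M / L)
  as.numeric(stats::rmultinom(1L, n_var, rep(1 / M, M)))
}
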