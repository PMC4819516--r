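# Shared fixtures: all built in code, no files.

# the mixed-coverage two-clade study design used across tests
demo_coverage <- function(tree) {
  cv <- stats::setNames(rep(1, length(tree$tip.label)), tree$tip.label)
  low <- grep("[45]$", names(cv))
  cv[low] <- 0.4
  cv
}

demo_sim <- function(seed = 1, L = 1e6, t_split = 54000, ...) {
  tree <- two_clade_tree(t_split = t_split, t_within = 40000,
                         t_outgroup = t_split + 16000)
  cfg <- sim_config(tree, L = L, coverage = demo_coverage(tree),
                    seed = seed, ...)
  simulate_snv_dataset(cfg)
}

clade_a <- sprintf("AUS%d", 1:5)
clade_b <- sprintf("ASN%d", 1:5)

# hand-built toy matrix: each call is explicit at the call site
toy_gm <- function(rows, positions = NULL, L = NULL) {
  calls <- do.call(rbind, rows)
  storage.mode(calls) <- "integer"
  args <- list(calls = calls)
  if (!is.null(positions)) args$positions <- positions
  if (!is.null(L)) args$L <- L
  do.call(geno_matrix, args)
}

# independent brute-force oracles (deliberately naive implementations)

oracle_pairwise_distance <- function(gm, i, j) {
  num <- 0; den <- gm$shared_callable[i, j]
  for (m in seq_len(ncol(gm$calls))) {
    a <- gm$calls[i, m]; b <- gm$calls[j, m]
    if (!is.na(a) && !is.na(b) && a != b) num <- num + 1
  }
  unname(num / den)
}

oracle_asd <- function(x, ga, gb) {
  tot <- 0; nl <- 0
  for (l in seq_len(ncol(x))) {
    if (any(is.na(x[c(ga, gb), l]))) next
    s <- 0; np <- 0
    for (a in ga) for (b in gb) { s <- s + (x[a, l] - x[b, l])^2; np <- np + 1 }
    tot <- tot + s / np; nl <- nl + 1
  }
  unname(tot / nl)
}

# rho by explicit enumeration over clade members and their path mutations
oracle_rho <- function(ht, gm, clade, ancestor) {
  tree <- ht$tree
  total_count <- 0
  for (s in clade) {
    tip <- match(s, tree$tip.label)
    node <- tip
    while (node != ancestor) {
      e <- which(tree$edge[, 2] == node)
      for (m in ht$edge_sites[[e]]) {
        if (!is.na(gm$calls[s, m])) total_count <- total_count + 1
      }
      node <- tree$edge[e, 1]
    }
  }
  total_count / sum(gm$L_s[clade])
}
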