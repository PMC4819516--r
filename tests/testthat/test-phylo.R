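# Distances, neighbor joining, rooting, parsimony mapping, clade support.

test_that("pairwise-deletion distance matches a hand enumeration", {
  # 10-site toy: i derived at {1,2,3}, j derived at {3,4}, site 5 missing in j
  ri <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  rj <- c(0, 0, 1, 1, NA, 0, 0, 0, 0, 0)
  gm <- toy_gm(list(i = ri, j = rj))
  expect_equal(pairwise_distance(gm, "i", "j"), 3 / 9)
  expect_equal(pairwise_distance(gm, "i", "j"),
               oracle_pairwise_distance(gm, "i", "j"))
  expect_equal(pairwise_distance(gm, "i", "i"), 0)
})

test_that("distances are symmetric and match the oracle on random matrices", {
  set.seed(404)
  for (rep in 1:5) {
    calls <- matrix(sample(c(0L, 1L, NA), 40, replace = TRUE,
                           prob = c(.5, .3, .2)),
                    nrow = 4, dimnames = list(letters[1:4], NULL))
    calls[1, ] <- ifelse(is.na(calls[1, ]), 1L, calls[1, ])  # keep pairs callable
    gm <- geno_matrix(calls)
    d <- pairwise_distances(gm)
    expect_equal(d, t(d))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(d[i, j], oracle_pairwise_distance(gm, i, j))
    }
  }
})

test_that("a zero mutually-callable pair is refused by name", {
  calls <- rbind(a = c(1L, NA), b = c(NA, 1L))
  gm <- geno_matrix(calls, L = 2)
  expect_error(pairwise_distances(gm), "a/b")
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("neighbor joining recovers the generating quartet from additive distances", {
  # brute force over the three possible quartet topologies via the 4-point rule
  quartet_truth <- function(d) {
    s1 <- d["A", "B"] + d["C", "D"]
    s2 <- d["A", "C"] + d["B", "D"]
    s3 <- d["A", "D"] + d["B", "C"]
    c("AB|CD", "AC|BD", "AD|BC")[which.min(c(s1, s2, s3))]
  }
  set.seed(11)
  for (rep in 1:20) {
    # random additive tree: ((A,B),(C,D)) with random positive branches
    b <- stats::runif(5, 0.1, 2)   # A, B, C, D, internal
    d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    d["A", "B"] <- d["B", "A"] <- b[1] + b[2]
    d["C", "D"] <- d["D", "C"] <- b[3] + b[4]
    for (x in c("A", "B")) for (y in c("C", "D")) {
      d[x, y] <- d[y, x] <- b[match(x, LETTERS)] + b[match(y, LETTERS)] + b[5]
    }
    expect_equal(quartet_truth(d), "AB|CD")
    tr <- neighbor_joining(d)
    expect_true(has_clade(tr, c("A", "B")))
  }
})

test_that("equal distances resolve deterministically and negatives are clamped", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4])); diag(d) <- 0
  t1 <- neighbor_joining(d); t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  dd <- d; dd[1, 2] <- 5
  expect_error(neighbor_joining(dd), "symmetric")
})

test_that("outgroup rooting is idempotent, leaf-preserving and recovers the true root", {
  sim <- demo_sim(seed = 61, L = 1e6)
  gm <- sim$matrix
  tr <- neighbor_joining(pairwise_distances(gm))
  r1 <- root_by_outgroup(tr, "OUT")
  r2 <- root_by_outgroup(r1, "OUT")
  expect_setequal(r1$tip.label, tr$tip.label)
  expect_identical(ape::write.tree(r1), ape::write.tree(r2))
  # true root bipartition: ingroup = both clades
  expect_true(has_clade(r1, c(clade_a, clade_b)))
  expect_error(root_by_outgroup(tr, c("OUT", "AUS1")), "not monophyletic")
})

test_that("parsimony maps singletons to terminal branches", {
  # 4 tips, one site derived only in c
  calls <- rbind(a = 0L, b = 0L, c = 1L, d = 0L)
  gm <- geno_matrix(calls, L = 10)
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ht <- map_mutations_parsimony(tree, gm)
  e <- ht$edge_of_site[1]
  expect_equal(tree$tip.label[tree$edge[e, 2]], "c")
  expect_equal(sum(ht$edge_counts), 1L)
})

test_that("parsimony assigns clade-defining sites to the stem and flags homoplasy", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,((c:1,d:1):1,e:1):1);")
  calls <- rbind(
    a = c(0L, 1L, 0L), b = c(0L, 1L, 0L),
    c = c(1L, 0L, 1L), d = c(1L, 0L, 0L), e = c(1L, 0L, 1L))
  # site 1: clade {c,d,e}; site 2: clade {a,b}; site 3: homoplasic {c,e}
  gm <- geno_matrix(calls, L = 10)
  ht <- map_mutations_parsimony(tree, gm)
  cde <- ape::extract.clade(tree, tree$edge[ht$edge_of_site[1], 2])$tip.label
  expect_setequal(cde, c("c", "d", "e"))
  ab <- ape::extract.clade(tree, tree$edge[ht$edge_of_site[2], 2])$tip.label
  expect_setequal(ab, c("a", "b"))
  expect_equal(ht$homoplasic, 3L)
  expect_true(is.na(ht$edge_of_site[3]))
})

test_that("with missing calls the mapping stays on the clade stem and counts are unbiased", {
  sim <- demo_sim(seed = 71, L = 1e6)
  gm <- sim$matrix
  tree <- sim$truth$tree
  ht <- map_mutations_parsimony(tree, gm)
  expect_equal(length(ht$homoplasic), 0L)
  # a site observed-derived in a strict subset of clade A (others masked)
  # must still be counted for every callable clade-A member via its path
  r_est <- rho(ht, gm, clade_a, ancestor = ape::getMRCA(tree, c(clade_a, clade_b)))
  expect_equal(r_est$rho_per_site, oracle_rho(ht, gm, clade_a, r_est$ancestor))
})

test_that("on fully-callable data parsimony recovers the true branch counts", {
  tree <- two_clade_tree(n_a = 4, n_b = 4, t_outgroup = 70000)
  sim <- simulate_snv_dataset(sim_config(tree, L = 1e6, coverage = 1, seed = 81))
  gm <- sim$matrix
  ht <- map_mutations_parsimony(tree, gm)
  expect_equal(sum(ht$edge_counts), ncol(gm$calls))
  expect_equal(length(ht$homoplasic) + length(ht$unassigned), 0L)
  # per-edge counts match the generator's ground truth exactly
  truth_counts <- sim$truth$edge_counts
  expect_equal(unname(ht$edge_counts), unname(truth_counts))
})

test_that("bootstrap support is 0/100-valued at one replicate and high for true clades", {
  sim <- demo_sim(seed = 91, L = 1e6)
  one <- bootstrap_support(sim$matrix, list(A = clade_a), n_reps = 1, seed = 2)
  expect_true(all(one$support %in% c(0, 100)))
  bs <- bootstrap_support(sim$matrix, list(A = clade_a, B = clade_b),
                          n_reps = 50, seed = 3)
  expect_true(all(bs$support >= 90))
  # determinism
  bs2 <- bootstrap_support(sim$matrix, list(A = clade_a, B = clade_b),
                           n_reps = 50, seed = 3)
  expect_identical(bs, bs2)
})

test_that("no-signal clades do not reach full support", {
  # {c,d,e} are mutually equidistant (one private singleton each): which
  # cherry forms is decided by the resampling noise, so no pair can be
  # supported in every replicate
  calls <- matrix(0L, 5, 7, dimnames = list(letters[1:5], NULL))
  calls[c("a", "b"), 1:2] <- 1L                 # real signal: clade {a,b}
  for (k in 1:5) calls[k, k + 2L] <- 1L         # private singletons
  gm <- geno_matrix(calls, L = 100)
  bs <- bootstrap_support(gm, list(cd = c("c", "d"), ab = c("a", "b")),
                          n_reps = 40, seed = 5)
  expect_lt(bs$support[bs$clade == "cd"], 100)
  expect_gt(bs$support[bs$clade == "ab"], bs$support[bs$clade == "cd"])
})

test_that("simulated deep clades are monophyletic in the NJ tree", {
  ok <- replicate(20, {
    s <- sample.int(1e6, 1)
    sim <- demo_sim(seed = s, L = 1e7, t_split = 54000)
    tr <- neighbor_joining(pairwise_distances(sim$matrix))
    has_clade(tr, clade_a) && has_clade(tr, clade_b)
  })
  expect_true(all(ok))
})

test_that("branch-mapped sites carry parsimony score one (external cross-check)", {
  skip_if_not_installed("phangorn")
  set.seed(2)
  for (r in 1:10) {
    tree <- ape::rtree(6, br = NULL)
    tree$edge.length <- rep(1, nrow(tree$edge))
    calls <- matrix(sample(c(0L, 1L, NA), 72, TRUE, prob = c(.5, .35, .15)),
                    6, dimnames = list(tree$tip.label, NULL))
    calls["t1", ] <- 0L   # an observed all-ancestral taxon frees the root
    calls <- calls[, colSums(calls == 1L, na.rm = TRUE) > 0, drop = FALSE]
    gm <- geno_matrix(calls, L = 50)
    ht <- map_mutations_parsimony(tree, gm)
    clean <- setdiff(seq_len(ncol(calls)), c(ht$homoplasic, ht$unassigned))
    if (!length(clean)) next
    ch <- matrix(ifelse(is.na(calls), "?", as.character(calls)),
                 nrow = nrow(calls), dimnames = dimnames(calls))
    pd <- phangorn::phyDat(ch[, clean, drop = FALSE], type = "USER",
                           levels = c("0", "1"), ambiguity = "?")
    expect_equal(phangorn::parsimony(tree, pd), length(clean))
  }
})
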