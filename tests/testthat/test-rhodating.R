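# The dating engine: rho, time conversion, calibration, and the three CIs.

rate_default <- mutation_rate(0.76e-9, 0.67e-9, 0.86e-9)

# two fully-callable tips with known path counts, plus an outgroup
toy_ht <- function(n1 = 4L, n2 = 6L, L = 1e6, c2 = 1.0) {
  tree <- ape::read.tree(text = "((s1:1,s2:1):1,out:2);")
  M <- n1 + n2
  calls <- rbind(
    s1 = c(rep(1L, n1), rep(0L, n2)),
    s2 = c(rep(0L, n1), rep(1L, n2)),
    out = rep(0L, M))
  gm <- geno_matrix(calls, L = L,
                    L_s = c(s1 = L, s2 = L * c2, out = L))
  list(ht = map_mutations_parsimony(tree, gm), gm = gm, tree = tree)
}

test_that("pooled rho matches direct arithmetic", {
  x <- toy_ht(4L, 6L, L = 1e6)
  anc <- ape::getMRCA(x$tree, c("s1", "s2"))
  r <- rho(x$ht, x$gm, c("s1", "s2"), ancestor = anc)
  expect_equal(r$count, 10)
  expect_equal(r$rho_per_site, (4 + 6) / (2 * 1e6))
  expect_equal(r$rho_per_site, oracle_rho(x$ht, x$gm, c("s1", "s2"), anc))
})

test_that("pooled aggregation divides by the summed callable totals", {
  # s1 fully callable with 4 observed, s2 half callable with 3 observed:
  # rho = (4+3)/(1.5e6)
  tree <- ape::read.tree(text = "((s1:1,s2:1):1,out:2);")
  calls <- rbind(s1 = c(1L, 1L, 1L, 1L, 0L, 0L, 0L),
                 s2 = c(0L, 0L, 0L, 0L, 1L, 1L, 1L),
                 out = rep(0L, 7))
  gm <- geno_matrix(calls, L = 1e6, L_s = c(s1 = 1e6, s2 = 0.5e6, out = 1e6))
  ht <- map_mutations_parsimony(tree, gm)
  anc <- ape::getMRCA(tree, c("s1", "s2"))
  r <- rho(ht, gm, c("s1", "s2"), ancestor = anc)
  expect_equal(r$rho_per_site, 7 / 1.5e6)
  expect_equal(r$rho_per_site, oracle_rho(ht, gm, c("s1", "s2"), anc))
})

test_that("mutations are only counted where the sample is callable", {
  tree <- ape::read.tree(text = "(((s1:1,s2:1):1,s3:2):1,out:3);")
  # site 1: cherry-stem mutation, masked in s2 -> counted for s1 only
  # site 2: cherry-stem mutation, observed in both -> counted for s1 and s2
  # site 3: singleton in s3 -> counted for s3
  calls <- rbind(s1 = c(1L, 1L, 0L),
                 s2 = c(NA, 1L, 0L),
                 s3 = c(0L, 0L, 1L),
                 out = c(0L, 0L, 0L))
  gm <- geno_matrix(calls, L = 100,
                    L_s = c(s1 = 100, s2 = 80, s3 = 100, out = 100))
  ht <- map_mutations_parsimony(tree, gm)
  clade <- c("s1", "s2", "s3")
  anc <- ape::getMRCA(tree, clade)
  r <- rho(ht, gm, clade, ancestor = anc)
  expect_equal(unname(r$sample_counts), c(2, 1, 1))
  expect_equal(r$rho_per_site, 4 / 280)
  expect_equal(r$rho_per_site, oracle_rho(ht, gm, clade, anc))
})

test_that("a clade with no path mutations has rho zero", {
  x <- toy_ht()
  r <- rho(x$ht, x$gm, "out")
  expect_equal(r$rho_per_site, 0)
})

test_that("divergence time is the averaged rho over the rate", {
  x <- toy_ht(5L, 5L, L = 1e6)
  te <- divergence_time(x$ht, x$gm, "s1", "s2",
                        rate = mutation_rate(0.76e-9, 0.76e-9, 0.76e-9))
  expect_equal(te$T_years, 5e-6 / 0.76e-9, tolerance = 1e-12)
  expect_equal(round(te$T_years, 1), 6578.9)
  expect_error(divergence_time(x$ht, x$gm, character(0), "s2"), "empty clade")
})

test_that("rate-CI propagation reproduces printed intervals after 0.1 ky rounding", {
  ky <- function(x) round(x / 100) / 10
  expect_equal(ky(rate_ci_propagate(54300, rate_default)), c(48.0, 61.6))
  expect_equal(ky(rate_ci_propagate(54100, rate_default)), c(47.8, 61.4))
  degen <- mutation_rate(1e-9, 1e-9, 1e-9)
  expect_equal(rate_ci_propagate(1234, degen), c(1234, 1234))
  # width/T is constant in T
  w <- function(T) diff(rate_ci_propagate(T, rate_default)) / T
  expect_equal(w(1000), w(987654))
})

test_that("combined CI applies the rate bounds multiplicatively", {
  expect_equal(round(combine_ci(c(50900, 58100), rate_default)[2] / 100) / 10,
               65.9)
  degen <- mutation_rate(1e-9, 1e-9, 1e-9)
  expect_equal(combine_ci(c(1000, 2000), degen), c(1000, 2000))
})

test_that("rate calibration inverts branch shortening arithmetically", {
  # constructed so (rho_modern - rho_ancient) / age = 0.76e-9 exactly:
  # modern tips carry 456 extra mutations over L=1e7... use direct toy
  tree <- ape::read.tree(text = "((mod:45000,anc:0):10000,out:60000);")
  n_mod <- 456L; n_anc <- 114L; n_shared <- 50L
  calls <- rbind(
    mod = c(rep(1L, n_mod), rep(0L, n_anc), rep(1L, n_shared)),
    anc = c(rep(0L, n_mod), rep(1L, n_anc), rep(1L, n_shared)),
    out = rep(0L, n_mod + n_anc + n_shared))
  L <- 1e7
  gm <- geno_matrix(calls, L = L, L_s = c(mod = L, anc = L, out = L))
  ht <- map_mutations_parsimony(tree, gm)
  r <- calibrate_rate(ht, gm, "anc", 45000, modern_tips = "mod")
  # (456 - 114)/1e7 / 45000 = 0.76e-9
  expect_equal(r$point, 0.76e-9, tolerance = 1e-12)
  # equal rho is a boundary error
  calls2 <- calls; calls2["anc", ] <- calls2["mod", ]
  gm2 <- geno_matrix(calls2, L = L, L_s = gm$L_s)
  ht2 <- map_mutations_parsimony(tree, gm2)
  expect_error(calibrate_rate(ht2, gm2, "anc", 45000, modern_tips = "mod"),
               "negative rate")
})

test_that("simulated ancient tips recover the generating rate", {
  tree <- two_clade_tree(n_a = 4, n_b = 4, t_split = 54000, t_within = 40000,
                         t_outgroup = 70000, ancient_age = 45000)
  moderns <- grep("^(AUS|ASN)", tree$tip.label, value = TRUE)
  rates <- replicate(30, {
    s <- sample.int(1e6, 1)
    sim <- simulate_snv_dataset(sim_config(tree, coverage = 1,
                                           ancient_tips = c(ANC = 45000),
                                           seed = s))
    ht <- map_mutations_parsimony(tree, sim$matrix)
    calibrate_rate(ht, sim$matrix, "ANC", 45000, modern_tips = moderns)$point
  })
  expect_lt(abs(mean(rates) / 0.76e-9 - 1), 0.1)
})

test_that("the site bootstrap is seed-deterministic and brackets the point estimate", {
  sim <- demo_sim(seed = 105, L = 1e6)
  gm <- sim$matrix
  rt <- root_by_outgroup(neighbor_joining(pairwise_distances(gm)), "OUT")
  ht <- map_mutations_parsimony(rt, gm)
  b1 <- site_bootstrap_ci(ht, gm, clade_a, clade_b, rate_default,
                          n_reps = 100, seed = 9)
  b2 <- site_bootstrap_ci(ht, gm, clade_a, clade_b, rate_default,
                          n_reps = 100, seed = 9)
  expect_identical(b1, b2)
  te <- divergence_time(ht, gm, clade_a, clade_b, rate_default)
  expect_lt(b1$ci[1], te$T_years)
  expect_gt(b1$ci[2], te$T_years)
  expect_error(site_bootstrap_ci(ht, gm, c("AUS1", "ASN1"), clade_b,
                                 rate_default, n_reps = 10, seed = 1),
               "not monophyletic")
})

test_that("pooled rho is unbiased across coverage levels", {
  # E[rho_pooled] must match the fully-callable rho at c in {0.3, 0.5, 1.0}
  tree <- two_clade_tree(n_a = 3, n_b = 3, t_split = 50000, t_within = 30000,
                         t_outgroup = NULL)
  for (cvg in c(0.3, 0.5, 1.0)) {
    est <- replicate(25, {
      s <- sample.int(1e6, 1)
      sim <- simulate_snv_dataset(sim_config(tree, L = 1e6, coverage = cvg,
                                             seed = s))
      ht <- map_mutations_parsimony(tree, sim$matrix)
      rho(ht, sim$matrix, sprintf("AUS%d", 1:3),
          ancestor = ape::Ntip(tree) + 1L)$rho_per_site
    })
    truth <- 0.76e-9 * 50000
    expect_lt(abs(mean(est) - truth) / truth, 3 * sd(est) / sqrt(25) / truth + 0.02)
  }
})

test_that("divergence time scales linearly in rho and inversely in rate", {
  x <- toy_ht(5L, 5L, L = 1e6)
  r1 <- mutation_rate(1e-9, 1e-9, 1e-9)
  r2 <- mutation_rate(2e-9, 2e-9, 2e-9)
  t1 <- divergence_time(x$ht, x$gm, "s1", "s2", rate = r1)$T_years
  t2 <- divergence_time(x$ht, x$gm, "s1", "s2", rate = r2)$T_years
  expect_equal(t1, 2 * t2)
  # doubling counts doubles T: reuse the pooled toy with twice the sites
  y <- toy_ht(10L, 10L, L = 1e6)
  t3 <- divergence_time(y$ht, y$gm, "s1", "s2", rate = r1)$T_years
  expect_equal(t3, 2 * t1)
})
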