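test_that("the bundled calibration setup matches the study design", {
  cal <- calibration_tree()
  expect_equal(ape::Ntip(cal$tree), 10)
  expect_equal(sum(cal$tree$edge.length), 3)
  expect_equal(n_partitions(cal$partition2), 2)
  expect_equal(n_partitions(cal$partition3), 3)
  # the over-split scheme only subdivides the generating foreground
  expect_equal(
    as.integer(cal$partition2) > 1L,
    as.integer(cal$partition3) > 1L
  )
  # the misassignable branch is a background terminal branch
  expect_equal(as.integer(cal$partition2)[cal$misassign_branch], 1L)
  cfg <- sim_config()
  expect_equal(cfg$proportions, c(0.5, 0.2, 0.3))
  expect_equal(cfg$omega[3, ], c(0.15, 0.65))
  expect_equal(cfg$kappa, 2)
  expect_equal(cfg$n_codons, 500)
  expect_equal(as.numeric(cfg$freqs), rep(1 / 61, 61))
})

test_that("simulated alignments have the configured shape and class mix", {
  sim <- simulate_alignment(sim_config(), seed = 21)
  expect_equal(dim(sim$alignment), c(10L, 500L))
  expect_length(sim$true_class, 500)
  frac <- tabulate(sim$true_class, 3) / 500
  expect_true(all(abs(frac - c(0.5, 0.2, 0.3)) < 0.08))
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_codons = 40)
  a <- simulate_alignment(cfg, seed = 5)
  b <- simulate_alignment(cfg, seed = 5)
  expect_identical(unclass(a$alignment), unclass(b$alignment))
  expect_identical(a$true_class, b$true_class)
  reps <- simulate_replicates(cfg, 3, base_seed = 4)
  expect_identical(
    unclass(reps[[1]]$alignment),
    unclass(simulate_alignment(cfg, seed = 5)$alignment)
  )
  expect_false(identical(
    unclass(reps[[1]]$alignment),
    unclass(reps[[2]]$alignment)
  ))
})

test_that("zero tree length copies the root codon to every tip", {
  cfg <- sim_config(n_codons = 30, total_length = 0)
  sim <- simulate_alignment(cfg, seed = 3)
  m <- unclass(sim$alignment)
  expect_true(all(m == rep(m[1, ], each = nrow(m))))
})

test_that("omega = 0 sites never change amino acid anywhere in the tree", {
  gc <- genetic_code()
  sim <- simulate_alignment(sim_config(n_codons = 300), seed = 17)
  m <- unclass(sim$alignment)
  aa <- matrix(gc$amino_acid[gc$codons[m]], nrow(m), ncol(m))
  invariant_sites <- which(sim$true_class == 1L)
  n_aa_variants <- vapply(
    invariant_sites,
    function(s) length(unique(aa[, s])), 1L
  )
  expect_true(all(n_aa_variants == 1L))
})

test_that("single-branch transition frequencies match the analytic matrix", {
  # two tips joined by one branch of total length 1 under M0; by
  # reversibility tip A is an equilibrium draw and B | A follows P(1)
  tr <- ape::read.tree(text = "(A:0.5,B:0.5);")
  cfg <- sim_config(
    tree = tr, partition = NULL, proportions = 1,
    omega = matrix(0.3), kappa = 2, n_codons = 50000, total_length = 1
  )
  sim <- simulate_alignment(cfg, seed = 12)
  q <- codon_rate_matrix(2, 0.3)
  p <- transition_matrix(q / mean_rate(q), 1)
  m <- unclass(sim$alignment)
  gc <- genetic_code()

  # GOF over the six codon-pair change categories
  pc <- gc$pair_class
  cat_obs <- tabulate(pc[cbind(m[1, ], m[2, ])] + 1L, 6)
  pi <- rep(1 / 61, 61)
  cat_exp <- vapply(0:5, function(cl) {
    sum((pi %o% rep(1, 61)) * p * (pc == cl))
  }, 1)
  gof <- stats::chisq.test(cat_obs, p = cat_exp / sum(cat_exp))
  expect_gt(gof$p.value, 0.01)

  # GOF of the full conditional given the most frequent parent state,
  # pooling cells with small expected counts
  s <- which.max(tabulate(m[1, ], 61))
  n_s <- sum(m[1, ] == s)
  obs <- tabulate(m[2, m[1, ] == s], 61)
  expected <- p[s, ] * n_s
  pool <- expected < 5
  obs2 <- c(obs[!pool], sum(obs[pool]))
  p2 <- c(p[s, !pool], sum(p[s, pool]))
  gof2 <- stats::chisq.test(obs2, p = p2 / sum(p2))
  expect_gt(gof2$p.value, 0.01)
})

test_that("long-branch codon frequencies converge to equilibrium", {
  tr <- ape::read.tree(text = "(A:5,B:5);")
  cfg <- sim_config(
    tree = tr, partition = NULL, proportions = 1,
    omega = matrix(0.5), kappa = 2, n_codons = 30000, total_length = 10
  )
  sim <- simulate_alignment(cfg, seed = 8)
  freq <- tabulate(unclass(sim$alignment)[2, ], 61) / 30000
  tv <- 0.5 * sum(abs(freq - 1 / 61))
  expect_lt(tv, 0.02)
})
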