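scaled_q <- function(kappa, omega, freqs = equal_frequencies()) {
  q <- codon_rate_matrix(kappa, omega, freqs)
  s <- scale_class_matrices(list(list(q)), 1)
  s$matrices[[1]][[1]]
}

test_that("transition matrices are stochastic, start at identity, and mix", {
  q <- scaled_q(2, 0.5)
  expect_equal(transition_matrix(q, 0), diag(61), ignore_attr = TRUE)
  p <- transition_matrix(q, 0.37)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-10)
  expect_true(all(p >= 0))
  # ergodic limit: every row converges to the equilibrium frequencies
  p_inf <- transition_matrix(q, 50)
  expect_lt(max(abs(sweep(p_inf, 2, rep(1 / 61, 61)))), 1e-6)
  expect_error(transition_matrix(q, -1), "branch length")
})

test_that("transition matrices satisfy the semigroup property", {
  for (omega in c(0, 0.3, 1.7)) {
    q <- scaled_q(2.5, omega)
    p <- transition_matrix(q, 0.4) %*% transition_matrix(q, 0.7)
    expect_equal(p, unclass(transition_matrix(q, 1.1)),
      tolerance = 1e-8, ignore_attr = TRUE
    )
  }
})

test_that("pruning equals brute-force enumeration on a quartet", {
  tr <- quartet_tree()
  aln <- random_alignment(4, 3, seed = 2)
  spec <- model_spec("M0")
  pars <- list(
    kappa = 2.3, omega = c(w0 = 0.4), props = numeric(0),
    branch_lengths = tr$edge.length
  )
  ll <- mixture_log_likelihood(spec, pars, tr, aln)
  q <- scaled_q(2.3, 0.4)
  p_list <- lapply(tr$edge.length, function(t) transition_matrix(q, t))
  bf <- brute_force_mixture_lnl(tr, list(p_list), 1, aln, rep(1 / 61, 61))
  expect_equal(ll, bf, tolerance = 1e-10)
})

test_that("mixture pruning equals brute force for a clade model", {
  tr <- quartet_tree()
  part <- assign_partitions(tr, list(list(tips = c("A", "B"), name = "fg")))
  aln <- random_alignment(4, 2, seed = 9)
  spec <- model_spec("CmC", n_partitions = 2)
  pars <- list(
    kappa = 1.8,
    omega = c(w0 = 0.21, w2_part1 = 0.4, w2_part2 = 1.9),
    props = c(0.55, 0.25),
    branch_lengths = tr$edge.length
  )
  ll <- mixture_log_likelihood(spec, pars, tr, aln, partition = part)

  # independent reconstruction of the class/partition matrices
  props <- c(0.55, 0.25, 0.2)
  qs <- list(
    bg = lapply(c(0.21, 1, 0.4), codon_rate_matrix, kappa = 1.8),
    fg = lapply(c(0.21, 1, 1.9), codon_rate_matrix, kappa = 1.8)
  )
  post <- ape::reorder.phylo(tr, "postorder")
  perm <- match(
    paste(post$edge[, 1], post$edge[, 2]),
    paste(tr$edge[, 1], tr$edge[, 2])
  )
  fg_edges <- as.integer(part) == 2L
  usage <- c(sum(tr$edge.length[!fg_edges]), sum(tr$edge.length[fg_edges])) /
    sum(tr$edge.length)
  rho <- sum(vapply(1:3, function(k) {
    props[k] * (usage[1] * mean_rate(qs$bg[[k]]) + usage[2] * mean_rate(qs$fg[[k]]))
  }, 1))
  p_lists <- lapply(1:3, function(k) {
    lapply(seq_len(nrow(tr$edge)), function(e) {
      qk <- if (fg_edges[e]) qs$fg[[k]] else qs$bg[[k]]
      transition_matrix(qk / rho, tr$edge.length[e])
    })
  })
  bf <- brute_force_mixture_lnl(tr, p_lists, props, aln, rep(1 / 61, 61))
  expect_equal(ll, bf, tolerance = 1e-10)
})

test_that("degenerate data: identical tips at t = 0 and all-missing sites", {
  star <- ape::read.tree(text = "(A:0,B:0,C:0);")
  aln <- codon_alignment(matrix(5L, 3, 1, dimnames = list(c("A", "B", "C"), NULL)))
  spec <- model_spec("M0")
  pars <- list(
    kappa = 2, omega = c(w0 = 0.5), props = numeric(0),
    branch_lengths = star$edge.length
  )
  expect_equal(
    mixture_log_likelihood(spec, pars, star, aln),
    log(1 / 61)
  )
  miss <- codon_alignment(matrix(NA_integer_, 3, 2,
    dimnames = list(c("A", "B", "C"), NULL)
  ))
  pars$branch_lengths <- rep(0.3, 3)
  expect_equal(mixture_log_likelihood(spec, pars, star, miss), 0)
})

test_that("clade model collapses to its site-model nulls at matched parameters", {
  tr <- quartet_tree()
  part <- assign_partitions(tr, list(list(tips = c("A", "B"), name = "fg")))
  aln <- random_alignment(4, 20, seed = 3)
  base <- list(kappa = 2.2, branch_lengths = tr$edge.length)

  cmc <- model_spec("CmC", n_partitions = 2)
  m2a <- model_spec("M2a_rel")
  ll_cmc <- mixture_log_likelihood(
    cmc,
    c(base, list(
      omega = c(w0 = 0.15, w2_part1 = 0.8, w2_part2 = 0.8),
      props = c(0.6, 0.2)
    )),
    tr, aln,
    partition = part
  )
  ll_m2a <- mixture_log_likelihood(
    m2a,
    c(base, list(omega = c(w0 = 0.15, w2 = 0.8), props = c(0.6, 0.2))),
    tr, aln
  )
  expect_equal(ll_cmc, ll_m2a, tolerance = 1e-8)

  # M1a with p0 -> 1 equals M0 at omega = omega0
  m1a <- model_spec("M1a")
  m0 <- model_spec("M0")
  ll_m1a <- mixture_log_likelihood(
    m1a,
    c(base, list(omega = c(w0 = 0.3), props = 1 - 1e-12)),
    tr, aln
  )
  ll_m0 <- mixture_log_likelihood(
    m0,
    c(base, list(omega = c(w0 = 0.3), props = numeric(0))),
    tr, aln
  )
  expect_equal(ll_m1a, ll_m0, tolerance = 1e-6)
})

test_that("log-likelihood is invariant to re-rooting", {
  tr <- quartet_tree()
  aln <- random_alignment(4, 15, seed = 6)
  spec <- model_spec("M0")
  ll <- function(tree) {
    mixture_log_likelihood(
      spec,
      list(
        kappa = 2, omega = c(w0 = 0.4), props = numeric(0),
        branch_lengths = tree$edge.length
      ),
      tree, aln
    )
  }
  tr2 <- ape::root(ape::unroot(tr), outgroup = "C", resolve.root = TRUE)
  expect_equal(ll(tr), ll(tr2), tolerance = 1e-8)
})

test_that("pattern compression preserves the likelihood", {
  tr <- quartet_tree()
  m <- unclass(random_alignment(4, 6, seed = 8))
  rep_aln <- codon_alignment(m[, c(1, 2, 1, 3, 2, 1, 4, 5, 6, 3)])
  rownames(rep_aln) <- rownames(m)
  spec <- model_spec("M0")
  pars <- list(
    kappa = 2, omega = c(w0 = 0.4), props = numeric(0),
    branch_lengths = tr$edge.length
  )
  ll <- mixture_log_likelihood(spec, pars, tr, rep_aln)
  # per-column evaluation, no shared patterns
  ll_cols <- sum(vapply(seq_len(ncol(rep_aln)), function(j) {
    one <- codon_alignment(unclass(rep_aln)[, j, drop = FALSE])
    rownames(one) <- rownames(rep_aln)
    mixture_log_likelihood(spec, pars, tr, one)
  }, 1))
  expect_equal(ll, ll_cols, tolerance = 1e-10)
  pat <- compress_patterns(rep_aln)
  expect_equal(sum(pat$weights), 10)
  expect_equal(ncol(pat$patterns), 6)
})
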