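# Shared fixtures, built in code.

quartet_tree <- function(lens = c(0.15, 0.3, 0.2, 0.05, 0.25, 0.1)) {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tr$edge.length <- lens[seq_len(nrow(tr$edge))]
  tr
}

random_alignment <- function(n_taxa, n_codons, seed = 1,
                             labels = LETTERS[seq_len(n_taxa)]) {
  set.seed(seed)
  codon_alignment(matrix(sample.int(61, n_taxa * n_codons, replace = TRUE),
    n_taxa, n_codons,
    dimnames = list(labels, NULL)
  ))
}

# exhaustive likelihood of one site pattern on a rooted/unrooted tree by
# summing over all internal-node state assignments (independent of the
# package's pruning path)
brute_force_site_lik <- function(tree, p_list, states, pi) {
  n_tip <- ape::Ntip(tree)
  n_internal <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_along(pi)), n_internal)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    state_of <- function(nd) {
      if (nd <= n_tip) states[nd] else grid[g, nd - n_tip]
    }
    p <- pi[state_of(n_tip + 1L)]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * p_list[[e]][
        state_of(tree$edge[e, 1]),
        state_of(tree$edge[e, 2])
      ]
    }
    tot <- tot + p
  }
  tot
}

# mixture brute force over classes with per-class transition matrices
brute_force_mixture_lnl <- function(tree, p_lists, proportions, aln, pi) {
  sum(vapply(seq_len(ncol(aln)), function(s) {
    lik <- sum(vapply(seq_along(proportions), function(k) {
      proportions[k] *
        brute_force_site_lik(tree, p_lists[[k]], unclass(aln)[, s], pi)
    }, 1))
    log(lik)
  }, 1))
}
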