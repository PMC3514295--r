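#' Configuration for the codon-alignment simulator
#'
#' Bundles everything needed to simulate codon alignments under a
#' site-class mixture model on a partitioned tree: topology and branch
#' lengths (rescaled to a total tree length in expected substitutions per
#' codon), the partition scheme, the true site-class proportions and
#' omegas, kappa and the codon frequencies.
#'
#' Defaults reproduce the calibration study's generating conditions:
#' clade model C on the bundled 10-taxon two-partition tree, 500 codons,
#' p = (0.5, 0.2, 0.3), omega = (0, 1, 0.15 | 0.65) with the divergent
#' class at 0.15 on the background ("solid") and 0.65 on the foreground
#' ("dashed") partition, kappa = 2, total tree length 3 substitutions per
#' codon, equal codon frequencies (1/61).
#'
#' @param tree An [ape::phylo] tree with edge lengths.
#' @param partition A [partition_scheme()] over `tree`.
#' @param proportions Site-class proportions (sum to 1).
#' @param omega Matrix of omegas, classes x partitions (columns recycled
#'   if a single column is given).
#' @param kappa Transition/transversion rate ratio.
#' @param freqs Codon equilibrium frequencies.
#' @param n_codons Alignment length in codons.
#' @param total_length If non-NULL, branch lengths are rescaled so they
#'   sum to this value (substitutions per codon).
#' @return A `sim_config` object.
#' @export
sim_config <- function(tree = NULL, partition = NULL,
                       proportions = c(0.5, 0.2, 0.3),
                       omega = rbind(c(0, 0), c(1, 1), c(0.15, 0.65)),
                       kappa = 2, freqs = equal_frequencies(),
                       n_codons = 500, total_length = 3) {
  if (is.null(tree)) {
    cal <- calibration_tree()
    tree <- cal$tree
    if (is.null(partition)) partition <- cal$partition2
  }
  if (is.null(partition)) partition <- rep(1L, nrow(tree$edge))
  omega <- as.matrix(omega)
  P <- n_partitions(partition)
  if (ncol(omega) == 1L) omega <- omega[, rep(1L, P), drop = FALSE]
  stopifnot(
    nrow(omega) == length(proportions), ncol(omega) == P,
    abs(sum(proportions) - 1) < 1e-8
  )
  if (!is.null(total_length)) {
    if (total_length < 0) stop("total_length must be >= 0")
    tl <- sum(tree$edge.length)
    tree$edge.length <- if (tl > 0) {
      tree$edge.length * total_length / tl
    } else {
      rep(total_length / nrow(tree$edge), nrow(tree$edge))
    }
  }
  structure(
    list(
      tree = tree, partition = partition, proportions = proportions,
      omega = omega, kappa = kappa, freqs = freqs, n_codons = n_codons
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(
    "Simulation config: ", ape::Ntip(x$tree), " taxa, ", x$n_codons,
    " codons, TL = ", format(sum(x$tree$edge.length), digits = 4),
    ", kappa = ", x$kappa, "\n",
    sep = ""
  )
  cat("  class proportions:", paste(x$proportions, collapse = ", "), "\n")
  invisible(x)
}

#' The bundled 10-taxon calibration tree and its partition schemes
#'
#' A symmetric 10-taxon topology with equal branch lengths (17 edges,
#' rescaled to total length 3 by [sim_config()]'s default). Partitions:
#' the generating scheme splits the tree into a "solid" background and a
#' "dashed" foreground clade (tips t5-t8 plus its stem, 7 edges); the
#' over-parameterized analysis scheme further splits that clade into
#' "dashed" ({t5, t6} and their stem) and "dotted" (the remainder). The
#' terminal branch of tip t10 (in the solid partition) is the branch
#' moved in the misspecification study.
#'
#' @return A list: `tree` (edge lengths summing to 3), `partition2`
#'   (solid/dashed), `partition3` (solid/dashed/dotted),
#'   `misassign_branch` (edge index of tip t10's terminal branch).
#' @export
calibration_tree <- function() {
  txt <- "(((t1,t2),(t3,t4)),((t5,t6),(t7,t8)),(t9,t10));"
  tree <- ape::read.tree(text = txt)
  tree$edge.length <- rep(3 / nrow(tree$edge), nrow(tree$edge))
  p2 <- assign_partitions(
    tree,
    list(list(tips = paste0("t", 5:8), name = "dashed")),
    background_label = "solid"
  )
  p3 <- assign_partitions(
    tree,
    list(
      list(tips = c("t5", "t6"), name = "dashed"),
      list(tips = c("t7", "t8"), name = "dotted_core")
    ),
    background_label = "solid"
  )
  # the remainder of the dashed clade (t7, t8 sub-clade + the clade stem)
  # forms the "dotted" partition: move the clade stem out of "solid"
  stem <- setdiff(which(as.integer(p2) == 2L), which(as.integer(p3) != 1L))
  p3int <- as.integer(p3)
  p3int[stem] <- 3L
  p3 <- new_partition_scheme(p3int, c("solid", "dashed", "dotted"))
  list(
    tree = tree,
    partition2 = p2,
    partition3 = p3,
    misassign_branch = tip_branch(tree, "t10")
  )
}

#' Simulate a codon alignment under a site-class mixture model
#'
#' Each site draws its class from the class proportions; the root codon is
#' drawn from the equilibrium frequencies and states evolve tip-ward by
#' sampling from the branch- and class-specific transition matrices (the
#' divergent class switches omega by tree partition). Rate matrices are
#' scaled exactly as in fitting, so branch lengths are expected
#' substitutions per codon averaged over site classes.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the simulation is deterministic given the
#'   seed.
#' @return A `sim_dataset`: list with `alignment` (a [codon_alignment()]),
#'   `true_class` (integer site labels), `config`, `seed`.
#' @export
simulate_alignment <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(config$tree, "postorder")
  perm <- match(
    paste(tree$edge[, 1], tree$edge[, 2]),
    paste(config$tree$edge[, 1], config$tree$edge[, 2])
  )
  part <- as.integer(config$partition)[perm]
  lens <- tree$edge.length
  K <- length(config$proportions)
  P <- ncol(config$omega)
  pi <- as.numeric(config$freqs)
  n <- config$n_codons

  wvals <- sort(unique(as.vector(config$omega)))
  qid <- matrix(match(config$omega, wvals), K, P)
  mats <- lapply(wvals, function(w) {
    codon_rate_matrix(config$kappa, w, config$freqs)
  })
  usage <- partition_usage_from_lengths(part, lens, P)
  rho <- mixture_scale_factor(
    list(qid = qid, mu = vapply(mats, mean_rate, 1)),
    config$proportions, usage
  )
  esys <- lapply(mats, eigen_system)

  true_class <- sample.int(K, n, replace = TRUE, prob = config$proportions)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  states <- matrix(NA_integer_, n_node, n)
  states[root, ] <- sample.int(61, n, replace = TRUE, prob = pi)

  # preorder = reversed postorder edges
  for (e in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    t_e <- lens[e] / rho
    for (k in seq_len(K)) {
      sites <- which(true_class == k)
      if (!length(sites)) next
      es <- esys[[qid[k, part[e]]]]
      p_mat <- es$right %*% (exp(es$values * lens[e] / rho) * es$left)
      p_mat[p_mat < 0] <- 0
      from <- states[parent, sites]
      for (s in unique(from)) {
        idx <- sites[from == s]
        states[child, idx] <- sample.int(61, length(idx),
          replace = TRUE, prob = p_mat[s, ]
        )
      }
    }
  }
  aln <- states[seq_len(n_tip), , drop = FALSE]
  rownames(aln) <- tree$tip.label
  structure(
    list(
      alignment = codon_alignment(aln),
      true_class = true_class,
      config = config,
      seed = seed
    ),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(
    "Simulated codon alignment: ", nrow(x$alignment), " taxa x ",
    ncol(x$alignment), " codons (seed ",
    if (is.null(x$seed)) "unset" else x$seed, ")\n",
    sep = ""
  )
  cat("  true class counts:", paste(tabulate(x$true_class), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate replicate datasets
#'
#' Replicate `r` uses seed `base_seed + r`, so any subset of replicates
#' can be regenerated independently.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Integer base seed.
#' @return A list of `sim_dataset` objects.
#' @export
simulate_replicates <- function(config, n_reps, base_seed = 0) {
  stopifnot(n_reps >= 1)
  lapply(seq_len(n_reps), function(r) {
    simulate_alignment(config, seed = base_seed + r)
  })
}
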