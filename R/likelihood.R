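#' Codon alignment container
#'
#' Represents an in-frame coding alignment as an integer matrix of codon
#' states (rows = taxa, columns = codon sites) over the 61 sense codons;
#' `NA` marks a missing/ambiguous codon (any codon containing a non-ACGT
#' character). Stop codons in the data are an input error unless
#' `stop_codons = "mask"`.
#'
#' @param x A character matrix of codon strings (taxa x sites), a character
#'   vector of nucleotide sequences (length divisible by 3), or an integer
#'   matrix of codon states 1..61.
#' @param stop_codons `"error"` (default) or `"mask"` (treat as missing).
#' @return A `codon_alignment` object.
#' @export
codon_alignment <- function(x, stop_codons = c("error", "mask")) {
  stop_codons <- match.arg(stop_codons)
  gc <- genetic_code()
  if (is.character(x) && !is.matrix(x)) {
    if (any(nchar(x) %% 3 != 0)) {
      stop("sequence length not divisible by 3")
    }
    if (length(unique(nchar(x))) != 1L) {
      stop("sequences have unequal (ragged) lengths")
    }
    nm <- names(x)
    x <- t(vapply(
      toupper(x),
      function(s) {
        substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      },
      character(nchar(x[1]) / 3)
    ))
    rownames(x) <- nm
  }
  if (is.character(x)) {
    codes <- match(toupper(x), gc$codons)
    dim(codes) <- dim(x)
    dimnames(codes) <- dimnames(x)
    is_stop <- toupper(x) %in% c("TAA", "TAG", "TGA")
    dim(is_stop) <- dim(x)
    if (any(is_stop)) {
      if (stop_codons == "error") {
        idx <- which(is_stop, arr.ind = TRUE)[1, ]
        stop(
          "stop codon in sequence ", idx[1], " at codon site ", idx[2],
          " (use stop_codons = \"mask\" to treat as missing)"
        )
      }
      codes[is_stop] <- NA
    }
    x <- codes
  }
  storage.mode(x) <- "integer"
  if (any(!is.na(x) & (x < 1L | x > 61L))) {
    stop("codon states must be in 1..61 or NA")
  }
  structure(x, codons = gc$codons, class = c("codon_alignment", "matrix", "array"))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(
    "Codon alignment: ", nrow(x), " taxa x ", ncol(x), " codons (",
    sum(is.na(x)), " missing cells)\n",
    sep = ""
  )
  invisible(x)
}

#' Collapse an alignment to its distinct site patterns
#'
#' @param aln A [codon_alignment()].
#' @return A list with `patterns` (taxa x n_pattern integer matrix, 0 for
#'   missing), `weights` (pattern multiplicities, summing to the alignment
#'   length) and `site_of` (pattern index per original site).
#' @export
compress_patterns <- function(aln) {
  m <- unclass(aln)
  m[is.na(m)] <- 0L
  key <- apply(m, 2, paste, collapse = ".")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(
    patterns = m[, first, drop = FALSE],
    weights = as.vector(table(factor(idx, levels = seq_len(sum(first))))),
    site_of = idx
  )
}

# Internal: fixed tree geometry shared by all likelihood evaluations.
# Reorders the tree into postorder and carries the partition assignment
# along (partition schemes are defined over the rows of tree$edge).
likelihood_engine <- function(tree, partition = NULL, data = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(partition)) partition <- rep(1L, nrow(tree$edge))
  stopifnot(length(partition) == nrow(tree$edge))
  post <- ape::reorder.phylo(tree, "postorder")
  key <- function(e) paste(e[, 1], e[, 2])
  perm <- match(key(post$edge), key(tree$edge))
  list(
    tree = post,
    partition = as.integer(partition)[perm],
    edge_perm = perm, # postorder row -> original tree$edge row
    n_tip = ape::Ntip(tree),
    n_node = ape::Ntip(tree) + tree$Nnode,
    root = ape::Ntip(tree) + 1L,
    pat = if (!is.null(data)) compress_patterns(data)
  )
}

# omega value for every (class, partition) cell given free-parameter values.
omega_table <- function(spec, omega_free) {
  om <- spec$omega
  val <- om$value
  free <- om$type != "fixed"
  if (any(free)) {
    val[free] <- omega_free[om$param[free]]
  }
  if (anyNA(val)) stop("missing value for free omega parameter(s)")
  matrix_from_cells(om$class, om$partition, val, spec$n_classes, spec$n_partitions)
}

matrix_from_cells <- function(class, partition, value, K, P) {
  m <- matrix(NA_real_, K, P)
  m[cbind(class, partition)] <- value
  m
}

# Distinct rate matrices + eigensystems for the current parameter point.
# Returns list(qid = K x P matrix of indices, eigensystems, mu = mean rates
# of the unscaled matrices, omegas = distinct omega values).
build_class_matrices <- function(spec, kappa, omega_free, freqs) {
  wmat <- omega_table(spec, omega_free)
  wvals <- sort(unique(as.vector(wmat)))
  qid <- matrix(match(wmat, wvals), nrow(wmat), ncol(wmat))
  mats <- lapply(wvals, function(w) codon_rate_matrix(kappa, w, freqs))
  list(
    qid = qid,
    matrices = mats,
    eigensystems = lapply(mats, eigen_system),
    mu = vapply(mats, mean_rate, 1)
  )
}

# The global mixture scale factor: mean rate averaged over site classes,
# each partition weighted by its share of tree length.
mixture_scale_factor <- function(cm, proportions, partition_usage) {
  K <- nrow(cm$qid)
  P <- ncol(cm$qid)
  rho <- 0
  for (k in seq_len(K)) {
    for (p in seq_len(P)) {
      rho <- rho + proportions[k] * partition_usage[p] * cm$mu[cm$qid[k, p]]
    }
  }
  if (rho <= 0) stop("mixture mean rate is zero; cannot scale")
  rho
}

partition_usage_from_lengths <- function(partition, lengths, n_part) {
  tot <- sum(lengths)
  if (tot <= 0) {
    return(rep(1 / n_part, n_part))
  }
  u <- vapply(seq_len(n_part), function(p) sum(lengths[partition == p]), 1)
  u / tot
}

# Per-pattern log-likelihood under each site class at a parameter point.
# branch_lengths are in the ORIGINAL tree$edge row order.
class_pattern_loglik <- function(spec, engine, kappa, omega_free, props_free,
                                 branch_lengths, freqs) {
  proportions <- class_proportions(spec, props_free)
  lens <- branch_lengths[engine$edge_perm]
  part <- engine$partition
  if (spec$n_partitions == 1L) {
    part <- rep(1L, length(part)) # site-only models ignore the partitioning
  } else if (max(part) != spec$n_partitions) {
    stop(
      "model expects ", spec$n_partitions,
      " partitions but the tree has ", max(part)
    )
  }
  cm <- build_class_matrices(spec, kappa, omega_free, freqs)
  usage <- partition_usage_from_lengths(part, lens, spec$n_partitions)
  rho <- mixture_scale_factor(cm, proportions, usage)
  es <- lapply(cm$eigensystems, function(e) {
    list(right = e$right, left = e$left, values = e$values / rho)
  })
  qindex <- cm$qid[, part, drop = FALSE] # n_class x n_edge
  ll <- class_site_loglik_cpp(
    edge = engine$tree$edge, lengths = lens, qindex = qindex,
    eigensystems = es, tipstates = engine$pat$patterns,
    pi = as.numeric(freqs), n_tip = engine$n_tip,
    n_node = engine$n_node, root = engine$root
  )
  list(loglik = ll, proportions = proportions, scale_factor = rho)
}

#' Mixture log-likelihood of an alignment under a site-class model
#'
#' Exact log-likelihood of a codon alignment given a tree with branch
#' partitions, computed by Felsenstein pruning over the 61 codon states,
#' summed over site classes: lnL = sum_sites ln( sum_k p_k L(site | k) ).
#'
#' @param spec A [model_spec()].
#' @param params Parameter list with elements `kappa` (ignored if the spec
#'   fixes kappa), `omega` (named vector over the spec's free omega
#'   parameters), `props` (free proportion parameters, see [model_spec()]),
#'   and `branch_lengths` (vector over rows of `tree$edge`).
#' @param tree An [ape::phylo] tree.
#' @param data A [codon_alignment()].
#' @param partition A [partition_scheme()] (default: single partition).
#' @param freqs Codon equilibrium frequencies.
#' @return The log-likelihood (single number).
#' @export
mixture_log_likelihood <- function(spec, params, tree, data,
                                   partition = NULL,
                                   freqs = equal_frequencies()) {
  engine <- likelihood_engine(tree, partition, data)
  kappa <- if (identical(spec$kappa, "free")) params$kappa else spec$kappa
  check_params(spec, params)
  cl <- class_pattern_loglik(
    spec, engine, kappa, params$omega, params$props,
    params$branch_lengths, freqs
  )
  pattern_mixture_lnl(cl$loglik, cl$proportions, engine$pat$weights)
}

pattern_mixture_lnl <- function(class_ll, proportions, weights) {
  # log-sum-exp across classes, then weight by pattern multiplicity
  m <- apply(class_ll, 1, max)
  mix <- m + log(as.vector(exp(class_ll - m) %*% proportions))
  sum(weights * mix)
}

check_params <- function(spec, params) {
  om <- spec$omega
  free <- om$type != "fixed"
  need <- unique(om$param[free])
  if (!all(need %in% names(params$omega))) {
    stop(
      "params$omega must name: ",
      paste(setdiff(need, names(params$omega)), collapse = ", ")
    )
  }
  for (i in which(free)) {
    w <- params$omega[[om$param[i]]]
    bad <- switch(om$type[i],
      bounded01 = w <= 0 || w >= 1,
      positive = w < 0,
      ge1 = w < 1,
      FALSE
    )
    if (bad) {
      stop(
        "omega parameter '", om$param[i], "' = ", w,
        " violates its constraint (", om$type[i], ")"
      )
    }
  }
  pr <- class_proportions(spec, params$props)
  if (any(pr < -1e-12) || abs(sum(pr) - 1) > 1e-8) {
    stop("class proportions must lie in the simplex")
  }
  invisible(TRUE)
}
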