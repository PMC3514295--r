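#' Codon substitution rate matrix
#'
#' Builds the 61 x 61 instantaneous rate matrix of the codon model in its
#' Goldman-Yang form. Off-diagonal rates for single-nucleotide changes are
#' proportional to the target codon's equilibrium frequency pi_j, times
#' kappa for transitions and omega for nonsynonymous changes; codon pairs
#' differing at two or more positions have rate zero; diagonals make rows
#' sum to zero. The matrix is returned unscaled (see [scale_class_matrices()]
#' for the mixture-level normalization that defines branch-length units).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param freqs A [codon_frequencies()] object (or 61-vector).
#' @return A `rate_matrix`: 61 x 61 matrix with attributes `omega`, `kappa`,
#'   `pi`, `scaled` (logical) and `scale_factor`.
#' @export
codon_rate_matrix <- function(kappa, omega, freqs = equal_frequencies()) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  gc <- genetic_code()
  pi <- as.numeric(freqs)
  stopifnot(length(pi) == 61L)
  pc <- gc$pair_class
  mult <- matrix(0, 61, 61, dimnames = dimnames(pc))
  mult[pc == 2L] <- kappa
  mult[pc == 3L] <- 1
  mult[pc == 4L] <- kappa * omega
  mult[pc == 5L] <- omega
  q <- mult * rep(pi, each = 61) # q[i, j] = mult * pi_j
  diag(q) <- -rowSums(q)
  structure(q,
    omega = omega, kappa = kappa, pi = pi,
    scaled = FALSE, scale_factor = 1,
    class = c("rate_matrix", "matrix", "array")
  )
}

#' Mean substitution rate of a rate matrix at equilibrium
#'
#' The expected number of substitutions per codon per unit time,
#' sum_i pi_i * (-q_ii).
#'
#' @param q A `rate_matrix`.
#' @param pi Equilibrium frequencies; defaults to those stored in `q`.
#' @return A single number.
#' @export
mean_rate <- function(q, pi = attr(q, "pi")) {
  sum(pi * -diag(unclass(q)))
}

#' Normalize a set of site-class rate matrices to unit mean rate
#'
#' Applies one global divisor to all class/partition matrices of a mixture
#' model so that the mixture-averaged mean rate equals 1, making branch
#' lengths expected substitutions per codon averaged over site classes.
#' Each partition's matrices are weighted by the expected fraction of tree
#' length falling in that partition, so a branch's length is measured under
#' the omega set that actually applies to it.
#'
#' @param class_matrices A list over site classes; each element is a list of
#'   `rate_matrix` objects, one per tree partition (length-1 lists are
#'   recycled across partitions).
#' @param proportions Site-class proportions (sum to 1).
#' @param partition_usage Expected fraction of tree length per partition
#'   (sums to 1); defaults to equal usage.
#' @return A list with `matrices` (same shape, each divided by the factor,
#'   with `scaled = TRUE`), and `scale_factor` (the divisor).
#' @export
scale_class_matrices <- function(class_matrices, proportions,
                                 partition_usage = NULL) {
  stopifnot(length(class_matrices) == length(proportions))
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("class proportions must sum to 1")
  }
  npart <- max(vapply(class_matrices, length, 1L))
  if (is.null(partition_usage)) partition_usage <- rep(1 / npart, npart)
  stopifnot(length(partition_usage) == npart)

  rho <- 0
  for (k in seq_along(class_matrices)) {
    mats <- class_matrices[[k]]
    if (length(mats) == 1L) mats <- rep(mats, npart)
    for (p in seq_len(npart)) {
      rho <- rho + proportions[k] * partition_usage[p] * mean_rate(mats[[p]])
    }
  }
  if (rho <= 0) {
    stop("mixture mean rate is zero; cannot scale (all classes have rate 0)")
  }
  scaled <- lapply(class_matrices, function(mats) {
    lapply(mats, function(q) {
      out <- q / rho
      attributes(out) <- attributes(q)
      attr(out, "scaled") <- TRUE
      attr(out, "scale_factor") <- attr(q, "scale_factor") * rho
      out
    })
  })
  list(matrices = scaled, scale_factor = rho)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by symmetric eigendecomposition of the reversible generator
#' (similarity transform by diag(sqrt(pi))), which is exact and stable for
#' these matrices. Entries are clamped at zero against roundoff.
#'
#' @param q A `rate_matrix` (normally scaled).
#' @param t Branch length (>= 0), expected substitutions per codon.
#' @return A 61 x 61 stochastic matrix.
#' @export
transition_matrix <- function(q, t) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  es <- eigen_system(q)
  p <- es$right %*% (exp(es$values * t) * es$left)
  p[p < 0] <- 0
  dimnames(p) <- dimnames(q)
  p
}

# Eigendecomposition of a reversible rate matrix.
# Returns right/left factors such that exp(Qt) = right %*% diag(exp(vt)) %*% left,
# with left pre-multiplied so that P(t) = right %*% (exp(v t) * left).
eigen_system <- function(q, pi = attr(q, "pi")) {
  if (is.null(pi)) stop("rate matrix lacks equilibrium frequencies")
  sq <- sqrt(pi)
  s <- unclass(q) * (sq / rep(sq, each = length(sq)))
  s <- (s + t(s)) / 2 # enforce exact symmetry
  es <- eigen(s, symmetric = TRUE)
  right <- es$vectors / sq
  left <- t(es$vectors * sq)
  list(values = es$values, right = right, left = left)
}
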