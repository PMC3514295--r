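#' Declarative specification of a codon site-class model
#'
#' Constructs the site-class structure of the dN/dS models in the package's
#' ladder. A model is a mixture over site classes; each class has one omega
#' per tree partition, and each omega carries a constraint tag:
#' `fixed(value)`, `bounded01` (0 < omega < 1), `positive` (omega > 0) or
#' `ge1` (omega >= 1, branch-site foreground).
#'
#' Supported kinds:
#' * `M0`: one class, one free omega.
#' * `M1a`: purifying (0 < omega0 < 1) + neutral (omega1 = 1).
#' * `M2a_rel`: M1a plus a third class with one tree-wide free omega.
#' * `M3`: `K` classes, all omegas free, shared across partitions.
#' * `Branch`: one class, one free omega per partition.
#' * `BranchSiteA`: four classes; foreground omega2 >= 1 applies to
#'   classes 2a/2b on non-background partitions; proportions derived from
#'   (p0, p1) as p0, p1, p0 p2/(1-p2), p1 p2/(1-p2) with p2 = 1-p0-p1.
#' * `BranchSiteA_null`: branch-site A with omega2 fixed at 1.
#' * `CmC`: purifying + neutral + a divergent class with a separately
#'   estimated omega per partition (the clade model; with more than two
#'   partitions this is the multi-clade form).
#' * `CmD`: `K` classes, all free, the last with per-partition omegas.
#'
#' @param kind Model kind (see above).
#' @param n_partitions Number of tree partitions the model sees. Branch,
#'   branch-site and clade kinds require at least 2.
#' @param K Number of site classes for `M3`/`CmD` (default 3).
#' @param kappa Either `"free"` (estimated) or a fixed numeric value.
#' @return A `model_spec` object.
#' @examples
#' model_spec("CmC", n_partitions = 2)
#' @export
model_spec <- function(kind = c(
                         "M0", "M1a", "M2a_rel", "M3", "Branch",
                         "BranchSiteA", "BranchSiteA_null", "CmC", "CmD"
                       ),
                       n_partitions = 1, K = 3, kappa = "free") {
  kind <- match.arg(kind)
  P <- as.integer(n_partitions)
  if (P < 1) stop("n_partitions must be >= 1")
  needs_parts <- c("Branch", "BranchSiteA", "BranchSiteA_null", "CmC", "CmD")
  if (kind %in% needs_parts && P < 2) {
    stop("model kind '", kind, "' requires at least 2 tree partitions")
  }

  cell <- function(class, param, type, value = NA_real_, partition = seq_len(P)) {
    data.frame(
      class = class, partition = partition, param = param,
      type = type, value = value, stringsAsFactors = FALSE
    )
  }
  omega <- switch(kind,
    M0 = cell(1L, "w0", "positive"),
    M1a = rbind(
      cell(1L, "w0", "bounded01"),
      cell(2L, NA, "fixed", 1)
    ),
    M2a_rel = rbind(
      cell(1L, "w0", "bounded01"),
      cell(2L, NA, "fixed", 1),
      cell(3L, "w2", "positive")
    ),
    M3 = do.call(rbind, lapply(seq_len(K), function(k) {
      cell(k, paste0("w", k - 1L), "positive")
    })),
    Branch = do.call(rbind, lapply(seq_len(P), function(p) {
      cell(1L, paste0("w_part", p), "positive", partition = p)
    })),
    BranchSiteA = ,
    BranchSiteA_null = {
      w2type <- if (kind == "BranchSiteA") "ge1" else "fixed"
      w2param <- if (kind == "BranchSiteA") "w2" else NA
      w2val <- if (kind == "BranchSiteA") NA_real_ else 1
      rbind(
        cell(1L, "w0", "bounded01"),
        cell(2L, NA, "fixed", 1),
        cell(3L, "w0", "bounded01", partition = 1L),
        cell(3L, w2param, w2type, w2val, partition = 2:P),
        cell(4L, NA, "fixed", 1, partition = 1L),
        cell(4L, w2param, w2type, w2val, partition = 2:P)
      )
    },
    CmC = rbind(
      cell(1L, "w0", "bounded01"),
      cell(2L, NA, "fixed", 1),
      do.call(rbind, lapply(seq_len(P), function(p) {
        cell(3L, paste0("w2_part", p), "positive", partition = p)
      }))
    ),
    CmD = rbind(
      do.call(rbind, lapply(seq_len(K - 1L), function(k) {
        cell(k, paste0("w", k - 1L), "positive")
      })),
      do.call(rbind, lapply(seq_len(P), function(p) {
        cell(K, paste0("w", K - 1L, "_part", p), "positive", partition = p)
      }))
    )
  )
  nclass <- max(omega$class)
  prop_model <- if (nclass == 1L) {
    "none"
  } else if (kind %in% c("BranchSiteA", "BranchSiteA_null")) {
    "bsA"
  } else {
    "stick"
  }
  new_model_spec(kind, P, nclass, omega, prop_model, kappa)
}

new_model_spec <- function(kind, P, nclass, omega, prop_model, kappa) {
  rownames(omega) <- NULL
  n_free_props <- switch(prop_model, none = 0L, bsA = 2L, nclass - 1L)
  structure(
    list(
      kind = kind, n_partitions = P, n_classes = nclass,
      omega = omega, prop_model = prop_model,
      n_free_props = n_free_props,
      kappa = kappa
    ),
    class = "model_spec"
  )
}

# Distinct free omega parameter ids, in stable order.
free_omega_params <- function(spec) {
  unique(spec$omega$param[spec$omega$type != "fixed" &
    !is.na(spec$omega$param)])
}

#' Count the free parameters of a model
#'
#' Free selection parameters (omegas + class proportions), plus kappa if
#' estimated, plus one branch length per edge if `n_branches` is given --
#' the "n.p." of the model tables.
#'
#' @param spec A `model_spec`.
#' @param n_branches Number of tree edges (0 to count selection parameters
#'   only).
#' @return Integer.
#' @export
n_free_parameters <- function(spec, n_branches = 0L) {
  length(free_omega_params(spec)) + spec$n_free_props +
    (identical(spec$kappa, "free")) + as.integer(n_branches)
}

#' Constrain one omega of a model to a fixed value
#'
#' Produces the nested model obtained by fixing a single free omega
#' parameter (for example the branch-site null, omega2 = 1, or the clade
#' test of whether a partition's divergent omega differs from 1). All
#' cells sharing the parameter are fixed together, so the free-parameter
#' count drops by exactly 1.
#'
#' @param spec A `model_spec`.
#' @param class Site-class index of the targeted omega.
#' @param partition Partition index (default 1; irrelevant for shared
#'   omegas).
#' @param value The value to fix the omega at.
#' @return A new `model_spec`.
#' @export
constrain_omega <- function(spec, class, partition = 1L, value = 1) {
  om <- spec$omega
  row <- which(om$class == class & om$partition == partition)
  if (!length(row)) stop("no such class/partition cell")
  par <- om$param[row[1]]
  if (om$type[row[1]] == "fixed" || is.na(par)) {
    stop("omega for class ", class, ", partition ", partition,
      " is already fixed",
      call. = FALSE
    )
  }
  hit <- !is.na(om$param) & om$param == par
  om$type[hit] <- "fixed"
  om$value[hit] <- value
  om$param[hit] <- NA
  kind <- if (spec$kind == "BranchSiteA" && identical(par, "w2")) {
    "BranchSiteA_null"
  } else {
    spec$kind
  }
  out <- new_model_spec(
    kind, spec$n_partitions, spec$n_classes, om,
    spec$prop_model, spec$kappa
  )
  attr(out, "constrained_from") <- spec$kind
  out
}

#' Is one model nested within another?
#'
#' Introspective check used before a likelihood ratio test: the null's
#' parameter space must be obtainable from the alternative's by equality
#' constraints alone. Same-kind pairs are nested when the null has fewer
#' free parameters (fixed omegas or merged partitions); across kinds the
#' recognised pairs are the ladder's standard ones (M1a or M2a_rel inside
#' CmC; M1a inside M2a_rel; M0 inside every site model and inside Branch;
#' branch-site A null inside branch-site A; M3 inside CmD; CmC inside CmD).
#'
#' @param null,alt `model_spec` objects.
#' @return Logical.
#' @export
is_nested <- function(null, alt) {
  npn <- n_free_parameters(null)
  npa <- n_free_parameters(alt)
  if (npn >= npa) {
    return(FALSE)
  }
  if (null$kind == alt$kind) {
    return(TRUE)
  }
  pairs <- list(
    c("M0", "M1a"), c("M0", "M2a_rel"), c("M0", "M3"), c("M0", "Branch"),
    c("M0", "CmC"), c("M0", "CmD"),
    c("M1a", "M2a_rel"), c("M1a", "CmC"), c("M1a", "BranchSiteA"),
    c("M1a", "BranchSiteA_null"),
    c("M2a_rel", "CmC"),
    c("BranchSiteA_null", "BranchSiteA"),
    c("M3", "CmD"), c("CmC", "CmD")
  )
  any(vapply(pairs, function(p) {
    null$kind == p[1] && alt$kind == p[2]
  }, logical(1)))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Codon model ", x$kind, ": ", x$n_classes, " site class(es), ",
    x$n_partitions, " partition(s), ",
    n_free_parameters(x), " free selection parameter(s)",
    if (identical(x$kappa, "free")) " + kappa" else
      paste0(" (kappa fixed at ", x$kappa, ")"),
    "\n",
    sep = ""
  )
  invisible(x)
}

# Class proportions from free proportion parameters (probability scale).
class_proportions <- function(spec, p_free) {
  switch(spec$prop_model,
    none = 1,
    bsA = {
      p0 <- p_free[1]
      p1 <- p_free[2]
      p2 <- 1 - p0 - p1
      base <- p0 + p1
      c(p0, p1, p0 * p2 / base, p1 * p2 / base)
    },
    p_free_to_simplex(p_free, spec$n_classes)
  )
}

p_free_to_simplex <- function(p_free, K) {
  stopifnot(length(p_free) == K - 1)
  c(p_free, 1 - sum(p_free))
}
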