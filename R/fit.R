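# Parameter packing: all free parameters are optimized on an unconstrained
# scale (log for positive omegas, kappa and branch lengths; logit for
# bounded omegas; stick-breaking logits for class proportions), with box
# bounds wide enough to act only as numerical guards.

param_template <- function(spec, n_edge) {
  wpar <- free_omega_params(spec)
  wtype <- vapply(wpar, function(p) {
    spec$omega$type[match(p, spec$omega$param)]
  }, character(1))
  n_kappa <- as.integer(identical(spec$kappa, "free"))
  sizes <- c(
    lens = n_edge, kappa = n_kappa,
    omega = length(wpar), props = spec$n_free_props
  )
  ends <- cumsum(sizes)
  idx <- Map(function(a, b) if (b >= a) a:b else integer(0),
    c(1, ends[-length(ends)] + 1), ends
  )
  names(idx) <- names(sizes)
  list(idx = idx, omega_params = wpar, omega_types = wtype, n = ends[[length(ends)]])
}

.t_floor <- 1e-8

pack_params <- function(spec, tpl, kappa, omega, props, lens) {
  theta <- numeric(tpl$n)
  theta[tpl$idx$lens] <- log(pmax(lens, .t_floor))
  if (length(tpl$idx$kappa)) theta[tpl$idx$kappa] <- log(kappa)
  if (length(tpl$idx$omega)) {
    theta[tpl$idx$omega] <- vapply(seq_along(tpl$omega_params), function(i) {
      w <- omega[[tpl$omega_params[i]]]
      switch(tpl$omega_types[i],
        positive = log(max(w, 1e-8)),
        bounded01 = stats::qlogis(min(max(w, 1e-8), 1 - 1e-8)),
        ge1 = log(max(w - 1, 1e-8))
      )
    }, 1)
  }
  if (length(tpl$idx$props)) {
    theta[tpl$idx$props] <- simplex_to_logits(props_to_simplex(spec, props))
  }
  theta
}

unpack_params <- function(spec, tpl, theta) {
  lens <- exp(theta[tpl$idx$lens])
  kappa <- if (length(tpl$idx$kappa)) exp(theta[tpl$idx$kappa]) else spec$kappa
  omega <- stats::setNames(
    vapply(seq_along(tpl$omega_params), function(i) {
      x <- theta[tpl$idx$omega[i]]
      switch(tpl$omega_types[i],
        positive = exp(x),
        bounded01 = stats::plogis(x),
        ge1 = 1 + exp(x)
      )
    }, 1),
    tpl$omega_params
  )
  props <- if (length(tpl$idx$props)) {
    simplex_from_logits(theta[tpl$idx$props])[seq_len(spec$n_free_props)]
  } else {
    numeric(0)
  }
  list(kappa = kappa, omega = omega, props = props, branch_lengths = lens)
}

param_bounds <- function(spec, tpl) {
  lower <- rep(-30, tpl$n)
  upper <- rep(30, tpl$n)
  lower[tpl$idx$lens] <- log(.t_floor)
  upper[tpl$idx$lens] <- log(50)
  if (length(tpl$idx$kappa)) {
    lower[tpl$idx$kappa] <- log(1e-3)
    upper[tpl$idx$kappa] <- log(999)
  }
  if (length(tpl$idx$omega)) {
    pos <- tpl$idx$omega[tpl$omega_types %in% c("positive", "ge1")]
    lower[pos] <- log(1e-8)
    upper[pos] <- log(999)
  }
  list(lower = lower, upper = upper)
}

# stick-breaking between a (K-1)-vector of logits and the first K-1
# coordinates of a K-simplex
simplex_from_logits <- function(z) {
  K <- length(z) + 1L
  p <- numeric(K)
  rem <- 1
  for (i in seq_along(z)) {
    p[i] <- rem * stats::plogis(z[i])
    rem <- rem - p[i]
  }
  p[K] <- rem
  p
}

simplex_to_logits <- function(p) {
  K <- length(p)
  z <- numeric(K - 1L)
  rem <- 1
  for (i in seq_len(K - 1L)) {
    z[i] <- stats::qlogis(min(max(p[i] / rem, 1e-10), 1 - 1e-10))
    rem <- rem - p[i]
  }
  z
}

# free proportion parameters -> full simplex over "stick" coordinates
# (for bsA the free parameters are (p0, p1) on the 3-simplex)
props_to_simplex <- function(spec, props) {
  if (spec$prop_model == "bsA") {
    c(props[1], props[2], 1 - props[1] - props[2])
  } else {
    c(props, 1 - sum(props))
  }
}

default_start <- function(spec, tree, restart) {
  wstarts <- c(0.1, 1.0, 2.0)
  bstarts <- c(0.2, 0.5, 0.8)
  i <- (restart - 1L) %% 3L + 1L
  omega <- stats::setNames(numeric(0), character(0))
  tpl_types <- spec$omega$type[spec$omega$type != "fixed"]
  for (p in free_omega_params(spec)) {
    ty <- spec$omega$type[match(p, spec$omega$param)]
    omega[p] <- switch(ty,
      positive = wstarts[i],
      bounded01 = bstarts[i],
      ge1 = 1 + wstarts[i]
    )
  }
  # spread shared-class starts a little so M3/CmD classes are not identical
  if (length(omega) > 1) {
    omega <- omega * exp(seq(-0.2, 0.2, length.out = length(omega)))
    ge1 <- vapply(names(omega), function(p) {
      spec$omega$type[match(p, spec$omega$param)] == "ge1"
    }, logical(1))
    omega[ge1] <- pmax(omega[ge1], 1 + 1e-6)
    b01 <- vapply(names(omega), function(p) {
      spec$omega$type[match(p, spec$omega$param)] == "bounded01"
    }, logical(1))
    omega[b01] <- pmin(omega[b01], 0.95)
  }
  props <- switch(spec$prop_model,
    none = numeric(0),
    bsA = c(0.45, 0.45),
    {
      K <- spec$n_classes
      p <- c(0.6, rep(0.4 / (K - 1), K - 1))
      p[seq_len(K - 1)]
    }
  )
  kappa <- if (identical(spec$kappa, "free")) c(2, 4)[(restart - 1L) %% 2L + 1L] else NULL
  lens <- tree$edge.length
  if (is.null(lens) || any(!is.finite(lens))) lens <- rep(0.1, nrow(tree$edge))
  lens <- pmax(lens, .t_floor)
  if (restart > 1L) lens <- lens * exp(stats::runif(length(lens), -0.3, 0.3))
  list(kappa = kappa, omega = omega, props = props, branch_lengths = lens)
}

#' Fit a codon site-class model by maximum likelihood
#'
#' Maximizes the mixture log-likelihood over branch lengths, kappa (unless
#' fixed by the spec) and the model's free selection parameters, using
#' bounded quasi-Newton (L-BFGS-B) on transformed parameters. The model is
#' fit from several starting points (omega and kappa perturbed between
#' restarts) to guard against local optima; the best restart is returned.
#'
#' @param spec A [model_spec()].
#' @param tree An [ape::phylo] tree (edge lengths, if present, seed the
#'   branch-length starting values).
#' @param data A [codon_alignment()].
#' @param partition A [partition_scheme()] over `tree`; default single
#'   partition.
#' @param freqs Codon equilibrium frequencies (default equal, 1/61).
#' @param n_restarts Number of optimizer restarts (>= 1).
#' @param seed Optional integer seed controlling restart jitter.
#' @param init Optional warm start: a parameter list as returned in
#'   `$params` of a previous fit (extra entries are ignored).
#' @param control Optimizer control overrides passed to [stats::optim()]
#'   (defaults: `maxit = 2000`, `factr = 1e7`, central-difference step
#'   `ndeps = 1e-5`).
#' @return A `cm_fit` object: maximized `lnL`, `kappa`, `omega` (class x
#'   partition matrix), `proportions`, `branch_lengths` (tree edge order),
#'   free-parameter count `np`, convergence diagnostics, and the inputs
#'   needed to re-evaluate the likelihood.
#' @export
fit_model <- function(spec, tree, data, partition = NULL,
                      freqs = equal_frequencies(),
                      n_restarts = 3, seed = NULL, init = NULL,
                      control = list()) {
  stopifnot(inherits(spec, "model_spec"))
  engine <- likelihood_engine(tree, partition, data)
  n_edge <- nrow(tree$edge)
  tpl <- param_template(spec, n_edge)
  bb <- param_bounds(spec, tpl)
  ctrl <- utils::modifyList(list(maxit = 2000, factr = 1e7), control)
  ev <- make_evaluators(spec, engine, freqs, tpl)

  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    if (!is.null(seed)) set.seed(seed + r)
    start <- if (!is.null(init) && r == 1L) {
      merge_start(default_start(spec, tree, r), init, tpl)
    } else {
      default_start(spec, tree, r)
    }
    theta0 <- pack_params(
      spec, tpl, start$kappa %||% 2, start$omega, start$props,
      start$branch_lengths[engine$edge_perm]
    )
    theta0 <- pmin(pmax(theta0, bb$lower), bb$upper)
    opt <- try(
      stats::optim(theta0, ev$negll,
        gr = ev$grad,
        method = "L-BFGS-B",
        lower = bb$lower, upper = bb$upper, control = ctrl
      ),
      silent = TRUE
    )
    if (inherits(opt, "try-error")) next
    runs[[r]] <- opt
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("optimization failed on all restarts")
  values <- vapply(runs, function(o) if (is.null(o)) Inf else o$value, 1)
  best <- runs[[which.min(values)]]
  params <- unpack_params(spec, tpl, best$par)
  params$branch_lengths <- reorder_back(params$branch_lengths, engine)

  structure(
    list(
      spec = spec,
      lnL = -best$value,
      kappa = unname(params$kappa),
      omega = omega_table(spec, params$omega),
      proportions = class_proportions(spec, params$props),
      branch_lengths = params$branch_lengths,
      params = params,
      np = n_free_parameters(spec, n_edge),
      n_restarts = n_restarts,
      converged = best$convergence == 0,
      restart_spread = if (sum(ok) > 1) {
        max(-values[is.finite(values)]) - min(-values[is.finite(values)])
      } else {
        0
      },
      tree = tree, partition = partition, freqs = freqs, data = data
    ),
    class = "cm_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Objective and gradient closures used by fit_model. The log-likelihood
# gradient with respect to every (scaled) branch length comes from one
# analytic outside/inside sweep in C++; the handful of selection
# parameters (kappa, omegas, proportion logits) use central differences.
# Eigensystems are cached across evaluations keyed by (kappa, omega), so
# branch-length and proportion moves never re-decompose rate matrices.
make_evaluators <- function(spec, engine, freqs, tpl, fd_step = 1e-5) {
  part <- engine$partition
  if (spec$n_partitions == 1L) {
    part <- rep(1L, length(part))
  } else if (max(part) != spec$n_partitions) {
    stop(
      "model expects ", spec$n_partitions,
      " partitions but the tree has ", max(part)
    )
  }
  pi <- as.numeric(freqs)
  weights <- engine$pat$weights
  cache <- new.env(parent = emptyenv())

  get_cm <- function(kappa, omega_free) {
    key <- paste(
      format(kappa, digits = 17),
      paste(format(omega_free, digits = 17), collapse = ","),
      sep = "|"
    )
    cm <- cache[[key]]
    if (is.null(cm)) {
      cm <- build_class_matrices(spec, kappa, omega_free, freqs)
      if (length(ls(cache)) > 64L) rm(list = ls(cache), envir = cache)
      cache[[key]] <- cm
    }
    cm
  }

  # shared setup at a parameter point (branch lengths in postorder slots)
  point <- function(pp) {
    kappa <- if (identical(spec$kappa, "free")) pp$kappa else spec$kappa
    cm <- get_cm(kappa, pp$omega)
    proportions <- class_proportions(spec, pp$props)
    lens <- pp$branch_lengths
    usage <- partition_usage_from_lengths(part, lens, spec$n_partitions)
    rho <- mixture_scale_factor(cm, proportions, usage)
    es <- lapply(cm$eigensystems, function(e) {
      list(right = e$right, left = e$left, values = e$values / rho)
    })
    list(
      cm = cm, proportions = proportions, lens = lens, rho = rho,
      es = es, qindex = cm$qid[, part, drop = FALSE]
    )
  }

  lnl_at <- function(pp) {
    pt <- point(pp)
    ll <- class_site_loglik_cpp(
      edge = engine$tree$edge, lengths = pt$lens, qindex = pt$qindex,
      eigensystems = pt$es, tipstates = engine$pat$patterns,
      pi = pi, n_tip = engine$n_tip, n_node = engine$n_node,
      root = engine$root
    )
    pattern_mixture_lnl(ll, pt$proportions, weights)
  }

  negll <- function(theta) {
    pp <- unpack_params(spec, tpl, theta)
    ll <- try(lnl_at(pp), silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) {
      return(1e10)
    }
    -ll
  }

  grad <- function(theta) {
    pp <- unpack_params(spec, tpl, theta)
    pt <- try(point(pp), silent = TRUE)
    if (inherits(pt, "try-error")) {
      return(rep(0, tpl$n))
    }
    res <- class_site_loglik_grad_cpp(
      edge = engine$tree$edge, lengths = pt$lens, qindex = pt$qindex,
      eigensystems = pt$es,
      generators = lapply(pt$cm$matrices, unclass),
      tipstates = engine$pat$patterns, pi = pi,
      n_tip = engine$n_tip, n_node = engine$n_node, root = engine$root,
      proportions = pt$proportions, weights = weights
    )
    # d lnL / d t_e, accounting for the scale factor's dependence on the
    # branch lengths through partition usage: u_f = t_f / rho(t)
    g_u <- res$grad_s
    lens <- pt$lens
    rho <- pt$rho
    tl <- sum(lens)
    m_p <- vapply(seq_len(spec$n_partitions), function(p) {
      sum(pt$proportions * pt$cm$mu[pt$cm$qid[, p]])
    }, 1)
    g_t <- g_u / rho - ((m_p[part] - rho) / (rho^2 * tl)) * sum(g_u * lens)
    out <- numeric(tpl$n)
    out[tpl$idx$lens] <- g_t * lens # chain to log scale

    # central differences for the selection parameters
    sel <- c(tpl$idx$kappa, tpl$idx$omega, tpl$idx$props)
    for (i in sel) {
      up <- theta
      dn <- theta
      up[i] <- up[i] + fd_step
      dn[i] <- dn[i] - fd_step
      out[i] <- (-negll(up) + negll(dn)) / (2 * fd_step)
    }
    -out
  }

  list(negll = negll, grad = grad, lnl_at = lnl_at)
}

# branch lengths are optimized in postorder slots; map back to tree$edge order
reorder_back <- function(lens_post, engine) {
  out <- numeric(length(lens_post))
  out[engine$edge_perm] <- lens_post
  out
}

merge_start <- function(start, init, tpl) {
  for (nm in c("kappa", "props", "branch_lengths")) {
    if (!is.null(init[[nm]]) && length(init[[nm]]) == length(start[[nm]])) {
      start[[nm]] <- init[[nm]]
    }
  }
  if (!is.null(init$omega)) {
    keep <- intersect(names(start$omega), names(init$omega))
    start$omega[keep] <- init$omega[keep]
  }
  start
}

#' @export
print.cm_fit <- function(x, ...) {
  cat("Codon model fit: ", x$spec$kind, "\n", sep = "")
  cat(
    "  lnL = ", formatC(x$lnL, format = "f", digits = 4),
    "  (np = ", x$np, ", converged: ", x$converged, ")\n",
    sep = ""
  )
  cat("  kappa =", formatC(x$kappa, digits = 4), "\n")
  cat("  class proportions:", paste(formatC(x$proportions, digits = 3),
    collapse = ", "
  ), "\n")
  cat("  omega (class x partition):\n")
  print(round(x$omega, 4))
  invisible(x)
}

#' @export
logLik.cm_fit <- function(object, ...) {
  structure(object$lnL, df = object$np, class = "logLik")
}
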