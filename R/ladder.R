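#' Run the full model ladder on a dataset
#'
#' Fits the site-only models (M0, M1a, M2a_rel) once, and, for every named
#' partition scheme supplied, the Branch model, branch-site model A with
#' its null, and clade models C and D. Emits the standard report tables:
#' an AIC ranking with Akaike weights across all fitted models, the LRT
#' matrix of every nested pair in the ladder, omega = 1 tests for each
#' partition's divergent-class omega under each clade model C fit, and the
#' empirical-Bayes site table under the best-fitting clade model.
#'
#' @param tree An [ape::phylo] tree.
#' @param data A [codon_alignment()].
#' @param partition_schemes Named list of [partition_scheme()] objects
#'   (may be empty: clade/branch models are then skipped with a message).
#' @param freqs Codon frequencies (default F3x4 from the data).
#' @param models Subset of partitioned model kinds to run per scheme.
#' @param n_restarts,seed Passed to [fit_model()].
#' @param pp_threshold Posterior-probability threshold for the site table.
#' @param omega_tests Run the omega = 1 clade tests (refits; can be slow).
#' @return A `cm_ladder` list: `fits` (named list of `cm_fit`), `aic`,
#'   `lrt`, `omega_tests`, `sites`, `best_clade_model`.
#' @export
run_model_ladder <- function(tree, data, partition_schemes = list(),
                             freqs = NULL,
                             models = c("Branch", "BranchSiteA", "CmC", "CmD"),
                             n_restarts = 2, seed = NULL,
                             pp_threshold = 0.75, omega_tests = TRUE) {
  if (is.null(freqs)) freqs <- f3x4_frequencies(data)
  if (length(partition_schemes) && is.null(names(partition_schemes))) {
    names(partition_schemes) <- paste0("scheme", seq_along(partition_schemes))
  }
  fits <- list()
  fit1 <- function(kind, ...) {
    fit_model(model_spec(kind, ...),
      tree = tree, data = data, freqs = freqs,
      n_restarts = n_restarts, seed = seed
    )
  }
  fits$M0 <- fit1("M0")
  fits$M1a <- fit1("M1a")
  fits$M2a_rel <- fit1("M2a_rel")

  if (!length(partition_schemes)) {
    message("no partition schemes supplied; clade and branch models skipped")
  }
  for (sn in names(partition_schemes)) {
    part <- partition_schemes[[sn]]
    P <- n_partitions(part)
    fitp <- function(kind, init = NULL) {
      fit_model(model_spec(kind, n_partitions = P),
        tree = tree, data = data, partition = part, freqs = freqs,
        n_restarts = n_restarts, seed = seed, init = init
      )
    }
    for (kind in models) {
      # warm-start each partitioned model from its natural nested fit so
      # the ladder's LRTs cannot go negative through a missed optimum
      init <- switch(kind,
        Branch = fits$M0$params,
        BranchSiteA = fits$M1a$params,
        CmC = fits$M2a_rel$params,
        CmD = (fits[[paste("CmC", sn)]] %||% fits$M2a_rel)$params,
        NULL
      )
      fits[[paste(kind, sn)]] <- fitp(kind, init)
      if (kind == "BranchSiteA") {
        fits[[paste("BranchSiteA_null", sn)]] <- fitp(
          "BranchSiteA_null",
          fits$M1a$params
        )
      }
    }
  }

  aic <- aic_rank(fits)
  lrt <- ladder_lrt_matrix(fits)

  cmc_names <- grep("^CmC ", names(fits), value = TRUE)
  best_cmc <- if (length(cmc_names)) {
    cmc_names[which.max(vapply(
      fits[cmc_names],
      function(f) f$lnL - f$np, 1
    ))]
  } else {
    NULL
  }
  omega_tbl <- NULL
  sites <- NULL
  if (!is.null(best_cmc)) {
    best_fit <- fits[[best_cmc]]
    if (omega_tests) {
      labs <- attr(best_fit$partition, "labels")
      omega_tbl <- dplyr::bind_rows(lapply(seq_along(labs), function(p) {
        res <- clade_omega_test(best_fit, p, n_restarts = n_restarts, seed = seed)
        tibble::tibble(
          model = best_cmc, partition = labs[p],
          omega_hat = best_fit$omega[best_fit$spec$n_classes, p],
          lnL_constrained = res$fit_null$lnL,
          stat = res$lrt$stat, p_value = res$lrt$p_value
        )
      }))
    }
    sites <- site_posteriors(best_fit, data, threshold = pp_threshold)
  }
  structure(
    list(
      fits = fits, aic = aic, lrt = lrt,
      omega_tests = omega_tbl, sites = sites,
      best_clade_model = best_cmc
    ),
    class = "cm_ladder"
  )
}

# every nested pair among the ladder's fits, respecting partition geometry:
# a pair qualifies if the null is partition-free, the two fits share a
# scheme, or (same model kind) the alternative's scheme refines the null's
ladder_lrt_matrix <- function(fits) {
  nm <- names(fits)
  rows <- list()
  for (i in seq_along(fits)) {
    for (j in seq_along(fits)) {
      if (i == j) next
      if (!is_nested(fits[[i]]$spec, fits[[j]]$spec)) next
      if (!schemes_compatible(fits[[i]], fits[[j]])) next
      r <- likelihood_ratio_test(fits[[i]], fits[[j]])
      r$null <- nm[i]
      r$alternative <- nm[j]
      rows[[length(rows) + 1L]] <- r
    }
  }
  dplyr::bind_rows(rows)
}

schemes_compatible <- function(fit_null, fit_alt) {
  pn <- fit_null$partition
  pa <- fit_alt$partition
  if (is.null(pn) || fit_null$spec$n_partitions == 1L) {
    return(TRUE)
  }
  if (is.null(pa)) {
    return(FALSE)
  }
  if (identical(as.integer(pn), as.integer(pa))) {
    return(TRUE)
  }
  fit_null$spec$kind == fit_alt$spec$kind && scheme_refines(pn, pa)
}

# does `fine` refine `coarse` (every fine partition within one coarse one)?
scheme_refines <- function(coarse, fine) {
  coarse <- as.integer(coarse)
  fine <- as.integer(fine)
  length(coarse) == length(fine) &&
    all(vapply(
      split(coarse, fine),
      function(x) length(unique(x)) == 1L, logical(1)
    ))
}

#' @export
print.cm_ladder <- function(x, ...) {
  cat("Codon model ladder:", length(x$fits), "fitted models\n")
  print(x$aic, n = Inf)
  if (!is.null(x$best_clade_model)) {
    cat(
      "Best clade model:", x$best_clade_model, "with",
      sum(x$sites$divergent_flag), "divergent-flagged sites\n"
    )
  }
  invisible(x)
}
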