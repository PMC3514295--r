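#' Likelihood ratio test between nested codon-model fits
#'
#' Twice the difference in maximized log-likelihoods, compared against a
#' chi-square distribution with degrees of freedom equal to the number of
#' extra free parameters, or (for boundary nulls such as the branch-site
#' test) against a 50:50 mixture of a point mass at 0 and chi-square with
#' 1 df.
#'
#' @param fit_null,fit_alt `cm_fit` objects; the null must be nested in
#'   the alternative.
#' @param null_distribution `"chi2"` or `"mix50"`.
#' @return A one-row tibble: `null`, `alternative`, `stat` (2 delta lnL,
#'   clamped at 0), `df`, `p_value`, `null_distribution`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt,
                                  null_distribution = c("chi2", "mix50")) {
  null_distribution <- match.arg(null_distribution)
  if (!is_nested(fit_null$spec, fit_alt$spec)) {
    stop(
      "models are not nested: ", fit_null$spec$kind, " vs ",
      fit_alt$spec$kind
    )
  }
  df <- fit_alt$np - fit_null$np
  stat <- 2 * (fit_alt$lnL - fit_null$lnL)
  if (stat < -1e-6) {
    warning(
      "alternative lnL below null by ", format(-stat / 2),
      "; check convergence"
    )
  }
  stat <- max(stat, 0)
  p <- if (null_distribution == "chi2") {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  } else {
    if (stat == 0) 1 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(
    null = fit_null$spec$kind, alternative = fit_alt$spec$kind,
    stat = stat, df = df, p_value = p,
    null_distribution = null_distribution
  )
}

#' AIC table with Akaike weights
#'
#' AIC = 2 np - 2 lnL; delta AIC is relative to the best model and Akaike
#' weights are w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2).
#'
#' @param fits A (optionally named) list of `cm_fit` objects.
#' @return A tibble sorted by AIC: `model`, `np`, `lnL`, `AIC`,
#'   `delta_AIC`, `weight`.
#' @export
aic_rank <- function(fits) {
  if (inherits(fits, "cm_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, function(f) f$spec$kind, character(1))
  aic <- unname(vapply(fits, function(f) 2 * f$np - 2 * f$lnL, 1))
  tb <- tibble::tibble(
    model = unname(nm),
    np = unname(vapply(fits, function(f) f$np, 1)),
    lnL = unname(vapply(fits, function(f) f$lnL, 1)),
    AIC = aic
  )
  tb <- dplyr::arrange(tb, .data$AIC)
  tb$delta_AIC <- tb$AIC - tb$AIC[1]
  tb$weight <- akaike_weights(tb$delta_AIC)
  tb
}

#' Akaike weights from delta-AIC values
#'
#' @param delta_aic Numeric vector of AIC differences from the best model.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(delta_aic) {
  w <- exp(-delta_aic / 2)
  w / sum(w)
}

#' Test whether a partition's divergent omega differs from 1
#'
#' Given a fitted clade model with a free divergent-class omega for the
#' named partition, refits with that omega constrained to 1 and returns
#' the 1-df likelihood ratio test (the test of positive selection versus
#' relaxed constraint in that partition).
#'
#' @param fit_alt A `cm_fit` of a CmC/CmD-type model (fitted with data
#'   stored, as [fit_model()] does).
#' @param partition Partition index or label whose divergent omega is
#'   tested.
#' @param value The constraint value (default 1).
#' @param n_restarts Restarts for the constrained refit.
#' @param seed Optional seed.
#' @return A list with `lrt` (tibble row as from
#'   [likelihood_ratio_test()]) and `fit_null` (the constrained fit).
#' @export
clade_omega_test <- function(fit_alt, partition, value = 1,
                             n_restarts = 2, seed = NULL) {
  spec <- fit_alt$spec
  p <- if (is.character(partition) && !is.null(fit_alt$partition)) {
    resolve_partition(fit_alt$partition, partition)
  } else {
    as.integer(partition)
  }
  divergent_class <- spec$n_classes
  spec0 <- constrain_omega(spec, divergent_class, p, value)
  fit0 <- fit_model(
    spec0, fit_alt$tree, fit_alt$data,
    partition = fit_alt$partition, freqs = fit_alt$freqs,
    n_restarts = n_restarts, seed = seed, init = fit_alt$params
  )
  list(
    lrt = likelihood_ratio_test(fit0, fit_alt),
    fit_null = fit0
  )
}

#' Posterior site-class membership (empirical Bayes)
#'
#' Plug-in (naive empirical Bayes) posterior probability that each codon
#' site belongs to each site class, computed at the maximum-likelihood
#' estimates: PP(k | site) proportional to p_k L(site | class k). Sites
#' whose posterior for the model's divergent class exceeds `threshold`
#' are flagged.
#'
#' @param fit A `cm_fit` of a mixture model (>= 2 classes).
#' @param data Alignment; defaults to the one stored in the fit.
#' @param threshold Flagging threshold on the divergent-class posterior
#'   (default 0.75).
#' @return A tibble with one row per alignment site: `site` (1-based codon
#'   position), `pp_class1` ... columns, `pp_divergent`, `divergent_flag`.
#' @export
site_posteriors <- function(fit, data = fit$data, threshold = 0.75) {
  spec <- fit$spec
  if (spec$n_classes < 2) {
    stop("site posteriors require a mixture model (>= 2 site classes)")
  }
  engine <- likelihood_engine(fit$tree, fit$partition, data)
  pp <- fit$params
  cl <- class_pattern_loglik(
    spec, engine, if (identical(spec$kappa, "free")) pp$kappa else spec$kappa,
    pp$omega, pp$props, pp$branch_lengths, fit$freqs
  )
  lw <- sweep(cl$loglik, 2, log(cl$proportions), "+")
  m <- apply(lw, 1, max)
  post <- exp(lw - m)
  post <- post / rowSums(post)
  post_sites <- post[engine$pat$site_of, , drop = FALSE]
  out <- tibble::as_tibble(post_sites, .name_repair = ~ paste0(
    "pp_class", seq_len(ncol(post_sites))
  ))
  out <- dplyr::bind_cols(tibble::tibble(site = seq_len(nrow(post_sites))), out)
  out$pp_divergent <- post_sites[, spec$n_classes]
  out$divergent_flag <- out$pp_divergent > threshold
  out
}

#' Per-branch dN and dS from an M0 fit
#'
#' Decomposes each branch's length (expected substitutions per codon) into
#' synonymous and nonsynonymous distances. The fitted rate matrix's mean
#' rate is split into synonymous and nonsynonymous shares by summing
#' pi_i q_ij over the corresponding single-step codon pairs; the numbers
#' of synonymous and nonsynonymous sites are the shares of mutational
#' opportunity under the same kappa and frequencies with omega = 1. Then
#' dS = t x (synonymous rate share) / (synonymous site proportion), and
#' dN analogously, so that dN/dS equals the fitted omega on every branch.
#' Used as the paper-style saturation check that per-branch dS stays well
#' below 1.
#'
#' @param fit_m0 A `cm_fit` with a single site class (M0).
#' @return A tibble with one row per edge: `edge`, `parent`, `child`,
#'   `label` (tip name for terminal branches), `t`, `dN`, `dS`.
#' @export
branch_dn_ds <- function(fit_m0) {
  spec <- fit_m0$spec
  if (spec$n_classes != 1 || spec$kind != "M0") {
    stop("branch dN/dS decomposition is defined for M0 fits")
  }
  omega <- fit_m0$omega[1, 1]
  kappa <- fit_m0$kappa
  freqs <- fit_m0$freqs
  shares <- rate_shares(kappa, omega, freqs)
  sites <- rate_shares(kappa, 1, freqs) # mutational opportunity, omega = 1
  prop_s <- sites$syn / (sites$syn + sites$nonsyn)
  prop_n <- 1 - prop_s
  t <- fit_m0$branch_lengths
  dS <- t * shares$syn / (shares$syn + shares$nonsyn) / prop_s
  dN <- t * shares$nonsyn / (shares$syn + shares$nonsyn) / prop_n
  tree <- fit_m0$tree
  child <- tree$edge[, 2]
  tibble::tibble(
    edge = seq_along(t),
    parent = tree$edge[, 1],
    child = child,
    label = ifelse(child <= ape::Ntip(tree), tree$tip.label[child], NA),
    t = t, dN = dN, dS = dS
  )
}

# synonymous / nonsynonymous components of the mean substitution rate
rate_shares <- function(kappa, omega, freqs) {
  gc <- genetic_code()
  q <- codon_rate_matrix(kappa, omega, freqs)
  pi <- as.numeric(freqs)
  flow <- pi * unclass(q) # pi_i q_ij
  pc <- gc$pair_class
  list(
    syn = sum(flow[pc == 2L | pc == 3L]),
    nonsyn = sum(flow[pc == 4L | pc == 5L])
  )
}
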