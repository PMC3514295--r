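#' Tidy a codon-model fit
#'
#' One row per estimated (or fixed) quantity, broom-style: omegas by class
#' and partition, class proportions, kappa.
#'
#' @param x A `cm_fit`.
#' @param branch_lengths Include per-edge branch lengths as rows.
#' @param ... Unused.
#' @return A tibble with columns `term`, `class`, `partition`, `estimate`,
#'   `fixed`.
#' @export
tidy.cm_fit <- function(x, branch_lengths = FALSE, ...) {
  om <- x$spec$omega
  rows <- tibble::tibble(
    term = paste0("omega[", om$class, ",", om$partition, "]"),
    class = om$class, partition = om$partition,
    estimate = x$omega[cbind(om$class, om$partition)],
    fixed = om$type == "fixed"
  )
  props <- tibble::tibble(
    term = paste0("p[", seq_along(x$proportions), "]"),
    class = seq_along(x$proportions), partition = NA_integer_,
    estimate = x$proportions,
    fixed = x$spec$prop_model == "none"
  )
  kappa <- tibble::tibble(
    term = "kappa", class = NA_integer_, partition = NA_integer_,
    estimate = x$kappa, fixed = !identical(x$spec$kappa, "free")
  )
  out <- dplyr::bind_rows(rows, props, kappa)
  if (branch_lengths) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("t[", seq_along(x$branch_lengths), "]"),
      class = NA_integer_, partition = NA_integer_,
      estimate = x$branch_lengths, fixed = FALSE
    ))
  }
  out
}

#' Glance at a codon-model fit
#'
#' @param x A `cm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `lnL`, `np`, `AIC`, `kappa`,
#'   `tree_length`, `converged`, `n_restarts`, `restart_spread`.
#' @export
glance.cm_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$kind,
    lnL = x$lnL,
    np = x$np,
    AIC = 2 * x$np - 2 * x$lnL,
    kappa = x$kappa,
    tree_length = sum(x$branch_lengths),
    converged = x$converged,
    n_restarts = x$n_restarts,
    restart_spread = x$restart_spread
  )
}

#' @export
tidy.cm_calibration <- function(x, ...) x$replicates

#' @export
glance.cm_calibration <- function(x, ...) x$summary

#' Generic for broom-style tidying (re-exported locally)
#' @param x Object to tidy.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic for broom-style one-row summaries (re-exported locally)
#' @param x Object to summarize.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
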