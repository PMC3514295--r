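fake_fit <- function(spec, lnL, np, ...) {
  structure(
    list(spec = spec, lnL = lnL, np = np, ...),
    class = "cm_fit"
  )
}

test_that("LRT p-values match the chi-square reference", {
  m1a <- fake_fit(model_spec("M1a", kappa = 2), -1000, 10)
  cmc <- fake_fit(model_spec("CmC", n_partitions = 2, kappa = 2), -1000, 13)
  # stat at the 5% critical value of chi2_1 (via a 1-df pair)
  m2a <- fake_fit(model_spec("M2a_rel", kappa = 2), -1000 - 3.8415 / 2, 12)
  lrt <- likelihood_ratio_test(m2a, cmc)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p_value, 0.05, tolerance = 1e-4 / 0.05)
  # the clade test statistic printed alongside a constrained lnL of
  # -3777.2771 against -3773.9931 gives 2dlnL = 6.568, p = 0.0104
  con <- fake_fit(model_spec("M2a_rel", kappa = 2), -3777.2771, 12)
  alt <- fake_fit(
    model_spec("CmC", n_partitions = 2, kappa = 2),
    -3777.2771 + 6.568 / 2, 13
  )
  expect_equal(likelihood_ratio_test(con, alt)$p_value, 0.0104,
    tolerance = 1e-4 / 0.0104
  )
  # 3-df case
  lrt3 <- likelihood_ratio_test(m1a, cmc)
  expect_equal(lrt3$df, 3)
  expect_equal(
    lrt3$p_value,
    pchisq(2 * (m1a$lnL - cmc$lnL) * -1, 3, lower.tail = FALSE)
  )
})

test_that("zero statistics and the boundary mixture null behave", {
  null <- fake_fit(model_spec("M1a", kappa = 2), -500, 10)
  alt <- fake_fit(model_spec("M2a_rel", kappa = 2), -500, 12)
  expect_equal(likelihood_ratio_test(null, alt)$p_value, 1)
  expect_equal(likelihood_ratio_test(null, alt, "mix50")$p_value, 1)
  alt2 <- fake_fit(model_spec("M2a_rel", kappa = 2), -498, 12)
  chi2 <- likelihood_ratio_test(null, alt2)
  mix <- likelihood_ratio_test(null, alt2, "mix50")
  expect_equal(mix$p_value, 0.5 * pchisq(4, 1, lower.tail = FALSE))
  expect_error(
    likelihood_ratio_test(alt2, null),
    "not nested"
  )
})

test_that("Akaike weights reproduce the worked model-table example", {
  delta <- c(0, 2.19, 3.55, 6.75, 7.39, 19.09, 19.92, 23.97)
  w <- akaike_weights(delta)
  expect_equal(w[1], 0.6394, tolerance = 5e-4 / 0.6394)
  expect_equal(w[2], 0.2143, tolerance = 5e-4 / 0.2143)
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("AIC tables rank models and weight them on the AIC scale", {
  f1 <- fake_fit(model_spec("M0", kappa = 2), -1000, 10)
  f2 <- fake_fit(model_spec("M1a", kappa = 2), -999, 11)
  tb <- aic_rank(list(M0 = f1, M1a = f2))
  expect_equal(tb$delta_AIC[1], 0)
  expect_equal(tb$AIC, 2 * tb$np - 2 * tb$lnL)
  expect_equal(sum(tb$weight), 1, tolerance = 1e-12)
  expect_equal(aic_rank(list(only = f1))$weight, 1)
  tb_tied <- aic_rank(list(a = f1, b = f1))
  expect_equal(tb_tied$weight, c(0.5, 0.5))
})

test_that("branch dN/dS decomposition honours the fitted omega", {
  tr <- quartet_tree()
  freqs <- equal_frequencies()
  base_fit <- function(omega, t = 0.1) {
    fake_fit(model_spec("M0", kappa = 2), -1, 1,
      omega = matrix(omega), kappa = 2, freqs = freqs,
      branch_lengths = rep(t, 6), tree = tr
    )
  }
  # omega = 1: dN = dS = t on every branch
  rates1 <- branch_dn_ds(base_fit(1))
  expect_equal(rates1$dN, rates1$dS)
  expect_equal(rates1$dS, rep(0.1, 6))
  # t = 0: no substitutions of either kind
  rates0 <- branch_dn_ds(base_fit(0.1476, t = 0))
  expect_equal(rates0$dN, rep(0, 6))
  expect_equal(rates0$dS, rep(0, 6))
  # dN/dS recovers omega, and dS matches an exhaustive pair-class summation
  omega <- 0.1476
  rates <- branch_dn_ds(base_fit(omega))
  expect_equal(rates$dN / rates$dS, rep(omega, 6), tolerance = 1e-8)
  gc <- genetic_code()
  rate_of <- function(om) {
    tot <- s <- 0
    for (i in 1:61) {
      for (j in 1:61) {
        pc <- gc$pair_class[i, j]
        if (!pc %in% 2:5) next
        r <- (1 / 61) * (1 / 61) *
          unname(c(`2` = 2, `3` = 1, `4` = 2 * om, `5` = om)[as.character(pc)])
        tot <- tot + r
        if (pc <= 3) s <- s + r
      }
    }
    c(total = tot, syn = s)
  }
  at_om <- rate_of(omega)
  at_1 <- rate_of(1)
  expected_ds <- 0.1 * (at_om["syn"] / at_om["total"]) /
    (at_1["syn"] / at_1["total"])
  expect_equal(rates$dS[1], unname(expected_ds), tolerance = 1e-10)
  # only defined for M0
  expect_error(
    branch_dn_ds(fake_fit(model_spec("M1a", kappa = 2), -1, 2)),
    "M0"
  )
})

test_that("site posteriors are plug-in empirical Bayes probabilities", {
  tr <- quartet_tree()
  aln <- random_alignment(4, 12, seed = 10)
  # two classes with identical omegas: class likelihoods are equal, so the
  # posterior must equal the fitted proportions at every site
  spec <- model_spec("M3", K = 2, kappa = 2)
  fit <- fake_fit(
    spec, -1, 3,
    params = list(
      omega = c(w0 = 0.4, w1 = 0.4), props = 0.7,
      branch_lengths = tr$edge.length
    ),
    proportions = c(0.7, 0.3), tree = tr, partition = NULL,
    freqs = equal_frequencies(), data = aln
  )
  pp <- site_posteriors(fit)
  expect_equal(pp$pp_class1, rep(0.7, 12), tolerance = 1e-9)
  expect_equal(pp$pp_class1 + pp$pp_class2, rep(1, 12))
  # threshold 1 flags nothing
  expect_false(any(site_posteriors(fit, threshold = 1)$divergent_flag))
  expect_error(
    site_posteriors(fake_fit(model_spec("M0", kappa = 2), -1, 1)),
    "mixture"
  )
})
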