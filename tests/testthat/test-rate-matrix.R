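test_that("rate matrix entries follow the GY94 parameterization", {
  q <- codon_rate_matrix(2, 0.5)
  expect_equal(q["TTT", "TTC"], 2 / 61) # synonymous transition
  expect_equal(q["TTT", "GAA"], 0) # multi-step
  expect_equal(q["CCT", "CCA"], 1 / 61) # Pro-Pro, synonymous transversion
  expect_equal(q["TTT", "GTT"], 0.5 / 61) # Phe-Val, nonsyn transversion
  expect_equal(q["TTT", "CTT"], 2 * 0.5 / 61) # Phe-Leu, nonsyn transition
  expect_error(codon_rate_matrix(-1, 0.5), "kappa")
  expect_error(codon_rate_matrix(2, -0.1), "omega")
})

test_that("rows sum to zero and detailed balance holds", {
  pi_uneq <- f3x4_frequencies(c("TTTCCCAAAGGGTTTTTT", "TTACCGATAGGTTTCTTA"))
  for (freqs in list(equal_frequencies(), pi_uneq)) {
    q <- codon_rate_matrix(3.1, 0.27, freqs)
    expect_lt(max(abs(rowSums(q))), 1e-10)
    flow <- as.numeric(freqs) * unclass(q)
    expect_lt(max(abs(flow - t(flow))), 1e-10)
  }
})

test_that("omega = kappa = 1 with equal frequencies equalizes single-step rates", {
  q <- codon_rate_matrix(1, 1)
  gc <- genetic_code()
  single <- gc$pair_class %in% 2:5
  expect_equal(unique(unclass(q)[single]), 1 / 61)
})

test_that("mean rate matches exhaustive summation over single-step pairs", {
  q <- codon_rate_matrix(2, 0.5)
  gc <- genetic_code()
  # independent summation: sum_i pi_i sum_{j != i, single step} rate(i, j)
  expected <- 0
  for (i in 1:61) {
    for (j in 1:61) {
      pc <- gc$pair_class[i, j]
      if (pc %in% 2:5) {
        rate <- c(`2` = 2, `3` = 1, `4` = 2 * 0.5, `5` = 0.5)[as.character(pc)]
        expected <- expected + (1 / 61) * rate * (1 / 61)
      }
    }
  }
  expect_equal(mean_rate(q), unname(expected), tolerance = 1e-12)
})

test_that("class-matrix scaling yields unit mixture mean rate", {
  q1 <- codon_rate_matrix(2, 0)
  q2 <- codon_rate_matrix(2, 1)
  # single class, single partition: plain normalization
  s1 <- scale_class_matrices(list(list(q2)), 1)
  expect_equal(mean_rate(s1$matrices[[1]][[1]]), 1, tolerance = 1e-12)
  # two classes with identical matrices: same factor as single class
  s2 <- scale_class_matrices(list(list(q2), list(q2)), c(0.5, 0.5))
  expect_equal(s2$scale_factor, s1$scale_factor)
  # half omega = 0, half omega = 1: brute-force mixture mean
  s3 <- scale_class_matrices(list(list(q1), list(q2)), c(0.5, 0.5))
  mixture_rate <- 0.5 * mean_rate(s3$matrices[[1]][[1]]) +
    0.5 * mean_rate(s3$matrices[[2]][[1]])
  expect_equal(mixture_rate, 1, tolerance = 1e-12)
  expect_equal(s3$scale_factor, 0.5 * mean_rate(q1) + 0.5 * mean_rate(q2))
})

test_that("scaling is idempotent and rejects all-zero rates", {
  q <- codon_rate_matrix(2, 0.3)
  s <- scale_class_matrices(list(list(q)), 1)
  s2 <- scale_class_matrices(s$matrices, 1)
  expect_equal(s2$scale_factor, 1, tolerance = 1e-12)
  # omega = 0 still leaves synonymous opportunity, so this scales fine;
  # a literal zero matrix must be rejected
  q0 <- codon_rate_matrix(2, 0)
  q0[] <- 0
  attr(q0, "pi") <- rep(1 / 61, 61)
  expect_error(scale_class_matrices(list(list(q0)), 1), "zero")
})
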