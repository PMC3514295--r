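test_that("free selection-parameter counts match the model ladder", {
  expect_equal(n_free_parameters(model_spec("M1a", kappa = 2)), 2) # p0, w0
  expect_equal(n_free_parameters(model_spec("M0", kappa = 2)), 1)
  expect_equal(n_free_parameters(model_spec("M2a_rel", kappa = 2)), 4)
  # CmC with 2 partitions has exactly 1 more parameter than M2a_rel,
  # and 3 more than M1a (the printed LRT df of the ladder)
  cmc2 <- model_spec("CmC", n_partitions = 2, kappa = 2)
  expect_equal(n_free_parameters(cmc2) - n_free_parameters(model_spec("M2a_rel", kappa = 2)), 1)
  expect_equal(n_free_parameters(cmc2) - n_free_parameters(model_spec("M1a", kappa = 2)), 3)
  # adding a partition to CmC adds exactly 1
  cmc3 <- model_spec("CmC", n_partitions = 3, kappa = 2)
  expect_equal(n_free_parameters(cmc3) - n_free_parameters(cmc2), 1)
  # multi-clade CmC vs M1a: 4 df
  expect_equal(n_free_parameters(cmc3) - n_free_parameters(model_spec("M1a", kappa = 2)), 4)
  # branch-site A: p0, p1, w0, w2; its null drops w2
  bsa <- model_spec("BranchSiteA", n_partitions = 2, kappa = 2)
  expect_equal(n_free_parameters(bsa), 4)
  expect_equal(
    n_free_parameters(model_spec("BranchSiteA_null", n_partitions = 2, kappa = 2)),
    3
  )
  # kappa and branch lengths enter the count
  expect_equal(n_free_parameters(model_spec("M0"), n_branches = 17), 19)
})

test_that("clade kinds demand partitioned trees", {
  expect_error(model_spec("CmC", n_partitions = 1), "partitions")
  expect_error(model_spec("Branch", n_partitions = 1), "partitions")
  expect_s3_class(model_spec("CmD", n_partitions = 2, K = 3), "model_spec")
})

test_that("constraining an omega drops one parameter, once", {
  cmc <- model_spec("CmC", n_partitions = 3)
  con <- constrain_omega(cmc, class = 3, partition = 2, value = 1)
  expect_equal(n_free_parameters(cmc) - n_free_parameters(con), 1)
  expect_error(constrain_omega(con, class = 3, partition = 2), "already fixed")
  # branch-site A -> its null via omega2 = 1
  bsa <- model_spec("BranchSiteA", n_partitions = 2)
  null <- constrain_omega(bsa, class = 3, partition = 2, value = 1)
  expect_equal(null$kind, "BranchSiteA_null")
  expect_true(is_nested(null, bsa))
})

test_that("branch-site A proportions derive from (p0, p1)", {
  spec <- model_spec("BranchSiteA", n_partitions = 2)
  p <- clademodels:::class_proportions(spec, c(0.6, 0.3))
  p2 <- 1 - 0.6 - 0.3
  expect_equal(p, c(0.6, 0.3, 0.6 * p2 / (1 - p2), 0.3 * p2 / (1 - p2)))
  expect_equal(sum(p), 1)
})

test_that("nesting introspection accepts the ladder's LRT pairs only", {
  k2 <- function(kind, ...) model_spec(kind, ..., kappa = 2)
  expect_true(is_nested(k2("M1a"), k2("CmC", n_partitions = 2)))
  expect_true(is_nested(k2("M2a_rel"), k2("CmC", n_partitions = 2)))
  expect_true(is_nested(
    k2("CmC", n_partitions = 2),
    k2("CmC", n_partitions = 3)
  ))
  expect_true(is_nested(k2("M0"), k2("Branch", n_partitions = 2)))
  expect_false(is_nested(k2("CmC", n_partitions = 2), k2("M2a_rel")))
  expect_false(is_nested(
    k2("CmC", n_partitions = 2),
    k2("BranchSiteA", n_partitions = 2)
  ))
})

test_that("partition assignment follows clade definitions", {
  tr <- quartet_tree()
  part <- assign_partitions(tr, list(list(tips = c("A", "B"), name = "fg")))
  expect_equal(sum(as.integer(part) == 2L), 3) # two tips + stem
  expect_equal(n_partitions(part), 2)
  no_stem <- assign_partitions(
    tr, list(list(tips = c("A", "B"), include_stem = FALSE))
  )
  expect_equal(sum(as.integer(no_stem) == 2L), 2)
  expect_error(
    assign_partitions(tr, list(list(tips = c("A", "C")))),
    "monophyletic"
  )
  expect_error(
    assign_partitions(tr, list(
      list(tips = c("A", "B")), list(tips = c("A", "B"))
    )),
    "overlap"
  )
})

test_that("partition schemes merge and move branches coherently", {
  cal <- calibration_tree()
  expect_equal(n_partitions(cal$partition3), 3)
  merged <- merge_partitions(cal$partition3, "dotted", "dashed")
  expect_equal(n_partitions(merged), 2)
  # merging the analysis split recovers the generating partition geometry
  expect_equal(
    as.integer(merged) > 1L,
    as.integer(cal$partition2) > 1L
  )
  moved <- move_branch(cal$partition3, cal$misassign_branch, "dashed")
  expect_equal(sum(as.integer(moved) == 2L), 4)
  # moving a branch already in the target partition changes nothing
  dashed_edge <- which(as.integer(cal$partition3) == 2L)[1]
  expect_equal(
    as.integer(move_branch(cal$partition3, dashed_edge, "dashed")),
    as.integer(cal$partition3)
  )
})
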