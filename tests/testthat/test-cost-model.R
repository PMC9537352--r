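test_that("cost files round-trip with missing-as-NA semantics", {
  p <- write_cost_file(c("feature,cost", "a,2.0", "b,0", "c,1.5"))
  tab <- load_cost_table(p)
  expect_s3_class(tab, "cost_table")
  expect_equal(tab$feature, c("a", "b", "c"))
  expect_equal(tab$cost, c(2, 0, 1.5))

  p2 <- write_cost_file(c("feature,cost", "a,2", "b,", "c,4"))
  tab2 <- load_cost_table(p2)
  expect_true(is.na(tab2$cost[2]))
  expect_false(identical(tab2$cost[2], 0))

  p3 <- write_cost_file(c("feature,cost,group", "a,1,g1", "b,2,g1"))
  pg <- write_cost_file(c("group,cost", "g1,2"))
  tab3 <- load_cost_table(p3, group_cost_path = pg)
  expect_true(has_groups(tab3))
  expect_equal(unname(group_costs(tab3)["g1"]), 2)
})

test_that("malformed cost files are rejected", {
  expect_error(load_cost_table(write_cost_file(
    c("feature,cost", "a,1", "a,2"))), "duplicate")
  expect_error(load_cost_table(write_cost_file(
    c("feature,cost", "a,-1"))), "negative")
  expect_error(load_cost_table(write_cost_file(
    c("feature,cost,group", "a,1,g1", "b,2,"))), "partially")
})

test_that("missing costs are mean-imputed and imputation is idempotent", {
  expect_equal(impute_missing_costs(cost_table(letters[1:3], c(2, NA, 4)))$cost,
               c(2, 3, 4))
  expect_equal(impute_missing_costs(cost_table(letters[1:3], c(5, 5, NA)))$cost,
               c(5, 5, 5))
  expect_equal(impute_missing_costs(cost_table(letters[1:2], c(0, NA)))$cost,
               c(0, 0))
  once <- impute_missing_costs(cost_table(letters[1:4], c(1, NA, 3, NA)))
  expect_identical(impute_missing_costs(once)$cost, once$cost)
  expect_equal(once$cost[c(1, 3)], c(1, 3))  # present costs untouched
  expect_error(impute_missing_costs(cost_table("a", NA_real_)), "all costs")
})

test_that("pseudocosts split the smallest nonzero gap and respect its bound", {
  tab <- apply_pseudocosts(cost_table(letters[1:4], c(0, 0, 1, 3)))
  pc <- attr(tab, "pseudocost")
  expect_equal(pc, c(2 / 6, 2 / 6, 0, 0))
  expect_lt(sum(pc), 2)                      # < min nonzero gap
  expect_equal(tab$cost, c(0, 0, 1, 3))      # originals untouched
  expect_true(attr(tab, "pseudocost_applied"))

  # no zero-cost features: a no-op
  expect_identical(apply_pseudocosts(cost_table(letters[1:2], c(1, 2)))$cost,
                   c(1, 2))
  expect_false(attr(apply_pseudocosts(cost_table(letters[1:2], c(1, 2))),
                    "pseudocost_applied"))

  # fewer than two distinct nonzero costs: gap falls back to min nonzero
  tab2 <- apply_pseudocosts(cost_table(letters[1:2], c(0, 5)))
  expect_equal(attr(tab2, "pseudocost"), c(5 / 4, 0))
  expect_lt(sum(attr(tab2, "pseudocost")), 5)
})

test_that("pseudocosts preserve nonzero cost order and rank zero costs", {
  set.seed(3)
  for (i in 1:20) {
    costs <- c(rep(0, sample(1:3, 1)), round(runif(5, 0.5, 4), 2))
    tab <- apply_pseudocosts(cost_table(paste0("f", seq_along(costs)), costs))
    eff <- unname(effective_costs(tab))
    nz <- costs > 0
    expect_identical(order(eff[nz]), order(costs[nz]))
    expect_true(all(eff > 0))
  }
})

test_that("uniform costs make budgets count features", {
  expect_equal(uniform_costs(c("a", "b", "c"))$cost, c(1, 1, 1))
  expect_equal(uniform_costs("solo")$cost, 1)
  expect_error(uniform_costs(character(0)), "nonempty")
  sol <- knapsack_select(c(5, 4, 3, 2), uniform_costs(letters[1:4]), 3)
  expect_length(sol$selected, 3)
})

test_that("total cost sums members, charges groups once, and is monotone", {
  tab <- cost_table(c("a", "b", "c"), c(2, 1, 1))
  expect_equal(total_cost(tab, c("b", "c")), 2)
  expect_equal(total_cost(tab, character(0)), 0)
  expect_error(total_cost(tab, "zz"), "unknown")

  g <- cost_table(c("a", "b", "c"), c(2, 2, 3),
                  groups = c("g1", "g1", "g2"),
                  group_costs = c(g1 = 2, g2 = 3))
  expect_equal(total_cost(g, c("a", "b")), 2)   # one panel, one charge
  expect_equal(total_cost(g, "a"), total_cost(g, c("a", "b")))
  expect_equal(total_cost(g, c("g1", "g2"), ids_are_groups = TRUE), 5)

  set.seed(11)
  for (i in 1:10) {
    sub <- sample(tab$feature, sample(0:3, 1))
    extra <- unique(c(sub, sample(tab$feature, 1)))
    expect_lte(total_cost(tab, sub), total_cost(tab, extra))
  }
})

test_that("group validation demands complete mappings and costs", {
  expect_error(cost_table(c("a", "b"), c(1, 2), groups = c("g1", NA)),
               "partially")
  expect_error(cost_table(c("a", "b"), c(1, 2), groups = c("g1", "g2"),
                          group_costs = c(g1 = 1)), "g2")
  # derived group costs use the max member cost, never the sum
  tab <- cost_table(c("a", "b"), c(1, 3), groups = c("g1", "g1"),
                    group_cost_from_members = TRUE)
  expect_equal(unname(group_costs(tab)["g1"]), 3)
})
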