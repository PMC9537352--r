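test_that("knapsack finds the enumerated optimum and honours edge budgets", {
  tab <- cost_table(c("f1", "f2", "f3"), c(2, 1, 1))
  sol <- knapsack_select(c(3, 2, 2), tab, 2)
  expect_setequal(sol$selected, c("f2", "f3"))
  expect_equal(sol$total_importance, 4)
  expect_equal(sol$realized_cost, 2)

  expect_length(knapsack_select(c(3, 2, 2), tab, 0)$selected, 0)
  expect_setequal(knapsack_select(c(3, 2, 2), tab, 100)$selected,
                  tab$feature)
  expect_error(knapsack_select(c(1, 1, 1), tab, 2, resolution = 0),
               "positive")
})

test_that("greedy ratio ordering can miss the optimum the knapsack finds", {
  tab <- cost_table(c("f1", "f2", "f3"), c(5, 3, 3))
  g <- greedy_select(c(10, 6, 6), tab, 6)   # all ratios 2; file order -> f1
  expect_identical(g$selected, "f1")
  expect_equal(g$total_importance, 10)
  k <- knapsack_select(c(10, 6, 6), tab, 6)
  expect_setequal(k$selected, c("f2", "f3"))
  expect_equal(k$total_importance, 12)

  solo <- greedy_select(c(1, 5), cost_table(c("a", "b"), c(10, 2)), 3)
  expect_identical(solo$selected, "b")
  expect_error(greedy_select(c(1, 1), cost_table(c("a", "b"), c(0, 1)), 1),
               "pseudocosts")
})

test_that("greedy skip-and-continue differs from stop-at-first-failure", {
  # ratios order a(3), b(2), c(1); b does not fit after a but c does
  tab <- cost_table(c("a", "b", "c"), c(2, 3, 1))
  phi <- c(6, 6, 1)
  skip <- greedy_select(phi, tab, 3)
  expect_setequal(skip$selected, c("a", "c"))
  halt <- greedy_select(phi, tab, 3, stop_at_first_failure = TRUE)
  expect_identical(halt$selected, "a")
})

test_that("knapsack equals the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:100) {
    M <- sample(3:12, 1)
    phi <- round(runif(M, 0, 10), 3)
    cvec <- sample(seq(0.25, 3, by = 0.25), M, replace = TRUE)
    tab <- cost_table(paste0("f", 1:M), cvec)
    k <- round(runif(1, 0, sum(cvec)), 2)
    # all costs are multiples of 0.25, so this resolution scales them exactly
    a <- knapsack_select(phi, tab, k, resolution = 0.25)
    b <- brute_force_select(phi, tab, k)
    expect_equal(a$total_importance, b$total_importance, tolerance = 1e-9)
    expect_lte(a$realized_cost, k + 1e-9)
    expect_lte(b$realized_cost, k + 1e-9)
    expect_lte(greedy_select(phi, tab, k)$total_importance,
               a$total_importance + 1e-9)
  }
})

test_that("total importance is monotone in the budget", {
  set.seed(17)
  phi <- runif(8, 0, 5)
  tab <- cost_table(paste0("f", 1:8), sample(1:6, 8, replace = TRUE))
  vals <- sapply(seq(0, sum(tab$cost), length.out = 15),
                 function(k) knapsack_select(phi, tab, k)$total_importance)
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("deterministic tie-breaking prefers cheaper sets then file order", {
  # equal importance everywhere, unit costs: first m features win
  tab <- uniform_costs(paste0("f", 1:5))
  sol <- knapsack_select(rep(1, 5), tab, 3)
  expect_identical(sol$selected, c("f1", "f2", "f3"))
  bf <- brute_force_select(rep(1, 5), tab, 3)
  expect_identical(bf$selected, c("f1", "f2", "f3"))
  # same value achievable cheaper: cheaper set wins
  tab2 <- cost_table(c("a", "b"), c(2, 1))
  expect_identical(knapsack_select(c(1, 1), tab2, 2)$selected, "b")
  expect_identical(brute_force_select(c(1, 1), tab2, 2)$selected, "b")
  # zero-importance features are never selected
  expect_identical(knapsack_select(c(0, 1), tab2, 3)$selected, "b")
})

test_that("group knapsack selects panels and reduces to features when singleton", {
  g <- cost_table(c("a", "b", "c"), c(2, 2, 2),
                  groups = c("g1", "g1", "g2"),
                  group_costs = c(g1 = 2, g2 = 2))
  sol <- group_knapsack_select(c(1, 2, 2.5), g, 2)
  expect_identical(sol$selected_groups, "g1")   # phi_g1 = 3 > 2.5
  expect_setequal(sol$selected, c("a", "b"))
  expect_equal(sol$realized_cost, 2)
  expect_length(group_knapsack_select(c(1, 2, 2.5), g, 0)$selected, 0)

  set.seed(4)
  phi <- runif(6, 0, 3)
  costs <- sample(1:4, 6, replace = TRUE)
  singleton <- cost_table(paste0("f", 1:6), costs,
                          groups = paste0("s", 1:6),
                          group_costs = setNames(costs, paste0("s", 1:6)))
  plain <- cost_table(paste0("f", 1:6), costs)
  for (k in c(2, 5, 9)) {
    expect_equal(group_knapsack_select(phi, singleton, k)$total_importance,
                 knapsack_select(phi, plain, k)$total_importance)
  }
  expect_error(group_knapsack_select(phi, plain, 3), "no groups")
})
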