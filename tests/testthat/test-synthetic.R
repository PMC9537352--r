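test_that("cohort generation is seed-deterministic and shaped as specified", {
  spec <- recovery_spec(200)
  a <- generate_cohort(spec, seed = 5)
  b <- generate_cohort(spec, seed = 5)
  expect_identical(a$data, b$data)
  c <- generate_cohort(spec, seed = 6)
  expect_false(identical(a$data, c$data))
  expect_equal(dim(a$data), c(200, 9))   # 8 blocks + label
  expect_true(all(a$data$label %in% 0:1))
})

test_that("uninformative features carry no class signal at large n", {
  spec <- synthetic_spec(20000, effects = c(1, 0), costs = c(1, 1),
                         prevalence = 0.3)
  coh <- generate_cohort(spec, seed = 9)
  d <- coh$data
  gap0 <- abs(mean(d$f2[d$label == 1]) - mean(d$f2[d$label == 0]))
  gap1 <- abs(mean(d$f1[d$label == 1]) - mean(d$f1[d$label == 0]))
  expect_lt(gap0, 0.08)
  expect_gt(gap1, 0.9)
})

test_that("closed-form subset AU-ROC matches its analytic values", {
  spec <- synthetic_spec(100, effects = c(1, 1, 0.5), costs = c(1, 1, 1))
  expect_equal(bayes_auroc(spec, character(0)), 0.5)
  expect_equal(bayes_auroc(spec, "f1"), pnorm(1 / sqrt(2)))  # 0.7602
  expect_equal(bayes_auroc(spec, c("f1", "f2")), pnorm(1))   # 0.8413
  expect_error(bayes_auroc(strategy_spec(100), "f1"), "independent")
})

test_that("empirical AU-ROC of the optimal linear score approaches the closed form", {
  spec <- synthetic_spec(100000, effects = c(0.8, 0.5, 0.3),
                         costs = c(1, 1, 1), prevalence = 0.2)
  coh <- generate_cohort(spec, seed = 12)
  X <- as.matrix(coh$data[, c("f1", "f2", "f3")])
  score <- drop(X %*% spec$features$effect)
  expect_equal(auroc(score, coh$data$label),
               bayes_auroc(spec, c("f1", "f2", "f3")),
               tolerance = 0.01)
})

test_that("the budget-optimal subset maximizes the squared effect norm", {
  spec <- synthetic_spec(100, effects = c(2, 1), costs = c(1, 1))
  expect_identical(true_best_subset(spec, 1), "f1")
  expect_setequal(true_best_subset(spec, 2), c("f1", "f2"))
  # squared-norm objective: one strong feature beats two moderate ones
  spec2 <- synthetic_spec(100, effects = c(3, 2, 2), costs = c(2, 1, 1))
  expect_identical(true_best_subset(spec2, 2), "f1")   # 9 > 4 + 4
  expect_setequal(true_best_subset(recovery_spec(100), 6),
                  c("f1", "f2", "f3"))
})

test_that("cohort templates mirror the intended clinical structures", {
  tr <- trauma_like_spec(100)
  expect_equal(nrow(tr$features), 45)
  expect_equal(sum(tr$features$cost == 0), 8)   # free dispatch block
  expect_equal(tr$prevalence, 0.06)

  icu <- icu_like_spec(100)
  expect_equal(nrow(icu$features), 43)
  expect_true(all(icu$features$cost == 1))

  op <- outpatient_like_spec(800)
  expect_equal(nrow(op$features), 35)
  expect_equal(length(unique(op$features$group)), 27)
  coh <- generate_cohort(op, seed = 3)
  d <- preprocess_data(coh$data, "label", seed = 3)
  expect_equal(ncol(d$X), 118)                  # one-hot expansion
  ct <- expand_cost_table(coh$costs, d)
  expect_true(has_groups(ct))
  expect_equal(length(unique(ct$group)), 27)
})

test_that("grouped specs expose group-level optimal subsets", {
  spec <- synthetic_spec(100, effects = c(1, 2, 2.5),
                         costs = c(2, 2, 2),
                         groups = c("g1", "g1", "g2"),
                         group_costs = c(g1 = 2, g2 = 2))
  # ||d_g1||^2 = 5 < 6.25 = ||d_g2||^2 at equal cost
  expect_identical(true_best_subset(spec, 2), "f3")
  expect_setequal(true_best_subset(spec, 4), c("f1", "f2", "f3"))
})
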