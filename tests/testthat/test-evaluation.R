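test_that("auroc matches the pair-counting oracle and handles ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(3, 2, 9), c(0, 0, 1)), 1)
  expect_equal(auroc(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")

  pair_count <- function(s, y) {          # brute-force oracle
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(21)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auroc(s, y), pair_count(s, y))
  }
})

test_that("recall at a precision target scans thresholds correctly", {
  expect_equal(recall_at_precision(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0), 0.2),
               1)                                 # threshold 0.7: prec 2/3
  expect_equal(recall_at_precision(c(9, 8, 1), c(0, 0, 1), 0.9), 0)
  expect_equal(recall_at_precision(c(5, 4, 1, 0), c(1, 1, 0, 0), 1), 1)
  # non-increasing in the target
  set.seed(31)
  s <- runif(60); y <- rbinom(60, 1, 0.3)
  recs <- sapply(seq(0.05, 0.95, by = 0.1),
                 function(p) recall_at_precision(s, y, p))
  expect_true(all(diff(recs) <= 1e-12))
})

test_that("deployment extrapolation reproduces the warned-case arithmetic", {
  expect_equal(deployment_extrapolation(0.5, 120000), 60000)
  expect_equal(warned_difference(81054, 44699), 36355)
  expect_equal(warned_difference(389809, 182653), 207156)
})

test_that("curve alignment uses previous-value interpolation", {
  cv <- data.frame(realized_cost = c(2, 5), auroc = c(0.7, 0.8),
                   replicate = 1)
  al <- align_curves(cv, n_grid = 4)            # grid 2, 3, 4, 5
  expect_equal(al$grid, c(2, 3, 4, 5))
  expect_equal(unname(al$values[1, ]), c(0.7, 0.7, 0.7, 0.8))

  # grid points below a replicate's cheapest model are masked ...
  cv2 <- rbind(cv, data.frame(realized_cost = c(4, 5), auroc = c(0.6, 0.9),
                              replicate = 2))
  al2 <- align_curves(cv2, n_grid = 4)
  expect_true(is.na(al2$values["2", 1]))
  # ... unless asked to carry the cheapest value down
  al3 <- align_curves(cv2, n_grid = 4, carry_cheapest = TRUE)
  expect_equal(unname(al3$values["2", 1]), 0.6)

  # step output never exceeds the replicate's best observed value
  expect_true(all(al2$values <= max(cv2$auroc), na.rm = TRUE))
})

test_that("paired curve comparison matches the closed-form t statistic", {
  A <- matrix(c(0.72, 0.73, 0.74), 3, 5)        # row means 0.72 0.73 0.74
  B <- A - c(0.02, 0.03, 0.04)
  out <- compare_curves(A, B)
  expect_equal(out$t, 0.03 / (0.01 / sqrt(3)), tolerance = 1e-10)  # 5.196
  expect_equal(out$mean_diff, 0.03)

  same <- compare_curves(A, A)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(shifted <- compare_curves(A + 0.05, A), "degenerate")
  expect_identical(shifted$t, Inf)
  expect_error(compare_curves(A[1, , drop = FALSE], B[1, , drop = FALSE]),
               "at least 2")
})

test_that("budget bisection finds a feasible model under monotone tradeoffs", {
  trainer <- function(lambda) list(cost = 100 / max(lambda, 1e-12),
                                   performance = 1 / (1 + lambda))
  out <- budget_binary_search(trainer, k = 10)
  expect_true(out$feasible)
  expect_lte(out$trainings, 128)
  expect_lte(out$best$cost, 10)
  # the best recorded candidate is the best-performing feasible one
  feas <- out$history[out$history$feasible, ]
  expect_equal(out$best$performance, max(feas$performance))

  # everything feasible from the start: one training can suffice
  cheap <- budget_binary_search(function(l) list(cost = 1, performance = 0.9),
                                k = 10, cost_tol = 10)
  expect_equal(cheap$trainings, 1L)

  # nothing feasible: reported as such, with the training count
  out2 <- budget_binary_search(function(l) list(cost = 99, performance = 1),
                               k = 10, max_iter = 16)
  expect_false(out2$feasible)
  expect_equal(out2$trainings, 16L)
})
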