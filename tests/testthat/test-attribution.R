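test_that("masked score interpolates between full input and background mean", {
  fn <- function(X) drop(X %*% c(2, -1)) + 0.5
  bg <- rbind(c(0, 0), c(2, 4))
  x <- c(1, 1)
  expect_equal(masked_score(fn, x, 1:2, bg), unname(fn(rbind(x))))
  expect_equal(masked_score(fn, x, integer(0), bg),
               mean(fn(bg)))                                     # none observed
  # linear analytic form: w_S . x_S + w_Sc . mean_Sc
  m <- colMeans(bg)
  expect_equal(masked_score(fn, x, 1L, bg), 2 * x[1] - 1 * m[2] + 0.5)
  expect_error(masked_score(fn, x, 1:2, rbind(c(1, 2, 3))), "columns")
  expect_error(masked_score(fn, x, 5L, bg), "out of range")
})

test_that("exact Shapley reproduces hand-enumerated attributions", {
  lin <- function(X) X[, 1] + 2 * X[, 2]
  phi <- shapley_exact(lin, c(1, 1), matrix(0, 1, 2))
  expect_equal(as.numeric(phi), c(1, 2))

  prod_fn <- function(X) X[, 1] * X[, 2]
  phi2 <- shapley_exact(prod_fn, c(1, 1), matrix(0, 1, 2))
  expect_equal(as.numeric(phi2), c(0.5, 0.5))   # both orderings of the pair
  expect_equal(attr(phi2, "base_value"), 0)

  # dummy axiom: an ignored coordinate gets zero
  ign <- function(X) X[, 1] + X[, 2]
  phi3 <- shapley_exact(ign, c(1, 2, 9), matrix(0, 2, 3))
  expect_equal(as.numeric(phi3)[3], 0)

  expect_error(shapley_exact(lin, rep(1, 13), matrix(0, 1, 13)), "cap")
})

test_that("exact Shapley satisfies local accuracy and symmetry on random models", {
  for (s in 1:100) {
    m <- sample(2:6, 1)
    mod <- random_small_model(m, seed = s)
    phi <- shapley_exact(mod$fn, mod$x, mod$bg)
    expect_lt(abs(sum(phi) + attr(phi, "base_value") -
                    mod$fn(rbind(mod$x))), 1e-8)
  }
  # symmetric treatment of coordinates 1 and 2 with a symmetric background
  sym <- function(X) X[, 1] + X[, 2] + 3 * X[, 1] * X[, 2]
  phi <- shapley_exact(sym, c(2, 2, 1), matrix(c(0, 0, 5), 1, 3))
  expect_equal(phi[[1]], phi[[2]])
})

test_that("sampled Shapley is seeded, converges, and is exact when exhaustive", {
  prod_fn <- function(X) X[, 1] * X[, 2]
  bg <- matrix(0, 1, 2)
  a <- shapley_sampled(prod_fn, c(1, 1), bg, n_permutations = 50, seed = 7)
  b <- shapley_sampled(prod_fn, c(1, 1), bg, n_permutations = 50, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))

  big <- shapley_sampled(prod_fn, c(1, 1), bg, n_permutations = 10000,
                         seed = 1)
  expect_lt(max(abs(as.numeric(big) - 0.5)), 0.05)

  # seed-averaged estimates agree with the exact value within 3 SE
  mod <- random_small_model(4, seed = 42)
  exact <- as.numeric(shapley_exact(mod$fn, mod$x, mod$bg))
  ests <- sapply(1:50, function(s) {
    as.numeric(shapley_sampled(mod$fn, mod$x, mod$bg,
                               n_permutations = 40, seed = s))
  })
  est_mean <- rowMeans(ests)
  est_se <- apply(ests, 1, sd) / sqrt(ncol(ests))
  expect_true(all(abs(est_mean - exact) <= 3 * pmax(est_se, 1e-12)))
})

test_that("linear attribution matches exact Shapley on linear models", {
  for (s in 1:10) {
    m <- sample(2:6, 1)
    set.seed(s)
    w <- rnorm(m); b <- rnorm(1)
    means <- rnorm(m); x <- rnorm(m)
    fn <- function(X) drop(X %*% w) + b
    la <- linear_attribution(w, b, means, x)
    ex <- shapley_exact(fn, x, matrix(means, 1))
    expect_equal(as.numeric(la), as.numeric(ex), tolerance = 1e-10)
    expect_equal(attr(la, "base_value"), attr(ex, "base_value"),
                 tolerance = 1e-10)
  }
  # baseline input attributes to zero everywhere
  z <- linear_attribution(c(2, -1), 0.3, c(1, 4), c(1, 4))
  expect_equal(as.numeric(z), c(0, 0))
  # matrix form attributes many rows at once
  A <- linear_attribution(c(2, -1), 0, c(0, 0), rbind(c(1, 1), c(0, 2)))
  expect_equal(unname(A), rbind(c(2, -1), c(0, -2)), ignore_attr = TRUE)
})

test_that("global importance reduces by mean or sum of absolutes", {
  A <- rbind(c(1, -2), c(3, 0))
  expect_equal(unname(global_importance(A, "mean_abs")), c(2, 1))
  expect_equal(unname(global_importance(A, "sum_abs")), c(4, 2))
  expect_equal(unname(global_importance(matrix(0, 3, 2))), c(0, 0))
  expect_error(global_importance(matrix(numeric(0), 0, 2)), "no samples")
  # the two reductions rank (and hence select) identically
  set.seed(5)
  B <- matrix(rnorm(40), 8, 5)
  expect_identical(order(global_importance(B, "mean_abs")),
                   order(global_importance(B, "sum_abs")))
})
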