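# Additive (Shapley) feature attribution for arbitrary scoring functions.
# A "scoring function" is any R function that maps a numeric matrix
# (samples x features) to a numeric vector of risk scores; masking uses
# interventional replacement from a background sample.

eval_scores <- function(fn, X) {
  X <- as.matrix(X)
  out <- tryCatch(fn(X), error = function(e) NULL)
  if (is.numeric(out) && length(out) == nrow(X)) return(as.numeric(out))
  # fall back to row-wise application for functions written for one vector
  apply(X, 1L, function(r) as.numeric(fn(r)))
}

check_bg <- function(bg, m) {
  bg <- as.matrix(bg)
  if (nrow(bg) == 0L) stop("background set must be nonempty")
  if (ncol(bg) != m) stop("background has ", ncol(bg),
                          " columns but the input has ", m)
  bg
}

#' Masked model score under interventional feature removal
#'
#' Estimates the expected model output when only the features in `S` are
#' observed: every background sample has its coordinates in `S` overwritten
#' by the corresponding values of `x`, the scoring function is evaluated on
#' the modified background, and the scores are averaged. With `S` equal to
#' all features this returns `fn(x)` exactly; with `S` empty it returns the
#' mean background score (the base value).
#'
#' @param fn Scoring function: numeric matrix (samples x features) -> numeric
#'   vector (one score per row). Functions written for a single vector are
#'   also accepted.
#' @param x Numeric feature vector.
#' @param S Integer or logical index of observed features (may be empty).
#' @param bg Background matrix (reference samples x features).
#' @return Scalar masked score.
#' @export
masked_score <- function(fn, x, S, bg) {
  x <- as.numeric(x)
  bg <- check_bg(bg, length(x))
  S <- if (is.logical(S)) which(S) else as.integer(S)
  if (length(S) && (min(S) < 1L || max(S) > length(x))) {
    stop("subset index out of range")
  }
  Xm <- bg
  if (length(S)) Xm[, S] <- matrix(x[S], nrow(bg), length(S), byrow = TRUE)
  mean(eval_scores(fn, Xm))
}

# Masked scores for every subset of 1..m, returned as a vector indexed by
# bitmask + 1. One scoring-function call per subset, each over the background.
all_subset_values <- function(fn, x, bg) {
  m <- length(x)
  n_sub <- bitwShiftL(1L, m)
  vals <- numeric(n_sub)
  for (mask in 0:(n_sub - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    vals[mask + 1L] <- masked_score(fn, x, S, bg)
  }
  vals
}

#' Exact Shapley attribution of one prediction
#'
#' Computes, for each feature, its permutation-averaged marginal contribution
#' to the model output: the average over all feature orderings of the change
#' in masked score when the feature is revealed after those before it. The
#' equivalent subset-weighted sum over all \eqn{2^M} subsets is used, so the
#' method is limited to small feature counts (default cap 12); use
#' [shapley_sampled()] beyond that. The result satisfies local accuracy
#' (attributions + base value = `fn(x)`), symmetry and the dummy axiom.
#'
#' @inheritParams masked_score
#' @param max_features Refuse inputs wider than this (exact mode is
#'   exponential in the feature count).
#' @return Numeric attribution vector with attribute `base_value` (the mean
#'   background score).
#' @export
shapley_exact <- function(fn, x, bg, max_features = 12L) {
  x <- as.numeric(x)
  m <- length(x)
  if (m > max_features) {
    stop("exact Shapley is exponential in features; ", m, " > cap of ",
         max_features, ". Use shapley_sampled().")
  }
  bg <- check_bg(bg, m)
  vals <- all_subset_values(fn, x, bg)
  # weight for a subset S not containing i: |S|! (M-|S|-1)! / M!
  wts <- exp(lfactorial(0:(m - 1L)) + lfactorial(m - 1L - (0:(m - 1L))) -
               lfactorial(m))
  phi <- numeric(m)
  n_sub <- bitwShiftL(1L, m)
  sizes <- vapply(0:(n_sub - 1L), function(mask) {
    sum(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
  }, integer(1))
  for (i in seq_len(m)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(n_sub - 1L), bit) == 0L) # masks w/o i (1-based)
    s <- sizes[without]
    phi[i] <- sum(wts[s + 1L] * (vals[without + bit] - vals[without]))
  }
  structure(phi, base_value = vals[1L])
}

#' Monte-Carlo Shapley attribution of one prediction
#'
#' Unbiased permutation-sampling estimator of the exact Shapley attribution:
#' feature orderings are drawn uniformly at random and each feature is
#' credited with its marginal change in masked score when revealed in that
#' ordering. Reproducible for a fixed seed; the standard error shrinks as
#' \eqn{1/\sqrt{n}} in the number of permutations.
#'
#' @inheritParams masked_score
#' @param n_permutations Number of sampled feature orderings (default 200).
#' @param seed Integer seed for the permutation draws.
#' @return Numeric attribution vector with attributes `base_value` and `se`
#'   (per-feature Monte-Carlo standard error).
#' @export
shapley_sampled <- function(fn, x, bg, n_permutations = 200L, seed = 1L) {
  x <- as.numeric(x)
  m <- length(x)
  bg <- check_bg(bg, m)
  if (n_permutations < 1L) stop("'n_permutations' must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  contrib <- matrix(0, n_permutations, m)
  base <- mean(eval_scores(fn, bg))
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(m)
    prev <- base
    Xm <- bg
    for (j in seq_len(m)) {
      i <- ord[j]
      Xm[, i] <- x[i]
      cur <- mean(eval_scores(fn, Xm))
      contrib[p, i] <- cur - prev
      prev <- cur
    }
  }
  phi <- colMeans(contrib)
  se <- apply(contrib, 2L, stats::sd) / sqrt(n_permutations)
  structure(phi, base_value = base, se = se)
}

# save/restore the global RNG state so seeded helpers don't disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Closed-form attribution for linear scoring functions
#'
#' For a linear model \eqn{f(x) = b + w \cdot x} with an independent-feature
#' background summarized by its means, the Shapley attribution of feature `i`
#' is exactly \eqn{w_i (x_i - \bar{x}_i)} with base value
#' \eqn{b + w\cdot\bar{x}}.
#'
#' @param weights Numeric coefficient vector.
#' @param intercept Scalar intercept.
#' @param bg_means Background feature means.
#' @param x Feature vector, or a matrix of rows to attribute at once.
#' @return For a vector `x`, an attribution vector with attribute
#'   `base_value`; for a matrix, an attribution matrix (rows aligned with
#'   `x`) with the same attribute.
#' @export
linear_attribution <- function(weights, intercept, bg_means, x) {
  weights <- as.numeric(weights)
  bg_means <- as.numeric(bg_means)
  base <- intercept + sum(weights * bg_means)
  if (is.matrix(x)) {
    A <- sweep(x, 2L, bg_means) %*% diag(weights, length(weights))
    dimnames(A) <- dimnames(x)
    return(structure(A, base_value = base))
  }
  structure(weights * (as.numeric(x) - bg_means), base_value = base)
}

#' Reduce an attribution matrix to global feature importance
#'
#' The global importance of a feature is the mean (default) or sum of the
#' absolute per-sample attributions. The two reductions differ only by the
#' constant factor `n`, so any budget selection based on them is identical.
#'
#' @param A Attribution matrix (samples x features).
#' @param reduction `"mean_abs"` or `"sum_abs"`.
#' @return Nonnegative named numeric vector, one entry per feature.
#' @export
global_importance <- function(A, reduction = c("mean_abs", "sum_abs")) {
  reduction <- match.arg(reduction)
  A <- as.matrix(A)
  if (nrow(A) == 0L) stop("attribution matrix has no samples")
  out <- switch(reduction,
                mean_abs = colMeans(abs(A)),
                sum_abs = colSums(abs(A)))
  if (!is.null(colnames(A))) names(out) <- colnames(A)
  out
}

#' Write an attribution matrix to a delimited file
#'
#' Exports samples x features attributions plus a `base_value` column.
#'
#' @param A Attribution matrix with a `base_value` attribute.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_attributions <- function(A, path, sep = ",") {
  df <- as.data.frame(as.matrix(A))
  df$base_value <- rep(attr(A, "base_value") %||% NA_real_, nrow(df))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
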