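# Discrimination metrics, cost-performance curve alignment/comparison,
# deployment extrapolation, and the budget-targeted bisection harness for
# learners tuned through a unitless cost-performance tradeoff parameter.

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive sample is scored above a
#' randomly chosen negative one, with ties counted one half (rank / Wilcoxon
#' formulation).
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (0/1 or logical).
#' @return Scalar in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Maximum recall at a precision target
#'
#' Scans all score thresholds (predict positive when score >= threshold) and
#' returns the largest recall among thresholds whose precision meets the
#' target; 0 if no threshold attains it. Fixing precision caps the
#' false-to-true positive ratio (a precision of 0.2 tolerates four false
#' alerts per true one), which is how alert fatigue is controlled when
#' comparing deployed risk scores.
#'
#' @inheritParams auroc
#' @param precision_target Required precision (positive predictive value),
#'   in (0, 1\].
#' @return Recall (sensitivity) in \[0, 1\].
#' @export
recall_at_precision <- function(scores, labels, precision_target = 0.2) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (precision_target <= 0 || precision_target > 1) {
    stop("'precision_target' must be in (0, 1]")
  }
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  n_pred <- seq_along(ord)
  # threshold boundaries fall after the last of each tied-score block
  keep <- c(diff(scores[ord]) != 0, TRUE)
  prec <- tp[keep] / n_pred[keep]
  rec <- tp[keep] / npos
  ok <- prec >= precision_target
  if (!any(ok)) return(0)
  max(rec[ok])
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Extrapolate recall to a deployed case count
#'
#' Multiplying a model's recall at the chosen operating point by the number
#' of positive cases in the deployment population gives the number of cases
#' the deployed model would flag in advance.
#'
#' @param recall Recall in \[0, 1\].
#' @param national_positives Number of positive cases in the target
#'   population (per year, say).
#' @return Integer count of warned cases (rounded half away from zero).
#' @export
deployment_extrapolation <- function(recall, national_positives) {
  stopifnot(recall >= 0, recall <= 1, national_positives >= 0)
  round_half_away(recall * national_positives)
}

#' Difference in warned cases between two deployments
#'
#' @param warned_a,warned_b Warned-case counts (see
#'   [deployment_extrapolation()]).
#' @return `warned_a - warned_b`.
#' @export
warned_difference <- function(warned_a, warned_b) warned_a - warned_b

#' Align cost-performance curves on a common cost grid
#'
#' Replicated cost-performance curves rarely share cost points, so they are
#' aligned by previous-value (step) interpolation along `n_grid` linearly
#' spaced costs between the cheapest and most expensive model observed
#' across all replicates: each cell takes the performance of the most
#' expensive model with cost at or below the grid point, a conservative
#' estimate. Grid points below a replicate's cheapest model are `NA` by
#' default (`carry_cheapest = TRUE` instead carries the cheapest model's
#' value down).
#'
#' @param curves Data frame with one row per fitted model, containing the
#'   cost column, the value column and a `replicate` column.
#' @param n_grid Number of grid points (default 100).
#' @param cost_col,value_col Column names for cost and performance.
#' @param carry_cheapest Extend each replicate's cheapest value to cheaper
#'   grid points instead of masking them.
#' @return List with `grid` (costs) and `values` (replicates x grid matrix,
#'   rownames = replicate ids).
#' @export
align_curves <- function(curves, n_grid = 100L, cost_col = "realized_cost",
                         value_col = "auroc", carry_cheapest = FALSE) {
  stopifnot(is.data.frame(curves),
            all(c(cost_col, value_col, "replicate") %in% names(curves)))
  if (!nrow(curves)) stop("empty curve table")
  reps <- unique(curves$replicate)
  rng <- range(curves[[cost_col]])
  grid <- if (rng[1] == rng[2]) rep(rng[1], n_grid)
          else seq(rng[1], rng[2], length.out = n_grid)
  vals <- matrix(NA_real_, length(reps), n_grid,
                 dimnames = list(as.character(reps), NULL))
  for (i in seq_along(reps)) {
    sub <- curves[curves$replicate == reps[i], ]
    sub <- sub[order(sub[[cost_col]]), ]
    # previous-value step: value of the most expensive model with cost <= g
    idx <- findInterval(grid + 1e-12, sub[[cost_col]])
    inside <- idx >= 1L
    vals[i, inside] <- sub[[value_col]][idx[inside]]
    if (carry_cheapest && any(!inside)) {
      vals[i, !inside] <- sub[[value_col]][1L]
    }
  }
  list(grid = grid, values = vals)
}

#' Paired comparison of two aligned curve sets
#'
#' Reduces each replicate's aligned curve to its mean performance over the
#' grid (masked cells excluded), then runs a two-sided paired-samples t-test
#' on the per-replicate means, paired by replicate (i.e. by train/test
#' split). When the paired differences have zero variance the t statistic is
#' degenerate: identical curves report t = 0, p = 1; a constant nonzero
#' shift reports a signed infinite t with p = 0 and a warning.
#'
#' @param aligned_a,aligned_b [align_curves()] results (or plain
#'   replicates x grid matrices) with matching replicates.
#' @return List with `t`, `p`, `mean_diff`, and the per-replicate means
#'   `means_a`, `means_b`.
#' @export
compare_curves <- function(aligned_a, aligned_b) {
  ma <- if (is.list(aligned_a)) aligned_a$values else aligned_a
  mb <- if (is.list(aligned_b)) aligned_b$values else aligned_b
  if (nrow(ma) != nrow(mb)) stop("replicate counts differ")
  if (nrow(ma) < 2L) stop("need at least 2 paired replicates")
  means_a <- rowMeans(ma, na.rm = TRUE)
  means_b <- rowMeans(mb, na.rm = TRUE)
  d <- means_a - means_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, mean_diff = 0, means_a = means_a,
                  means_b = means_b))
    }
    warning("paired differences are constant and nonzero; t is degenerate")
    return(list(t = sign(mean(d)) * Inf, p = 0, mean_diff = mean(d),
                means_a = means_a, means_b = means_b))
  }
  tt <- stats::t.test(means_a, means_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
       means_a = means_a, means_b = means_b)
}

#' Budget-targeted bisection over a unitless tradeoff parameter
#'
#' Learners whose cost-performance tradeoff is controlled by a unitless
#' penalty \eqn{\lambda} (model cost and accuracy both decreasing in
#' \eqn{\lambda}) cannot target a cost budget directly: a model must be
#' trained, its cost checked, and \eqn{\lambda} adjusted. This harness
#' performs bisection with explicit bounds: train at \eqn{\lambda_i}; if the
#' model's cost is within budget, record it as a candidate and lower the
#' upper bound, otherwise raise the lower bound; continue at the midpoint,
#' for at most `max_iter` trainings or until a candidate's cost is within
#' `cost_tol` of the budget. Every iteration is one model training — the
#' quantity this harness exists to count.
#'
#' @param trainer `function(lambda)` returning `list(cost = , performance = )`
#'   (deterministic per lambda).
#' @param k Target cost budget.
#' @param lambda_min,lambda_max Search bounds (defaults 0 and 1e6).
#' @param lambda0 First \eqn{\lambda} evaluated (default 1).
#' @param max_iter Maximum trainings `T` (default 128).
#' @param cost_tol Early stop when a feasible candidate's cost is within
#'   this of `k` (default 0: run all iterations).
#' @return List with `best` (the best-performing feasible model's
#'   `lambda`, `cost`, `performance`, or `NULL`), `feasible`, `trainings`,
#'   and the full `history` data frame.
#' @export
budget_binary_search <- function(trainer, k, lambda_min = 0,
                                 lambda_max = 1e6, lambda0 = 1,
                                 max_iter = 128L, cost_tol = 0) {
  stopifnot(lambda_min <= lambda0, lambda0 <= lambda_max, max_iter >= 1L)
  lo <- lambda_min; hi <- lambda_max
  lambda <- lambda0
  hist <- vector("list", max_iter)
  best <- NULL
  n_train <- 0L
  for (i in seq_len(max_iter)) {
    res <- trainer(lambda)
    n_train <- i
    feasible <- res$cost <= k
    hist[[i]] <- data.frame(iter = i, lambda = lambda, cost = res$cost,
                            performance = res$performance,
                            feasible = feasible)
    if (feasible) {
      if (is.null(best) || res$performance > best$performance) {
        best <- list(lambda = lambda, cost = res$cost,
                     performance = res$performance)
      }
      hi <- lambda
      if (k - res$cost <= cost_tol) break
    } else {
      lo <- lambda
    }
    lambda <- (lo + hi) / 2
  }
  list(best = best, feasible = !is.null(best), trainings = n_train,
       history = do.call(rbind, hist[seq_len(n_train)]))
}
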