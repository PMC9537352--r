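# Synthetic clinical-style tabular cohorts with known ground truth.
#
# Features are class-conditional Gaussians: block j is d_j * y + noise with
# unit-variance noise, so the Bayes-optimal score on any subset S of
# independent continuous blocks is the linear score d_S . x_S and its AU-ROC
# has the closed form pnorm(||d_S|| / sqrt(2)). That closed form, together
# with brute-force enumeration of subsets under the cost budget, gives every
# pipeline stage an exact ground-truth target without any real data.

#' Specify a synthetic cohort
#'
#' @param n_samples Number of samples to draw.
#' @param effects Per-feature-block effect sizes `d` (class-mean shift in
#'   noise SDs). At least one must be nonzero.
#' @param costs Per-block acquisition costs (nonnegative).
#' @param groups Optional per-block group ids (all or none).
#' @param group_costs Named per-group costs (required with `groups`).
#' @param levels Per-block level counts: 1 (or `NA`) for a continuous block,
#'   >= 2 for a categorical block obtained by quantile-binning the latent
#'   Gaussian. Categorical indicator columns share the block's group and
#'   cost downstream.
#' @param prevalence Outcome prevalence, strictly inside (0, 1).
#' @param correlation Optional blocks x blocks noise correlation matrix
#'   (identity = the independent design with closed-form oracles).
#' @param names Feature-block names (default `f1`, `f2`, ...).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, effects, costs, groups = NULL,
                           group_costs = NULL, levels = NULL,
                           prevalence = 0.1, correlation = NULL,
                           names = NULL) {
  m <- length(effects)
  stopifnot(m >= 1L, length(costs) == m, all(is.finite(effects)),
            all(costs >= 0), n_samples >= 2L)
  if (!any(effects != 0)) stop("at least one informative block is required")
  if (prevalence <= 0 || prevalence >= 1) {
    stop("'prevalence' must be strictly inside (0, 1)")
  }
  if (is.null(names)) names <- paste0("f", seq_len(m))
  if (is.null(levels)) levels <- rep(1L, m)
  levels[is.na(levels)] <- 1L
  stopifnot(length(levels) == m, all(levels >= 1L))
  if (!is.null(groups)) {
    stopifnot(length(groups) == m, !is.null(group_costs),
              all(groups %in% names(group_costs)))
  }
  if (!is.null(correlation)) {
    stopifnot(is.matrix(correlation), nrow(correlation) == m,
              ncol(correlation) == m,
              max(abs(correlation - t(correlation))) < 1e-8)
  }
  structure(list(n_samples = as.integer(n_samples),
                 features = data.frame(name = names,
                                       effect = as.numeric(effects),
                                       cost = as.numeric(costs),
                                       group = if (is.null(groups)) NA_character_
                                               else as.character(groups),
                                       levels = as.integer(levels),
                                       stringsAsFactors = FALSE),
                 group_costs = group_costs,
                 prevalence = prevalence,
                 correlation = correlation),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: n=%d, %d feature blocks (%d categorical), prevalence %.3g\n",
              x$n_samples, nrow(x$features), sum(x$features$levels > 1L),
              x$prevalence))
  invisible(x)
}

is_grouped_spec <- function(spec) !all(is.na(spec$features$group))

spec_cost_table <- function(spec) {
  f <- spec$features
  if (is_grouped_spec(spec)) {
    cost_table(f$name, f$cost, groups = f$group,
               group_costs = spec$group_costs)
  } else {
    cost_table(f$name, f$cost)
  }
}

#' Generate a synthetic cohort
#'
#' Draws labels at the specified prevalence, then each feature block as
#' `effect * y` plus (optionally correlated) unit Gaussian noise.
#' Categorical blocks are quantile-binned into their level count and
#' returned as factors, so downstream one-hot encoding expands them into
#' indicator columns sharing the block's group and cost. Deterministic for a
#' fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List of class `synthetic_cohort`: `data` (raw data frame with a
#'   binary `label` column), `costs` (a [cost_table()] on the raw feature
#'   names) and `truth` (the spec).
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- spec$n_samples
  f <- spec$features
  m <- nrow(f)
  y <- stats::rbinom(n, 1L, spec$prevalence)
  if (length(unique(y)) < 2L) {           # tiny-n guard: force one of each
    y[1:2] <- c(0L, 1L)
  }
  Z <- matrix(stats::rnorm(n * m), n, m)
  if (!is.null(spec$correlation)) Z <- Z %*% chol(spec$correlation)
  lat <- Z + outer(y, f$effect)
  df <- as.data.frame(lat)
  names(df) <- f$name
  for (j in which(f$levels > 1L)) {
    L <- f$levels[j]
    qs <- stats::quantile(lat[, j], probs = seq_len(L - 1L) / L)
    df[[j]] <- factor(paste0("l", findInterval(lat[, j], qs) + 1L),
                      levels = paste0("l", seq_len(L)))
  }
  df$label <- y
  structure(list(data = df, costs = spec_cost_table(spec), truth = spec),
            class = "synthetic_cohort")
}

check_oracle_spec <- function(spec, idx) {
  if (!is.null(spec$correlation)) {
    stop("closed-form oracle requires independent blocks")
  }
  if (any(spec$features$levels[idx] > 1L)) {
    stop("closed-form oracle requires continuous blocks")
  }
}

#' Closed-form AU-ROC of the Bayes-optimal score on a feature subset
#'
#' For independent continuous blocks, the optimal score on subset S is the
#' linear combination `d_S . x_S`; its class-conditional distributions are
#' Gaussian with equal variance, giving AU-ROC
#' \eqn{\Phi(\lVert d_S \rVert_2 / \sqrt{2})}. The empty subset scores 0.5.
#'
#' @param spec A [synthetic_spec()] with independent continuous blocks.
#' @param subset Character vector of block names (or integer indices).
#' @return Scalar AU-ROC.
#' @export
bayes_auroc <- function(spec, subset) {
  stopifnot(inherits(spec, "synthetic_spec"))
  idx <- subset_index(spec, subset)
  if (!length(idx)) return(0.5)
  check_oracle_spec(spec, idx)
  d <- spec$features$effect[idx]
  stats::pnorm(sqrt(sum(d^2)) / sqrt(2))
}

subset_index <- function(spec, subset) {
  if (is.numeric(subset)) return(as.integer(subset))
  idx <- match(as.character(subset), spec$features$name)
  if (anyNA(idx)) stop("unknown feature block(s): ",
                       paste(subset[is.na(idx)], collapse = ", "))
  idx
}

#' Cost-constrained Bayes-optimal feature subset
#'
#' Brute-force enumeration of all block (or group) subsets with total cost
#' within the budget, maximizing the closed-form AU-ROC — equivalently the
#' squared effect norm \eqn{\lVert d_S \rVert_2^2}. Ties broken like
#' [brute_force_select()] (lower cost, then earlier order). This is the
#' parameter-recovery target for the end-to-end pipeline.
#'
#' @inheritParams bayes_auroc
#' @param k Cost budget.
#' @return Character vector of block names (expanded from groups when the
#'   spec is grouped).
#' @export
true_best_subset <- function(spec, k) {
  stopifnot(inherits(spec, "synthetic_spec"))
  f <- spec$features
  check_oracle_spec(spec, seq_len(nrow(f)))
  d2 <- f$effect^2
  if (is_grouped_spec(spec)) {
    gids <- unique(f$group)
    if (length(gids) > 20L) stop("brute force is limited to 20 groups")
    val <- vapply(gids, function(g) sum(d2[f$group == g]), numeric(1))
    gtab <- cost_table(gids, unname(spec$group_costs[gids]))
    sol <- brute_force_select(val, gtab, k)
    return(f$name[f$group %in% sol$selected])
  }
  if (nrow(f) > 20L) stop("brute force is limited to 20 blocks")
  sol <- brute_force_select(d2, cost_table(f$name, f$cost), k)
  sol$selected
}

#' Trauma-like synthetic spec
#'
#' Emulates a prehospital trauma cohort: 45 mixed features where dispatch
#' and procedure information is free (cost 0) and vitals/assessments carry
#' minute-scale time costs, with a rare outcome (prevalence 0.06). Effects
#' taper geometrically so a handful of features carry most of the signal.
#'
#' @param n_samples Cohort size.
#' @return A [synthetic_spec()].
#' @export
trauma_like_spec <- function(n_samples = 5000L) {
  n_free <- 8L; n_timed <- 37L
  effects <- c(round(1.2 * 0.7^(seq_len(n_free) - 1L), 3),
               round(1.0 * 0.85^(seq_len(n_timed) - 1L), 3))
  costs <- c(rep(0, n_free),
             rep(c(0.25, 0.5, 0.75, 1, 1.5, 2), length.out = n_timed))
  synthetic_spec(n_samples, effects, costs, prevalence = 0.06,
                 names = c(paste0("dispatch", seq_len(n_free)),
                           paste0("vital", seq_len(n_timed))))
}

#' ICU-like synthetic spec
#'
#' Emulates an intensive-care mortality cohort where model cost is simply
#' the number of features: 43 unit-cost features, prevalence 0.09.
#'
#' @inheritParams trauma_like_spec
#' @return A [synthetic_spec()].
#' @export
icu_like_spec <- function(n_samples = 5000L) {
  m <- 43L
  effects <- round(1.1 * 0.88^(seq_len(m) - 1L), 3)
  synthetic_spec(n_samples, effects, rep(1, m), prevalence = 0.09,
                 names = paste0("icu", seq_len(m)))
}

#' Outpatient-like synthetic spec with grouped dollar costs
#'
#' Emulates an outpatient survey cohort where features arrive in paid
#' groups (panels): 27 groups give rise to 35 features — 16 continuous
#' features in 8 two-member panels, 5 continuous singletons, and 14
#' categorical singletons (13 with 7 levels, one with 6) that one-hot
#' expand to 118 encoded columns. Physical-exam-style groups are free
#' (cost 0); lab-style groups carry dollar costs.
#'
#' @inheritParams trauma_like_spec
#' @return A [synthetic_spec()].
#' @export
outpatient_like_spec <- function(n_samples = 5000L) {
  m <- 35L
  groups <- c(rep(paste0("panel", 1:8), each = 2L),      # 16 paired features
              paste0("single", 1:19))                    # 19 singletons
  levels <- c(rep(1L, 21L), rep(7L, 13L), 6L)
  effects <- round(1.0 * 0.9^(seq_len(m) - 1L), 3)
  costs <- rep(c(7.2, 11.5, 3.4, 22.8, 0, 5.9, 14.1), length.out = m)
  group_costs <- stats::setNames(numeric(27L), unique(groups))
  for (g in unique(groups)) {
    group_costs[g] <- max(costs[groups == g])
  }
  synthetic_spec(n_samples, effects, costs, groups = groups,
                 group_costs = group_costs, levels = levels,
                 prevalence = 0.12,
                 names = paste0("op", seq_len(m)))
}

#' Recovery benchmark spec
#'
#' Eight independent continuous blocks with strictly decreasing effects and
#' strictly increasing distinct costs, away from selection ties, so the
#' budget-constrained optimal subset is unambiguous and the end-to-end
#' pipeline can be scored on whether it recovers it.
#'
#' @inheritParams trauma_like_spec
#' @return A [synthetic_spec()].
#' @export
recovery_spec <- function(n_samples = 5000L) {
  synthetic_spec(n_samples,
                 effects = c(1.5, 1.2, 0.9, 0.6, 0.3, 0.15, 0.1, 0.05),
                 costs = 1:8, prevalence = 0.25)
}

#' Strategy-comparison spec
#'
#' Five blocks engineered so the selection strategies genuinely part ways:
#' two strong but expensive features, a cheap moderate feature whose noise
#' is correlated (rho = 0.75) with the second strong one — so the
#' full-feature model shares its credit and masking-without-retraining
#' mis-weights it — and two weak fillers. The greedy importance-per-cost
#' ranking commits to the cheap feature early and at mid budgets cannot
#' afford the pair of strong features that the exact knapsack takes.
#'
#' @inheritParams trauma_like_spec
#' @return A [synthetic_spec()].
#' @export
strategy_spec <- function(n_samples = 3000L) {
  corr <- diag(5)
  corr[2, 3] <- corr[3, 2] <- 0.75
  synthetic_spec(n_samples,
                 effects = c(0.9, 0.8, 0.35, 0.1, 0.1),
                 costs = c(4, 4, 1, 2, 2),
                 prevalence = 0.25, correlation = corr)
}
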