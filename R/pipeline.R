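# End-to-end cost-aware training: preprocess, fit the full-feature model,
# attribute, select a subset within budget, retrain on the selection.

derive_seeds <- function(seed) {
  seed <- as.integer(seed) %% 1000000L
  list(split = seed * 3L + 1L, model = seed * 3L + 2L,
       attribution = seed * 3L + 3L)
}

#' Preprocess a raw table into a modeling dataset
#'
#' Continuous features are standardized to zero mean and unit variance and
#' missing values mean-imputed, both using *train-split* statistics only, so
#' no information leaks from validation or test rows. Categorical
#' (factor/character) columns are one-hot encoded into one indicator per
#' level (missing values become their own level), and all indicators of one
#' categorical record the originating column so they can share a group and a
#' cost. Samples are split into train/validation/test by a seeded shuffle.
#'
#' @param df Data frame with one row per sample and a binary outcome column.
#' @param label_col Name of the outcome column (values coercible to 0/1).
#' @param fractions Named split fractions, summing to 1.
#' @param seed Integer seed for the shuffle.
#' @param split Optional precomputed factor with levels
#'   train/validation/test, overriding the seeded shuffle.
#' @return An object of class `cw_dataset`: list with the encoded matrix
#'   `X`, labels `y`, `feature_ids`, split factor `split`, `origin` (encoded
#'   column -> raw feature), and the train-split `center`, `scale` and
#'   `train_means` used.
#' @export
preprocess_data <- function(df, label_col = "label",
                            fractions = c(train = 0.64, validation = 0.16,
                                          test = 0.20),
                            seed = 1L, split = NULL) {
  if (!label_col %in% names(df)) stop("no label column '", label_col, "'")
  y <- df[[label_col]]
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  feats <- df[setdiff(names(df), label_col)]
  n <- nrow(df)

  if (is.null(split)) {
    stopifnot(abs(sum(fractions) - 1) < 1e-8,
              all(c("train", "validation", "test") %in% names(fractions)))
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    idx <- sample.int(n)
    n_tr <- floor(fractions[["train"]] * n)
    n_va <- floor(fractions[["validation"]] * n)
    split <- factor(rep("test", n), levels = c("train", "validation", "test"))
    split[idx[seq_len(n_tr)]] <- "train"
    split[idx[n_tr + seq_len(n_va)]] <- "validation"
  } else {
    split <- factor(split, levels = c("train", "validation", "test"))
    stopifnot(length(split) == n, !anyNA(split))
  }
  if (length(unique(y[split == "train"])) < 2L) {
    stop("train split must contain both classes")
  }

  cols <- list(); origin <- character(0)
  for (nm in names(feats)) {
    v <- feats[[nm]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      v <- as.character(v)
      v[is.na(v)] <- "(missing)"
      for (lev in unique(v)) {
        cn <- paste0(nm, "=", lev)
        cols[[cn]] <- as.numeric(v == lev)
        origin[cn] <- nm
      }
    } else {
      if (all(is.na(v))) stop("feature '", nm, "' is entirely missing")
      cols[[nm]] <- as.numeric(v)
      origin[nm] <- nm
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  tr <- split == "train"
  center <- apply(X[tr, , drop = FALSE], 2L, mean, na.rm = TRUE)
  scale_ <- apply(X[tr, , drop = FALSE], 2L, stats::sd, na.rm = TRUE)
  const <- !is.finite(scale_) | scale_ == 0
  if (any(const)) {
    warning("constant feature(s) standardized to zero: ",
            paste(colnames(X)[const], collapse = ", "))
    scale_[const] <- 1
  }
  for (j in seq_len(ncol(X))) {           # train-mean imputation, then z-score
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- center[j]
  }
  X <- sweep(sweep(X, 2L, center), 2L, scale_, `/`)

  structure(list(X = X, y = as.numeric(y), feature_ids = colnames(X),
                 split = split, origin = origin,
                 center = center, scale = scale_,
                 train_means = colMeans(X[tr, , drop = FALSE])),
            class = "cw_dataset")
}

#' @export
print.cw_dataset <- function(x, ...) {
  cat(sprintf("cw_dataset: %d samples x %d encoded features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s=%d", levels(x$split), table(x$split)),
                    collapse = ", ")))
  invisible(x)
}

#' Expand a raw-feature cost table to a dataset's encoded columns
#'
#' One-hot encoding turns one raw feature into several columns that are
#' acquired together; this maps a cost table defined on raw features onto
#' the encoded columns, grouping indicator columns of one categorical (or
#' the members of a raw-feature group) under a single group cost.
#'
#' @param costs A [cost_table()] on raw feature names.
#' @param data A [preprocess_data()] result.
#' @return A [cost_table()] on encoded column names (grouped whenever any
#'   raw feature expanded or the input was grouped).
#' @export
expand_cost_table <- function(costs, data) {
  stopifnot(inherits(costs, "cost_table"), inherits(data, "cw_dataset"))
  orig <- data$origin
  unknown <- setdiff(unique(orig), costs$feature)
  if (length(unknown)) stop("no cost for raw feature(s): ",
                            paste(unknown, collapse = ", "))
  row <- match(orig, costs$feature)
  if (has_groups(costs)) {
    grp <- costs$group[row]
    gc <- group_costs(costs)
  } else if (anyDuplicated(orig)) {
    grp <- unname(orig)
    gc <- stats::setNames(costs$cost, costs$feature)[unique(orig)]
  } else {
    return(cost_table(data$feature_ids, costs$cost[row]))
  }
  cost_table(data$feature_ids, costs$cost[row], groups = grp,
             group_costs = gc)
}

split_matrix <- function(data, which) {
  data$X[data$split == which, , drop = FALSE]
}
split_labels <- function(data, which) data$y[data$split == which]

#' Attribution configuration for the pipeline
#'
#' @param method `"auto"` uses the base model's fast attribution path when it
#'   has one and falls back to permutation sampling; `"sampling"` forces the
#'   Monte-Carlo estimator; `"exact"` forces subset enumeration (small
#'   feature counts only).
#' @param n_permutations Permutations per sample for the sampling estimator.
#' @param max_samples Cap on evaluation samples used to estimate global
#'   importance (seeded subsample beyond it).
#' @param max_background Cap on background rows for masking.
#' @param reduction Passed to [global_importance()].
#' @param eval_split Which split the attributions are computed on.
#' @return A config list for [fit_costaware()].
#' @export
attribution_config <- function(method = c("auto", "sampling", "exact"),
                               n_permutations = 200L, max_samples = 200L,
                               max_background = 100L,
                               reduction = c("mean_abs", "sum_abs"),
                               eval_split = c("validation", "train", "test")) {
  list(method = match.arg(method), n_permutations = n_permutations,
       max_samples = max_samples, max_background = max_background,
       reduction = match.arg(reduction), eval_split = match.arg(eval_split))
}

# Global importance of a fitted model over the configured evaluation split.
compute_importance <- function(base, fitted, data, features, config, seed) {
  Xe <- split_matrix(data, config$eval_split)[, features, drop = FALSE]
  if (nrow(Xe) == 0L) stop("evaluation split '", config$eval_split,
                           "' is empty")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (nrow(Xe) > config$max_samples) {
    Xe <- Xe[sample.int(nrow(Xe), config$max_samples), , drop = FALSE]
  }
  bg_means <- data$train_means[features]
  use_fast <- config$method == "auto" && !is.null(base$attribution_fn)
  if (use_fast) {
    A <- base$attribution_fn(fitted, Xe, bg_means)
  } else if (config$method == "exact") {
    fn <- function(M) base_predict(base, fitted, M)
    bg <- matrix(bg_means, 1L, dimnames = list(NULL, features))
    A <- t(apply(Xe, 1L, function(r) shapley_exact(fn, r, bg)))
  } else {
    fn <- function(M) base_predict(base, fitted, M)
    Xtr <- split_matrix(data, "train")[, features, drop = FALSE]
    if (nrow(Xtr) > config$max_background) {
      Xtr <- Xtr[sample.int(nrow(Xtr), config$max_background), , drop = FALSE]
    }
    A <- t(vapply(seq_len(nrow(Xe)), function(i) {
      as.numeric(shapley_sampled(fn, Xe[i, ], Xtr,
                                 n_permutations = config$n_permutations,
                                 seed = seed + i))
    }, numeric(length(features))))
    colnames(A) <- features
  }
  global_importance(A, reduction = config$reduction)
}

condition_costs <- function(costs) {
  costs <- impute_missing_costs(costs)
  if (any(costs$cost == 0) && !isTRUE(attr(costs, "pseudocost_applied"))) {
    costs <- apply_pseudocosts(costs)
  }
  costs
}

# Selector dispatch; with groups, greedy and knapsack both operate at the
# group level (acquisition is per group) and expand back to features.
select_subset <- function(phi, costs, k, strategy, resolution = NULL) {
  if (has_groups(costs)) {
    if (strategy == "greedy") {
      gids <- unique(costs$group)
      phi_g <- vapply(gids, function(g) sum(phi[costs$group == g]),
                      numeric(1))
      gtab <- cost_table(gids, unname(group_costs(costs)[gids]))
      if (any(gtab$cost == 0)) gtab <- apply_pseudocosts(gtab)
      inner <- greedy_select(phi_g, gtab, k)
      feats <- costs$feature[costs$group %in% inner$selected]
      return(new_budget_solution(feats, inner$realized_cost,
                                 sum(phi[costs$feature %in% feats]), k,
                                 "greedy", selected_groups = inner$selected))
    }
    return(group_knapsack_select(phi, costs, k, resolution = resolution))
  }
  switch(strategy,
         greedy = greedy_select(phi, costs, k),
         knapsack_select(phi, costs, k, resolution = resolution))
}

#' Fit a cost-aware model for one budget
#'
#' The core procedure: (1) fit the base model on all features of the train
#' split; (2) compute global additive feature importance on the evaluation
#' split; (3) select the importance-maximizing feature (or group) subset
#' within the budget by the chosen strategy; (4) retrain the same model
#' class with the same hyperparameters on the selected features. For the
#' knapsack strategy this costs exactly two base-model fits. Passing a
#' `cache` environment reuses the full-feature model and its importances, so
#' each additional budget costs one fit.
#'
#' Strategies: `"knapsack"` (exact selection + retrain), `"greedy"`
#' (importance-per-cost ranking + retrain), `"rfe"` (iterative
#' lowest-ratio elimination with re-attribution, see [fit_costaware_rfe()]),
#' `"knapsack_no_retrain"` (exact selection, unselected features masked to
#' train means at prediction time; see [fit_costaware_no_retrain()]).
#'
#' @param data A [preprocess_data()] dataset.
#' @param costs A [cost_table()] covering all dataset features (missing
#'   costs are mean-imputed; zero costs receive pseudocosts automatically).
#' @param k Nonnegative cost budget.
#' @param base A [new_base_model()] adapter (default logistic regression).
#' @param strategy Selection strategy.
#' @param attribution An [attribution_config()].
#' @param seed Pipeline seed; model and attribution seeds derive from it.
#' @param cache Optional environment for reusing the full fit and
#'   importances across budgets.
#' @param resolution Knapsack cost-scaling resolution (see
#'   [knapsack_select()]).
#' @return An object of class `cw_model`.
#' @export
fit_costaware <- function(data, costs, k, base = base_logistic(),
                          strategy = c("knapsack", "greedy", "rfe",
                                       "knapsack_no_retrain"),
                          attribution = attribution_config(), seed = 1L,
                          cache = NULL, resolution = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(data, "cw_dataset"))
  if (k < 0) stop("budget must be nonnegative")
  if (strategy == "rfe") {
    return(fit_costaware_rfe(data, costs, k, base = base,
                             attribution = attribution, seed = seed))
  }
  if (strategy == "knapsack_no_retrain") {
    return(fit_costaware_no_retrain(data, costs, k, base = base,
                                    attribution = attribution, seed = seed,
                                    cache = cache, resolution = resolution))
  }
  costs <- condition_costs(costs)
  missing_costs <- setdiff(data$feature_ids, costs$feature)
  if (length(missing_costs)) stop("no cost for feature(s): ",
                                  paste(missing_costs, collapse = ", "))
  seeds <- derive_seeds(seed)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$full)) {
    cache$full <- base_fit(base, split_matrix(data, "train"),
                           split_labels(data, "train"), seeds$model)
    cache$phi <- compute_importance(base, cache$full, data,
                                    data$feature_ids, attribution,
                                    seeds$attribution)
  }
  phi <- cache$phi
  sol <- select_subset(phi, costs, k, strategy, resolution = resolution)
  sel <- sol$selected

  affordable <- min(effective_costs(costs)) <= k
  if (!length(sel) && k > 0 && affordable && any(phi > 0)) {
    stop("selection came back empty although affordable features exist")
  }

  if (length(sel)) {
    fitted <- base_fit(base, split_matrix(data, "train")[, sel, drop = FALSE],
                       split_labels(data, "train"), seeds$model)
    phi_restricted <- compute_importance(base, fitted, data, sel,
                                         attribution, seeds$attribution)
  } else {
    fitted <- NULL
    phi_restricted <- stats::setNames(numeric(0), character(0))
  }
  new_cw_model(budget = k, solution = sol, fitted = fitted, base = base,
               strategy = strategy, phi_full = phi,
               phi_restricted = phi_restricted, seed = seed,
               train_base_rate = mean(split_labels(data, "train")),
               train_means = data$train_means,
               attribution = attribution)
}

#' Cost-aware model without retraining
#'
#' Selects the budget subset exactly as the knapsack strategy does but keeps
#' the full-feature model: at prediction time the unselected features are
#' replaced by their train-split means before scoring. One base-model fit in
#' total. Faster to train than the retraining strategy but typically less
#' accurate, because the full model's coefficients/splits were estimated in
#' the presence of the now-masked features.
#'
#' @inheritParams fit_costaware
#' @return A `cw_model` with strategy `"knapsack_no_retrain"`.
#' @export
fit_costaware_no_retrain <- function(data, costs, k, base = base_logistic(),
                                     attribution = attribution_config(),
                                     seed = 1L, cache = NULL,
                                     resolution = NULL) {
  stopifnot(inherits(data, "cw_dataset"))
  if (k < 0) stop("budget must be nonnegative")
  costs <- condition_costs(costs)
  seeds <- derive_seeds(seed)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$full)) {
    cache$full <- base_fit(base, split_matrix(data, "train"),
                           split_labels(data, "train"), seeds$model)
    cache$phi <- compute_importance(base, cache$full, data,
                                    data$feature_ids, attribution,
                                    seeds$attribution)
  }
  sol <- select_subset(cache$phi, costs, k, "knapsack",
                       resolution = resolution)
  sol$selector <- "knapsack_no_retrain"
  new_cw_model(budget = k, solution = sol, fitted = cache$full, base = base,
               strategy = "knapsack_no_retrain", phi_full = cache$phi,
               phi_restricted = cache$phi[sol$selected], seed = seed,
               train_base_rate = mean(split_labels(data, "train")),
               train_means = data$train_means,
               attribution = attribution,
               all_features = data$feature_ids)
}

#' Cost-aware model by recursive feature elimination
#'
#' Iteratively fits the base model on the current feature set, computes
#' attributions, and removes the feature with the lowest importance-per-cost
#' ratio, until the total cost of the surviving features is within the
#' budget; the last within-budget fit is the final model. Because
#' attributions are recomputed on every iteration the procedure can track
#' feature dependence, at the price of one fit per removal (`removals + 1`
#' fits in total). `target_count` switches the stopping rule from cost to a
#' desired number of surviving features.
#'
#' @inheritParams fit_costaware
#' @param target_count Optional: stop when this many features remain instead
#'   of when the cost constraint is met.
#' @return A `cw_model` with strategy `"rfe"`.
#' @export
fit_costaware_rfe <- function(data, costs, k, base = base_logistic(),
                              attribution = attribution_config(), seed = 1L,
                              target_count = NULL) {
  stopifnot(inherits(data, "cw_dataset"))
  if (k < 0) stop("budget must be nonnegative")
  costs <- condition_costs(costs)
  seeds <- derive_seeds(seed)
  ec <- effective_costs(costs)
  current <- data$feature_ids
  fitted <- NULL
  phi_cur <- NULL
  done <- function(feats) {
    if (!is.null(target_count)) length(feats) <= target_count
    else total_cost(costs, feats) <= k
  }
  repeat {
    if (!length(current)) break
    fitted <- base_fit(base, split_matrix(data, "train")[, current,
                                                         drop = FALSE],
                       split_labels(data, "train"), seeds$model)
    phi_cur <- compute_importance(base, fitted, data, current, attribution,
                                  seeds$attribution)
    if (done(current)) break
    omega <- phi_cur / ec[current]
    drop_i <- which.min(omega)           # earliest index wins ties
    current <- current[-drop_i]
    fitted <- NULL
  }
  if (!length(current)) {
    fitted <- NULL
    phi_cur <- stats::setNames(numeric(0), character(0))
  }
  sol <- new_budget_solution(current,
                             realized_cost = total_cost(costs, current),
                             total_importance = sum(phi_cur),
                             budget = k, selector = "rfe")
  new_cw_model(budget = k, solution = sol, fitted = fitted, base = base,
               strategy = "rfe", phi_full = NULL,
               phi_restricted = phi_cur, seed = seed,
               train_base_rate = mean(split_labels(data, "train")),
               train_means = data$train_means,
               attribution = attribution)
}

new_cw_model <- function(budget, solution, fitted, base, strategy, phi_full,
                         phi_restricted, seed, train_base_rate, train_means,
                         attribution, all_features = NULL) {
  structure(list(budget = budget, solution = solution,
                 selected = solution$selected, fitted = fitted,
                 base = base, strategy = strategy, phi_full = phi_full,
                 phi_restricted = phi_restricted, seed = seed,
                 train_base_rate = train_base_rate,
                 train_means = train_means,
                 attribution = attribution,
                 all_features = all_features),
            class = "cw_model")
}

#' @export
print.cw_model <- function(x, ...) {
  cat(sprintf("Cost-aware model [%s/%s]: budget %.4g, %d feature(s), cost %.4g\n",
              x$strategy, x$base$name, x$budget, length(x$selected),
              x$solution$realized_cost))
  invisible(x)
}

#' Score new samples with a cost-aware model
#'
#' For retrained models, scores come from the restricted model applied to
#' the selected columns of `X` (columns outside the selection are ignored).
#' For the no-retrain strategy, unselected columns are replaced by their
#' train means and the full model scores the result. A model whose budget
#' admitted no features scores every sample at the train-split base rate.
#'
#' @param model A `cw_model`.
#' @param X Numeric matrix with named columns covering the model's selected
#'   features (for no-retrain, all original features).
#' @return Numeric risk scores, one per row.
#' @export
predict_risk <- function(model, X) {
  stopifnot(inherits(model, "cw_model"))
  X <- as.matrix(X)
  if (model$strategy == "knapsack_no_retrain") {
    need <- model$all_features
    miss <- setdiff(need, colnames(X))
    if (length(miss)) stop("missing feature column(s): ",
                           paste(miss, collapse = ", "))
    Xm <- X[, need, drop = FALSE]
    masked <- setdiff(need, model$selected)
    if (length(masked)) {
      Xm[, masked] <- matrix(model$train_means[masked], nrow(Xm),
                             length(masked), byrow = TRUE)
    }
    return(base_predict(model$base, model$fitted, Xm))
  }
  if (!length(model$selected)) {
    return(rep(stats::qlogis(model$train_base_rate), nrow(X)))
  }
  miss <- setdiff(model$selected, colnames(X))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(miss, collapse = ", "))
  base_predict(model$base, model$fitted,
               X[, model$selected, drop = FALSE])
}

#' Default budget grid for a cost table
#'
#' Quantiles of random subset costs, plus 0 and the total cost, giving a
#' grid that covers the attainable cost range roughly evenly.
#'
#' @param costs A [cost_table()].
#' @param n Number of budgets.
#' @param seed Seed for the subset sampling.
#' @return Ascending numeric vector of budgets.
#' @export
default_budgets <- function(costs, n = 10L, seed = 1L) {
  stopifnot(inherits(costs, "cost_table"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  base_costs <- if (has_groups(costs)) unname(group_costs(costs)) else costs$cost
  total <- sum(base_costs)
  sums <- replicate(512L, sum(base_costs[stats::runif(length(base_costs)) < 0.5]))
  qs <- unname(stats::quantile(sums, probs = seq(0.05, 0.95,
                                                 length.out = max(1L, n - 2L))))
  sort(unique(c(0, qs, total)))
}

#' Sweep a budget grid into a cost-performance curve
#'
#' Fits one cost-aware model per budget, reusing the cached full-feature
#' model and importances (one fit for the full model plus one per budget for
#' the knapsack strategy), and records each model's realized cost and test
#' AU-ROC.
#'
#' @inheritParams fit_costaware
#' @param budgets Ascending numeric budgets.
#' @param replicate Replicate id recorded in the curve (e.g. a split seed).
#' @return List with `models` (one `cw_model` per budget) and `curve`, a
#'   data frame with columns `budget`, `realized_cost`, `auroc`,
#'   `total_importance`, `n_features`, `replicate`.
#' @export
sweep_budgets <- function(data, costs, budgets, base = base_logistic(),
                          strategy = "knapsack",
                          attribution = attribution_config(), seed = 1L,
                          replicate = 1L, resolution = NULL) {
  if (!length(budgets)) stop("'budgets' must be nonempty")
  budgets <- sort(budgets)
  cache <- new.env(parent = emptyenv())
  Xte <- split_matrix(data, "test")
  yte <- split_labels(data, "test")
  models <- vector("list", length(budgets))
  rows <- vector("list", length(budgets))
  for (i in seq_along(budgets)) {
    m <- fit_costaware(data, costs, budgets[i], base = base,
                       strategy = strategy, attribution = attribution,
                       seed = seed, cache = cache, resolution = resolution)
    scores <- predict_risk(m, Xte)
    a <- if (length(unique(yte)) < 2L || length(unique(scores)) == 1L) 0.5
         else auroc(scores, yte)
    models[[i]] <- m
    rows[[i]] <- data.frame(budget = budgets[i],
                            realized_cost = m$solution$realized_cost,
                            auroc = a,
                            total_importance = m$solution$total_importance,
                            n_features = length(m$selected),
                            replicate = replicate)
  }
  list(models = models, curve = do.call(rbind, rows))
}

#' Feature-importance-by-budget matrix
#'
#' One column per swept budget; entry (i, k) is the global importance of
#' feature i in the *retrained* budget-k model, zero when the feature was
#' not selected. Membership need not be monotone in the budget: a feature
#' can enter at a small budget and be displaced at a larger one. Zero-cost
#' features can be collapsed into a single aggregate row.
#'
#' @param sweep A [sweep_budgets()] result.
#' @param features Row order (default: union of all selected features in
#'   first-selection order).
#' @param costs Optional [cost_table()], required for
#'   `collapse_zero_cost`.
#' @param collapse_zero_cost Aggregate all zero-cost features into one
#'   `"(zero-cost)"` row by summing their importances.
#' @return Numeric matrix features x budgets.
#' @export
importance_by_budget <- function(sweep, features = NULL, costs = NULL,
                                 collapse_zero_cost = FALSE) {
  models <- sweep$models
  if (is.null(features)) {
    features <- unique(unlist(lapply(models, `[[`, "selected")))
  }
  M <- matrix(0, length(features), length(models),
              dimnames = list(features,
                              vapply(models, function(m) format(m$budget),
                                     character(1))))
  for (j in seq_along(models)) {
    phi <- models[[j]]$phi_restricted
    common <- intersect(names(phi), features)
    M[common, j] <- phi[common]
  }
  if (collapse_zero_cost) {
    if (is.null(costs)) stop("'costs' is required to collapse zero-cost rows")
    zc <- intersect(features, costs$feature[costs$cost == 0])
    if (length(zc)) {
      agg <- colSums(M[zc, , drop = FALSE])
      M <- rbind(`(zero-cost)` = agg, M[setdiff(features, zc), , drop = FALSE])
    }
  }
  M
}

#' Write a model card to JSON
#'
#' Records the selected features with their importances and costs, realized
#' cost, budget, strategy and seeds — everything needed to audit what a
#' deployed budgeted model asks for.
#'
#' @param model A `cw_model`.
#' @param costs The [cost_table()] used at fit time.
#' @param path Output JSON path.
#' @export
write_model_card <- function(model, costs, path) {
  sel <- model$selected
  card <- list(
    strategy = model$strategy,
    base_model = model$base$name,
    budget = model$budget,
    realized_cost = model$solution$realized_cost,
    total_importance = model$solution$total_importance,
    seed = model$seed,
    features = data.frame(
      feature = sel,
      importance = as.numeric(model$phi_restricted[sel]),
      cost = costs$cost[match(sel, costs$feature)]),
    groups = model$solution$selected_groups)
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
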