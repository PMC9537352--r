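# Base-model adapters. A base model is an opaque learner the pipeline can
# (re)fit on any feature subset with the *same* hyperparameters as the
# full-feature model; every fit is counted so training-complexity contracts
# can be asserted.

#' Create a base-model adapter
#'
#' @param name Short model-class name.
#' @param fit `function(X, y, seed)` returning an opaque fitted state. `X` is
#'   a numeric matrix restricted to the features in play.
#' @param predict `function(fitted, X)` returning one real risk score per row.
#' @param attribution Optional fast attribution path
#'   `function(fitted, X, bg_means)` returning a samples x features
#'   attribution matrix (used instead of permutation sampling when present).
#' @return An object of class `base_model` carrying a fit counter.
#' @export
new_base_model <- function(name, fit, predict, attribution = NULL) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  structure(list(name = name, fit_fn = fit, predict_fn = predict,
                 attribution_fn = attribution, counter = counter),
            class = "base_model")
}

#' Fit a base model (counted)
#' @param base A [new_base_model()] adapter.
#' @param X Numeric feature matrix.
#' @param y Binary labels.
#' @param seed Integer seed for any stochastic fitting.
#' @return The fitted state.
#' @export
base_fit <- function(base, X, y, seed = 1L) {
  stopifnot(inherits(base, "base_model"))
  base$counter$n <- base$counter$n + 1L
  base$fit_fn(X, y, seed)
}

#' Score new samples with a fitted base model
#' @inheritParams base_fit
#' @param fitted State returned by [base_fit()].
#' @return Numeric risk scores, one per row of `X`.
#' @export
base_predict <- function(base, fitted, X) base$predict_fn(fitted, X)

#' Number of fit invocations performed by an adapter
#' @inheritParams base_fit
#' @return Integer count (monotone over the adapter's lifetime).
#' @export
training_count <- function(base) base$counter$n

#' Reset an adapter's fit counter to zero
#' @inheritParams base_fit
#' @export
reset_training_count <- function(base) {
  base$counter$n <- 0L
  invisible(base)
}

#' Logistic-regression base model
#'
#' Unpenalized logistic regression via iteratively reweighted least squares.
#' Scores are on the linear-predictor (log-odds) scale, which is what the
#' closed-form linear attribution path expects; AU-ROC is invariant to the
#' monotone link. Collinear columns get coefficient zero.
#'
#' @return A `base_model` adapter with a closed-form attribution path.
#' @export
base_logistic <- function() {
  fit <- function(X, y, seed) {
    X <- as.matrix(X)
    if (ncol(X) == 0L) {
      return(list(coef = numeric(0), intercept = stats::qlogis(mean(y)),
                  features = character(0)))
    }
    fm <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                     family = stats::binomial()))
    beta <- fm$coefficients
    beta[is.na(beta)] <- 0
    list(coef = beta[-1L], intercept = beta[[1L]], features = colnames(X))
  }
  predict <- function(fitted, X) {
    X <- as.matrix(X)
    if (length(fitted$coef) == 0L) return(rep(fitted$intercept, nrow(X)))
    drop(X %*% fitted$coef) + fitted$intercept
  }
  attribution <- function(fitted, X, bg_means) {
    linear_attribution(fitted$coef, fitted$intercept, bg_means, as.matrix(X))
  }
  new_base_model("logistic", fit, predict, attribution)
}

#' Gradient-boosted tree base model
#'
#' Gradient boosting via the xgboost package with defaults oriented to
#' clinical tabular risk prediction: learning rate 0.01, up to 1000 trees
#' with early stopping after 100 stagnant rounds on an internal 20%
#' validation split, minimum child weight 10. Scores are on the margin
#' (log-odds) scale. The fast attribution path uses the package's built-in
#' per-prediction tree attribution (`predcontrib`), whose rows sum to the
#' margin output.
#'
#' @param eta Learning rate.
#' @param nrounds Maximum boosting rounds.
#' @param early_stopping_rounds Stop after this many rounds without
#'   validation improvement; `NULL` disables early stopping (all `nrounds`
#'   are used).
#' @param max_depth Maximum tree depth.
#' @param min_child_weight Minimum sum of instance weight in a child.
#' @param subsample Row subsampling rate.
#' @return A `base_model` adapter.
#' @export
base_gbm <- function(eta = 0.01, nrounds = 1000L, early_stopping_rounds = 100L,
                     max_depth = 4L, min_child_weight = 10, subsample = 1.0) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("base_gbm() requires the 'xgboost' package")
  }
  params <- list(objective = "binary:logitraw", eta = eta,
                 max_depth = max_depth, min_child_weight = min_child_weight,
                 subsample = subsample, nthread = 1L)
  fit <- function(X, y, seed) {
    X <- as.matrix(X)
    if (ncol(X) == 0L) {
      return(list(constant = stats::qlogis(mean(y))))
    }
    set.seed(as.integer(seed))
    p <- c(params, list(seed = as.integer(seed)))
    if (!is.null(early_stopping_rounds) && nrow(X) >= 50L) {
      n <- nrow(X)
      hold <- sample.int(n, max(1L, floor(0.2 * n)))
      dtrain <- xgboost::xgb.DMatrix(X[-hold, , drop = FALSE],
                                     label = y[-hold], nthread = 1L)
      dval <- xgboost::xgb.DMatrix(X[hold, , drop = FALSE],
                                   label = y[hold], nthread = 1L)
      booster <- xgboost::xgb.train(p, dtrain, nrounds = nrounds,
                                    evals = list(val = dval),
                                    early_stopping_rounds = early_stopping_rounds,
                                    verbose = 0L)
    } else {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
      booster <- xgboost::xgb.train(p, dtrain, nrounds = nrounds,
                                    verbose = 0L)
    }
    list(booster = booster, features = colnames(X))
  }
  predict <- function(fitted, X) {
    X <- as.matrix(X)
    if (!is.null(fitted$constant)) return(rep(fitted$constant, nrow(X)))
    stats::predict(fitted$booster, xgboost::xgb.DMatrix(X, nthread = 1L))
  }
  attribution <- function(fitted, X, bg_means) {
    X <- as.matrix(X)
    if (!is.null(fitted$constant)) {
      return(structure(matrix(0, nrow(X), 0), base_value = fitted$constant))
    }
    contrib <- stats::predict(fitted$booster,
                              xgboost::xgb.DMatrix(X, nthread = 1L),
                              predcontrib = TRUE)
    p <- ncol(contrib) - 1L
    structure(contrib[, seq_len(p), drop = FALSE],
              base_value = contrib[1L, p + 1L])
  }
  new_base_model("gbm", fit, predict, attribution)
}
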