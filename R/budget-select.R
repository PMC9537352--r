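# Budget-constrained subset selection: given per-feature importance phi and
# per-feature (or per-group) acquisition costs, find the subset maximizing
# total importance under a cost budget. The exact solver is a 0/1 knapsack
# dynamic program over integer-scaled costs; a greedy importance-per-cost
# heuristic and an exhaustive oracle are provided for comparison and testing.
#
# Tie-breaking everywhere: maximum total importance, then minimum realized
# cost, then earliest file order (lexicographically smallest index set).
# Selection feasibility uses effective costs (pseudocosts included); realized
# costs are always reported on the original cost scale.

new_budget_solution <- function(selected, realized_cost, total_importance,
                                budget, selector, selected_groups = NULL) {
  structure(list(selected = selected,
                 selected_groups = selected_groups,
                 realized_cost = realized_cost,
                 total_importance = total_importance,
                 budget = budget,
                 selector = selector),
            class = "budget_solution")
}

#' @export
print.budget_solution <- function(x, ...) {
  cat(sprintf("Budget solution [%s]: %d feature(s), importance %.4g, cost %.4g (budget %.4g)\n",
              x$selector, length(x$selected), x$total_importance,
              x$realized_cost, x$budget))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$selected_groups)) {
    cat("  groups:", paste(x$selected_groups, collapse = ", "), "\n")
  }
  invisible(x)
}

align_phi <- function(phi, features) {
  if (!is.null(names(phi))) {
    missing <- setdiff(features, names(phi))
    if (length(missing)) stop("no importance for feature(s): ",
                              paste(missing, collapse = ", "))
    phi <- phi[features]
  } else if (length(phi) != length(features)) {
    stop("'phi' must be named or have one entry per feature")
  }
  if (any(phi < 0)) stop("importances must be nonnegative")
  as.numeric(phi)
}

# Core DP on a value/weight/original-cost triple. Returns indices (into the
# given vectors) of the selected items. Weights must be positive or zero.
knapsack_core <- function(value, eff_cost, orig_cost, k, resolution) {
  m <- length(value)
  if (k < 0) stop("budget must be nonnegative")
  if (resolution <= 0) stop("'resolution' must be positive")
  keep_item <- value > 0            # zero-importance items can never help
  idx_map <- which(keep_item)
  v <- value[idx_map]; ec <- eff_cost[idx_map]; oc <- orig_cost[idx_map]
  if (!length(v) || k == 0 && any(ec > 0)) {
    # k == 0 admits only zero-effective-cost items
    if (k == 0) {
      free <- idx_map[ec == 0]
      return(free)
    }
    if (!length(v)) return(integer(0))
  }
  ws <- as.integer(ceiling(ec / resolution - 1e-9))
  W <- as.integer(floor(k / resolution + 1e-9))
  if (is.na(W) || W < 0) W <- 0L
  n <- length(v)
  if (as.double(n) * (as.double(W) + 1) > 5e7) {
    stop("scaled knapsack table exceeds 5e7 cells; use a coarser 'resolution'")
  }
  vtol <- 1e-9 * max(1, max(abs(v)))
  ctol <- 1e-9 * max(1, max(abs(oc)))
  dp_v <- numeric(W + 1L)
  dp_c <- numeric(W + 1L)
  keep <- matrix(FALSE, n, W + 1L)
  for (i in seq_len(n)) {
    wi <- ws[i]
    if (wi > W) next
    idx <- (wi + 1L):(W + 1L)
    cand_v <- dp_v[idx - wi] + v[i]
    cand_c <- dp_c[idx - wi] + oc[i]
    better <- cand_v > dp_v[idx] + vtol |
      (cand_v >= dp_v[idx] - vtol & cand_c < dp_c[idx] - ctol)
    if (any(better)) {
      upd <- idx[better]
      dp_v[upd] <- cand_v[better]
      dp_c[upd] <- cand_c[better]
      keep[i, upd] <- TRUE
    }
  }
  sel <- integer(0)
  w <- W
  for (i in n:1) {
    if (keep[i, w + 1L]) {
      sel <- c(i, sel)
      w <- w - ws[i]
    }
  }
  idx_map[sel]
}

# Default scaling: 1e-3 of the smallest nonzero *original* cost, so that
# tiny pseudocosts refine the ranking without blowing up the DP table.
default_resolution <- function(orig_cost, eff_cost = orig_cost) {
  nz <- orig_cost[orig_cost > 0]
  if (!length(nz)) nz <- eff_cost[eff_cost > 0]
  if (!length(nz)) return(1e-3)
  1e-3 * min(nz)
}

#' Optimal feature subset within a cost budget (0/1 knapsack)
#'
#' Maximizes total importance \eqn{\sum_{i \in S} \phi_i} subject to
#' \eqn{\sum_{i \in S} c_i \le k} by dynamic programming over integer-scaled
#' costs \eqn{\lceil c_i / \mathrm{resolution} \rceil} with capacity
#' \eqn{\lfloor k / \mathrm{resolution} \rfloor}; the solution is optimal for
#' the scaled instance (exact whenever all costs are multiples of the
#' resolution). Ties are broken by lower realized cost, then file order.
#'
#' @param phi Nonnegative importance vector, named by feature or aligned with
#'   the cost table's feature order.
#' @param costs A [cost_table()] (apply [apply_pseudocosts()] first if it
#'   contains zero-cost features and you want them ranked).
#' @param k Nonnegative cost budget.
#' @param resolution Cost-scaling resolution; default 1e-3 of the smallest
#'   nonzero original cost. The scaled solution is conservative (never over
#'   budget); it is exact whenever every cost is a multiple of the
#'   resolution.
#' @return A `budget_solution` with the selected features, realized cost
#'   (original costs), total importance and the budget.
#' @export
knapsack_select <- function(phi, costs, k, resolution = NULL) {
  stopifnot(inherits(costs, "cost_table"))
  phi <- align_phi(phi, costs$feature)
  ec <- unname(effective_costs(costs))
  if (is.null(resolution)) resolution <- default_resolution(costs$cost, ec)
  if (k >= sum(costs$cost)) {
    # unconstrained: neither pseudocosts nor cost scaling may push a useful
    # feature out of reach, so skip the DP
    if (k < 0) stop("budget must be nonnegative")
    sel <- which(phi > 0)
  } else {
    sel <- knapsack_core(phi, ec, costs$cost, min(k, sum(ec)), resolution)
  }
  feats <- costs$feature[sel]
  new_budget_solution(feats,
                      realized_cost = sum(costs$cost[sel]),
                      total_importance = sum(phi[sel]),
                      budget = k, selector = "knapsack")
}

#' Greedy importance-per-cost feature selection
#'
#' Features are ranked by \eqn{\omega_i = \phi_i / c_i} (effective costs;
#' every cost must be positive, so apply pseudocosts first when zero-cost
#' features exist) and added from the highest ratio down. By default a
#' feature that no longer fits the remaining budget is skipped and the scan
#' continues to the end of the list; with `stop_at_first_failure = TRUE` the
#' scan stops at the first feature that does not fit.
#'
#' @inheritParams knapsack_select
#' @param stop_at_first_failure Stop scanning at the first unaffordable
#'   feature instead of skipping it.
#' @return A `budget_solution`.
#' @export
greedy_select <- function(phi, costs, k, stop_at_first_failure = FALSE) {
  stopifnot(inherits(costs, "cost_table"))
  phi <- align_phi(phi, costs$feature)
  ec <- unname(effective_costs(costs))
  if (any(ec <= 0)) {
    stop("greedy ratios need positive costs; apply_pseudocosts() first")
  }
  if (k < 0) stop("budget must be nonnegative")
  omega <- phi / ec
  ord <- order(-omega, seq_along(omega))   # ties by file order
  sel <- integer(0)
  remaining <- if (k >= sum(costs$cost)) sum(ec) else k  # see knapsack_select
  for (i in ord) {
    if (ec[i] <= remaining + 1e-12) {
      sel <- c(sel, i)
      remaining <- remaining - ec[i]
    } else if (stop_at_first_failure) {
      break
    }
  }
  sel <- sort(sel)
  new_budget_solution(costs$feature[sel],
                      realized_cost = sum(costs$cost[sel]),
                      total_importance = sum(phi[sel]),
                      budget = k, selector = "greedy")
}

#' Knapsack selection over feature groups
#'
#' For grouped acquisition (lab panels, one-hot blocks) the knapsack is
#' solved over groups: each group's importance is the sum of its members'
#' importances and its cost is the single group cost. The solution reports
#' both the selected groups and the expanded feature set; the realized cost
#' is the sum of the selected group costs. Zero-cost groups receive the same
#' pseudocost treatment as zero-cost features.
#'
#' @inheritParams knapsack_select
#' @param costs A [cost_table()] with a complete group mapping and group
#'   costs.
#' @return A `budget_solution` whose `selected` is the expanded feature set
#'   and `selected_groups` the chosen group ids.
#' @export
group_knapsack_select <- function(phi, costs, k, resolution = NULL) {
  stopifnot(inherits(costs, "cost_table"))
  if (!has_groups(costs)) stop("cost table has no groups")
  phi <- align_phi(phi, costs$feature)
  gids <- unique(costs$group)              # first-appearance order
  phi_g <- vapply(gids, function(g) sum(phi[costs$group == g]), numeric(1))
  gtab <- cost_table(gids, unname(group_costs(costs)[gids]))
  if (any(gtab$cost == 0)) gtab <- apply_pseudocosts(gtab)
  inner <- knapsack_select(phi_g, gtab, k, resolution = resolution)
  sel_groups <- inner$selected
  feats <- costs$feature[costs$group %in% sel_groups]
  new_budget_solution(feats,
                      realized_cost = inner$realized_cost,
                      total_importance = sum(phi[costs$feature %in% feats]),
                      budget = k, selector = "group_knapsack",
                      selected_groups = sel_groups)
}

# TRUE if sorted index set a precedes b (element-wise; a proper prefix wins)
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0) {
    for (j in seq_len(n)) {
      if (a[j] < b[j]) return(TRUE)
      if (a[j] > b[j]) return(FALSE)
    }
  }
  length(a) < length(b)
}

#' Exhaustive-search feature selection (test oracle)
#'
#' Enumerates all \eqn{2^M} subsets and returns the guaranteed optimum under
#' the same tie-breaking as [knapsack_select()]. Exponential: refused beyond
#' 20 features.
#'
#' @inheritParams knapsack_select
#' @return A `budget_solution`.
#' @export
brute_force_select <- function(phi, costs, k) {
  stopifnot(inherits(costs, "cost_table"))
  m <- nrow(costs)
  if (m > 20L) stop("brute force is limited to 20 features")
  if (k < 0) stop("budget must be nonnegative")
  phi <- align_phi(phi, costs$feature)
  ec <- unname(effective_costs(costs))
  oc <- costs$cost
  sv <- 0; sec <- 0; soc <- 0
  for (i in seq_len(m)) {           # subset sums by doubling; bit i-1 = item i
    sv <- c(sv, sv + phi[i])
    sec <- c(sec, sec + ec[i])
    soc <- c(soc, soc + oc[i])
  }
  vtol <- 1e-9 * max(1, max(abs(sv)))
  ctol <- 1e-9 * max(1, max(abs(soc)))
  feas <- which(sec <= k + ctol)
  best_v <- max(sv[feas])
  cand <- feas[sv[feas] >= best_v - vtol]
  best_c <- min(soc[cand])
  cand <- cand[soc[cand] <= best_c + ctol]
  if (length(cand) > 1L) {
    sets <- lapply(cand - 1L, function(mask) {
      which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    })
    best <- 1L
    for (j in seq_along(sets)[-1L]) {
      if (lex_less(sets[[j]], sets[[best]])) best <- j
    }
    mask <- cand[best] - 1L
  } else {
    mask <- cand - 1L
  }
  sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
  new_budget_solution(costs$feature[sel],
                      realized_cost = sum(oc[sel]),
                      total_importance = sum(phi[sel]),
                      budget = k, selector = "brute_force")
}
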