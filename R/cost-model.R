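#' Construct a feature-cost table
#'
#' A cost table records, for every model feature, the cost of acquiring it in
#' the deployment setting (minutes of provider time, dollars, or simply a
#' count of one per feature). Features acquired together by a single action
#' (e.g. all analytes of one lab panel, or all indicator columns of one
#' categorical variable) can share a *group* with a single group-level cost.
#'
#' @param features Character vector of feature identifiers. Order matters:
#'   downstream selection breaks ties by this order.
#' @param costs Numeric vector of nonnegative acquisition costs, one per
#'   feature. `NA` marks an unknown cost (see [impute_missing_costs()]).
#' @param groups Optional character vector mapping each feature to a group id.
#'   Either every feature has a group or none does.
#' @param group_costs Optional named numeric vector of per-group costs. Must
#'   cover every group referenced in `groups`, unless
#'   `group_cost_from_members` is `TRUE`.
#' @param group_cost_from_members If `TRUE` and `group_costs` is missing, each
#'   group's cost is the maximum of its members' feature costs (grouped
#'   acquisition is one action, so member costs are never summed).
#' @return An object of class `cost_table`: a data frame with columns
#'   `feature`, `cost` and optionally `group`, carrying attributes
#'   `group_costs`, `pseudocost` (per-feature amounts, all zero until
#'   [apply_pseudocosts()] is used) and `pseudocost_applied`.
#' @seealso [load_cost_table()], [apply_pseudocosts()], [total_cost()]
#' @export
cost_table <- function(features, costs, groups = NULL, group_costs = NULL,
                       group_cost_from_members = FALSE) {
  features <- as.character(features)
  costs <- as.numeric(costs)
  if (length(features) == 0L) stop("cost table needs at least one feature")
  if (length(costs) != length(features)) {
    stop("'features' and 'costs' must have the same length")
  }
  if (anyDuplicated(features)) {
    stop("duplicate feature id(s): ",
         paste(unique(features[duplicated(features)]), collapse = ", "))
  }
  if (any(!is.na(costs) & costs < 0)) stop("negative cost(s) are not allowed")

  tab <- data.frame(feature = features, cost = costs,
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (length(groups) != length(features)) {
      stop("'groups' must have one entry per feature")
    }
    if (anyNA(groups)) stop("group column is only partially filled")
    tab$group <- groups
    gids <- unique(groups)
    if (is.null(group_costs)) {
      if (!group_cost_from_members) {
        stop("groups are present but no group costs were supplied; ",
             "pass 'group_costs' or set group_cost_from_members = TRUE")
      }
      if (anyNA(costs)) {
        stop("cannot derive group costs from members with missing feature costs")
      }
      group_costs <- vapply(gids, function(g) max(costs[groups == g]),
                            numeric(1))
      names(group_costs) <- gids
    }
    missing_groups <- setdiff(gids, names(group_costs))
    if (length(missing_groups)) {
      stop("no cost for group(s): ", paste(missing_groups, collapse = ", "))
    }
    if (any(group_costs < 0)) stop("negative group cost(s) are not allowed")
    group_costs <- group_costs[gids]
  }
  structure(tab,
            group_costs = group_costs,
            pseudocost = numeric(length(features)),
            pseudocost_applied = FALSE,
            class = c("cost_table", "data.frame"))
}

#' Read a feature-cost table from a delimited text file
#'
#' The file must have a header with columns `feature` and `cost`, and
#' optionally `group`. Blank or `NA` cost cells are kept as missing (not
#' zero); use [impute_missing_costs()] to fill them. Group costs live in a
#' separate two-column file `group,cost`.
#'
#' @param path Path to the cost file.
#' @param group_cost_path Optional path to a `group,cost` file.
#' @param sep Field separator (default comma).
#' @inheritParams cost_table
#' @return A [cost_table()] with features in file order.
#' @export
load_cost_table <- function(path, group_cost_path = NULL, sep = ",",
                            group_cost_from_members = FALSE) {
  if (!file.exists(path)) stop("cost file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("feature", "cost")
  if (!all(need %in% names(raw))) {
    stop("cost file must have columns 'feature' and 'cost'")
  }
  groups <- if ("group" %in% names(raw)) {
    g <- as.character(raw$group)
    g[!is.na(g) & g == ""] <- NA_character_
    if (all(is.na(g))) NULL else g
  }
  group_costs <- NULL
  if (!is.null(group_cost_path)) {
    gc_raw <- utils::read.table(group_cost_path, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE)
    if (!all(c("group", "cost") %in% names(gc_raw))) {
      stop("group-cost file must have columns 'group' and 'cost'")
    }
    group_costs <- stats::setNames(as.numeric(gc_raw$cost),
                                   as.character(gc_raw$group))
  }
  cost_table(raw$feature, raw$cost, groups = groups,
             group_costs = group_costs,
             group_cost_from_members = group_cost_from_members)
}

#' Mean-impute missing feature costs
#'
#' Unknown acquisition costs are replaced by the arithmetic mean of the known
#' ones; known costs are unchanged. Idempotent.
#'
#' @param table A [cost_table()].
#' @return The table with no missing costs.
#' @export
impute_missing_costs <- function(table) {
  stopifnot(inherits(table, "cost_table"))
  miss <- is.na(table$cost)
  if (all(miss)) stop("all costs are missing; nothing to impute from")
  if (any(miss)) table$cost[miss] <- mean(table$cost[!miss])
  table
}

#' Assign pseudocosts to zero-cost features
#'
#' Features free to acquire (e.g. information already present at dispatch)
#' have cost zero and therefore no defined importance-per-cost ratio. Each
#' zero-cost feature receives a pseudocost
#' \eqn{\varepsilon = g / (2(z+1))}, where \eqn{g} is the smallest absolute
#' difference between two distinct nonzero costs and \eqn{z} the number of
#' zero-cost features, so that the *sum* of all pseudocosts is strictly less
#' than the difference between any two non-zero-cost features. When fewer
#' than two distinct nonzero costs exist the gap is vacuous and \eqn{g} falls
#' back to the minimum nonzero cost. Nonzero costs are never changed, and
#' realized model costs are always reported with the original costs.
#'
#' @param table A [cost_table()] without missing costs.
#' @return The table with attribute `pseudocost` filled in and
#'   `pseudocost_applied = TRUE`. If no zero-cost feature exists the table is
#'   returned unchanged.
#' @export
apply_pseudocosts <- function(table) {
  stopifnot(inherits(table, "cost_table"))
  if (anyNA(table$cost)) stop("impute missing costs before applying pseudocosts")
  zero <- table$cost == 0
  if (!any(zero)) return(table)
  nz <- sort(unique(table$cost[!zero]))
  if (length(nz) >= 2L) {
    g <- min(diff(nz))
  } else if (length(nz) == 1L) {
    g <- nz
  } else {
    stop("all costs are zero; pseudocosts are undefined without a nonzero cost")
  }
  z <- sum(zero)
  eps <- g / (2 * (z + 1))
  pc <- numeric(nrow(table))
  pc[zero] <- eps
  attr(table, "pseudocost") <- pc
  attr(table, "pseudocost_applied") <- TRUE
  table
}

#' Uniform ("count the features") cost table
#'
#' Assigns cost 1 to every feature, so a budget of `k` simply admits at most
#' `k` features — the convention used when the burden of a model is measured
#' by how many inputs it requires rather than by time or money.
#'
#' @param feature_ids Nonempty character vector of feature identifiers.
#' @return A [cost_table()] with unit costs.
#' @export
uniform_costs <- function(feature_ids) {
  if (length(feature_ids) == 0L) stop("'feature_ids' must be nonempty")
  cost_table(feature_ids, rep(1, length(feature_ids)))
}

#' Effective (selection) costs of a cost table
#'
#' Original cost plus any pseudocost; used for ranking and budget
#' feasibility, while realized costs are reported on the original scale.
#'
#' @param table A [cost_table()].
#' @return Named numeric vector of per-feature effective costs.
#' @export
effective_costs <- function(table) {
  stopifnot(inherits(table, "cost_table"))
  stats::setNames(table$cost + attr(table, "pseudocost"), table$feature)
}

#' Group costs of a cost table
#'
#' @param table A [cost_table()].
#' @return Named numeric vector of group costs, or `NULL` when ungrouped.
#' @export
group_costs <- function(table) attr(table, "group_costs")

#' Does the table carry feature groups?
#' @param table A [cost_table()].
#' @return Logical scalar.
#' @export
has_groups <- function(table) !is.null(table$group)

#' Total acquisition cost of a feature or group subset
#'
#' For an ungrouped table, the sum of the members' costs. When the table has
#' groups and a *feature* subset is given, the cost is the sum of the costs of
#' the distinct groups touched — acquiring one member of a panel acquires the
#' panel. A subset of group ids can also be given directly with
#' `ids_are_groups = TRUE`.
#'
#' @param table A [cost_table()].
#' @param subset Character vector of feature ids (or group ids).
#' @param ids_are_groups Interpret `subset` as group ids.
#' @return Nonnegative scalar cost (original costs, pseudocosts excluded).
#' @export
total_cost <- function(table, subset, ids_are_groups = FALSE) {
  stopifnot(inherits(table, "cost_table"))
  subset <- as.character(subset)
  if (length(subset) == 0L) return(0)
  if (ids_are_groups) {
    gc <- group_costs(table)
    if (is.null(gc)) stop("table has no groups")
    unknown <- setdiff(subset, names(gc))
    if (length(unknown)) stop("unknown group id(s): ",
                              paste(unknown, collapse = ", "))
    return(sum(gc[unique(subset)]))
  }
  unknown <- setdiff(subset, table$feature)
  if (length(unknown)) stop("unknown feature id(s): ",
                            paste(unknown, collapse = ", "))
  if (has_groups(table)) {
    touched <- unique(table$group[table$feature %in% subset])
    sum(group_costs(table)[touched])
  } else {
    sum(table$cost[table$feature %in% subset])
  }
}

#' @export
print.cost_table <- function(x, ...) {
  cat("Feature cost table:", nrow(x), "features")
  if (has_groups(x)) cat(",", length(unique(x$group)), "groups")
  if (isTRUE(attr(x, "pseudocost_applied"))) cat(" (pseudocosts applied)")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}
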