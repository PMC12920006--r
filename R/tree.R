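#' Tree search configuration
#'
#' Controls the significance-filtered, positivity-constrained recursive
#' partitioning of the exposure space.
#'
#' @param d_max Maximum tree depth (number of splits along any root-to-leaf
#'   path), default 3. With up to ~10 exposures a depth of 2-3 usually
#'   exhausts the signal while keeping rules readable.
#' @param min_node Minimum observations per child node (default 10).
#' @param epsilon Positivity bound: a candidate split is discarded when any
#'   estimated split propensity falls outside `[epsilon, 1 - epsilon]`.
#'   Default 0.01; sensible values lie in [0.001, 0.05].
#' @param min_cell Minimum effective cell count: every covariate-stratum by
#'   split-arm cell must contain at least this many observations for a
#'   candidate split to be considered supported (default 5). Together with
#'   `epsilon` this implements the node-level positivity diagnostics
#'   (empirical probabilities and effective cell counts).
#' @param alpha Significance level for the split test (default 0.05).
#' @param objective `"max"` to seek the region with the highest mean
#'   outcome, `"min"` for the lowest.
#' @param exhaustive If `TRUE`, branch on every valid split and return the
#'   globally best terminal leaf instead of the greedy path.
#' @param threshold_strategy Candidate cutpoint rule: `"rounded"` (round to
#'   `decimals`, then unique values), `"unique"` (all unique observed
#'   values), or `"quantile"` (at most `q` interior quantiles).
#' @param decimals Decimals for the `"rounded"` strategy (default 1).
#' @param q Quantile count for the `"quantile"` strategy (default 20).
#' @param seed Integer seed for any stochastic component of the search.
#' @return Object of class `tree_config`.
#' @export
tree_config <- function(d_max = 3L, min_node = 10L, epsilon = 0.01,
                        min_cell = 5L,
                        alpha = 0.05, objective = c("max", "min"),
                        exhaustive = FALSE,
                        threshold_strategy = c("rounded", "unique", "quantile"),
                        decimals = 1L, q = 20L, seed = 1L) {
  objective <- match.arg(objective)
  threshold_strategy <- match.arg(threshold_strategy)
  if (d_max < 1) stop("aretree_error_config: d_max must be >= 1")
  if (min_node < 2) stop("aretree_error_config: min_node must be >= 2")
  if (!(epsilon > 0 && epsilon < 0.5)) {
    stop("aretree_error_config: epsilon must be in (0, 0.5)")
  }
  if (!(alpha > 0 && alpha < 1)) {
    stop("aretree_error_config: alpha must be in (0, 1)")
  }
  structure(list(d_max = as.integer(d_max), min_node = as.integer(min_node),
                 epsilon = epsilon, min_cell = as.integer(min_cell),
                 alpha = alpha, objective = objective,
                 exhaustive = isTRUE(exhaustive),
                 threshold_strategy = threshold_strategy,
                 decimals = as.integer(decimals), q = as.integer(q),
                 seed = as.integer(seed)),
            class = "tree_config")
}

#' Candidate cutpoints for one exposure
#'
#' Enumerates candidate split thresholds from the observed values of one
#' exposure column. The maximum observed value is always excluded (a split
#' there leaves the upper child empty under the `A <= s` convention).
#'
#' @param values Numeric exposure column.
#' @param strategy `"unique"`, `"rounded"` or `"quantile"`.
#' @param decimals Rounding digits for `"rounded"`.
#' @param q Number of interior quantiles for `"quantile"`.
#' @return Sorted numeric vector of cutpoints (possibly empty).
#' @export
enumerate_thresholds <- function(values, strategy = c("rounded", "unique",
                                                      "quantile"),
                                 decimals = 1L, q = 20L) {
  strategy <- match.arg(strategy)
  values <- values[is.finite(values)]
  if (length(values) == 0) return(numeric(0))
  if (strategy == "quantile") {
    probs <- seq_len(q) / (q + 1)
    cuts <- unique(as.numeric(stats::quantile(values, probs, names = FALSE)))
    return(sort(cuts[cuts < max(values)]))
  }
  v <- if (strategy == "rounded") round(values, decimals) else values
  u <- sort(unique(v))
  u[u < max(u)]
}

#' Positivity check for a candidate split
#'
#' Estimates the split propensity pi(W) = P(T = 1 | W) and passes when all
#' estimates lie in `[epsilon, 1 - epsilon]`. A single-class T fails
#' automatically.
#'
#' @param T_ind Binary split indicator.
#' @param W Covariate matrix.
#' @param epsilon Positivity bound.
#' @param propensity_estimator Function `(T, W) ->` probability vector;
#'   defaults to the coarse shallow-tree stratification estimator used
#'   throughout the tree search (stratum means of T over the leaves of a
#'   depth-2 regression tree of T on W).
#' @return List with `pass` (logical), `pi_min`, `pi_max`, `pi_hat`.
#' @export
check_positivity <- function(T_ind, W, epsilon,
                             propensity_estimator = NULL) {
  T_ind <- as.numeric(T_ind)
  if (length(unique(T_ind)) < 2) {
    return(list(pass = FALSE, pi_min = mean(T_ind), pi_max = mean(T_ind),
                pi_hat = rep(mean(T_ind), length(T_ind))))
  }
  if (is.null(propensity_estimator)) {
    strata <- propensity_strata(T_ind, W)
    pi_hat <- stratified_propensity(T_ind, strata)
  } else {
    pi_hat <- propensity_estimator(T_ind, W)
  }
  lo <- min(pi_hat); hi <- max(pi_hat)
  list(pass = (lo >= epsilon && hi <= 1 - epsilon),
       pi_min = lo, pi_max = hi, pi_hat = pi_hat)
}

#' Evaluate one candidate split
#'
#' For a split `T = 1{A_j <= s}` at a node, checks the minimum-node-size
#' and positivity filters, obtains targeted (TMLE-updated) mean outcomes
#' for the two children, and tests the improving child's difference from
#' the parent mean with a two-sided Wald test based on the child's
#' influence-function standard error (the parent mean is treated as a
#' fixed constant). The candidate is valid only when the child in the
#' objective direction improves on the parent and its p-value is below
#' `alpha`.
#'
#' @param A_j Numeric exposure column at the node.
#' @param W Covariate matrix at the node.
#' @param Y_scaled Scaled outcome at the node.
#' @param s Candidate cutpoint.
#' @param parent_mean Parent node mean on the *scaled* outcome scale.
#' @param config A [tree_config()].
#' @param exposure_name Name of the exposure (for reporting).
#' @param record Outcome-scaling record (for reporting in outcome units).
#' @param strata Optional precomputed covariate strata (factor) for the
#'   split-propensity estimator; when `NULL` they are derived from a
#'   depth-2 regression tree of `A_j` on `W`, which is shared by every
#'   cutpoint of the same exposure.
#' @return List of class `split_candidate`: `exposure`, `cutpoint`,
#'   `valid`, `reason`, `theta_left`, `theta_right` (scaled), `p_left`,
#'   `p_right`, `pi_min`, `pi_max`, `n_left`, `n_right`, `score` (the
#'   improving child's scaled mean, NA when invalid), `improving`
#'   (`"left"` or `"right"`).
#' @export
evaluate_split <- function(A_j, W, Y_scaled, s, parent_mean, config,
                           exposure_name = "A",
                           record = list(min = 0, range = 1),
                           strata = NULL) {
  T_ind <- as.integer(A_j <= s)
  n <- length(T_ind)
  n_left <- sum(T_ind); n_right <- n - n_left
  out <- list(exposure = exposure_name, cutpoint = s, valid = FALSE,
              reason = "", theta_left = NA_real_, theta_right = NA_real_,
              p_left = NA_real_, p_right = NA_real_,
              se_left = NA_real_, se_right = NA_real_,
              pi_min = NA_real_, pi_max = NA_real_,
              n_left = n_left, n_right = n_right,
              score = NA_real_, score_se = NA_real_, n_improving = NA_real_,
              improving = NA_character_)
  class(out) <- "split_candidate"
  if (n_left < config$min_node || n_right < config$min_node) {
    out$reason <- "min_node"
    return(out)
  }
  if (is.null(strata)) {
    strata <- propensity_strata(A_j, W, min_bucket = strata_bucket(config,
                                                                   length(A_j)))
  }
  pos <- check_positivity(T_ind, W, config$epsilon,
                          propensity_estimator = function(T_ind, W) {
                            stratified_propensity(T_ind, strata)
                          })
  out$pi_min <- pos$pi_min; out$pi_max <- pos$pi_max
  cell_counts <- table(strata, factor(T_ind, levels = c(0, 1)))
  if (!pos$pass || min(cell_counts) < config$min_cell) {
    out$reason <- "positivity"
    return(out)
  }
  g <- pmin(pmax(pos$pi_hat, config$epsilon), 1 - config$epsilon)
  Qf <- stratum_outcome(T_ind, strata, Y_scaled)
  left <- tryCatch(
    tmle_node_mean(list(Qarm = clip01(Qf$Q1), QT = clip01(Qf$QT), g = g),
                   T_ind, Y_scaled, "treated"),
    error = function(e) NULL)
  right <- tryCatch(
    tmle_node_mean(list(Qarm = clip01(Qf$Q0), QT = clip01(Qf$QT), g = g),
                   T_ind, Y_scaled, "control"),
    error = function(e) NULL)
  if (is.null(left) || is.null(right) ||
      abs(left$eps_fluct) >= 10 || abs(right$eps_fluct) >= 10) {
    # a fluctuation stuck at the solver boundary is a non-convergent,
    # untrustworthy update; treat the candidate as invalid
    out$reason <- "tmle_failure"
    return(out)
  }
  # tmle_node_mean is called with the identity record here, so theta and se
  # are both on the scaled scale; the test statistic is scale-free.
  wald_p <- function(child) {
    if (child$se <= 0) return(as.numeric(child$theta_scaled == parent_mean))
    2 * stats::pnorm(-abs((child$theta_scaled - parent_mean) / child$se))
  }
  out$theta_left <- left$theta_scaled
  out$theta_right <- right$theta_scaled
  out$se_left <- left$se
  out$se_right <- right$se
  out$p_left <- wald_p(left)
  out$p_right <- wald_p(right)
  better <- if (config$objective == "max") {
    c(left = left$theta_scaled > parent_mean,
      right = right$theta_scaled > parent_mean)
  } else {
    c(left = left$theta_scaled < parent_mean,
      right = right$theta_scaled < parent_mean)
  }
  if (!any(better)) {
    out$reason <- "no_improvement"
    return(out)
  }
  # the improving child in the objective direction carries the test
  cand <- c(left = left$theta_scaled, right = right$theta_scaled)
  cand[!better] <- NA_real_
  imp <- if (config$objective == "max") which.max(cand) else which.min(cand)
  imp_name <- names(cand)[imp]
  p_imp <- if (imp_name == "left") out$p_left else out$p_right
  if (p_imp >= config$alpha) {
    out$reason <- "not_significant"
    return(out)
  }
  out$valid <- TRUE
  out$reason <- "ok"
  out$improving <- imp_name
  out$score <- cand[[imp]]
  out$score_se <- if (imp_name == "left") left$se else right$se
  out$n_improving <- if (imp_name == "left") n_left else n_right
  out$score_z <- if (out$score_se > 0) (out$score - parent_mean) / out$score_se
                 else 0
  out
}

# Minimum stratum size for the split-propensity stratification: a stratum
# must be large enough that both split arms can plausibly meet the
# effective-cell-count floor, and strata should not shrink below ~10% of
# the node.
strata_bucket <- function(config, n_node) {
  max(config$min_node, 4L * config$min_cell, ceiling(0.1 * n_node))
}

# Evaluate all candidate splits at a node; returns list(cands, trace_rows).
node_candidates <- function(A, W, Y_scaled, parent_mean, config, record) {
  cands <- list()
  for (j in seq_len(ncol(A))) {
    cuts <- enumerate_thresholds(A[, j], config$threshold_strategy,
                                 config$decimals, config$q)
    if (!length(cuts)) next
    # covariate strata for the split propensity depend only on the
    # exposure, so they are shared by all of its cutpoints
    strata <- propensity_strata(A[, j], W,
                                min_bucket = strata_bucket(config, nrow(A)))
    for (s in cuts) {
      cands[[length(cands) + 1L]] <-
        evaluate_split(A[, j], W, Y_scaled, s, parent_mean, config,
                       exposure_name = colnames(A)[j], record = record,
                       strata = strata)
    }
  }
  cands
}

trace_from_candidates <- function(cands, depth) {
  if (!length(cands)) return(NULL)
  data.frame(
    depth = depth,
    exposure = vapply(cands, `[[`, character(1), "exposure"),
    cutpoint = vapply(cands, `[[`, numeric(1), "cutpoint"),
    n_left = vapply(cands, `[[`, numeric(1), "n_left"),
    n_right = vapply(cands, `[[`, numeric(1), "n_right"),
    theta_left = vapply(cands, `[[`, numeric(1), "theta_left"),
    theta_right = vapply(cands, `[[`, numeric(1), "theta_right"),
    p_left = vapply(cands, `[[`, numeric(1), "p_left"),
    p_right = vapply(cands, `[[`, numeric(1), "p_right"),
    pi_min = vapply(cands, `[[`, numeric(1), "pi_min"),
    pi_max = vapply(cands, `[[`, numeric(1), "pi_max"),
    valid = vapply(cands, `[[`, logical(1), "valid"),
    reason = vapply(cands, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
}

# Choose the best valid split: the most *significant* improvement over the
# parent (largest |z| of the improving child in the objective direction),
# the selection convention of test-based recursive partitioning. Flat
# dose-response plateaus make many cutpoints population-equivalent; argmax
# over raw point estimates then systematically favours small, noisy
# children, while the z criterion favours the well-supported boundary
# cutpoint (same numerator, smaller standard error) and coincides with
# argmax-by-mean when candidate children are equally precise. Exact ties
# fall to enumeration order (exposure column order, then smaller cutpoint).
pick_best <- function(cands, objective) {
  z <- vapply(cands, function(cc) {
    if (is.na(cc$score)) NA_real_ else cc$score_z
  }, numeric(1))
  ok <- which(!is.na(z))
  if (!length(ok)) return(NULL)
  best <- if (objective == "max") ok[which.max(z[ok])]
          else ok[which.min(z[ok])]
  cands[[best]]
}

#' Greedy significance-filtered tree search
#'
#' Recursively partitions the exposure space. At each node every candidate
#' split `A_j <= s` is evaluated ([evaluate_split()]); among valid splits
#' the one with the most extreme improving-child targeted mean is chosen,
#' and each child is recursed on with *its own* targeted mean as the new
#' parent mean, until `d_max` is reached or no valid split remains. The
#' root's parent mean is the sample mean of the outcome.
#'
#' @param data A [mixture_dataset()].
#' @param config A [tree_config()].
#' @return Object of class `region_tree`: a nested node structure (each
#'   node has `depth`, `region`, `node_estimate` on the outcome scale,
#'   `split` and `children` when internal) plus `trace` (a data frame with
#'   every candidate's decision and reason) and the scaling `record`.
#' @export
build_tree_greedy <- function(data, config = tree_config()) {
  stopifnot(inherits(data, "mixture_dataset"))
  sc <- scale_outcome(data$Y)
  trace_env <- new.env(parent = emptyenv())
  trace_env$rows <- list()
  root <- grow_node(data$A, data$W, sc$Y_scaled, depth = 0L,
                    parent_mean = mean(sc$Y_scaled), region = region(),
                    config = config, record = sc$record,
                    trace_env = trace_env)
  structure(list(root = root, trace = do.call(
    rbind, c(trace_env$rows, list(make.row.names = FALSE))),
    record = sc$record, config = config), class = "region_tree")
}

grow_node <- function(A, W, Y_scaled, depth, parent_mean, region, config,
                      record, trace_env, parent_se = 0) {
  node <- list(depth = depth, region = region,
               node_estimate = unscale_estimate(parent_mean, record, "mean"),
               mean_scaled = parent_mean, se_scaled = parent_se,
               split = NULL, children = NULL)
  if (depth >= config$d_max || length(Y_scaled) < 2L * config$min_node) {
    return(node)
  }
  # the split test compares each child's targeted mean against the node's
  # own sample mean: a targeted mean inherited from the parent's split can
  # carry a small adjustment offset that would manufacture spurious
  # "improvements" at deeper levels
  cands <- node_candidates(A, W, Y_scaled, mean(Y_scaled), config, record)
  tr <- trace_from_candidates(cands, depth)
  if (!is.null(tr)) trace_env$rows[[length(trace_env$rows) + 1L]] <- tr
  best <- pick_best(cands, config$objective)
  if (is.null(best)) return(node)
  j <- match(best$exposure, colnames(A))
  left_idx <- A[, j] <= best$cutpoint
  rule_le <- threshold_rule(best$exposure, "LE", best$cutpoint)
  rule_gt <- threshold_rule(best$exposure, "GT", best$cutpoint)
  node$split <- best
  node$children <- list(
    left = grow_node(A[left_idx, , drop = FALSE], W[left_idx, , drop = FALSE],
                     Y_scaled[left_idx], depth + 1L, best$theta_left,
                     region_add_rule(region, rule_le), config, record,
                     trace_env, parent_se = best$se_left),
    right = grow_node(A[!left_idx, , drop = FALSE], W[!left_idx, , drop = FALSE],
                      Y_scaled[!left_idx], depth + 1L, best$theta_right,
                      region_add_rule(region, rule_gt), config, record,
                      trace_env, parent_se = best$se_right))
  node
}

collect_leaves <- function(node) {
  if (is.null(node$children)) return(list(node))
  c(collect_leaves(node$children$left), collect_leaves(node$children$right))
}

#' Extract the extremal-leaf region from a built tree
#'
#' Walks the tree to the leaf whose targeted mean deviates most
#' significantly from the overall mean in the objective direction (the
#' same standardized-deviation convention used to select splits) and
#' returns the (normalized) conjunction of rules along that path. A
#' single-leaf tree yields the full-space region, flagged as no region
#' found.
#'
#' @param tree A `region_tree` from [build_tree_greedy()].
#' @param objective `"max"` or `"min"`; defaults to the tree's own.
#' @return List with `region`, `estimate` (outcome units) and `found`
#'   (FALSE when the tree never split).
#' @export
extract_region <- function(tree, objective = NULL) {
  stopifnot(inherits(tree, "region_tree"))
  if (is.null(objective)) objective <- tree$config$objective
  leaves <- collect_leaves(tree$root)
  est <- vapply(leaves, `[[`, numeric(1), "node_estimate")
  best <- if (objective == "max") which.max(est) else which.min(est)
  leaf <- leaves[[best]]
  list(region = normalize_region(leaf$region), estimate = leaf$node_estimate,
       found = !is_full_space(leaf$region))
}

#' Exhaustive search over all valid split branches
#'
#' Branches on *every* candidate split that passes the size, positivity
#' and significance filters, recurses each branch to `d_max`, collects
#' every terminal leaf and returns the one with the most extreme targeted
#' mean. Guaranteed to find the globally best leaf in the admissible
#' family up to `d_max`, at exponential cost in depth and cutpoint count.
#'
#' @param data A [mixture_dataset()].
#' @param config A [tree_config()]; `exhaustive` is implied.
#' @return List with `region`, `estimate` (outcome units), `found`, and
#'   `n_leaves` (number of terminal leaves examined).
#' @export
search_exhaustive <- function(data, config = tree_config(exhaustive = TRUE)) {
  stopifnot(inherits(data, "mixture_dataset"))
  sc <- scale_outcome(data$Y)
  leaves <- exhaustive_branch(data$A, data$W, sc$Y_scaled, depth = 0L,
                              parent_mean = mean(sc$Y_scaled),
                              region = region(), config = config,
                              record = sc$record)
  # rank terminal leaves by the same significance convention the greedy
  # search applies to candidate splits: the standardized deviation of the
  # leaf's targeted mean from its parent node's sample mean
  z <- vapply(leaves, `[[`, numeric(1), "z_sel")
  best <- if (config$objective == "max") which.max(z) else which.min(z)
  leaf <- leaves[[best]]
  list(region = leaf$region, estimate = leaf$estimate,
       found = !is_full_space(leaf$region), n_leaves = length(leaves))
}

exhaustive_branch <- function(A, W, Y_scaled, depth, parent_mean, region,
                              config, record, parent_se = 0, z_entry = 0) {
  self_leaf <- list(list(region = normalize_region(region),
                         estimate = unscale_estimate(parent_mean, record,
                                                     "mean"),
                         estimate_scaled = parent_mean,
                         se = parent_se, n = length(Y_scaled),
                         z_sel = z_entry))
  if (depth >= config$d_max || length(Y_scaled) < 2L * config$min_node) {
    return(self_leaf)
  }
  raw_mean <- mean(Y_scaled)
  cands <- node_candidates(A, W, Y_scaled, raw_mean, config, record)
  valid <- Filter(function(cc) cc$valid, cands)
  if (!length(valid)) return(self_leaf)
  out <- list()
  for (cc in valid) {
    j <- match(cc$exposure, colnames(A))
    left_idx <- A[, j] <= cc$cutpoint
    zL <- if (cc$se_left > 0) (cc$theta_left - raw_mean) / cc$se_left else 0
    zR <- if (cc$se_right > 0) (cc$theta_right - raw_mean) / cc$se_right else 0
    # branch on the split; both children stay in the terminal-leaf pool
    out <- c(out,
      exhaustive_branch(A[left_idx, , drop = FALSE],
                        W[left_idx, , drop = FALSE], Y_scaled[left_idx],
                        depth + 1L, cc$theta_left,
                        region_add_rule(region,
                          threshold_rule(cc$exposure, "LE", cc$cutpoint)),
                        config, record, parent_se = cc$se_left, z_entry = zL),
      exhaustive_branch(A[!left_idx, , drop = FALSE],
                        W[!left_idx, , drop = FALSE], Y_scaled[!left_idx],
                        depth + 1L, cc$theta_right,
                        region_add_rule(region,
                          threshold_rule(cc$exposure, "GT", cc$cutpoint)),
                        config, record, parent_se = cc$se_right, z_entry = zR))
  }
  out
}

#' @export
print.region_tree <- function(x, ...) {
  ex <- extract_region(x)
  cat("significance-filtered region tree\n")
  cat("  objective:", x$config$objective, " d_max:", x$config$d_max, "\n")
  cat("  extremal leaf:", format(ex$region), "\n")
  cat(sprintf("  leaf estimate: %.4g\n", ex$estimate))
  invisible(x)
}
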